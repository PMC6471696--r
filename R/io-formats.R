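#' Sequence sets
#'
#' A sequence set is a tibble with columns `id` (unique character) and `seq`
#' (uppercase DNA over the alphabet A, C, G, T, N). All sequence-consuming
#' functions in the package accept this shape, so sets read from FASTA and
#' sets produced by the synthetic generators are interchangeable.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of DNA strings (same length as `id`).
#' @return A tibble of class `seq_set` with columns `id` and `seq`.
#' @export
seq_set <- function(id, seq) {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id)) || anyNA(id)) abort("Sequence ids must be non-empty.")
  if (anyDuplicated(id)) {
    abort(paste0("Duplicate sequence id: ", id[duplicated(id)][1]))
  }
  if (any(!nzchar(seq))) abort("Sequences must be non-empty.")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    n_bad <- sum(lengths(regmatches(seq, gregexpr("[^ACGTN]", seq))))
    warn(sprintf("%d non-ACGT characters mapped to N.", n_bad))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  out <- tibble(id = id, seq = seq)
  class(out) <- c("seq_set", class(out))
  out
}

#' Read a FASTA file into a sequence set
#'
#' Lowercase residues are mapped to uppercase; characters outside
#' \{A,C,G,T,N\} are mapped to N with a warning giving the count.
#'
#' @param path Path to a FASTA file.
#' @return A [seq_set] tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) abort("FASTA record with empty id.")
  seq_set(ids, as.character(x))
}

#' Write a sequence set to FASTA
#'
#' @param seqs A [seq_set] (or any data frame with `id` and `seq` columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- PWM collections ------------------------------------------------------

#' Read a PWM collection
#'
#' Supports two common dialects of position frequency matrix files:
#' JASPAR-style records (`>ID name` header followed by four base rows,
#' optionally in `A [ 1 2 3 ]` form) and TRANSFAC-style flat files
#' (records with `ID`/`P0` header lines, numbered position rows `01..L`,
#' and `//` terminators). Count matrices are converted to scoring matrices
#' with [build_pwm()].
#'
#' @param path Path to the matrix file.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param pseudocount Pseudocount added to every cell (default 0.25).
#' @return A named list of [build_pwm()] objects.
#' @export
read_pwms <- function(path, dialect = c("jaspar", "transfac"),
                      pseudocount = 0.25) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  recs <- switch(dialect,
    jaspar = parse_jaspar(lines),
    transfac = parse_transfac(lines)
  )
  pwms <- lapply(names(recs), function(id) {
    counts <- recs[[id]]
    check_counts(counts, id)
    build_pwm(counts, id = id, pseudocount = pseudocount)
  })
  setNames(pwms, names(recs))
}

check_counts <- function(counts, id) {
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "Negative count in matrix '%s' at position %d, base %s.",
      id, neg[1, 1], c("A", "C", "G", "T")[neg[1, 2]]
    ))
  }
}

parse_jaspar <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("No JASPAR records ('>' headers) found.")
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) {
      abort(sprintf("JASPAR record '%s': expected 4 base rows, got %d.",
                    id, length(body)))
    }
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) abort(sprintf("Non-numeric count in record '%s'.", id))
      v
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("JASPAR record '%s': base rows have unequal lengths.", id))
    }
    # rows are A, C, G, T across positions; transpose to L x 4
    counts <- t(do.call(rbind, rows))
    colnames(counts) <- c("A", "C", "G", "T")
    recs[[id]] <- counts
  }
  recs
}

parse_transfac <- function(lines) {
  lines <- trimws(lines)
  recs <- list()
  cur_id <- NULL
  cur_rows <- list()
  col_order <- c("A", "C", "G", "T")
  flush <- function() {
    if (!is.null(cur_id)) {
      if (length(cur_rows) == 0) {
        abort(sprintf("TRANSFAC record '%s' has no position rows.", cur_id))
      }
      counts <- do.call(rbind, cur_rows)
      colnames(counts) <- c("A", "C", "G", "T")
      recs[[cur_id]] <<- counts
    }
  }
  for (l in lines) {
    if (grepl("^ID\\s+", l)) {
      flush()
      cur_id <- sub("^ID\\s+", "", l)
      cur_rows <- list()
      col_order <- c("A", "C", "G", "T")
    } else if (grepl("^P0\\s+", l) || grepl("^PO\\s+", l)) {
      col_order <- strsplit(sub("^P[0O]\\s+", "", l), "\\s+")[[1]]
      if (!setequal(col_order, c("A", "C", "G", "T"))) {
        abort("TRANSFAC P0 header must name bases A, C, G, T.")
      }
    } else if (grepl("^\\d\\d\\s+", l)) {
      fields <- strsplit(l, "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(fields[2:5]))
      if (anyNA(v)) {
        abort(sprintf("Non-numeric count at position row '%s'.", fields[1]))
      }
      v <- v[match(c("A", "C", "G", "T"), col_order)]
      cur_rows[[length(cur_rows) + 1L]] <- v
    } else if (identical(l, "//")) {
      flush()
      cur_id <- NULL
      cur_rows <- list()
    }
  }
  flush()
  if (length(recs) == 0) abort("No TRANSFAC records found.")
  recs
}

# ---- Signalling networks --------------------------------------------------

#' Construct a signalling graph
#'
#' A weighted, signed, directed reaction network. Edge costs must be
#' strictly positive; signs are +1 (activation) or -1 (inhibition). Nodes
#' may carry a `kind` (protein, complex, gene, TF) and a `gene` mapping
#' (the gene encoding the node's product) used for feedback-loop closure.
#'
#' @param edges Data frame with columns `from`, `to`, `sign`, `cost` and
#'   optionally `regulatory` (logical; TRUE for TF-to-gene regulatory edges).
#' @param nodes Optional data frame with columns `id` and optionally
#'   `kind`, `gene`. Missing nodes are added from edge endpoints.
#' @return An object of class `signaling_graph` (list with tibbles `edges`
#'   and `nodes`).
#' @export
signaling_graph <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "sign", "cost") %in% names(edges)))
  if (!"regulatory" %in% names(edges)) edges$regulatory <- FALSE
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(-1L, 1L))) {
    abort("Edge signs must be +1 or -1.")
  }
  if (any(!is.finite(edges$cost)) || any(edges$cost <= 0)) {
    abort("Edge costs must be strictly positive.")
  }
  ids <- union(edges$from, edges$to)
  if (is.null(nodes)) {
    nodes <- tibble(id = ids, kind = "protein", gene = NA_character_)
  } else {
    nodes <- as_tibble(nodes)
    if (!"kind" %in% names(nodes)) nodes$kind <- "protein"
    if (!"gene" %in% names(nodes)) nodes$gene <- NA_character_
    missing <- setdiff(ids, nodes$id)
    if (length(missing) > 0) {
      nodes <- dplyr::bind_rows(
        nodes, tibble(id = missing, kind = "protein", gene = NA_character_)
      )
    }
  }
  structure(list(edges = edges, nodes = nodes), class = "signaling_graph")
}

#' @export
print.signaling_graph <- function(x, ...) {
  cat(sprintf("<signaling_graph: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a signalling network edge list
#'
#' Tab-separated lines `source<TAB>sign<TAB>target[<TAB>cost]`. Signs may
#' be written `+1`/`-1` or `+`/`-`; the cost defaults to 1 when absent and
#' must be strictly positive. When the same source/target pair appears more
#' than once the last line wins and a warning reports the count.
#'
#' @param path Path to the edge-list file.
#' @return A [signaling_graph].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  raw <- raw[!grepl("^#", raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    abort(sprintf("Malformed edge line %d: need source, sign, target.",
                  which(n_fields < 3)[1]))
  }
  sign_txt <- vapply(parts, `[`, "", 2L)
  sign <- dplyr::case_match(sign_txt, c("+", "+1", "1") ~ 1L,
                            c("-", "-1") ~ -1L, .default = NA_integer_)
  if (anyNA(sign)) {
    abort(sprintf("Malformed sign '%s' on line %d.",
                  sign_txt[is.na(sign)][1], which(is.na(sign))[1]))
  }
  cost <- vapply(seq_along(parts), function(i) {
    if (n_fields[i] >= 4) as.numeric(parts[[i]][4]) else 1.0
  }, 0.0)
  if (anyNA(cost) || any(cost <= 0)) {
    abort(sprintf("Edge cost must be a positive number (line %d).",
                  which(is.na(cost) | cost <= 0)[1]))
  }
  edges <- tibble(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 3L),
    sign = sign, cost = cost
  )
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) {
    warn(sprintf("%d duplicate edges; keeping the last occurrence of each.",
                 sum(duplicated(key))))
    edges <- edges[!duplicated(key, fromLast = TRUE), ]
  }
  signaling_graph(edges)
}

#' Write a signalling graph as an edge list
#'
#' @param graph A [signaling_graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path) {
  e <- graph$edges
  lines <- sprintf("%s\t%+d\t%s\t%s", e$from, e$sign, e$to,
                   format_num(e$cost))
  writeLines(lines, path)
  invisible(path)
}

# ---- Sample matrices ------------------------------------------------------

#' Construct a sample matrix
#'
#' A numeric features-by-samples matrix tagged with a value kind. Beta-value
#' matrices must lie in \[0, 1\].
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param kind `"expression"` or `"beta"`.
#' @return The matrix with class `sample_matrix` and attribute `kind`.
#' @export
sample_matrix <- function(x, kind = c("expression", "beta")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("A sample matrix needs feature rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(x))) abort("Duplicate feature ids.")
  if (anyDuplicated(colnames(x))) abort("Duplicate sample ids.")
  if (!is.numeric(x) || anyNA(x)) abort("Values must be numeric and non-missing.")
  if (kind == "beta" && (any(x < 0) || any(x > 1))) {
    abort("Beta values must lie in [0, 1].")
  }
  structure(x, kind = kind, class = c("sample_matrix", class(x)))
}

#' Read a TSV sample matrix
#'
#' First column holds feature ids, header row holds sample ids.
#'
#' @inheritParams sample_matrix
#' @param path Path to the TSV file.
#' @return A [sample_matrix].
#' @export
read_matrix_tsv <- function(path, kind = c("expression", "beta")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) abort("Matrix file needs at least one sample column.")
  feats <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(feats, names(df)[-1]))
  if (anyNA(vals)) abort("Non-numeric cell in matrix file.")
  sample_matrix(vals, kind = kind)
}

format_num <- function(x) {
  trimws(formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a sample matrix (or data frame) as TSV
#'
#' Numeric values are written with 6 significant digits so that files
#' round-trip at text-level equality.
#'
#' @param x A matrix with dimnames, or a data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(feature = rownames(x),
                     apply(x, 2, format_num),
                     check.names = FALSE)
  } else {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], format_num)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- BED intervals --------------------------------------------------------

#' Read a BED4 interval file
#'
#' Intervals use the BED-native 0-based half-open convention, which is the
#' single coordinate convention of the whole package.
#'
#' @param path Path to a BED file (3 or 4 columns).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 3) abort("BED file needs at least 3 columns.")
  out <- tibble(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4) df[[4]] else NA_character_
  )
  if (anyNA(out$start) || anyNA(out$end)) abort("Non-integer BED coordinate.")
  if (any(out$start < 0) || any(out$start >= out$end)) {
    abort("BED intervals require 0 <= start < end.")
  }
  out
}

#' Write intervals as BED4
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  nm[is.na(nm)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start), as.integer(intervals$end), nm)
  writeLines(lines, path)
  invisible(path)
}
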