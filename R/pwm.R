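#' Build a position weight matrix
#'
#' Converts an L-by-4 count matrix into a Match-style scoring object.
#' Frequencies are `(count + pseudocount) / (rowsum + 4 * pseudocount)`,
#' the per-position information vector is `I(i) = sum_b f(i,b) ln(4 f(i,b))`
#' (with `0 ln 0 := 0`), and raw window scores `sum_i I(i) f(i, base_i)` are
#' min-max normalised to \[0, 1\] using the attainable score bounds, the
#' TRANSFAC "matrix similarity score" convention.
#'
#' @param counts Numeric L-by-4 matrix of base counts (columns A, C, G, T).
#' @param id Matrix identifier.
#' @param pseudocount Non-negative pseudocount per cell (default 0.25, which
#'   avoids degenerate zero frequencies on sparse count matrices).
#' @return An object of class `pwm`.
#' @export
build_pwm <- function(counts, id = "pwm", pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) abort("`counts` must have 4 columns (A, C, G, T).")
  if (nrow(counts) < 1) abort("`counts` must have at least one position.")
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0)) {
    abort("All-zero count row requires a positive pseudocount.")
  }
  freq <- (counts + pseudocount) / (rs + 4 * pseudocount)
  colnames(freq) <- c("A", "C", "G", "T")
  # information content per position, natural log; 0*log(0) treated as 0
  plogp <- freq * log(4 * freq)
  plogp[freq == 0] <- 0
  info <- rowSums(plogp)
  weights <- info * freq # L x 4 raw score contributions
  min_raw <- sum(apply(weights, 1, min))
  max_raw <- sum(apply(weights, 1, max))
  # reverse-complement weights: position order reversed, A<->T, C<->G
  w_rc <- weights[rev(seq_len(nrow(weights))), c(4, 3, 2, 1), drop = FALSE]
  colnames(w_rc) <- c("A", "C", "G", "T")
  consensus <- paste(c("A", "C", "G", "T")[apply(freq, 1, which.max)],
                     collapse = "")
  structure(
    list(id = id, length = nrow(counts), counts = counts, freq = freq,
         info = info, weights = weights, weights_rc = w_rc,
         min_raw = min_raw, max_raw = max_raw,
         pseudocount = pseudocount, consensus = consensus),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: length %d, consensus %s>\n",
              x$id, x$length, x$consensus))
  invisible(x)
}

#' Encode a DNA string as integers
#'
#' A, C, G, T map to 0..3; anything else to -1 (treated as N).
#'
#' @param seq A single DNA string.
#' @return Integer vector.
#' @keywords internal
encode_dna <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  as.integer(m - 1L)
}

#' Score a single word against a PWM
#'
#' Returns the min-max normalised information-weighted score in \[0, 1\];
#' the consensus word of a non-degenerate matrix scores exactly 1, the
#' per-position worst word exactly 0. Words containing N score 0.
#'
#' @param pwm A [build_pwm()] object.
#' @param word A string of length `pwm$length`.
#' @return Score in \[0, 1\].
#' @export
match_score <- function(pwm, word) {
  enc <- encode_dna(word)
  if (length(enc) != pwm$length) {
    abort(sprintf("Word length %d does not match PWM length %d.",
                  length(enc), pwm$length))
  }
  rng <- pwm$max_raw - pwm$min_raw
  if (!(rng > 0)) return(0)
  if (any(enc < 0)) return(0)
  raw <- sum(pwm$weights[cbind(seq_len(pwm$length), enc + 1L)])
  (raw - pwm$min_raw) / rng
}

#' Scan sequences for PWM matches
#'
#' Slides the matrix over every window of every sequence (both strands by
#' default; minus-strand hits are reported at their forward-strand window
#' start) and returns all windows scoring at least `cutoff`. Windows
#' containing N score 0. Sequences shorter than the matrix produce no rows
#' and a warning.
#'
#' @param pwm A [build_pwm()] object, or a list of them.
#' @param seqs A [seq_set] tibble (columns `id`, `seq`).
#' @param cutoff Minimum normalised score in \[0, 1\].
#' @param both_strands Scan the reverse strand too? Default TRUE.
#' @return Tibble with columns `pwm_id`, `seq_id`, `start` (0-based),
#'   `strand` (`"+"`/`"-"`), `score`, sorted by sequence, position, strand.
#' @export
scan_pwm <- function(pwm, seqs, cutoff = 0.8, both_strands = TRUE) {
  if (inherits(pwm, "pwm")) pwm <- list(pwm)
  if (cutoff < 0 || cutoff > 1) abort("`cutoff` must be in [0, 1].")
  enc <- lapply(seqs$seq, encode_dna)
  lens <- lengths(enc)
  res <- purrr::map(pwm, function(p) {
    if (any(lens < p$length)) {
      warn(sprintf("%d sequence(s) shorter than PWM '%s'; no matches there.",
                   sum(lens < p$length), p$id))
    }
    d <- .cpp_scan_pwm_set(enc, p$weights, p$weights_rc, p$min_raw,
                           p$max_raw, cutoff, both_strands)
    if (length(d$start) == 0) return(NULL)
    tibble(pwm_id = p$id, seq_id = seqs$id[d$seq_idx], start = d$start,
           strand = c("+", "-")[d$strand + 1L], score = d$score)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(pwm_id = character(), seq_id = character(),
                  start = integer(), strand = character(),
                  score = numeric()))
  }
  dplyr::arrange(out, .data$pwm_id, .data$seq_id, .data$start,
                 dplyr::desc(.data$strand == "+"))
}

#' Keep the top-scoring matches
#'
#' Retains the `kappa` highest-scoring matches (per PWM and sequence when
#' the table covers several); ties broken by smaller start, then `+` strand.
#'
#' @param matches A match tibble from [scan_pwm()].
#' @param kappa Positive integer, number of matches to keep.
#' @return Filtered match tibble.
#' @export
top_matches <- function(matches, kappa) {
  if (kappa < 1) abort("`kappa` must be >= 1.")
  matches |>
    dplyr::group_by(.data$pwm_id, .data$seq_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$start,
                   dplyr::desc(.data$strand == "+"), .by_group = TRUE) |>
    dplyr::slice_head(n = kappa) |>
    dplyr::ungroup()
}

#' Reverse-complement DNA strings
#'
#' @param seq Character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
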