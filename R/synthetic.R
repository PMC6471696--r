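#' Generate background DNA sequences
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2`; fully determined by the seed.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc GC fraction in (0, 1) (default 0.5).
#' @param seed RNG seed.
#' @param prefix Id prefix (default "seq").
#' @return A [seq_set] tibble.
#' @export
sim_background <- function(n, length, gc = 0.5, seed = 1, prefix = "seq") {
  if (gc <= 0 || gc >= 1) abort("`gc` must be in (0, 1).")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  }, "")
  seq_set(sprintf("%s_%03d", prefix, seq_len(n)), seqs)
}

#' Plant a composite module into a fraction of sequences
#'
#' In a random subset of `ceiling(fraction * n)` sequences, writes the
#' consensus word of every PWM at a position drawn within a window of
#' width `2 * sigma` around a random centre, emulating a clustered
#' composite module. Planting is by consensus words (not sampled words)
#' so recovery targets are unambiguous.
#'
#' @param seqs A [seq_set].
#' @param pwms List of [build_pwm()] objects to plant.
#' @param sigma Half-width (bp) of the placement window (default 10).
#' @param fraction Fraction of sequences receiving the module.
#' @param seed RNG seed.
#' @param center Optional fixed module centre (0-based position); by
#'   default the centre is drawn uniformly within the feasible range.
#' @return List with `seqs` (modified set), `truth` (tibble `seq_id`,
#'   `pwm_id`, `start`) and `labels` (tibble `seq_id`, `present`).
#' @export
sim_planted_module <- function(seqs, pwms, sigma = 10, fraction = 0.5,
                               seed = 1, center = NULL) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  set.seed(seed)
  n <- nrow(seqs)
  lens <- nchar(seqs$seq)
  widths <- vapply(pwms, `[[`, 0L, "length")
  if (min(lens) < max(widths) + 2 * sigma) {
    abort("Sequences too short for the requested motifs and window.")
  }
  n_plant <- ceiling(fraction * n)
  planted_idx <- if (n_plant > 0) sort(sample.int(n, n_plant)) else integer(0)
  out <- seqs$seq
  truth <- list()
  for (i in planted_idx) {
    l <- lens[i]
    margin <- max(widths) + sigma
    ctr <- center %||% sample(seq(margin, l - margin), 1)
    taken <- matrix(numeric(0), ncol = 2) # occupied [start, end) spans
    for (p in pwms) {
      # rejection-sample a position that keeps planted words disjoint
      for (attempt in 1:200) {
        start <- ctr + sample(seq(-sigma, sigma), 1)
        end <- start + p$length
        ok <- start >= 0 && end <= l &&
          (nrow(taken) == 0 ||
             all(end <= taken[, 1] | start >= taken[, 2]))
        if (ok) break
      }
      if (!ok) abort("Could not place motifs without overlap; increase sigma.")
      taken <- rbind(taken, c(start, end))
      substr(out[i], start + 1, end) <- p$consensus
      truth[[length(truth) + 1L]] <- tibble(
        seq_id = seqs$id[i], pwm_id = p$id, start = start
      )
    }
  }
  list(
    seqs = seq_set(seqs$id, out),
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble(seq_id = character(), pwm_id = character(), start = integer()),
    labels = tibble(seq_id = seqs$id,
                    present = seq_len(n) %in% planted_idx)
  )
}

#' Generate trait values coupled to module presence
#'
#' `value = effect * present + N(0, noise_sd)`, optionally clipped to
#' \[0, 1\] when emulating beta-values.
#'
#' @param labels Tibble `seq_id`, `present` (from [sim_planted_module()]).
#' @param effect Additive effect of module presence.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param clip Clip to \[0, 1\]? Default FALSE.
#' @return Tibble `seq_id`, `value`, `present`.
#' @export
sim_trait_values <- function(labels, effect = 0.6, noise_sd = 0.2,
                             seed = 1, clip = FALSE) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  set.seed(seed)
  v <- effect * labels$present + rnorm(nrow(labels), 0, noise_sd)
  if (clip) v <- pmin(pmax(v, 0), 1)
  tibble(seq_id = labels$seq_id, value = v, present = labels$present)
}

#' Generate a toy signalling network with a planted master regulator
#'
#' Builds a random sparse decoy network over `n_nodes` nodes plus a set
#' of input TF nodes. Decoys are organised into zones of two inputs each
#' (decoy-to-decoy edges stay within a zone), so no decoy can reach more
#' than two inputs however it chains, while the planted regulator reaches
#' every input directly at low cost. When `feedback`, a positive
#' regulatory loop is closed through the regulator's own gene
#' (input TF -> gene -> regulator) and an off-loop twin with the same
#' wiring to the inputs but slightly cheaper edges is added: without
#' context weighting the twin outranks the regulator, with context on the
#' loop nodes the ranking flips — the walking-pathways signature.
#'
#' @param n_nodes Number of decoy nodes (>= n_inputs + 2).
#' @param planted Plant a true master regulator? Default TRUE.
#' @param feedback Close a positive feedback loop through the regulator's
#'   gene and add the off-loop twin? Default FALSE.
#' @param n_inputs Number of input TF nodes (default 5).
#' @param seed RNG seed.
#' @param input_ids Optional ids for the input TF nodes (length
#'   `n_inputs`); defaults to `TF01`, `TF02`, ...
#' @return List with `graph` ([signaling_graph]) and `truth` (list:
#'   `regulator`, `twin`, `inputs`, `loop_nodes`, `gene_of`).
#' @export
sim_network <- function(n_nodes = 50, planted = TRUE, feedback = FALSE,
                        n_inputs = 5, seed = 1, input_ids = NULL) {
  if (n_nodes < n_inputs + 2) abort("`n_nodes` must be >= n_inputs + 2.")
  set.seed(seed)
  inputs <- input_ids %||% sprintf("TF%02d", seq_len(n_inputs))
  stopifnot(length(inputs) == n_inputs)
  decoys <- sprintf("N%03d", seq_len(n_nodes))
  n_zones <- max(1L, n_inputs %/% 2L)
  zone_of_input <- pmin((seq_len(n_inputs) + 1L) %/% 2L, n_zones)
  zone <- sample.int(n_zones, n_nodes, replace = TRUE)
  edges <- list()
  add_edge <- function(from, to, cost = NULL, sign = 1L, regulatory = FALSE) {
    edges[[length(edges) + 1L]] <<- tibble(
      from = from, to = to, sign = sign,
      cost = cost %||% runif(1, 0.8, 2), regulatory = regulatory
    )
  }
  for (i in seq_along(decoys)) {
    peers <- which(zone == zone[i])
    peers <- peers[peers > i]
    n_out <- sample(0:2, 1)
    if (length(peers) > 0 && n_out > 0) {
      for (t in sample(decoys[peers], min(n_out, length(peers)))) {
        add_edge(decoys[i], t)
      }
    }
    zone_inputs <- inputs[zone_of_input == zone[i]]
    n_in <- sample(0:length(zone_inputs), 1)
    if (n_in > 0) {
      for (t in sample(zone_inputs, n_in)) add_edge(decoys[i], t)
    }
  }
  truth <- list(regulator = NA_character_, twin = NA_character_,
                inputs = inputs, loop_nodes = character(),
                gene_of = character())
  nodes <- tibble(id = c(decoys, inputs),
                  kind = c(rep("protein", length(decoys)),
                           rep("TF", length(inputs))),
                  gene = NA_character_)
  if (planted) {
    reg <- "REG"
    for (t in inputs) add_edge(reg, t, cost = 0.6)
    nodes <- dplyr::bind_rows(nodes, tibble(
      id = reg, kind = "protein", gene = "gene_REG"
    ))
    truth$regulator <- reg
    truth$gene_of <- c(REG = "gene_REG")
    if (feedback) {
      twin <- "TWIN"
      gene <- "gene_REG"
      for (t in inputs) add_edge(twin, t, cost = 0.55)
      add_edge(inputs[1], gene, cost = 1, sign = 1L, regulatory = TRUE)
      add_edge(gene, reg, cost = 1, sign = 1L)
      nodes <- dplyr::bind_rows(nodes, tibble(
        id = c(twin, gene), kind = c("protein", "gene"),
        gene = NA_character_
      ))
      truth$twin <- twin
      truth$loop_nodes <- c(reg, inputs[1], gene)
    }
  }
  g <- signaling_graph(dplyr::bind_rows(edges), nodes)
  list(graph = g, truth = truth)
}

#' Generate a two-class beta-value cohort
#'
#' Control betas are drawn from a clipped normal around `base`; case
#' betas are shifted upward per marker by `effects` (hypermethylation).
#'
#' @param n_case,n_control Samples per class (defaults 12 and 12).
#' @param n_markers Number of CpG markers (default 6).
#' @param effects Per-marker beta shift in cases (scalar or vector).
#' @param noise_sd Gaussian noise sd (default 0.05).
#' @param base Control mean beta (default 0.1).
#' @param seed RNG seed.
#' @return List with `beta` (a beta [sample_matrix], markers x samples)
#'   and `labels` (tibble `sample`, `class` in \{"case", "control"\}).
#' @export
sim_cohort <- function(n_case = 12, n_control = 12, n_markers = 6,
                       effects = 0.5, noise_sd = 0.05, base = 0.1,
                       seed = 1) {
  set.seed(seed)
  effects <- rep_len(effects, n_markers)
  n <- n_case + n_control
  cls <- c(rep("case", n_case), rep("control", n_control))
  shift <- outer(effects, as.numeric(cls == "case"))
  m <- base + shift + matrix(rnorm(n_markers * n, 0, noise_sd),
                             n_markers, n)
  m <- pmin(pmax(m, 0), 1 - 1e-6)
  rownames(m) <- sprintf("cg%06d", seq_len(n_markers))
  colnames(m) <- sprintf("s%02d_%s", seq_len(n), substr(cls, 1, 2))
  list(beta = sample_matrix(m, kind = "beta"),
       labels = tibble(sample = colnames(m), class = cls))
}
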