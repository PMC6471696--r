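#' Binomial site-overrepresentation p-value
#'
#' Upper-tail binomial test of the number of predicted sites in the Yes
#' set against the site rate observed in the No set: `P(X >= yes_sites)`
#' with `X ~ Binomial(yes_positions, rate_no)`. When the No set has no
#' sites a continuity-corrected rate `(no_sites + 1) / (no_positions + 2)`
#' is used.
#'
#' @param yes_sites,no_sites Site counts in each set.
#' @param yes_positions,no_positions Scanned window counts in each set.
#' @return p-value in \[0, 1\].
#' @export
site_overrep_pvalue <- function(yes_sites, yes_positions,
                                no_sites, no_positions) {
  if (any(yes_positions <= 0)) abort("`yes_positions` must be positive.")
  if (any(no_positions <= 0)) abort("`no_positions` must be positive.")
  if (any(yes_sites < 0) || any(no_sites < 0)) abort("Counts must be >= 0.")
  if (any(yes_sites > yes_positions) || any(no_sites > no_positions)) {
    abort("Site counts cannot exceed position counts.")
  }
  rate <- ifelse(no_sites == 0,
                 (no_sites + 1) / (no_positions + 2),
                 no_sites / no_positions)
  pbinom(yes_sites - 1, yes_positions, rate, lower.tail = FALSE)
}

#' Fisher sequence-overrepresentation p-value
#'
#' One-sided Fisher exact test (enrichment direction) on the 2x2 table of
#' sequences with / without at least one site in the Yes and No sets,
#' computed from the hypergeometric tail.
#'
#' @param yes_hits,no_hits Numbers of sequences with at least one site.
#' @param yes_total,no_total Set sizes.
#' @return p-value in \[0, 1\].
#' @export
seq_overrep_pvalue <- function(yes_hits, yes_total, no_hits, no_total) {
  if (any(c(yes_hits, no_hits, yes_total, no_total) < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(yes_hits > yes_total) || any(no_hits > no_total)) {
    abort("Hits cannot exceed totals.")
  }
  phyper(yes_hits - 1, yes_total, no_total, yes_hits + no_hits,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1,
#' order-preserving with the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

# number of values in `sorted` (ascending) that are >= each x
count_ge <- function(x, sorted) {
  length(sorted) - findInterval(x, sorted, left.open = TRUE)
}

# Per-cutoff enrichment table for one PWM, vectorised over all candidate
# cutoffs (the distinct observed scores, plus 1.0). Site counts come from
# the sorted score vectors; a sequence has a site at cutoff c iff its
# maximum score is >= c, so sequence hits reduce to the same counting.
cutoff_table <- function(yes_scored, no_scored, yes_meta, no_meta) {
  cand <- sort(unique(c(yes_scored$score, no_scored$score, 1.0)),
               decreasing = TRUE)
  ys_sorted <- sort(yes_scored$score)
  ns_sorted <- sort(no_scored$score)
  ymax <- sort(tapply(yes_scored$score, yes_scored$seq_id, max))
  nmax <- sort(tapply(no_scored$score, no_scored$seq_id, max))
  tibble(
    cutoff = cand,
    yes_sites = count_ge(cand, ys_sorted),
    no_sites = count_ge(cand, ns_sorted),
    yes_seq_hits = count_ge(cand, ymax),
    no_seq_hits = count_ge(cand, nmax),
    yes_positions = yes_meta$positions, no_positions = no_meta$positions,
    yes_total = yes_meta$n, no_total = no_meta$n
  )
}

haldane_or <- function(a, b, c, d) {
  ((a + 0.5) / (b + 0.5)) / ((c + 0.5) / (d + 0.5))
}

#' Optimise a PWM score cutoff for Yes/No enrichment
#'
#' Evaluates every candidate cutoff (the distinct observed match scores in
#' the union of both sets, plus 1.0) and, among the candidates whose
#' criterion p-value is at most `alpha`, returns the cutoff maximising the
#' odds ratio of a predicted site (or site-bearing sequence) being in the
#' Yes set. If no candidate reaches `alpha` the minimal-p candidate is
#' returned with `significant = FALSE`.
#'
#' @param pwm A [build_pwm()] object.
#' @param yes,no [seq_set] tibbles (foreground / background).
#' @param criterion `"site"` (binomial on site counts) or `"sequence"`
#'   (Fisher on sequences with at least one site).
#' @param alpha Significance level for the optimiser (default 0.05).
#' @param min_score Scan floor below which windows are not considered
#'   candidate sites (default 0.5).
#' @param both_strands Scan both strands (default TRUE).
#' @return A one-row tibble: `pwm_id`, `cutoff`, counts, rates, `odds_ratio`,
#'   `p_binomial`, `p_fisher`, `p_criterion`, `significant`.
#' @export
optimize_cutoff <- function(pwm, yes, no, criterion = c("sequence", "site"),
                            alpha = 0.05, min_score = 0.5,
                            both_strands = TRUE) {
  criterion <- match.arg(criterion)
  if (nrow(yes) == 0 || nrow(no) == 0) abort("Both sets must be non-empty.")
  ym <- scan_pwm(pwm, yes, cutoff = min_score, both_strands = both_strands)
  nm <- scan_pwm(pwm, no, cutoff = min_score, both_strands = both_strands)
  strands <- if (both_strands) 2L else 1L
  yes_meta <- list(n = nrow(yes),
                   positions = sum(pmax(nchar(yes$seq) - pwm$length + 1L, 0L)) *
                     strands)
  no_meta <- list(n = nrow(no),
                  positions = sum(pmax(nchar(no$seq) - pwm$length + 1L, 0L)) *
                    strands)
  tab <- cutoff_table(ym, nm, yes_meta, no_meta)
  tab$p_binomial <- site_overrep_pvalue(tab$yes_sites, tab$yes_positions,
                                        tab$no_sites, tab$no_positions)
  tab$p_fisher <- seq_overrep_pvalue(tab$yes_seq_hits, tab$yes_total,
                                     tab$no_seq_hits, tab$no_total)
  if (criterion == "site") {
    tab$p_criterion <- tab$p_binomial
    tab$odds_ratio <- haldane_or(
      tab$yes_sites, tab$yes_positions - tab$yes_sites,
      tab$no_sites, tab$no_positions - tab$no_sites
    )
  } else {
    tab$p_criterion <- tab$p_fisher
    tab$odds_ratio <- haldane_or(
      tab$yes_seq_hits, tab$yes_total - tab$yes_seq_hits,
      tab$no_seq_hits, tab$no_total - tab$no_seq_hits
    )
  }
  ok <- tab$p_criterion <= alpha
  if (any(ok)) {
    sub <- tab[ok, ]
    # maximise odds ratio; ties broken to the stricter (larger) cutoff
    best <- sub[order(-sub$odds_ratio, -sub$cutoff), ][1, ]
    significant <- TRUE
  } else {
    best <- tab[order(tab$p_criterion, -tab$cutoff), ][1, ]
    significant <- FALSE
  }
  tibble(
    pwm_id = pwm$id, cutoff = best$cutoff,
    yes_sites = best$yes_sites, no_sites = best$no_sites,
    yes_seq_hits = best$yes_seq_hits, no_seq_hits = best$no_seq_hits,
    yes_positions = best$yes_positions, no_positions = best$no_positions,
    yes_total = best$yes_total, no_total = best$no_total,
    site_rate_yes = best$yes_sites / best$yes_positions,
    site_rate_no = best$no_sites / best$no_positions,
    odds_ratio = best$odds_ratio,
    p_binomial = best$p_binomial, p_fisher = best$p_fisher,
    p_criterion = best$p_criterion, significant = significant
  )
}

#' F-Match style enrichment over a PWM collection
#'
#' Runs [optimize_cutoff()] for every matrix and controls the false
#' discovery rate across matrices with Benjamini-Hochberg on the criterion
#' p-values (the per-matrix cutoff optimisation itself is not corrected,
#' matching the published per-matrix optimised-threshold reporting).
#'
#' @inheritParams optimize_cutoff
#' @param pwms A list of [build_pwm()] objects.
#' @return Tibble with one row per PWM, sorted by ascending `p_adjusted`.
#' @export
fmatch <- function(pwms, yes, no, criterion = c("sequence", "site"),
                   alpha = 0.05, min_score = 0.5, both_strands = TRUE) {
  criterion <- match.arg(criterion)
  if (length(pwms) == 0) {
    return(tibble(pwm_id = character(), cutoff = numeric(),
                  odds_ratio = numeric(), p_criterion = numeric(),
                  p_adjusted = numeric(), significant = logical()))
  }
  rows <- purrr::map(pwms, optimize_cutoff, yes = yes, no = no,
                     criterion = criterion, alpha = alpha,
                     min_score = min_score, both_strands = both_strands)
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_criterion)
  res <- dplyr::arrange(out, .data$p_adjusted, .data$p_criterion)
  class(res) <- c("fmatch_result", class(res))
  res
}

#' Plot an enrichment result
#'
#' Odds ratio versus adjusted significance for each matrix.
#'
#' @param object An [fmatch()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmatch_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = log2(.data$odds_ratio), y = -log10(pmax(.data$p_adjusted, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "log2 odds ratio (Yes vs No)",
                  y = "-log10 adjusted p",
                  colour = "optimiser\nsignificant") +
    ggplot2::theme_minimal()
}
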