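#' Methylation beta-value
#'
#' `beta = M / (U + M + 100)` from methylated (M) and unmethylated (U)
#' probe intensities; the +100 offset regularises low-intensity probes,
#' so beta is always strictly below 1.
#'
#' @param M,U Non-negative intensity vectors.
#' @return Beta values in \[0, 1).
#' @export
beta_value <- function(M, U) {
  if (any(M < 0) || any(U < 0)) abort("Intensities must be non-negative.")
  M / (U + M + 100)
}

#' Per-feature differential statistics between two groups
#'
#' Log2 fold change of group means (with a tiny offset for expression
#' values so zero means are defined) and a two-sided Welch t-test per
#' feature, Benjamini-Hochberg adjusted across features. For beta-value
#' matrices the log fold change is the log2 fold change of mean betas,
#' so the conventional 1.5 / 0.67 fold-change thresholds map to
#' +/- log2(1.5).
#'
#' @param group_a,group_b [sample_matrix] objects (or plain matrices)
#'   sharing feature ids; at least 2 samples per group.
#' @param kind `"expression"` or `"beta"`; defaults to the matrices' kind.
#' @return Tibble: `feature`, `mean_a`, `mean_b`, `logFC` (a over b),
#'   `p`, `p_adjusted`.
#' @export
diff_stats <- function(group_a, group_b, kind = NULL) {
  if (is.null(kind)) kind <- attr(group_a, "kind") %||% "expression"
  feats <- intersect(rownames(group_a), rownames(group_b))
  if (length(feats) == 0) abort("No shared feature ids.")
  a <- group_a[feats, , drop = FALSE]
  b <- group_b[feats, , drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2 || nb < 2) abort("Need at least 2 samples per group.")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  eps <- if (kind == "expression") 1e-9 else 0
  logfc <- log2((ma + eps) / (mb + eps))
  # Welch t statistic and Satterthwaite degrees of freedom
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate features: no variance in either group
  flat <- se2 == 0
  p[flat] <- ifelse(ma[flat] == mb[flat], 1, 0)
  tibble(feature = feats, mean_a = unname(ma), mean_b = unname(mb),
         logFC = unname(logfc), p = unname(p),
         p_adjusted = unname(bh_adjust(p)))
}

#' Split differential results into up- and down-regulated feature lists
#'
#' @param results A [diff_stats()] tibble.
#' @param lfc_hi,lfc_lo Log fold-change thresholds (defaults +1.5 / -1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with tibbles `up` (`p_adjusted < alpha`, `logFC > lfc_hi`)
#'   and `down` (`p_adjusted < alpha`, `logFC < lfc_lo`).
#' @export
filter_features <- function(results, lfc_hi = 1.5, lfc_lo = -1.5,
                            alpha = 0.05) {
  if (!all(is.finite(c(lfc_hi, lfc_lo, alpha)))) {
    abort("Thresholds must be finite.")
  }
  sig <- results$p_adjusted < alpha
  list(up = results[sig & results$logFC > lfc_hi, ],
       down = results[sig & results$logFC < lfc_lo, ])
}

#' Critical value of the correlation coefficient
#'
#' Large-sample normal approximation for the Spearman correlation:
#' `z_(1 - alpha/2) / sqrt(n - 1)`. At a few hundred samples and
#' alpha = 0.05 this gives the familiar ~0.18 threshold used to call a
#' CpG-gene correlation significant.
#'
#' @param n Sample count (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Critical absolute correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 4)) abort("`n` must be >= 4.")
  qnorm(1 - alpha / 2) / sqrt(n - 1)
}

#' CpG-gene Spearman correlation
#'
#' Correlates each CpG probe's beta values with each paired gene's
#' expression over the shared samples; a pair passes when |rho| exceeds
#' [critical_r()] at the given alpha.
#'
#' @param meth Beta-value [sample_matrix] (probes x samples).
#' @param expr Expression [sample_matrix] (genes x samples).
#' @param pairs Data frame with columns `probe`, `gene` naming the pairs
#'   to test. When omitted, every probe is tested against every gene
#'   (suitable only for small panels); use [pair_by_distance()] to build
#'   proximity-based pairs.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return Tibble: `probe`, `gene`, `rho`, `n`, `passes`.
#' @export
cpg_gene_correlation <- function(meth, expr, pairs = NULL, alpha = 0.05) {
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 4) abort("Need at least 4 shared samples.")
  m <- meth[, samples, drop = FALSE]
  x <- expr[, samples, drop = FALSE]
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(probe = rownames(m), gene = rownames(x))
  }
  pairs <- as_tibble(pairs)
  keep <- pairs$probe %in% rownames(m) & pairs$gene %in% rownames(x)
  pairs <- pairs[keep, ]
  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    mv <- m[pairs$probe[i], ]
    xv <- x[pairs$gene[i], ]
    if (length(unique(mv)) == 1 || length(unique(xv)) == 1) {
      return(NA_real_)
    }
    cor(mv, xv, method = "spearman")
  }, 0.0)
  crit <- critical_r(length(samples), alpha)
  tibble(probe = pairs$probe, gene = pairs$gene, rho = rho,
         n = length(samples),
         passes = !is.na(rho) & abs(rho) > crit)
}

#' Pair CpG probes with genes by genomic proximity
#'
#' A probe is paired with every gene whose span, extended by `max_dist`
#' on both sides (default 2 kb, the usual proximal regulatory window),
#' contains the probe position.
#'
#' @param probes Data frame: `probe`, `chrom`, `pos` (0-based).
#' @param genes Data frame: `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param max_dist Extension in bp (default 2000).
#' @return Tibble with columns `probe`, `gene`.
#' @export
pair_by_distance <- function(probes, genes, max_dist = 2000) {
  pg <- GenomicRanges::GRanges(
    probes$chrom, IRanges::IRanges(probes$pos + 1L, probes$pos + 1L)
  )
  gg <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - max_dist, 0L) + 1L,
                     genes$end + max_dist)
  )
  hits <- GenomicRanges::findOverlaps(pg, gg)
  tibble(probe = probes$probe[S4Vectors::queryHits(hits)],
         gene = genes$gene[S4Vectors::subjectHits(hits)])
}

#' Build merged windows around CpG positions
#'
#' Each CpG gets the half-open interval
#' `[pos - window/2, pos + window/2)`, clipped at zero; overlapping or
#' touching windows on the same chromosome are merged and the result is
#' sorted.
#'
#' @param cpgs Data frame with columns `chrom`, `pos` (0-based) and
#'   optionally `probe`.
#' @param window Even positive window size in bp (default 200).
#' @return Tibble of non-overlapping intervals: `chrom`, `start`, `end`.
#' @export
regions_around <- function(cpgs, window = 200) {
  if (window <= 0 || window %% 2 != 0) {
    abort("`window` must be a positive even number of bp.")
  }
  half <- window %/% 2
  start0 <- pmax(cpgs$pos - half, 0)
  end0 <- cpgs$pos + half
  gr <- GenomicRanges::GRanges(
    cpgs$chrom, IRanges::IRanges(start0 + 1L, end0)
  )
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
}
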