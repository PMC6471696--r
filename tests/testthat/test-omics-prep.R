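test_that("beta-value follows the intensity formula and stays below 1", {
  expect_equal(beta_value(0, 500), 0)
  expect_equal(beta_value(900, 0), 0.9)
  expect_equal(beta_value(450, 450), 0.45)
  expect_error(beta_value(-1, 10), "non-negative")
  # monotone in M, anti-monotone in U, always < 1
  m <- seq(0, 1e5, length.out = 50)
  expect_true(all(diff(beta_value(m, 100)) > 0))
  expect_true(all(diff(beta_value(100, m)) < 0))
  expect_true(all(beta_value(m, 0) < 1))
})

mk_groups <- function(n_feat = 20, n = 6, shift = 0, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_feat * n, 5, 1), n_feat, n,
              dimnames = list(paste0("f", 1:n_feat), paste0("a", 1:n)))
  b <- matrix(rnorm(n_feat * n, 5 + shift, 1), n_feat, n,
              dimnames = list(paste0("f", 1:n_feat), paste0("b", 1:n)))
  list(a = a, b = b)
}

test_that("differential statistics have the stated closed-form behaviour", {
  g <- mk_groups()
  same <- diff_stats(g$a, g$a[, c(4:6, 1:3)])
  expect_true(all(abs(same$logFC) < 1e-12))

  doubled <- diff_stats(2 * g$a, g$a)
  expect_equal(doubled$logFC, rep(1, nrow(g$a)), tolerance = 1e-9)

  # antisymmetry under group swap; p unchanged
  d1 <- diff_stats(g$a, g$b)
  d2 <- diff_stats(g$b, g$a)
  expect_equal(d1$logFC, -d2$logFC, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)

  # Welch p agrees with stats::t.test per feature
  for (f in c("f1", "f7")) {
    tt <- t.test(g$a[f, ], g$b[f, ])
    expect_equal(d1$p[d1$feature == f], tt$p.value, tolerance = 1e-9)
  }

  # zero variance in both groups
  a <- matrix(1, 2, 3, dimnames = list(c("x", "y"), paste0("a", 1:3)))
  b <- a
  b["y", ] <- 2
  dz <- diff_stats(a, b)
  expect_equal(dz$p[dz$feature == "x"], 1)
  expect_equal(dz$p[dz$feature == "y"], 0)
  expect_error(diff_stats(g$a[, 1, drop = FALSE], g$b), "2 samples")
})

test_that("null features hold the nominal type-I rate", {
  rates <- vapply(1:20, function(seed) {
    g <- mk_groups(n_feat = 100, n = 10, shift = 0, seed = seed)
    d <- diff_stats(g$a, g$b)
    mean(d$p < 0.05)
  }, 0.0)
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.08)
})

test_that("feature filtering applies both thresholds", {
  res <- tibble::tibble(
    feature = paste0("f", 1:4),
    logFC = c(1.6, 1.6, -2, 0.5),
    p = 0.01,
    p_adjusted = c(0.01, 0.06, 0.01, 0.01)
  )
  out <- filter_features(res, 1.5, -1.5, 0.05)
  expect_equal(out$up$feature, "f1")    # f2 fails alpha
  expect_equal(out$down$feature, "f3")
  # hand-filter oracle on a random table
  set.seed(9)
  res2 <- tibble::tibble(feature = paste0("g", 1:10),
                         logFC = rnorm(10, 0, 2), p = runif(10),
                         p_adjusted = runif(10))
  out2 <- filter_features(res2, 1, -1, 0.2)
  expect_equal(out2$up$feature,
               res2$feature[res2$p_adjusted < 0.2 & res2$logFC > 1])
  expect_equal(out2$down$feature,
               res2$feature[res2$p_adjusted < 0.2 & res2$logFC < -1])
})

test_that("critical_r reproduces the conventional 0.18 threshold", {
  expect_equal(critical_r(120, 0.05), qnorm(0.975) / sqrt(119))
  expect_equal(round(critical_r(120, 0.05), 2), 0.18)
  expect_gt(critical_r(50, 0.01), critical_r(50, 0.05))
  expect_lt(critical_r(10000), 0.02)
  expect_error(critical_r(3), ">= 4")
})

test_that("CpG-gene correlation flags pairs beyond the critical value", {
  set.seed(2)
  n <- 30
  samples <- paste0("s", 1:n)
  beta <- matrix(runif(2 * n, 0.1, 0.9), 2, n,
                 dimnames = list(c("cg1", "cg2"), samples))
  expr <- matrix(0, 2, n, dimnames = list(c("g1", "g2"), samples))
  expr["g1", ] <- 10 - 5 * beta["cg1", ]        # perfect monotone link
  expr["g2", ] <- rnorm(n)
  out <- cpg_gene_correlation(
    sample_matrix(beta, "beta"), sample_matrix(expr, "expression"),
    pairs = tibble::tibble(probe = c("cg1", "cg2"), gene = c("g1", "g2"))
  )
  expect_equal(out$rho[1], -1)
  expect_true(out$passes[1])
  expect_equal(out$n, rep(n, 2))
  expect_error(
    cpg_gene_correlation(sample_matrix(beta[, 1:3], "beta"),
                         sample_matrix(expr[, 1:3], "expression")),
    "4 shared samples"
  )
})

test_that("independent probes pass at roughly the nominal rate", {
  rates <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 30
    samples <- paste0("s", 1:n)
    beta <- matrix(runif(50 * n), 50, n,
                   dimnames = list(paste0("cg", 1:50), samples))
    expr <- matrix(rnorm(50 * n), 50, n,
                   dimnames = list(paste0("g", 1:50), samples))
    out <- cpg_gene_correlation(
      sample_matrix(beta, "beta"), sample_matrix(expr, "expression"),
      pairs = tibble::tibble(probe = paste0("cg", 1:50),
                             gene = paste0("g", 1:50))
    )
    mean(out$passes)
  }, 0.0)
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.09)
})

test_that("proximity pairing respects the distance window", {
  probes <- tibble::tibble(probe = c("p1", "p2"), chrom = "chr1",
                           pos = c(1000L, 99000L))
  genes <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                          start = c(2000L, 50000L), end = c(3000L, 51000L))
  pairs <- pair_by_distance(probes, genes, max_dist = 2000)
  expect_equal(pairs, tibble::tibble(probe = "p1", gene = "g1"))
})

test_that("CpG windows are built, clipped, merged and sorted", {
  out <- regions_around(tibble::tibble(chrom = "chr1", pos = 1000L),
                        window = 200)
  expect_equal(out$start, 900L)
  expect_equal(out$end, 1100L)

  merged <- regions_around(
    tibble::tibble(chrom = "chr1", pos = c(1000L, 1100L)), window = 200
  )
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(900L, 1200L))

  clipped <- regions_around(tibble::tibble(chrom = "chr1", pos = 10L), 200)
  expect_equal(clipped$start, 0L)

  # interval-union oracle over random CpGs
  set.seed(14)
  cpgs <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                         pos = sample(0:5000, 100))
  out <- regions_around(cpgs, window = 200)
  covered <- function(chrom, x) {
    any(out$chrom == chrom & out$start <= x & x < out$end)
  }
  # every point of every window is covered, and nothing else
  base <- unlist(lapply(seq_len(nrow(cpgs)), function(i) {
    paste(cpgs$chrom[i],
          seq(max(cpgs$pos[i] - 100, 0), cpgs$pos[i] + 99))
  }))
  base <- unique(base)
  out_pts <- unlist(lapply(seq_len(nrow(out)), function(i) {
    paste(out$chrom[i], seq(out$start[i], out$end[i] - 1))
  }))
  expect_setequal(out_pts, base)
  # non-overlapping and sorted per chromosome
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  expect_error(regions_around(cpgs, window = 0), "positive even")
})
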