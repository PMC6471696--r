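test_that("binomial site-overrepresentation matches exact tail summation", {
  expect_equal(site_overrep_pvalue(0, 1000, 5, 1000), 1.0)
  p <- site_overrep_pvalue(10, 1000, 2, 1000)
  expect_equal(p, oracle_binom_tail(10, 1000, 2 / 1000), tolerance = 1e-12)
  # continuity correction when the No set is empty of sites
  p0 <- site_overrep_pvalue(3, 500, 0, 800)
  expect_equal(p0, oracle_binom_tail(3, 500, 1 / 802), tolerance = 1e-12)
  # equal rates at large n give an unremarkable p
  p_eq <- site_overrep_pvalue(50, 10000, 50, 10000)
  expect_gt(p_eq, 0.05)
  expect_lt(abs(p_eq - 0.5), 0.25)
  expect_error(site_overrep_pvalue(5, 0, 1, 10), "positive")
  expect_error(site_overrep_pvalue(11, 10, 1, 10), "exceed")
})

test_that("Fisher sequence-overrepresentation equals hypergeometric enumeration", {
  expect_equal(seq_overrep_pvalue(8, 10, 2, 10),
               oracle_fisher_onesided(8, 10, 2, 10), tolerance = 1e-12)
  # agreement with fisher.test one-sided as a second, independent route
  ft <- stats::fisher.test(matrix(c(8, 2, 2, 8), 2), alternative = "greater")
  expect_equal(seq_overrep_pvalue(8, 10, 2, 10), ft$p.value,
               tolerance = 1e-9)
  # extreme table: all yes hit, no no hits
  expect_equal(seq_overrep_pvalue(10, 10, 0, 10),
               oracle_fisher_onesided(10, 10, 0, 10), tolerance = 1e-12)
  expect_equal(seq_overrep_pvalue(10, 10, 0, 10), 1 / choose(20, 10),
               tolerance = 1e-12)
  # identical rates with identical totals are not enriched
  expect_gte(seq_overrep_pvalue(5, 10, 5, 10), 0.5)
  # sweep of small tables against the enumeration oracle
  for (yh in 0:6) {
    for (nh in 0:6) {
      expect_equal(seq_overrep_pvalue(yh, 6, nh, 6),
                   oracle_fisher_onesided(yh, 6, nh, 6), tolerance = 1e-12)
    }
  }
  expect_error(seq_overrep_pvalue(-1, 5, 0, 5), "non-negative")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(42)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cutoff optimisation equals the brute-force argmax", {
  pwm <- consensus_pwm("TGACTCA", id = "planted")
  fx <- planted_enrichment_fixture(pwm, n = 60, len = 120, seed = 7)
  for (crit in c("site", "sequence")) {
    res <- optimize_cutoff(pwm, fx$yes, fx$no, criterion = crit,
                           alpha = 0.05)
    oracle <- oracle_optimize_cutoff(pwm, fx$yes, fx$no, crit, 0.05)
    expect_equal(res$cutoff, unname(oracle["cutoff"]), tolerance = 1e-12)
    expect_equal(res$odds_ratio, unname(oracle["or"]), tolerance = 1e-9)
    expect_equal(res$p_criterion, unname(oracle["p"]), tolerance = 1e-12)
  }
})

test_that("the optimiser isolates a planted motif and flags exchangeable sets", {
  pwm <- consensus_pwm("TGACTCA", id = "planted")
  fx <- planted_enrichment_fixture(pwm, n = 200, len = 200, seed = 3)
  res <- optimize_cutoff(pwm, fx$yes, fx$no, criterion = "sequence",
                         alpha = 0.05)
  expect_true(res$significant)
  expect_lt(res$p_fisher, 1e-6)
  # planted consensus scores 1; the chosen cutoff admits the planted sites
  expect_gt(res$cutoff, 0.8)

  same <- sim_background(50, 150, seed = 5)
  null_res <- optimize_cutoff(pwm, same, same, criterion = "sequence")
  expect_false(null_res$significant)
})

test_that("cutoff optimisation is invariant to sequence order", {
  pwm <- consensus_pwm("TGACTCA")
  fx <- planted_enrichment_fixture(pwm, n = 40, len = 120, seed = 9)
  res1 <- optimize_cutoff(pwm, fx$yes, fx$no)
  shuffled <- fx$yes[rev(seq_len(nrow(fx$yes))), ]
  res2 <- optimize_cutoff(pwm, shuffled, fx$no)
  expect_equal(res1$cutoff, res2$cutoff)
  expect_equal(res1$p_criterion, res2$p_criterion)
})

test_that("fmatch ranks a planted motif first and handles empty pools", {
  planted <- consensus_pwm("TGACTCA", id = "planted")
  decoys <- lapply(1:8, function(i) {
    consensus_pwm(random_word(7, seed = 500 + i), id = paste0("D", i))
  })
  fx <- planted_enrichment_fixture(planted, n = 150, len = 200, seed = 11)
  res <- fmatch(c(list(planted), decoys), fx$yes, fx$no,
                criterion = "sequence")
  expect_equal(res$pwm_id[1], "planted")
  expect_lt(res$p_adjusted[1], 0.01)

  expect_equal(nrow(fmatch(list(), fx$yes, fx$no)), 0)
})

test_that("label swap never flags the same PWM as enriched both ways", {
  planted <- consensus_pwm("TGACTCA", id = "planted")
  fx <- planted_enrichment_fixture(planted, n = 100, len = 150, seed = 13)
  fwd <- optimize_cutoff(planted, fx$yes, fx$no, criterion = "sequence")
  swp <- optimize_cutoff(planted, fx$no, fx$yes, criterion = "sequence")
  expect_false(fwd$significant && swp$significant)
})
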