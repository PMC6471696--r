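pool2 <- function() {
  list(P1 = consensus_pwm("TGACTCAGC", id = "P1"),
       P2 = consensus_pwm("CCGGAAGTG", id = "P2"))
}

test_that("cm_score closed forms hold", {
  p <- consensus_pwm("ACGT", id = "p1")
  mod <- composite_module("p1", cutoffs = 0.5, kappas = 1, sigma = 10)
  # single match q = 0.9 centred at 50
  m <- tibble::tibble(pwm_id = "p1", seq_id = "s", start = 48L,
                      strand = "+", score = 0.9)
  res <- cm_score(mod, m, seq_length = 100, pwms = list(p1 = p))
  expect_equal(res$x_max, 50L)
  expect_equal(res$score, 0.9 / (10 * sqrt(2 * pi)), tolerance = 1e-9)

  # no matches above cutoff
  none <- cm_score(mod, m[m$score > 1, ], 100, list(p1 = p))
  expect_equal(none, list(score = 0, x_max = 0L))

  # two matches at centres 50 and 60: symmetric optimum at 55
  m2 <- tibble::tibble(pwm_id = "p1", seq_id = "s",
                       start = c(48L, 58L), strand = "+",
                       score = c(0.8, 0.8))
  mod2 <- composite_module("p1", 0.5, 2, 10)
  res2 <- cm_score(mod2, m2, 100, list(p1 = p))
  oracle <- oracle_cm_score(c(50, 60), c(0.8, 0.8), 10, 100)
  expect_equal(res2$score, oracle$score, tolerance = 1e-9)
  expect_equal(res2$x_max, 55L)
  expect_error(composite_module("p1", 0.5, 1, sigma = 0), "sigma")
})

test_that("cm_score equals the exhaustive oracle on random instances", {
  set.seed(99)
  for (i in 1:50) {
    len <- sample(50:500, 1)
    n_pwm <- sample(1:3, 1)
    pwms <- lapply(seq_len(n_pwm), function(k) {
      consensus_pwm(random_word(sample(5:9, 1), seed = i * 10 + k),
                    id = paste0("q", k))
    })
    names(pwms) <- vapply(pwms, `[[`, "", "id")
    sigma <- runif(1, 5, 60)
    n_matches <- sample(0:6, 1)
    m <- tibble::tibble(
      pwm_id = sample(names(pwms), n_matches, replace = TRUE),
      seq_id = "s",
      start = sample(0:(len - 10), max(n_matches, 1))[seq_len(n_matches)],
      strand = sample(c("+", "-"), n_matches, replace = TRUE),
      score = runif(n_matches, 0.5, 1)
    )
    # kappa above the match count so every match enters, as in the oracle
    mod <- composite_module(names(pwms), rep(0.5, n_pwm),
                            rep(6L, n_pwm), sigma)
    res <- cm_score(mod, m, len, pwms)
    centers <- vapply(seq_len(nrow(m)), function(j) {
      m$start[j] + pwms[[m$pwm_id[j]]]$length %/% 2
    }, 0)
    oracle <- oracle_cm_score(centers, m$score, sigma, len)
    expect_equal(res$score, oracle$score, tolerance = 1e-9)
    expect_equal(res$x_max, oracle$x_max)
  }
})

test_that("cm_score is translation-equivariant in the interior", {
  p <- consensus_pwm("ACGTA", id = "p1")
  mod <- composite_module("p1", 0.5, 3, 8)
  base <- tibble::tibble(pwm_id = "p1", seq_id = "s",
                         start = c(100L, 110L, 118L), strand = "+",
                         score = c(0.9, 0.7, 0.8))
  r0 <- cm_score(mod, base, 400, list(p1 = p))
  shifted <- dplyr::mutate(base, start = start + 60L)
  r1 <- cm_score(mod, shifted, 400, list(p1 = p))
  expect_equal(r1$score, r0$score, tolerance = 1e-12)
  expect_equal(r1$x_max, r0$x_max + 60L)
})

test_that("reg_score is the unconditional sum over modules", {
  p <- pool2()
  m <- tibble::tibble(pwm_id = c("P1", "P2"), seq_id = "s",
                      start = c(20L, 40L), strand = "+",
                      score = c(0.95, 0.85))
  mod1 <- composite_module("P1", 0.5, 1, 20)
  mod2 <- composite_module("P2", 0.5, 1, 30)
  single <- regulatory_model(list(mod1))
  expect_equal(reg_score(single, m, 100, p),
               cm_score(mod1, m, 100, p)$score)
  doubled <- regulatory_model(list(mod1, mod1))
  expect_equal(reg_score(doubled, m, 100, p),
               2 * cm_score(mod1, m, 100, p)$score, tolerance = 1e-12)
  both <- regulatory_model(list(mod1, mod2))
  expect_equal(reg_score(both, m, 100, p),
               cm_score(mod1, m, 100, p)$score +
                 cm_score(mod2, m, 100, p)$score,
               tolerance = 1e-12)
})

test_that("spearman_rho matches the explicit average-rank formula", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1.0)
  x <- c(1, 2, 2, 4)
  y <- c(3, 1, 4, 5)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:5, 20, replace = TRUE)
    b <- rnorm(20)
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(c(1, 1, 1), 1:3),
               class = "pathwalker_constant_input")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("fitness closed forms and monotonicity hold", {
  expect_equal(cma_fitness(0, 2, 0), 0)
  expect_equal(cma_fitness(0.9, 2, 0), 1.0, tolerance = 1e-12)
  expect_equal(cma_fitness(-0.9, 2, 0), 1.0, tolerance = 1e-12)
  expect_equal(cma_fitness(0.9, 10, 1), 0.1, tolerance = 1e-12)
  # increasing in |rho| at fixed complexity
  rhos <- seq(0, 0.95, by = 0.05)
  f <- cma_fitness(rhos, 3, 1)
  expect_true(all(diff(f) > 0))
  # decreasing in complexity when penalty > 0
  f2 <- vapply(1:8, function(cx) cma_fitness(0.8, cx, 0.5), 0.0)
  expect_true(all(diff(f2) < 0))
  # penalty 0: complexity has no effect
  expect_equal(cma_fitness(0.8, 1, 0), cma_fitness(0.8, 10, 0))
  # |rho| = 1 stays finite
  expect_true(is.finite(cma_fitness(1, 2, 0)))
})

test_that("the genetic algorithm is seed-reproducible", {
  fx <- planted_cma_fixture(n = 60, len = 200, seed = 21)
  cfg <- cma_ga_config(population = 10, generations = 5, max_pwms = 2,
                       seed = 77)
  f1 <- cma_fit(fx$seqs, fx$values[, c("seq_id", "value")], fx$pool,
                config = cfg)
  f2 <- cma_fit(fx$seqs, fx$values[, c("seq_id", "value")], fx$pool,
                config = cfg)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$rho, f2$rho)
  # elitism makes the best-fitness trajectory non-decreasing
  expect_true(all(diff(f1$trajectory$best_fitness) >= 0))
})

test_that("a single-PWM pool forces the model composition", {
  fx <- planted_cma_fixture(n = 40, len = 200, seed = 31)
  pool1 <- fx$pool["P1"]
  cfg <- cma_ga_config(population = 8, generations = 4, n_modules = 1,
                       max_pwms = 1, seed = 1)
  fit <- cma_fit(fx$seqs, fx$values[, c("seq_id", "value")], pool1,
                 config = cfg)
  expect_equal(unique(tidy(fit)$pwm_id), "P1")
})

test_that("the GA recovers a planted module on a desk-scale fixture", {
  fx <- planted_cma_fixture(n = 150, len = 250, seed = 41)
  fit <- cma_fit(fx$seqs, fx$values[, c("seq_id", "value")], fx$pool,
                 config = test_ga_config(seed = 41))
  expect_true(any(tidy(fit)$pwm_id %in% c("P1", "P2")))
  expect_gte(abs(fit$rho), 0.5)
})

test_that("score_regions reports flags and a consistent correlation", {
  fx <- planted_cma_fixture(n = 30, len = 200, seed = 51)
  mod <- composite_module(c("P1", "P2"), c(0.9, 0.9), c(1L, 1L), 20)
  model <- regulatory_model(list(mod), cm_score_cutoff = 0)
  rep <- score_regions(model, fx$seqs, fx$pool,
                       values = fx$values[, c("seq_id", "value")])
  per_seq <- rep[!duplicated(rep$seq_id), ]
  expect_equal(attr(rep, "rho"),
               spearman_rho(per_seq$reg_score, per_seq$value),
               tolerance = 1e-12)
  # cutoff 0: every sequence with any site is flagged
  expect_true(all(rep$matched[rep$cm_score > 0]))
  # a cutoff above the maximum disables all flags
  model_hi <- regulatory_model(list(mod),
                               cm_score_cutoff = max(rep$cm_score) + 1)
  rep_hi <- score_regions(model_hi, fx$seqs, fx$pool)
  expect_false(any(rep_hi$matched))
})
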