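# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths (pure-R loops, closed forms, enumeration).

# concentrated count matrix whose consensus is `word`
consensus_pwm <- function(word, id = word, depth = 12, pseudocount = 0.25) {
  enc <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(0, length(enc), 4)
  counts[cbind(seq_along(enc), enc)] <- depth
  build_pwm(counts, id = id, pseudocount = pseudocount)
}

random_counts <- function(L, seed) {
  set.seed(seed)
  matrix(sample(0:20, L * 4, replace = TRUE), L, 4)
}

random_word <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# exhaustive per-position evaluation of the composite-module score:
# max over x of sum_j q_j * dnorm(|x - c_j|, 0, sigma)
oracle_cm_score <- function(centers, scores, sigma, len) {
  if (length(centers) == 0) return(list(score = 0, x_max = 0L))
  best <- -Inf
  best_x <- 0L
  for (x in 0:(len - 1)) {
    s <- 0
    for (j in seq_along(centers)) {
      s <- s + scores[j] * stats::dnorm(abs(x - centers[j]), 0, sigma)
    }
    if (s > best) {
      best <- s
      best_x <- x
    }
  }
  list(score = best, x_max = best_x)
}

# Spearman rho from the explicit average-rank formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  covr <- sum((rx - mean(rx)) * (ry - mean(ry))) / (n - 1)
  covr / (stats::sd(rx) * stats::sd(ry))
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# one-sided Fisher p by exhaustive hypergeometric enumeration over tables
# with the same margins and yes-hits at least as extreme
oracle_fisher_onesided <- function(yes_hits, yes_total, no_hits, no_total) {
  k <- yes_hits + no_hits
  total <- yes_total + no_total
  p <- 0
  for (a in 0:k) {
    b <- k - a
    if (a > yes_total || b > no_total) next
    if (a >= yes_hits) {
      p <- p + choose(yes_total, a) * choose(no_total, b) / choose(total, k)
    }
  }
  p
}

# exact upper binomial tail by summation
oracle_binom_tail <- function(k, n, prob) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, prob))
}

# brute-force cutoff optimisation mirror of the stated rule
oracle_optimize_cutoff <- function(pwm, yes, no, criterion, alpha,
                                   min_score = 0.5) {
  ym <- scan_pwm(pwm, yes, cutoff = min_score)
  nm <- scan_pwm(pwm, no, cutoff = min_score)
  L <- pwm$length
  yes_pos <- sum(pmax(nchar(yes$seq) - L + 1, 0)) * 2
  no_pos <- sum(pmax(nchar(no$seq) - L + 1, 0)) * 2
  cand <- sort(unique(c(ym$score, nm$score, 1)), decreasing = TRUE)
  rows <- lapply(cand, function(ct) {
    ys <- sum(ym$score >= ct)
    ns <- sum(nm$score >= ct)
    yh <- length(unique(ym$seq_id[ym$score >= ct]))
    nh <- length(unique(nm$seq_id[nm$score >= ct]))
    if (criterion == "site") {
      p <- site_overrep_pvalue(ys, yes_pos, ns, no_pos)
      or <- ((ys + 0.5) / (yes_pos - ys + 0.5)) /
        ((ns + 0.5) / (no_pos - ns + 0.5))
    } else {
      p <- seq_overrep_pvalue(yh, nrow(yes), nh, nrow(no))
      or <- ((yh + 0.5) / (nrow(yes) - yh + 0.5)) /
        ((nh + 0.5) / (nrow(no) - nh + 0.5))
    }
    c(cutoff = ct, p = p, or = or)
  })
  tab <- do.call(rbind, rows)
  ok <- tab[, "p"] <= alpha
  if (any(ok)) {
    sub <- tab[ok, , drop = FALSE]
    sub[order(-sub[, "or"], -sub[, "cutoff"]), , drop = FALSE][1, ]
  } else {
    tab[order(tab[, "p"], -tab[, "cutoff"]), , drop = FALSE][1, ]
  }
}

# planted enrichment fixture: motif present in a fraction of yes and no
planted_enrichment_fixture <- function(pwm, n = 200, len = 200,
                                       frac_yes = 0.6, frac_no = 0.05,
                                       seed = 1) {
  yes <- sim_background(n, len, seed = seed, prefix = "yes")
  no <- sim_background(n, len, seed = seed + 1000, prefix = "no")
  set.seed(seed + 2000)
  plant <- function(ss, frac) {
    idx <- sample.int(nrow(ss), round(frac * nrow(ss)))
    for (i in idx) {
      pos <- sample.int(len - pwm$length, 1)
      substr(ss$seq[i], pos, pos + pwm$length - 1) <- pwm$consensus
    }
    ss
  }
  list(yes = plant(yes, frac_yes), no = plant(no, frac_no))
}

# planted two-PWM module fixture for model fitting
planted_cma_fixture <- function(n = 400, len = 300, fraction = 0.5,
                                effect = 0.6, noise_sd = 0.2, seed = 1) {
  pool <- lapply(seq_len(8), function(i) {
    if (i <= 2) {
      consensus_pwm(c("TGACTCAGC", "CCGGAAGTG")[i],
                    id = paste0("P", i))
    } else {
      consensus_pwm(random_word(9, seed = 9000 + i),
                    id = paste0("D", i - 2))
    }
  })
  names(pool) <- vapply(pool, `[[`, "", "id")
  bg <- sim_background(n, len, seed = seed)
  pl <- sim_planted_module(bg, pool[c("P1", "P2")], sigma = 15,
                           fraction = fraction, seed = seed + 1)
  vals <- sim_trait_values(pl$labels, effect = effect, noise_sd = noise_sd,
                           seed = seed + 2)
  list(seqs = pl$seqs, values = vals, pool = pool, truth = pl$truth,
       labels = pl$labels)
}

# lean GA settings used throughout the tests (desk-scale search)
test_ga_config <- function(seed, ...) {
  cma_ga_config(population = 24, generations = 30, n_modules = 2,
                max_pwms = 3, seed = seed, ...)
}
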