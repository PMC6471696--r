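#' Composite regulatory modules
#'
#' A composite module is a set of PWMs with per-PWM score cutoffs and
#' top-match counts, plus a Gaussian width `sigma` (bp) describing how
#' tightly the sites cluster. Its score on a sequence is the maximum over
#' positions x of the sum of match scores weighted by a normal density of
#' the site-centre distance from x (see [cm_score()]).
#'
#' @param pwm_ids Character vector of PWM identifiers.
#' @param cutoffs Numeric vector of score cutoffs in \[0, 1\], one per PWM.
#' @param kappas Integer vector (>= 1), the number of top matches per PWM
#'   entering the score.
#' @param sigma Positive Gaussian width in bp.
#' @return An object of class `composite_module`.
#' @export
composite_module <- function(pwm_ids, cutoffs, kappas, sigma) {
  pwm_ids <- as.character(pwm_ids)
  if (length(pwm_ids) < 1) abort("A module needs at least one PWM.")
  if (length(cutoffs) != length(pwm_ids) || length(kappas) != length(pwm_ids)) {
    abort("`cutoffs` and `kappas` must match `pwm_ids` in length.")
  }
  if (any(cutoffs < 0 | cutoffs > 1)) abort("Cutoffs must be in [0, 1].")
  if (any(kappas < 1)) abort("`kappas` must be >= 1.")
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  structure(
    list(pwm_ids = pwm_ids, cutoffs = as.numeric(cutoffs),
         kappas = as.integer(kappas), sigma = as.numeric(sigma)),
    class = "composite_module"
  )
}

#' @export
print.composite_module <- function(x, ...) {
  cat(sprintf("<composite_module: %d PWMs, sigma = %g>\n",
              length(x$pwm_ids), x$sigma))
  for (i in seq_along(x$pwm_ids)) {
    cat(sprintf("  %s  cutoff %.3f  kappa %d\n",
                x$pwm_ids[i], x$cutoffs[i], x$kappas[i]))
  }
  invisible(x)
}

#' Full regulatory-region model
#'
#' An ordered list of composite modules; the model score of a sequence
#' ([reg_score()]) is the unconditional sum of the module scores. The
#' `cm_score_cutoff` is a reporting threshold only: modules scoring above
#' it are flagged as matched in [score_regions()], but the threshold never
#' enters the additive score.
#'
#' @param modules A list of [composite_module()] objects (length T >= 1).
#' @param cm_score_cutoff Non-negative reporting threshold (default 0).
#' @return An object of class `regulatory_model`.
#' @export
regulatory_model <- function(modules, cm_score_cutoff = 0) {
  if (inherits(modules, "composite_module")) modules <- list(modules)
  if (length(modules) < 1) abort("A model needs at least one module.")
  if (!all(vapply(modules, inherits, TRUE, "composite_module"))) {
    abort("`modules` must be composite_module objects.")
  }
  if (cm_score_cutoff < 0) abort("`cm_score_cutoff` must be >= 0.")
  structure(
    list(modules = modules, cm_score_cutoff = cm_score_cutoff),
    class = "regulatory_model"
  )
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat(sprintf("<regulatory_model: %d modules, complexity %d, cutoff %g>\n",
              length(x$modules), model_complexity(x), x$cm_score_cutoff))
  invisible(x)
}

#' Model complexity
#'
#' The number of distinct PWM identifiers across all modules of a model;
#' this is the quantity penalised by the fitness function.
#'
#' @param model A [regulatory_model()].
#' @return Integer count.
#' @export
model_complexity <- function(model) {
  length(unique(unlist(lapply(model$modules, `[[`, "pwm_ids"))))
}

# match-window centre: start + floor(L / 2); symmetric under strand flips
match_center <- function(start, pwm_length) {
  start + pwm_length %/% 2
}

#' Composite-module score of one sequence
#'
#' Filters the matches of each module PWM to those scoring at least the
#' module cutoff, keeps the top `kappa` per PWM, and maximises over every
#' nucleotide position x the sum of match scores weighted by the normal
#' density (mean 0, sd `sigma`) of the distance between x and the match
#' window centre. Ties go to the smallest x; a sequence with no qualifying
#' matches scores (0, 0).
#'
#' @param module A [composite_module()].
#' @param matches Match tibble for one sequence ([scan_pwm()] columns).
#' @param seq_length Length of the sequence in bp.
#' @param pwms Named list of [build_pwm()] objects (for match widths).
#' @return List with elements `score` and `x_max`.
#' @export
cm_score <- function(module, matches, seq_length, pwms) {
  if (module$sigma <= 0) abort("`sigma` must be positive.")
  cen <- numeric(0)
  sco <- numeric(0)
  for (i in seq_along(module$pwm_ids)) {
    pid <- module$pwm_ids[i]
    m <- matches[matches$pwm_id == pid & matches$score >= module$cutoffs[i], ]
    if (nrow(m) == 0) next
    m <- top_matches(m, module$kappas[i])
    L <- pwms[[pid]]$length
    cen <- c(cen, match_center(m$start, L))
    sco <- c(sco, m$score)
  }
  v <- .cpp_cm_score(cen, sco, module$sigma, as.integer(seq_length))
  list(score = v[1], x_max = as.integer(v[2]))
}

#' Additive model score of one sequence
#'
#' The sum of [cm_score()] values over the T modules of the model. The
#' reporting threshold `cm_score_cutoff` is not applied inside the sum.
#'
#' @param model A [regulatory_model()].
#' @inheritParams cm_score
#' @return Non-negative numeric score.
#' @export
reg_score <- function(model, matches, seq_length, pwms) {
  sum(vapply(model$modules, function(mod) {
    cm_score(mod, matches, seq_length, pwms)$score
  }, 0.0))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their average rank).
#' Constant input is signalled as an error rather than returning NaN.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("Spearman correlation is undefined for constant input.",
          class = "pathwalker_constant_input")
  }
  cor(x, y, method = "spearman")
}

#' CMAcorrel fitness
#'
#' `fitness = -complexity^(-penalty) * log10(1 - |rho|)`, strictly
#' increasing in |rho| and, for positive penalty, strictly decreasing in
#' model complexity. |rho| is clamped to `1 - 1e-12` before the log.
#'
#' @param rho Spearman correlation between model scores and trait values.
#' @param complexity Distinct-PWM count of the model ([model_complexity()]).
#' @param penalty Non-negative complexity penalty exponent.
#' @return Non-negative fitness value.
#' @export
cma_fitness <- function(rho, complexity, penalty = 0) {
  if (!is.finite(penalty) || penalty < 0) abort("`penalty` must be >= 0.")
  if (complexity < 1) abort("`complexity` must be >= 1.")
  r <- pmin(abs(rho), 1 - 1e-12)
  -(complexity^(-penalty)) * log10(1 - r)
}

# ---- match cache ----------------------------------------------------------

# Scans every PWM once over every sequence at the global floor and stores,
# per PWM and sequence, a (center, score) matrix sorted by descending score
# (ties: smaller centre, '+' strand first). Module-level cutoffs and kappas
# are applied by prefix-filtering these matrices, which is what makes the
# genetic algorithm affordable.
build_match_cache <- function(pwms, seqs, floor = 0.5, both_strands = TRUE) {
  pwm_ids <- vapply(pwms, `[[`, "", "id")
  all_matches <- scan_pwm(pwms, seqs, cutoff = floor,
                          both_strands = both_strands)
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("center", "score")))
  cache <- lapply(seq_along(pwms), function(k) {
    L <- pwms[[k]]$length
    mk <- all_matches[all_matches$pwm_id == pwm_ids[k], ]
    lapply(seqs$id, function(sid) {
      m <- mk[mk$seq_id == sid, ]
      if (nrow(m) == 0) return(empty)
      ord <- order(-m$score, m$start, m$strand != "+")
      cbind(center = match_center(m$start[ord], L), score = m$score[ord])
    })
  })
  list(cache = cache, pwm_ids = pwm_ids,
       seq_len = nchar(seqs$seq), seq_id = seqs$id, floor = floor)
}

# model in GA representation: list of modules, each
# list(pwm = int indices, cutoff, kappa, sigma)
ga_model_scores <- function(cache, modules) {
  .cpp_model_scores(cache$cache, as.integer(cache$seq_len), modules)
}

ga_eval <- function(cache, modules, values, penalty) {
  reg <- ga_model_scores(cache, modules)
  if (length(unique(reg)) == 1) {
    return(list(fitness = 0, rho = 0, reg = reg))
  }
  rho <- spearman_rho(reg, values)
  cx <- length(unique(unlist(lapply(modules, `[[`, "pwm"))))
  list(fitness = cma_fitness(rho, cx, penalty), rho = rho, reg = reg)
}

#' Genetic-algorithm configuration for [cma_fit()]
#'
#' Hyperparameters of the mutation-and-selection search over model space.
#' Defaults target a thorough desk-scale search; tests and the pipeline use
#' smaller populations and generation counts.
#'
#' @param population Population size (default 50).
#' @param generations Number of generations (default 200).
#' @param tournament Tournament size for parent selection (default 3).
#' @param elitism Number of elite models copied unchanged (default 2).
#' @param p_add,p_drop Probability of adding / dropping a PWM in a module
#'   (defaults 0.2).
#' @param p_cutoff,p_sigma,p_kappa Probabilities of perturbing a cutoff,
#'   the module width, or a top-match count (defaults 0.3).
#' @param sigma_bounds,sigma_init Bounds and initial value of the module
#'   width in bp (defaults \[10, 150\], 30).
#' @param kappa_bounds Bounds on the top-match count (default \[1, 3\]).
#' @param max_pwms Maximum PWMs per module (default 10).
#' @param n_modules Number of composite modules T in the model (default 2).
#' @param scan_floor Global score floor for the shared match cache
#'   (default 0.5); module cutoffs live in \[`scan_floor`, 1\].
#' @param seed RNG seed; identical seed and config reproduce the run
#'   bit-for-bit.
#' @return A list of class `cma_ga_config`.
#' @export
cma_ga_config <- function(population = 50, generations = 200, tournament = 3,
                          elitism = 2, p_add = 0.2, p_drop = 0.2,
                          p_cutoff = 0.3, p_sigma = 0.3, p_kappa = 0.3,
                          sigma_bounds = c(10, 150), sigma_init = 30,
                          kappa_bounds = c(1L, 3L), max_pwms = 10,
                          n_modules = 2, scan_floor = 0.5, seed = 1) {
  cfg <- list(population = population, generations = generations,
              tournament = tournament, elitism = elitism,
              p_add = p_add, p_drop = p_drop, p_cutoff = p_cutoff,
              p_sigma = p_sigma, p_kappa = p_kappa,
              sigma_bounds = sigma_bounds, sigma_init = sigma_init,
              kappa_bounds = as.integer(kappa_bounds),
              max_pwms = max_pwms, n_modules = n_modules,
              scan_floor = scan_floor, seed = seed)
  rates <- c(cfg$p_add, cfg$p_drop, cfg$p_cutoff, cfg$p_sigma, cfg$p_kappa)
  if (any(rates < 0 | rates > 1)) abort("Mutation rates must be in [0, 1].")
  if (cfg$population < cfg$elitism) {
    abort("`population` must be at least `elitism`.")
  }
  if (cfg$population < 2 || cfg$generations < 1) {
    abort("Need population >= 2 and generations >= 1.")
  }
  if (diff(cfg$sigma_bounds) < 0 || cfg$sigma_bounds[1] <= 0) {
    abort("`sigma_bounds` must be positive and ordered.")
  }
  structure(cfg, class = "cma_ga_config")
}

ga_random_module <- function(n_pool, cfg) {
  k <- sample.int(min(2L, n_pool), 1)
  list(
    pwm = sample.int(n_pool, k),
    cutoff = runif(k, cfg$scan_floor, min(cfg$scan_floor + 0.3, 1)),
    kappa = sample(seq(cfg$kappa_bounds[1], cfg$kappa_bounds[2]), k,
                   replace = TRUE),
    sigma = cfg$sigma_init
  )
}

ga_mutate <- function(model, n_pool, cfg) {
  for (t in seq_along(model)) {
    mod <- model[[t]]
    if (runif(1) < cfg$p_add && length(mod$pwm) < cfg$max_pwms) {
      free <- setdiff(seq_len(n_pool), mod$pwm)
      if (length(free) > 0) {
        new <- free[sample.int(length(free), 1)]
        mod$pwm <- c(mod$pwm, new)
        mod$cutoff <- c(mod$cutoff,
                        runif(1, cfg$scan_floor, min(cfg$scan_floor + 0.3, 1)))
        mod$kappa <- c(mod$kappa,
                       sample(seq(cfg$kappa_bounds[1], cfg$kappa_bounds[2]), 1))
      }
    }
    if (runif(1) < cfg$p_drop && length(mod$pwm) > 1) {
      i <- sample.int(length(mod$pwm), 1)
      mod$pwm <- mod$pwm[-i]
      mod$cutoff <- mod$cutoff[-i]
      mod$kappa <- mod$kappa[-i]
    }
    if (runif(1) < cfg$p_cutoff) {
      i <- sample.int(length(mod$pwm), 1)
      mod$cutoff[i] <- min(max(mod$cutoff[i] + rnorm(1, 0, 0.05),
                               cfg$scan_floor), 1)
    }
    if (runif(1) < cfg$p_sigma) {
      mod$sigma <- min(max(mod$sigma * exp(rnorm(1, 0, 0.2)),
                           cfg$sigma_bounds[1]), cfg$sigma_bounds[2])
    }
    if (runif(1) < cfg$p_kappa) {
      i <- sample.int(length(mod$pwm), 1)
      mod$kappa[i] <- min(max(mod$kappa[i] + sample(c(-1L, 1L), 1),
                              cfg$kappa_bounds[1]), cfg$kappa_bounds[2])
    }
    model[[t]] <- mod
  }
  model
}

ga_to_model <- function(ga_model, pwm_ids, cm_score_cutoff = 0) {
  mods <- lapply(ga_model, function(m) {
    composite_module(pwm_ids[m$pwm], m$cutoff, m$kappa, m$sigma)
  })
  regulatory_model(mods, cm_score_cutoff = cm_score_cutoff)
}

#' Fit a composite-module model by genetic algorithm (CMAcorrel)
#'
#' Optimises a model of T composite modules so that the additive model
#' score of each sequence correlates (Spearman) with a quantitative trait
#' attached to the sequence — an expression log fold change, a
#' methylation-expression correlation, a ChIP signal, or any other
#' per-region value. Each PWM is scanned once per sequence at the cache
#' floor; the genetic algorithm then evolves module composition, cutoffs,
#' top-match counts and widths under tournament selection with elitism,
#' maximising `-complexity^(-penalty) * log10(1 - |rho|)`.
#'
#' @param seqs A [seq_set] tibble.
#' @param values Data frame with columns `seq_id` and `value`, or a numeric
#'   vector aligned with (or named by) `seqs$id`. At least 3 values, not
#'   all identical.
#' @param pwms Named list of [build_pwm()] objects (the PWM pool).
#' @param config A [cma_ga_config()].
#' @param penalty Non-negative complexity penalty exponent (default 0).
#' @param cm_score_cutoff Reporting threshold stored on the fitted model
#'   (default 0).
#' @return An object of class `cma_fit`: the best `model`, its `fitness`
#'   and `rho`, per-sequence `scores`, and a per-generation `trajectory`
#'   tibble. Supports [tidy()], [glance()] and [autoplot()].
#' @export
cma_fit <- function(seqs, values, pwms, config = cma_ga_config(),
                    penalty = 0, cm_score_cutoff = 0) {
  if (length(pwms) == 0) abort("PWM pool must be non-empty.")
  vals <- align_values(seqs, values)
  if (length(vals) < 3) abort("Need at least 3 scored sequences.")
  if (length(unique(vals)) == 1) abort("Trait values must not all be equal.")
  cache <- build_match_cache(pwms, seqs, floor = config$scan_floor)
  n_pool <- length(pwms)
  set.seed(config$seed)
  pop <- replicate(config$population, {
    lapply(seq_len(config$n_modules), function(i) {
      ga_random_module(n_pool, config)
    })
  }, simplify = FALSE)
  evals <- lapply(pop, ga_eval, cache = cache, values = vals,
                  penalty = penalty)
  traj <- vector("list", config$generations)
  for (gen in seq_len(config$generations)) {
    fit <- vapply(evals, `[[`, 0.0, "fitness")
    ord <- order(-fit)
    elites <- pop[ord[seq_len(config$elitism)]]
    elite_evals <- evals[ord[seq_len(config$elitism)]]
    n_off <- config$population - config$elitism
    offspring <- vector("list", n_off)
    for (i in seq_len(n_off)) {
      cand <- sample.int(config$population, config$tournament, replace = TRUE)
      parent <- pop[[cand[which.max(fit[cand])]]]
      offspring[[i]] <- ga_mutate(parent, n_pool, config)
    }
    pop <- c(elites, offspring)
    evals <- c(elite_evals,
               lapply(offspring, ga_eval, cache = cache, values = vals,
                      penalty = penalty))
    fit <- vapply(evals, `[[`, 0.0, "fitness")
    b <- which.max(fit)
    traj[[gen]] <- tibble(generation = gen, best_fitness = fit[b],
                          best_rho = evals[[b]]$rho)
  }
  fit <- vapply(evals, `[[`, 0.0, "fitness")
  b <- which.max(fit)
  best_model <- ga_to_model(pop[[b]], cache$pwm_ids, cm_score_cutoff)
  structure(
    list(model = best_model, fitness = fit[b], rho = evals[[b]]$rho,
         scores = tibble(seq_id = cache$seq_id,
                         reg_score = evals[[b]]$reg, value = vals),
         trajectory = dplyr::bind_rows(traj),
         penalty = penalty, config = config, pwm_ids = cache$pwm_ids),
    class = "cma_fit"
  )
}

align_values <- function(seqs, values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("seq_id", "value") %in% names(values)))
    idx <- match(seqs$id, values$seq_id)
    if (anyNA(idx)) abort("Every sequence needs a trait value.")
    values$value[idx]
  } else if (!is.null(names(values))) {
    idx <- match(seqs$id, names(values))
    if (anyNA(idx)) abort("Every sequence needs a trait value.")
    unname(values[idx])
  } else {
    if (length(values) != nrow(seqs)) {
      abort("`values` must align with `seqs`.")
    }
    as.numeric(values)
  }
}

#' @export
print.cma_fit <- function(x, ...) {
  cat(sprintf("<cma_fit: fitness %.4f, rho %.4f, complexity %d>\n",
              x$fitness, x$rho, model_complexity(x$model)))
  invisible(x)
}

#' @rdname cma_fit
#' @param x A `cma_fit` object.
#' @param ... Unused.
#' @export
tidy.cma_fit <- function(x, ...) {
  purrr::imap_dfr(x$model$modules, function(mod, t) {
    tibble(module = t, pwm_id = mod$pwm_ids, cutoff = mod$cutoffs,
           kappa = mod$kappas, sigma = mod$sigma)
  })
}

#' @rdname cma_fit
#' @export
glance.cma_fit <- function(x, ...) {
  tibble(fitness = x$fitness, rho = x$rho,
         complexity = model_complexity(x$model),
         n_modules = length(x$model$modules),
         penalty = x$penalty,
         generations = x$config$generations,
         population = x$config$population,
         n_sequences = nrow(x$scores))
}

#' @rdname cma_fit
#' @param object A `cma_fit` object.
#' @export
autoplot.cma_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness") +
    ggplot2::theme_minimal()
}

#' Score sequences with a fitted model and report module matches
#'
#' Deterministic per-sequence report: each module's score and maximising
#' position, a flag for module scores exceeding the model's reporting
#' threshold, the additive model score, and (when trait values are given)
#' the overall Spearman correlation as attribute `rho`.
#'
#' @param model A [regulatory_model()] (or a [cma_fit()], whose model is
#'   used).
#' @param seqs A [seq_set] tibble.
#' @param pwms Named list of [build_pwm()] objects covering the model.
#' @param values Optional trait values as in [cma_fit()].
#' @param scan_floor Scan floor for site search (default: smallest module
#'   cutoff).
#' @return A tibble of class `cma_report` with columns `seq_id`, `module`,
#'   `cm_score`, `x_max`, `matched`, `reg_score` and optionally `value`.
#' @export
score_regions <- function(model, seqs, pwms, values = NULL,
                          scan_floor = NULL) {
  if (inherits(model, "cma_fit")) model <- model$model
  used <- unique(unlist(lapply(model$modules, `[[`, "pwm_ids")))
  missing <- setdiff(used, vapply(pwms, `[[`, "", "id"))
  if (length(missing) > 0) {
    abort(paste0("PWMs not in pool: ", paste(missing, collapse = ", ")))
  }
  pwms <- setNames(pwms, vapply(pwms, `[[`, "", "id"))[used]
  if (is.null(scan_floor)) {
    scan_floor <- min(unlist(lapply(model$modules, `[[`, "cutoffs")))
  }
  matches <- scan_pwm(pwms, seqs, cutoff = scan_floor)
  rows <- purrr::map2_dfr(seqs$id, nchar(seqs$seq), function(sid, len) {
    m <- matches[matches$seq_id == sid, ]
    per_mod <- purrr::imap_dfr(model$modules, function(mod, t) {
      cs <- cm_score(mod, m, len, pwms)
      tibble(seq_id = sid, module = t, cm_score = cs$score,
             x_max = cs$x_max)
    })
    per_mod$matched <- per_mod$cm_score > model$cm_score_cutoff
    per_mod$reg_score <- sum(per_mod$cm_score)
    per_mod
  })
  if (!is.null(values)) {
    vals <- align_values(seqs, values)
    rows$value <- vals[match(rows$seq_id, seqs$id)]
    per_seq <- rows[!duplicated(rows$seq_id), ]
    attr(rows, "rho") <- spearman_rho(per_seq$reg_score, per_seq$value)
  }
  class(rows) <- c("cma_report", class(rows))
  rows
}

#' Plot model score versus trait value
#'
#' The scatter of additive model score against the per-sequence trait,
#' one point per sequence, with the Spearman correlation in the subtitle.
#'
#' @param object A [score_regions()] report containing trait values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cma_report <- function(object, ...) {
  if (!"value" %in% names(object)) {
    abort("Report has no trait values to plot.")
  }
  df <- as_tibble(object[!duplicated(object$seq_id), ])
  rho <- attr(object, "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reg_score, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "model score", y = "trait value",
                  subtitle = if (!is.null(rho)) {
                    sprintf("Spearman rho = %.3f", rho)
                  } else NULL) +
    ggplot2::theme_minimal()
}

#' Fitness of a model on a scored sequence set
#'
#' Convenience wrapper: computes per-sequence model scores, the Spearman
#' correlation with the trait values, and the penalised fitness.
#'
#' @inheritParams score_regions
#' @param penalty Non-negative complexity penalty exponent.
#' @return List with `fitness`, `rho` and `complexity`.
#' @export
model_fitness <- function(model, seqs, pwms, values, penalty = 0) {
  rep <- score_regions(model, seqs, pwms, values)
  rho <- attr(rep, "rho")
  cx <- model_complexity(if (inherits(model, "cma_fit")) model$model else model)
  list(fitness = cma_fitness(rho, cx, penalty), rho = rho, complexity = cx)
}
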