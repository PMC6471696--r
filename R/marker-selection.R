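#' Pairwise marker correlation
#'
#' Pearson correlation between candidate probes over all samples (cases
#' and controls pooled). Constant probes yield undefined correlations,
#' which are flagged with a warning and returned as NA.
#'
#' @param beta Beta-value [sample_matrix] (probes x samples).
#' @param probes Optional probe subset; defaults to all rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
marker_correlation <- function(beta, probes = NULL) {
  if (is.null(probes)) probes <- rownames(beta)
  x <- t(beta[probes, , drop = FALSE])
  if (nrow(x) < 3) abort("Need at least 3 samples.")
  flat <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(flat)) {
    warn(paste0("Constant probe(s): ",
                paste(probes[flat], collapse = ", "),
                "; correlations undefined."))
  }
  suppressWarnings(cor(x))
}

#' Drop redundant (highly correlated) markers
#'
#' Greedy redundancy pruning: pairs are visited by descending absolute
#' correlation; whenever both members of a pair above `threshold` are
#' still present, the one with the smaller absolute univariate effect is
#' dropped (ties: lexicographically larger id dropped). Deterministic.
#'
#' @param candidates Character vector of probe ids.
#' @param corr Correlation matrix over (at least) the candidates.
#' @param effect Named numeric vector of univariate effects per probe
#'   (e.g. absolute methylation logFC).
#' @param threshold Absolute-correlation threshold in (0, 1).
#' @return Character vector of retained probe ids (input order).
#' @export
decorrelate_markers <- function(candidates, corr, effect, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1).")
  }
  keep <- candidates
  if (length(candidates) < 2) return(keep)
  cm <- abs(corr[candidates, candidates, drop = FALSE])
  pairs <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(keep)
  ord <- order(-cm[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  alive <- setNames(rep(TRUE, length(candidates)), candidates)
  for (r in seq_len(nrow(pairs))) {
    a <- candidates[pairs[r, 1]]
    b <- candidates[pairs[r, 2]]
    if (!alive[a] || !alive[b]) next
    ea <- abs(effect[[a]])
    eb <- abs(effect[[b]])
    drop <- if (ea < eb) a else if (eb < ea) b else max(a, b)
    alive[drop] <- FALSE
  }
  candidates[alive[candidates]]
}

default_classifier <- function(train_x, train_y) {
  fit <- e1071::svm(train_x, factor(train_y), kernel = "linear", cost = 1,
                    scale = FALSE)
  function(new_x) as.character(predict(fit, new_x))
}

#' Evaluate a marker panel by repeated random splits
#'
#' Repeatedly splits the samples into training and held-out halves
#' (stratified per class), fits the classifier on the training half, and
#' records the held-out accuracy. The default classifier is a linear
#' soft-margin support vector machine with unit cost.
#'
#' @param features Feature [sample_matrix] restricted to the panel
#'   (features x samples).
#' @param labels Binary class labels, one per sample (character, factor
#'   or logical).
#' @param n_splits Number of random splits (default 100).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.5).
#' @param seed RNG seed; identical seed gives identical per-split
#'   accuracies.
#' @param classifier Function `(train_x, train_y)` returning a prediction
#'   function `(new_x) -> labels`; defaults to the linear SVM.
#' @return Object of class `panel_eval` with `mean_accuracy`, `sd`,
#'   `accuracies`, `n_splits`, `seed`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
evaluate_panel <- function(features, labels, n_splits = 100,
                           train_fraction = 0.5, seed = 1,
                           classifier = default_classifier) {
  labels <- as.character(labels)
  x <- t(features)
  if (length(labels) != nrow(x)) {
    abort("One label per sample is required.")
  }
  classes <- unique(labels)
  if (length(classes) != 2) abort("Exactly two classes are required.")
  if (min(table(labels)) < 2) abort("Need at least 2 samples per class.")
  set.seed(seed)
  acc <- numeric(n_splits)
  resampled <- 0L
  for (i in seq_len(n_splits)) {
    repeat {
      train_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        sample(idx, max(1L, round(length(idx) * train_fraction)))
      }))
      test_idx <- setdiff(seq_along(labels), train_idx)
      if (length(unique(labels[train_idx])) == 2 &&
          length(test_idx) > 0) break
      resampled <- resampled + 1L
    }
    predict_fn <- classifier(x[train_idx, , drop = FALSE], labels[train_idx])
    pred <- predict_fn(x[test_idx, , drop = FALSE])
    acc[i] <- mean(pred == labels[test_idx])
  }
  if (resampled > 0) {
    inform(sprintf("%d degenerate split(s) resampled.", resampled))
  }
  structure(
    list(mean_accuracy = mean(acc), sd = sd(acc), accuracies = acc,
         n_splits = n_splits, seed = seed,
         markers = rownames(features)),
    class = "panel_eval"
  )
}

#' @export
print.panel_eval <- function(x, ...) {
  cat(sprintf("<panel_eval: %d markers, mean accuracy %.3f (sd %.3f, %d splits)>\n",
              length(x$markers), x$mean_accuracy, x$sd, x$n_splits))
  invisible(x)
}

#' @rdname evaluate_panel
#' @param x A `panel_eval`.
#' @param ... Unused.
#' @export
tidy.panel_eval <- function(x, ...) {
  tibble(split = seq_len(x$n_splits), accuracy = x$accuracies)
}

#' @rdname evaluate_panel
#' @export
glance.panel_eval <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, sd = x$sd,
         n_splits = x$n_splits, n_markers = length(x$markers),
         seed = x$seed)
}

#' @rdname evaluate_panel
#' @param object A `panel_eval`.
#' @export
autoplot.panel_eval <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "held-out accuracy", y = "splits") +
    ggplot2::theme_minimal()
}

#' Backward-eliminate a panel to a minimum size
#'
#' Starting from `start` probes, repeatedly drops the probe whose removal
#' gives the highest (or least degraded) mean accuracy under
#' [evaluate_panel()], until `min_size` probes remain. Returns the final
#' panel and the full elimination trace.
#'
#' @inheritParams evaluate_panel
#' @param start Character vector of starting probe ids.
#' @param min_size Target panel size (< length of `start`).
#' @return List with `panel` (retained probes) and `trace` (tibble:
#'   `size`, `dropped`, `mean_accuracy`).
#' @export
minimize_panel <- function(features, labels, start, min_size,
                           n_splits = 100, train_fraction = 0.5, seed = 1,
                           classifier = default_classifier) {
  if (min_size >= length(start)) {
    abort("`min_size` must be smaller than the starting panel.")
  }
  panel <- start
  ev <- evaluate_panel(features[panel, , drop = FALSE], labels,
                       n_splits = n_splits,
                       train_fraction = train_fraction, seed = seed,
                       classifier = classifier)
  trace <- list(tibble(size = length(panel), dropped = NA_character_,
                       mean_accuracy = ev$mean_accuracy))
  while (length(panel) > min_size) {
    accs <- vapply(seq_along(panel), function(i) {
      sub <- panel[-i]
      evaluate_panel(features[sub, , drop = FALSE], labels,
                     n_splits = n_splits,
                     train_fraction = train_fraction, seed = seed,
                     classifier = classifier)$mean_accuracy
    }, 0.0)
    best <- which.max(accs)
    dropped <- panel[best]
    panel <- panel[-best]
    trace[[length(trace) + 1L]] <- tibble(
      size = length(panel), dropped = dropped, mean_accuracy = accs[best]
    )
  }
  list(panel = panel, trace = dplyr::bind_rows(trace))
}
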