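#' Threshold-free binary classification metrics
#'
#' Confusion counts and the four headline metrics at a fixed label vector:
#' recall = TP/(TP+FN), precision = TP/(TP+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN) and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TN+FN)(TP+FN)(TN+FP)}}.}
#' A metric whose denominator is zero is reported as 0 and flagged via the
#' `degenerate` column (kept numeric rather than NA so reports always
#' serialize).
#'
#' @param y_true Binary \{0, 1\} vector of reference labels.
#' @param y_pred Binary \{0, 1\} vector of predicted labels, same length.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`, `recall`,
#'   `precision`, `acc`, `mcc`, `degenerate` (logical).
#' @examples
#' binary_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
binary_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  if (length(y_true) < 1) abort("empty label vectors")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) abort("labels must be in {0, 1}")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe_div <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  r <- safe_div(tp, tp + fn)
  p <- safe_div(tp, tp + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tn + fn, tp + fn, tn + fp)))
  m <- if (mcc_den == 0) c(0, TRUE) else c((tp * tn - fp * fn) / mcc_den, FALSE)
  tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    recall = r[1], precision = p[1],
    acc = (tp + tn) / length(y_true),
    mcc = m[1],
    degenerate = any(c(r[2], p[2], m[2]) == 1)
  )
}

#' ROC and precision-recall curves with their areas
#'
#' Sweeps prediction scores from high to low with tie-grouping (all samples
#' sharing a score enter together). The ROC curve collects
#' (false-positive rate, true-positive rate) points and its area is computed
#' by the trapezoid rule; the precision-recall curve collects (recall,
#' precision) points and its area by the step-wise, right-continuous rule
#' (the trapezoid rule is optimistic for precision-recall and is deliberately
#' not used).
#'
#' @param y_true Binary \{0, 1\} labels; both classes must be present.
#' @param scores Real-valued prediction scores, higher = more positive.
#' @return An object of class `ppi_curves`: list with tibbles `roc`
#'   (`threshold`, `fpr`, `tpr`) and `pr` (`threshold`, `recall`,
#'   `precision`), and scalars `auroc`, `auprc`.
#' @examples
#' curves_and_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auroc
#' @export
curves_and_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) abort("y_true and scores lengths differ")
  if (!all(y_true %in% c(0L, 1L))) abort("labels must be in {0, 1}")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present for curves")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  # tie groups share a threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  thr <- s[last]; tp <- tp[last]; fp <- fp[last]
  roc <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  auroc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / n1
  pr <- tibble(threshold = thr, recall = rec, precision = prec)
  auprc <- sum(diff(c(0, rec)) * prec)
  structure(list(roc = roc, pr = pr, auroc = auroc, auprc = auprc),
            class = "ppi_curves")
}

#' @method print ppi_curves
#' @export
print.ppi_curves <- function(x, ...) {
  cat(sprintf("<ppi_curves> AUROC = %.4f, AUPRC = %.4f (%d ROC points)\n",
              x$auroc, x$auprc, nrow(x$roc)))
  invisible(x)
}

#' Full evaluation report for one set of predictions
#'
#' Combines [binary_metrics()] at `threshold` with [curves_and_auc()] on the
#' raw scores.
#'
#' @param y_true Binary \{0, 1\} labels.
#' @param scores Predicted class-1 probabilities (or any monotone score).
#' @param threshold Probability threshold for hard labels.
#' @return A list of class `ppi_eval`: `metrics` (one-row tibble), `curves`
#'   (`ppi_curves`) and `threshold`.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  metrics <- binary_metrics(y_true, as.integer(scores >= threshold))
  curves <- curves_and_auc(y_true, scores)
  metrics$auroc <- curves$auroc
  metrics$auprc <- curves$auprc
  structure(list(metrics = metrics, curves = curves, threshold = threshold),
            class = "ppi_eval")
}

#' @method print ppi_eval
#' @export
print.ppi_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<ppi_eval> acc %.4f | recall %.4f | precision %.4f | mcc %.4f | auroc %.4f | auprc %.4f\n",
              m$acc, m$recall, m$precision, m$mcc, m$auroc, m$auprc))
  invisible(x)
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin over folds, so fold sizes differ by at most one per class.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  if (k < 2) abort("k must be >= 2")
  if (min(table(y)) < k) abort("k exceeds the size of the minority class")
  set.seed(seed)
  fold <- integer(length(y))
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    # continue the deal where the previous class stopped so overall fold
    # sizes stay within one of each other even for unbalanced labels
    fold[idx[sample.int(length(idx))]] <-
      ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Cross-validate the select-then-boost pipeline
#'
#' Stratified k-fold cross-validation over protein pairs. Per-protein
#' encoding is label-free and computed once; within each fold, L1-regularized
#' logistic selection and the gradient-boosting classifier are fitted on the
#' training pairs only and evaluated on the held-out pairs. Splits are over
#' pairs, not proteins, so a protein may contribute features to both sides of
#' a split; this mirrors the common benchmark protocol and is a known
#' caveat, not silently corrected.
#'
#' @param pair_features Output of [encode_pairs()] including a `label`
#'   column; or any feature tibble/matrix plus `labels`.
#' @param labels Optional explicit label vector.
#' @param k Number of folds (default 5).
#' @param C L1 selection trade-off (default 1).
#' @param M,learning_rate,max_depth Boosting parameters (see [train_gtb()]).
#' @param threshold Probability threshold for hard labels.
#' @param seed Master seed; folds and per-fold fits derive from it.
#' @return An object of class `ppi_cv`: `per_fold` (one row of metrics per
#'   fold), `summary` (mean and standard deviation per metric), `fold` (fold
#'   assignment per pair), `support_sizes`, and the per-fold curves.
#' @export
cross_validate <- function(pair_features, labels = NULL, k = 5L, C = 1,
                           M = 1000L, learning_rate = 0.1, max_depth = 3L,
                           threshold = 0.5, seed = 0L) {
  parts <- coerce_xy(pair_features, labels)
  x <- parts$x; y <- parts$y
  fold <- stratified_folds(y, k, seed = seed)
  fold_rows <- vector("list", k)
  curves <- vector("list", k)
  support_sizes <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    sel <- fit_l1rlr(x[tr, , drop = FALSE], y[tr], C = C, seed = seed + f)
    support_sizes[f] <- length(sel$support)
    xtr <- apply_selection(x[tr, , drop = FALSE], sel)
    xte <- apply_selection(x[te, , drop = FALSE], sel)
    gtb <- train_gtb(xtr, y[tr], M = M, learning_rate = learning_rate,
                     max_depth = max_depth, seed = seed + f)
    p <- predict(gtb, xte, type = "prob")
    ev <- evaluate_predictions(y[te], p, threshold = threshold)
    fold_rows[[f]] <- mutate(ev$metrics, fold = f, .before = 1)
    curves[[f]] <- ev$curves
  }
  per_fold <- bind_rows(fold_rows)
  metric_cols <- c("recall", "precision", "acc", "mcc", "auroc", "auprc")
  summary <- tidyr::pivot_longer(per_fold[, c("fold", metric_cols)],
                                 -"fold", names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop") %>%
    mutate(metric = factor(.data$metric, levels = metric_cols)) %>%
    arrange(.data$metric) %>%
    mutate(metric = as.character(.data$metric))
  structure(list(
    per_fold = per_fold,
    summary = summary,
    fold = fold,
    support_sizes = support_sizes,
    curves = curves,
    k = as.integer(k),
    seed = as.integer(seed),
    params = list(C = C, M = M, learning_rate = learning_rate,
                  max_depth = max_depth, threshold = threshold)
  ), class = "ppi_cv")
}

#' @method print ppi_cv
#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("<ppi_cv> %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `ppi_cv` object.
#' @param ... Unused.
#' @export
tidy.ppi_cv <- function(x, ...) x$per_fold

#' @rdname cross_validate
#' @export
glance.ppi_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  bind_cols(tibble(k = x$k, seed = x$seed), wide)
}

#' Plot ROC and precision-recall curves
#'
#' @param object A `ppi_curves`, `ppi_eval` or `ppi_cv` object.
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC curve (AUROC = %.3f)", object$auroc))
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("PR curve (AUPRC = %.3f)", object$auprc))
  }
}

#' @rdname autoplot.ppi_curves
#' @export
autoplot.ppi_eval <- function(object, which = c("roc", "pr"), ...) {
  autoplot(object$curves, which = which, ...)
}

#' @rdname autoplot.ppi_curves
#' @export
autoplot.ppi_cv <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  tabs <- purrr::imap(object$curves, function(cv, f) {
    tab <- if (which == "roc") cv$roc else cv$pr
    mutate(tab, fold = factor(f))
  })
  df <- bind_rows(tabs)
  if (which == "roc") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                     colour = .data$fold)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = "Per-fold ROC curves")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                     colour = .data$fold)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = "Per-fold PR curves")
  }
}
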