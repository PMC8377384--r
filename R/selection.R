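#' L1-regularized logistic-regression feature selection
#'
#' Fits the sparse logistic model
#' \deqn{\min_\omega \|\omega\|_1 + C \sum_i \log(1 + e^{-y_i \omega^\top x_i})}
#' (labels internally mapped \{0,1\} to \{-1,+1\}; unpenalized intercept) and
#' records the support: the columns whose fitted weight exceeds `zero_tol` in
#' magnitude. Larger `C` weakens the relative penalty and admits more
#' features. The optimization is performed by glmnet's coordinate descent;
#' the objective above equals glmnet's binomial objective at
#' `lambda = 1 / (n * C)` up to a positive factor, so the minimizer is the
#' same.
#'
#' @param features A feature tibble (id columns are detected and ignored) or
#'   a numeric matrix.
#' @param labels Binary vector in \{0, 1\}, one per row; both classes must be
#'   present. May be omitted if `features` carries a `label` column.
#' @param C Positive penalty trade-off; default 1.
#' @param zero_tol Weights with absolute value at or below this are treated
#'   as exactly zero (default 1e-8).
#' @param standardize Standardize columns internally before fitting (glmnet
#'   convention); off by default so features enter as encoded.
#' @param seed Integer seed, recorded for provenance (the solver itself is
#'   deterministic).
#' @return An object of class `l1rlr` with fields `C`, `weights`,
#'   `intercept`, `support` (sorted 1-based column indices), `zero_tol`,
#'   `feature_names` (names of supported columns) and `all_names`.
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' y <- as.integer(x[, 1] - x[, 2] + rnorm(100, sd = 0.3) > 0)
#' fit <- fit_l1rlr(x, y, C = 1)
#' fit$support
#' @export
fit_l1rlr <- function(features, labels = NULL, C = 1, zero_tol = 1e-8,
                      standardize = FALSE, seed = 0L) {
  if (C <= 0) abort("C must be positive")
  parts <- coerce_xy(features, labels)
  x <- parts$x; y <- parts$y
  n <- nrow(x)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  if (any(!is.finite(x))) abort("feature matrix contains non-finite values")
  set.seed(seed)
  lambda_target <- 1 / (n * C)
  # Warm-start path down to the target lambda improves coordinate-descent
  # convergence; only the final fit is kept.
  lambda_path <- sort(unique(c(lambda_target * c(64, 16, 4, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambda_path, standardize = standardize,
                        intercept = TRUE, thresh = 1e-12, maxit = 5e5)
  beta <- as.numeric(stats::coef(fit, s = lambda_target, exact = FALSE))
  intercept <- beta[1]
  weights <- beta[-1]
  support <- which(abs(weights) > zero_tol)
  structure(list(
    C = C,
    weights = weights,
    intercept = intercept,
    support = support,
    zero_tol = zero_tol,
    feature_names = colnames(x)[support],
    all_names = colnames(x),
    standardize = standardize,
    seed = as.integer(seed),
    n = n
  ), class = "l1rlr")
}

coerce_xy <- function(features, labels) {
  if (is.matrix(features)) {
    x <- features
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    y <- labels
  } else {
    parts <- feature_parts(features)
    x <- parts$x
    y <- if (is.null(labels) && "label" %in% names(parts$ids)) parts$ids$label else labels
  }
  if (is.null(y)) abort("labels are required (argument or 'label' column)")
  y <- as.integer(y)
  if (length(y) != nrow(x)) abort("labels length must match the number of rows")
  if (!all(y %in% c(0L, 1L))) abort("labels must be in {0, 1}")
  list(x = x, y = y)
}

#' Project a feature table onto a selection model's support
#'
#' @param features Feature tibble or matrix with the same columns, in the
#'   same order, as the matrix the model was fitted on.
#' @param model An `l1rlr` model.
#' @return The input restricted to the supported feature columns (id columns
#'   preserved for tibbles); row order unchanged.
#' @export
apply_selection <- function(features, model) {
  stopifnot(inherits(model, "l1rlr"))
  if (length(model$support) == 0) {
    abort("no features selected (empty support); refusing to emit a 0-column matrix")
  }
  if (is.matrix(features)) {
    if (ncol(features) != length(model$all_names)) {
      abort(sprintf("feature matrix has %d columns; model was fitted on %d",
                    ncol(features), length(model$all_names)))
    }
    return(features[, model$support, drop = FALSE])
  }
  parts <- feature_parts(features)
  if (ncol(parts$x) != length(model$all_names)) {
    abort(sprintf("feature table has %d feature columns; model was fitted on %d",
                  ncol(parts$x), length(model$all_names)))
  }
  bind_cols(parts$ids, as_tibble(parts$x[, model$support, drop = FALSE]))
}

#' @method print l1rlr
#' @export
print.l1rlr <- function(x, ...) {
  cat(sprintf("<l1rlr> C = %g: %d of %d features selected\n",
              x$C, length(x$support), length(x$all_names)))
  invisible(x)
}

#' Tidy an L1-regularized logistic selection model
#'
#' @param x An `l1rlr` object.
#' @param all Include zero-weight features as well.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `index`, `weight`, `selected`.
#' @export
tidy.l1rlr <- function(x, all = FALSE, ...) {
  out <- tibble(
    feature = x$all_names,
    index = seq_along(x$weights),
    weight = x$weights,
    selected = abs(x$weights) > x$zero_tol
  )
  if (!all) out <- filter(out, .data$selected)
  out
}

#' @rdname tidy.l1rlr
#' @export
glance.l1rlr <- function(x, ...) {
  tibble(
    C = x$C,
    n_features = length(x$all_names),
    n_selected = length(x$support),
    intercept = x$intercept,
    n_obs = x$n
  )
}

# Value of the Eq.-style objective ||w||_1 + C * sum log(1 + exp(-y w'x))
# (y in {-1,+1}); used by tests to audit optimality.
l1rlr_objective <- function(x, y01, weights, intercept, C) {
  ypm <- ifelse(y01 == 1, 1, -1)
  eta <- as.numeric(x %*% weights) + intercept
  sum(abs(weights)) + C * sum(log1p(exp(-ypm * eta)))
}

# Max subgradient-optimality violation of the penalized coordinates.
l1rlr_kkt_violation <- function(x, y01, weights, intercept, C) {
  ypm <- ifelse(y01 == 1, 1, -1)
  eta <- as.numeric(x %*% weights) + intercept
  g <- -C * as.numeric(t(x) %*% (ypm * stats::plogis(-ypm * eta)))
  active <- weights != 0
  viol_active <- if (any(active)) max(abs(g[active] + sign(weights[active]))) else 0
  viol_zero <- if (any(!active)) max(pmax(abs(g[!active]) - 1, 0)) else 0
  max(viol_active, viol_zero)
}
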