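#' Gradient tree boosting for binary classification
#'
#' Stagewise additive modelling under the binomial deviance loss
#' \eqn{L(y, F) = -2[y \log p + (1-y)\log(1-p)]}, \eqn{p = 1/(1+e^{-F})}.
#' The score is initialized at the empirical log-odds
#' \eqn{F_0 = \log(\bar y / (1 - \bar y))}. At stage m a regression tree
#' \eqn{h_m} is fitted (rpart, squared-error splitting) to the negative
#' gradient of the loss, the residual \eqn{r_i = y_i - p_i}; each terminal
#' region then receives the one-step Newton value
#' \eqn{b_{jm} = \sum_{i \in R_{jm}} r_i / \sum_{i \in R_{jm}} p_i (1 - p_i)},
#' which solves the per-region line search of the staged objective, and the
#' score is updated \eqn{F_m = F_{m-1} + \nu \, h_m} with learning rate
#' \eqn{\nu}. No subsampling and no early stopping are performed.
#'
#' @param features Feature tibble (id columns detected and ignored) or
#'   numeric matrix.
#' @param labels Binary \{0, 1\} vector, both classes present. May be omitted
#'   if `features` carries a `label` column.
#' @param M Number of boosting iterations (trees); default 1000.
#' @param learning_rate Shrinkage \eqn{\nu > 0}; default 0.1.
#' @param max_depth Maximum depth of each regression tree; default 3.
#' @param seed Integer seed (tree fitting is deterministic; recorded for
#'   provenance and future stochastic variants).
#' @param min_obs Minimum observations in a node for a split to be attempted.
#' @return An object of class `gtb` with the fitted trees, `initial_score`
#'   (\eqn{F_0}), per-stage training deviance (`train_deviance`) and the
#'   training feature names.
#' @examples
#' x <- matrix(c(rnorm(40, -1), rnorm(40, 1)), ncol = 2)
#' y <- rep(c(0L, 1L), each = 20)
#' fit <- train_gtb(x, y, M = 25)
#' mean((predict(fit, x) > 0.5) == y)
#' @export
train_gtb <- function(features, labels = NULL, M = 1000L, learning_rate = 0.1,
                      max_depth = 3L, seed = 0L, min_obs = 2L) {
  if (M < 1) abort("M must be >= 1")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (max_depth < 1) abort("max_depth must be >= 1")
  parts <- coerce_xy(features, labels)
  x <- parts$x; y <- parts$y
  if (any(!is.finite(x))) abort("feature matrix contains non-finite values")
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  set.seed(seed)
  n <- nrow(x)
  feature_names <- colnames(x)
  df <- as.data.frame(x)
  safe_names <- paste0("x", seq_len(ncol(x)))
  names(df) <- safe_names
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0,
                               minsplit = min_obs, minbucket = 1L,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L)
  form <- stats::as.formula(paste(".gtb_resid ~", paste(safe_names, collapse = "+")))

  p_bar <- mean(y)
  f0 <- log(p_bar / (1 - p_bar))
  fx <- rep(f0, n)
  trees <- vector("list", M)
  train_deviance <- numeric(M)
  for (m in seq_len(M)) {
    p <- stats::plogis(fx)
    df$.gtb_resid <- y - p
    tree <- rpart::rpart(form, data = df, method = "anova", control = ctrl)
    leaf_rows <- unique(tree$where)
    num <- tapply(y - p, tree$where, sum)
    den <- tapply(p * (1 - p), tree$where, sum)
    gamma <- num / pmax(den, 1e-12)
    tree$frame$yval <- 0
    tree$frame$yval[leaf_rows] <- gamma[as.character(leaf_rows)]
    fx <- fx + learning_rate * as.vector(gamma[as.character(tree$where)])
    trees[[m]] <- slim_tree(tree)
    p_new <- stats::plogis(fx)
    train_deviance[m] <- binomial_deviance(y, p_new)
  }
  structure(list(
    M = as.integer(M),
    learning_rate = learning_rate,
    max_depth = as.integer(max_depth),
    loss = "deviance",
    initial_score = f0,
    trees = trees,
    train_deviance = train_deviance,
    feature_names = feature_names,
    safe_names = safe_names,
    seed = as.integer(seed),
    n = n
  ), class = "gtb")
}

# Drop training-only baggage so serialized models stay small while
# predict.rpart keeps working.
slim_tree <- function(tree) {
  tree$where <- NULL
  tree$y <- NULL
  tree$call <- NULL
  tree$variable.importance <- NULL
  tree$cptable <- NULL
  tree$functions <- NULL
  attr(tree, "xlevels") <- NULL
  tree$model <- NULL
  tree
}

binomial_deviance <- function(y, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Additive score F_M(x) for a fitted model.
gtb_score <- function(object, x) {
  if (ncol(x) != length(object$feature_names)) {
    abort(sprintf("feature matrix has %d columns; model was trained on %d",
                  ncol(x), length(object$feature_names)))
  }
  df <- as.data.frame(x)
  names(df) <- object$safe_names
  fx <- rep(object$initial_score, nrow(x))
  for (tree in object$trees) {
    fx <- fx + object$learning_rate * unname(predict(tree, newdata = df))
  }
  fx
}

#' Predict interaction probabilities or labels from a boosted model
#'
#' @param object A `gtb` model.
#' @param features Feature tibble or matrix with the training columns.
#' @param type `"prob"` for class-1 probabilities (logistic transform of the
#'   additive score), `"label"` for thresholded \{0, 1\} labels, `"score"`
#'   for the raw additive score \eqn{F_M(x)}.
#' @param threshold Probability threshold in (0, 1) for `type = "label"`;
#'   a prediction is 1 iff its probability is >= `threshold`.
#' @param ... Unused.
#' @return Numeric (prob/score) or integer (label) vector, one value per row.
#' @export
predict.gtb <- function(object, features, type = c("prob", "label", "score"),
                        threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- if (is.matrix(features)) features else feature_parts(features)$x
  fx <- gtb_score(object, x)
  if (type == "score") return(fx)
  p <- stats::plogis(fx)
  if (type == "prob") return(p)
  if (!(threshold > 0 && threshold < 1)) abort("threshold must be in (0, 1)")
  as.integer(p >= threshold)
}

#' @method print gtb
#' @export
print.gtb <- function(x, ...) {
  cat(sprintf("<gtb> %d trees (depth <= %d, nu = %g, deviance loss); final training deviance %.4f\n",
              x$M, x$max_depth, x$learning_rate,
              x$train_deviance[x$M]))
  invisible(x)
}

#' Tidy and glance methods for boosted models
#'
#' `tidy()` returns the per-stage training deviance trace; `glance()`
#' one-row model summary.
#'
#' @param x A `gtb` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gtb <- function(x, ...) {
  tibble(stage = seq_len(x$M), train_deviance = x$train_deviance)
}

#' @rdname tidy.gtb
#' @export
glance.gtb <- function(x, ...) {
  tibble(
    M = x$M,
    learning_rate = x$learning_rate,
    max_depth = x$max_depth,
    loss = x$loss,
    initial_score = x$initial_score,
    final_train_deviance = x$train_deviance[x$M],
    n_obs = x$n
  )
}
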