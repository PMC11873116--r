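# Classifiers: random forest (compiled CART backend), forward
# stepwise-AIC logistic regression, and the transfer-learning style
# classifier head on a frozen convolutional backbone.

#' Assemble a feature dataset for classification
#'
#' @param x numeric feature matrix (one row per subject).
#' @param labels factor/character vector of class labels (`"PD"`/`"HC"`);
#'   `"PD"` is the positive class.
#' @param subject_ids unique subject identifiers (one row per subject —
#'   the identity-independence contract of all evaluations).
#' @return A list of class `"FeatureDataset"` with `x`, `y` (0/1),
#'   `labels`, `subject_ids`, `feature_names`.
#' @export
featureDataset <- function(x, labels, subject_ids = rownames(x)) {
  x <- as.matrix(x)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(subject_ids)) stop("one row per subject required (duplicated subject_ids)")
  if (length(labels) != nrow(x)) stop("labels must match rows")
  y <- as.integer(labels == "PD")
  structure(list(x = x, y = y, labels = labels,
                 subject_ids = as.character(subject_ids),
                 feature_names = colnames(x)),
            class = "FeatureDataset")
}

#' Classifier hyperparameter specification
#'
#' Defaults are the study's printed settings: random forest with 1000
#' trees, 6 candidate variables per split and terminal node minimum size
#' 5; forward stepwise-AIC logistic regression; classifier head trained
#' with adam (learning rate 0.001), 10 epochs, batch size 4, dropout 0.2.
#'
#' @param kind `"random_forest"`, `"stepwise_lr"` or `"cnn_head"`.
#' @param ... overrides of the defaults listed above (`n_trees`,
#'   `vars_per_split`, `min_node`; `epochs`, `batch_size`, `dropout`,
#'   `lr`, `hidden`, `backbone`).
#' @return A list of class `"ModelSpec"`.
#' @export
modelSpec <- function(kind = c("random_forest", "stepwise_lr", "cnn_head"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(n_trees = 1000L, vars_per_split = 6L, min_node = 5L),
    stepwise_lr = list(max_steps = Inf),
    cnn_head = list(epochs = 10L, batch_size = 4L, dropout = 0.2, lr = 0.001,
                    hidden = 1024L, backbone = "tiny-random"))
  spec <- utils::modifyList(defaults, list(...))
  spec$kind <- kind
  structure(spec, class = "ModelSpec")
}

#' Fit a random forest classifier
#'
#' Breiman's algorithm (bootstrap-aggregated CART with Gini splits over
#' `vars_per_split` random candidate features) via the package's compiled
#' backend. When the feature count is below `vars_per_split`, the latter
#' falls back to `ceiling(sqrt(p))`.
#'
#' @param train a `FeatureDataset` with at least 10 rows and both classes.
#' @param spec a `ModelSpec` of kind `"random_forest"`.
#' @param seed integer seed (NULL = current RNG).
#' @return List of class `"rfModel"` with the fitted forest, an
#'   `importance` data.frame (mean decrease Gini per feature, all
#'   non-negative) and `predict` usable via [predictModel()].
#' @export
fitRandomForest <- function(train, spec = modelSpec("random_forest"),
                            seed = NULL) {
  stopifnot(inherits(train, "FeatureDataset"))
  if (nrow(train$x) < 10L) stop("need at least 10 training rows")
  if (length(unique(train$y)) < 2L) stop("single-class training set")
  mtry <- if (ncol(train$x) < spec$vars_per_split)
    as.integer(ceiling(sqrt(ncol(train$x)))) else as.integer(spec$vars_per_split)
  fit <- withSeed(seed,
    .rf_fit(train$x, as.integer(train$y), as.integer(spec$n_trees), mtry,
            as.integer(spec$min_node)))
  imp <- data.frame(feature = train$feature_names,
                    importance = as.numeric(fit$importance),
                    method = "mean_decrease_gini",
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$importance), ]
  structure(list(forest = fit, importance = imp,
                 feature_names = train$feature_names),
            class = "rfModel")
}

#' Fit a forward stepwise-AIC logistic regression
#'
#' Starting from the intercept-only model, the feature whose addition
#' minimizes the AIC is added at each step; selection stops when no
#' addition improves the AIC, and the final model is refit on the full
#' training split. Under (quasi-)perfect separation the fit falls back to
#' a ridge-penalized logistic model and is flagged.
#'
#' @param train a `FeatureDataset` with at least 12 rows and both classes.
#' @param seed unused (the procedure is deterministic); kept for a uniform
#'   classifier interface.
#' @return List of class `"lrModel"` with `selected` (feature names in
#'   inclusion order), `fit` and `separation_flagged`.
#' @export
fitLogisticStepwise <- function(train, seed = NULL) {
  stopifnot(inherits(train, "FeatureDataset"))
  n <- nrow(train$x)
  if (n < 12L) stop("need at least 12 rows for 3-fold-feasible stepwise selection")
  if (length(unique(train$y)) < 2L) stop("single-class training set")
  x <- train$x
  y <- train$y
  p <- ncol(x)
  selected <- integer(0)
  aicOf <- function(cols) {
    df <- data.frame(y = y, x[, cols, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(), data = df))
    list(aic = stats::AIC(fit), fit = fit)
  }
  cur <- aicOf(integer(0))
  best_aic <- cur$aic
  repeat {
    cand <- setdiff(seq_len(p), selected)
    if (!length(cand)) break
    aics <- vapply(cand, function(j) aicOf(c(selected, j))$aic, numeric(1))
    j <- cand[which.min(aics)]
    if (min(aics) >= best_aic - 1e-8) break
    selected <- c(selected, j)
    best_aic <- min(aics)
  }
  final <- aicOf(selected)
  separated <- !final$fit$converged ||
    any(abs(stats::fitted(final$fit) - 0.5) > 0.5 - 1e-8)
  ridge <- NULL
  if (separated && length(selected) >= 1L) {
    xm <- x[, selected, drop = FALSE]
    if (ncol(xm) == 1L) xm <- cbind(xm, 0)
    ridge <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                            lambda = 1e-2)
  }
  structure(list(selected = train$feature_names[selected],
                 selected_idx = selected, fit = final$fit, ridge = ridge,
                 separation_flagged = separated,
                 feature_names = train$feature_names),
            class = "lrModel")
}

#' Predict class-1 (PD) probability scores
#'
#' @param model a fitted `rfModel`, `lrModel` or `cnnModel`.
#' @param newdata a `FeatureDataset`/matrix (feature models) or an
#'   `ImageDataset` (cnn).
#' @return Numeric scores in `[0, 1]`.
#' @export
predictModel <- function(model, newdata) {
  UseMethod("predictModel")
}

#' @export
predictModel.rfModel <- function(model, newdata) {
  x <- if (inherits(newdata, "FeatureDataset")) newdata$x else as.matrix(newdata)
  as.numeric(.rf_predict(model$forest, x))
}

#' @export
predictModel.lrModel <- function(model, newdata) {
  x <- if (inherits(newdata, "FeatureDataset")) newdata$x else as.matrix(newdata)
  if (!is.null(model$ridge)) {
    xm <- x[, model$selected_idx, drop = FALSE]
    if (ncol(xm) == 1L) xm <- cbind(xm, 0)
    return(as.numeric(stats::predict(model$ridge, xm, type = "response")))
  }
  df <- data.frame(x[, model$selected_idx, drop = FALSE])
  if (!length(model$selected_idx)) df <- data.frame(row.names = seq_len(nrow(x)))
  as.numeric(suppressWarnings(stats::predict(model$fit, newdata = df,
                                             type = "response")))
}
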