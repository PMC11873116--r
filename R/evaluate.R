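# Repeated-holdout evaluation, rank-statistic AUC, Monte-Carlo Shapley
# importance and AUC-distribution comparison.

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with mid-rank tie handling: the probability
#' that a random positive outscores a random negative, ties counting 1/2.
#' Invariant to any strictly monotone transform of the scores.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or `"HC"`/`"PD"`) labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucScore(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels) else as.integer(labels == "PD")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated-holdout evaluation of a classifier
#'
#' Randomly splits the dataset into `train_frac` training and the rest
#' testing at the subject level (no subject appears on both sides;
#' splits are simple random, matching the evaluated protocol — a
#' stratified option exists behind `stratified`), fits the model of
#' `spec` on the training part and computes the held-out AUC;
#' repeated `n_iter` times. A split leaving one side single-class is
#' resampled (and counted in `resampled`).
#'
#' @param ds a `FeatureDataset` or `ImageDataset`.
#' @param spec a `ModelSpec`.
#' @param n_iter number of random splits (default 100).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed; iteration seeds are derived from it.
#' @param stratified logical, stratify splits by class (default FALSE).
#' @param keep_last logical, keep the final iteration's fitted model (for
#'   importance inspection).
#' @return An [EvalResult-class]; attribute `last_model` when
#'   `keep_last`, attribute `resampled` with the resample count.
#' @export
repeatedHoldout <- function(ds, spec, n_iter = 100L, train_frac = 0.7,
                            seed = 1L, stratified = FALSE, keep_last = FALSE) {
  is_img <- inherits(ds, "ImageDataset")
  if (!is_img && !inherits(ds, "FeatureDataset"))
    stop("'ds' must be a FeatureDataset or ImageDataset")
  n <- length(ds$y)
  subsetDs <- function(idx) {
    if (is_img)
      structure(list(images = ds$images[idx, , , drop = FALSE],
                     y = ds$y[idx], labels = ds$labels[idx],
                     subject_ids = ds$subject_ids[idx]),
                class = "ImageDataset")
    else
      structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                     labels = ds$labels[idx],
                     subject_ids = ds$subject_ids[idx],
                     feature_names = ds$feature_names),
                class = "FeatureDataset")
  }
  n_train <- round(train_frac * n)
  aucs <- numeric(n_iter)
  seeds <- integer(n_iter)
  resampled <- 0L
  last_model <- NULL
  for (it in seq_len(n_iter)) {
    it_seed <- stageSeed(seed, paste0("holdout", it))
    seeds[it] <- it_seed
    idx_train <- withSeed(it_seed, {
      tries <- 0L
      repeat {
        tr <- if (stratified) {
          c(sample(which(ds$y == 1L), round(train_frac * sum(ds$y == 1L))),
            sample(which(ds$y == 0L), round(train_frac * sum(ds$y == 0L))))
        } else sample.int(n, n_train)
        te <- setdiff(seq_len(n), tr)
        if (length(unique(ds$y[tr])) == 2L &&
            length(unique(ds$y[te])) == 2L) break
        tries <- tries + 1L
        resampled <- resampled + 1L
        if (tries > 1000L) stop("could not draw a two-class split")
      }
      tr
    })
    idx_test <- setdiff(seq_len(n), idx_train)
    stopifnot(length(intersect(ds$subject_ids[idx_train],
                               ds$subject_ids[idx_test])) == 0L)
    train <- subsetDs(idx_train)
    test <- subsetDs(idx_test)
    model <- switch(spec$kind,
      random_forest = fitRandomForest(train, spec, seed = it_seed),
      stepwise_lr = fitLogisticStepwise(train, seed = it_seed),
      cnn_head = fitCnnHead(train, spec, seed = it_seed))
    aucs[it] <- aucScore(predictModel(model, test), test$y)
    if (keep_last && it == n_iter) last_model <- model
  }
  res <- new("EvalResult", auc = aucs, seeds = as.numeric(seeds),
             model = spec$kind, n_train = n_train, n_test = n - n_train)
  attr(res, "resampled") <- resampled
  if (keep_last) attr(res, "last_model") <- last_model
  res
}

#' Monte-Carlo Shapley feature importance
#'
#' Permutation-sampling estimate of Shapley values for each observation
#' (Strumbelj-Kononenko style): for each of `n_samples` draws a random
#' feature permutation and a random reference row are taken, and the
#' marginal contribution of each feature to the model score is
#' accumulated. The importance table reports the mean absolute Shapley
#' value per feature across observations; per-observation values are
#' returned in the `shap` attribute.
#'
#' @param model a fitted model accepted by [predictModel()].
#' @param data a `FeatureDataset` (rows to explain; also the reference
#'   distribution).
#' @param n_samples Monte-Carlo samples per observation (>= 10; default
#'   100).
#' @param seed integer seed.
#' @return data.frame `feature`, `importance` (mean |SHAP|), `method`;
#'   attributes `shap` (observations x features matrix) and `baseline`.
#' @export
shapImportance <- function(model, data, n_samples = 100L, seed = 1L) {
  stopifnot(inherits(data, "FeatureDataset"))
  if (n_samples < 10L) stop("'n_samples' must be >= 10")
  X <- data$x
  n <- nrow(X); p <- ncol(X)
  phi <- matrix(0, n, p)
  withSeed(seed, {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(p)
      ref <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
      # walk the permutation: switch features from reference to actual
      cur <- ref
      prev_score <- predictModel(model, cur)
      for (j in perm) {
        cur[, j] <- X[, j]
        new_score <- predictModel(model, cur)
        phi[, j] <- phi[, j] + (new_score - prev_score)
        prev_score <- new_score
      }
    }
  })
  phi <- phi / n_samples
  out <- data.frame(feature = data$feature_names,
                    importance = colMeans(abs(phi)),
                    method = "mean_abs_shap", stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  attr(out, "shap") <- phi
  attr(out, "baseline") <- mean(predictModel(model, X))
  out
}

#' Compare two AUC distributions (Wilcoxon rank-sum)
#'
#' Two-sided unpaired Wilcoxon rank-sum test on the per-iteration AUC
#' samples (exact for small samples without ties, normal approximation
#' with tie correction otherwise). A paired signed-rank option is
#' provided for evaluations sharing identical splits.
#'
#' @param a,b [EvalResult-class] objects (or numeric AUC vectors).
#' @param paired logical, use the signed-rank test (default FALSE).
#' @return List: `p_value`, `statistic`, `method`.
#' @export
compareAucDistributions <- function(a, b, paired = FALSE) {
  va <- if (is(a, "EvalResult")) a@auc else as.numeric(a)
  vb <- if (is(b, "EvalResult")) b@auc else as.numeric(b)
  if (!length(va) || !length(vb)) stop("empty AUC sample")
  ht <- suppressWarnings(stats::wilcox.test(va, vb, paired = paired,
                                            exact = NULL))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       method = ht$method)
}
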