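# Classifiers and the evaluation harness.

plantedData <- function(n = 60L, p = 33L, seed = 1L, signal_col = 5L,
                        noise_sd = 0.1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2L)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, signal_col] <- y + stats::rnorm(n, 0, noise_sd)
  colnames(X) <- paste0("f", seq_len(p))
  featureDataset(X, ifelse(y == 1L, "PD", "HC"))
}

test_that("AUC rank statistic handles separation, ties and pairs", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  # brute-force concordant pairs: (0.9,0.3) pos vs (0.8,0.2) neg -> 3/4
  expect_equal(aucScore(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(aucScore(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(5)
  s <- stats::runif(40)
  y <- rep(c(1, 0), 20)
  expect_equal(aucScore(s, y), aucScore(exp(3 * s) + 2, y))  # monotone invariance
})

test_that("random forest finds a planted signal feature", {
  hits <- 0L
  for (r in 1:20) {
    ds <- plantedData(seed = r)
    m <- fitRandomForest(ds, seed = r)
    expect_true(all(m$importance$importance >= 0))
    expect_setequal(m$importance$feature, ds$feature_names)
    if (m$importance$feature[1L] == "f5") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # memorization sanity on separable data
  ds <- plantedData(seed = 99, noise_sd = 0.05)
  m <- fitRandomForest(ds, seed = 1)
  expect_gte(aucScore(predictModel(m, ds), ds$y), 0.99)
  expect_error(fitRandomForest(featureDataset(ds$x[1:8, ], ds$labels[1:8],
                                              ds$subject_ids[1:8])),
               "10")
  one_class <- featureDataset(ds$x[1:12, ], rep("PD", 12),
                              ds$subject_ids[1:12])
  expect_error(fitRandomForest(one_class), "single-class")
})

test_that("label permutation drives held-out RF AUC to chance", {
  set.seed(17)
  n <- 60L
  X <- matrix(stats::rnorm(n * 33L), n, 33L)
  colnames(X) <- paste0("f", 1:33)
  ds <- featureDataset(X, sample(rep(c("PD", "HC"), each = 30L)))
  ev <- repeatedHoldout(ds, modelSpec("random_forest"), n_iter = 20L, seed = 3L)
  expect_length(aucValues(ev), 20L)
  expect_gte(mean(aucValues(ev)), 0.4)
  expect_lte(mean(aucValues(ev)), 0.6)
})

test_that("repeated holdout is deterministic under its seed", {
  ds <- plantedData(seed = 23, noise_sd = 0.5)
  e1 <- repeatedHoldout(ds, modelSpec("random_forest", n_trees = 200L),
                        n_iter = 5L, seed = 7L)
  e2 <- repeatedHoldout(ds, modelSpec("random_forest", n_trees = 200L),
                        n_iter = 5L, seed = 7L)
  expect_identical(aucValues(e1), aucValues(e2))
  expect_s4_class(e1, "EvalResult")
  expect_equal(summary(e1)$n_iter, 5L)
})

test_that("forward stepwise-AIC logistic regression selects the signal", {
  hits <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    y <- rep(c(1L, 0L), each = 24L)
    X <- matrix(stats::rnorm(48L * 10L), 48L, 10L)
    X[, 3L] <- 2 * y + stats::rnorm(48L, 0, 0.5)
    colnames(X) <- paste0("g", 1:10)
    m <- fitLogisticStepwise(featureDataset(X, ifelse(y == 1, "PD", "HC")))
    if ("g3" %in% m$selected) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # null features: selection stays small on average
  sizes <- vapply(1:10, function(r) {
    set.seed(200 + r)
    X <- matrix(stats::rnorm(48L * 10L), 48L, 10L)
    colnames(X) <- paste0("g", 1:10)
    length(fitLogisticStepwise(
      featureDataset(X, rep(c("PD", "HC"), 24L)))$selected)
  }, numeric(1))
  expect_lte(mean(sizes), 2)
  small <- featureDataset(matrix(stats::rnorm(20), 10, 2,
                                 dimnames = list(NULL, c("a", "b"))),
                          rep(c("PD", "HC"), 5))
  expect_error(fitLogisticStepwise(small), "12")
})

test_that("Monte-Carlo Shapley attribution respects additive structure", {
  # a transparent additive scorer stands in for a fitted model
  predictModel.additiveToy <<- function(model, newdata) {
    x <- if (inherits(newdata, "FeatureDataset")) newdata$x else as.matrix(newdata)
    0.6 * x[, 1L] + 0.2 * x[, 2L] + 0 * x[, 3L]
  }
  on.exit(rm("predictModel.additiveToy", envir = globalenv()), add = TRUE)
  toy <- structure(list(), class = "additiveToy")
  set.seed(31)
  X <- matrix(stats::runif(150 * 3), 150, 3,
              dimnames = list(NULL, c("a", "b", "nul")))
  ds <- featureDataset(X, rep(c("PD", "HC"), 75))
  imp <- shapImportance(toy, ds, n_samples = 200L, seed = 2L)
  tab <- stats::setNames(imp$importance, imp$feature)
  expect_lt(tab["nul"], 0.01)                       # ignored feature
  expect_lt(abs(tab["a"] / tab["b"] - 3), 0.6)      # coefficient ratio 3 +/- 20%
  # efficiency: per-observation attributions sum to score - baseline
  # (up to Monte-Carlo error of the reference draws)
  phi <- attr(imp, "shap")
  resid <- rowSums(phi) - (predictModel(toy, ds) - attr(imp, "baseline"))
  expect_lt(mean(abs(resid)), 0.02)
  expect_lt(max(abs(resid)), 0.1)
  expect_error(shapImportance(toy, ds, n_samples = 5L), "10")
})

test_that("Wilcoxon AUC comparison behaves at the extremes", {
  set.seed(41)
  a <- stats::rnorm(100, 0.95, 0.03)
  expect_gte(compareAucDistributions(a, a)$p_value, 0.99)
  expect_lt(compareAucDistributions(a + 1, a)$p_value, 1e-10)
  expect_error(compareAucDistributions(numeric(0), a), "empty")
})

test_that("the classifier head learns separable images and reports history", {
  set.seed(51)
  n <- 40L
  mkimg <- function(shift) {
    m <- matrix(stats::rnorm(128 * 128, 0, 0.05), 128, 128)
    m[(40:50) + shift, ] <- m[(40:50) + shift, ] + 0.8
    pmin(pmax(m, 0), 1)
  }
  y <- rep(c(1L, 0L), each = n / 2L)
  imgs <- array(0, c(n, 128L, 128L))
  for (i in seq_len(n)) imgs[i, , ] <- mkimg(if (y[i] == 1L) 12L else 0L)
  ds <- structure(list(images = imgs, y = y,
                       labels = ifelse(y == 1L, "PD", "HC"),
                       subject_ids = paste0("S", seq_len(n))),
                  class = "ImageDataset")
  # frozen backbone is deterministic
  f1 <- backboneFeatures(ds)
  f2 <- backboneFeatures(ds)
  expect_identical(f1, f2)
  ev <- repeatedHoldout(ds, modelSpec("cnn_head"), n_iter = 1L, seed = 9L,
                        keep_last = TRUE)
  expect_gte(aucValues(ev), 0.8)
  hist <- attr(ev, "last_model")$history
  expect_equal(nrow(hist), 10L)
  expect_lt(hist$train_loss[10L], hist$train_loss[1L])
})
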