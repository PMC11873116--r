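# Transfer-learning style image classifier: a frozen convolutional
# backbone feeding a trainable multilayer-perceptron head
# (batch normalization -> dense 1024 relu -> dense 1024 relu ->
# dropout 0.2 -> dense 2 softmax), trained with adam. The pretrained
# Inception backbone of the original recipe is pluggable but unavailable
# offline; the shipped "tiny-random" backbone is a fixed-seed random
# convolutional feature extractor (random convolutional features are a
# classical strong baseline) accepting 128 x 128 inputs.

#' Assemble an image dataset from spectrogram matrices
#'
#' Each matrix is clamped to `[-80, 0]`, mapped to `[0, 1]` and bilinearly
#' resized to `size x size` (frequency vertical, low frequencies at the
#' bottom), giving the normalized single-channel images the classifier
#' head consumes.
#'
#' @param mats list of [SpectrogramMatrix-class] objects (one per subject).
#' @param labels class labels (`"PD"`/`"HC"`).
#' @param subject_ids unique subject identifiers.
#' @param size image side length (default 128, the tiny-random backbone
#'   input size).
#' @return List of class `"ImageDataset"`: `images` (n x size x size
#'   array in `[0, 1]`), `y`, `labels`, `subject_ids`.
#' @export
imageDataset <- function(mats, labels, subject_ids = NULL, size = 128L) {
  n <- length(mats)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  if (anyDuplicated(subject_ids)) stop("one image per subject required")
  imgs <- array(0, dim = c(n, size, size))
  for (i in seq_len(n)) {
    v <- pmin(pmax(mats[[i]]@values, -80), 0) / 80 + 1
    imgs[i, , ] <- resizeBilinear(t(v)[rev(seq_len(ncol(v))), , drop = FALSE],
                                  size, size)
  }
  structure(list(images = imgs, y = as.integer(labels == "PD"),
                 labels = labels, subject_ids = as.character(subject_ids)),
            class = "ImageDataset")
}

# 2-D valid convolution with stride, via patch matrix multiplication.
# img: H x W x Cin array; W_k: (k*k*Cin) x Cout; returns H' x W' x Cout.
convStride <- function(img, W_k, k, stride) {
  d <- dim(img)
  H <- d[1L]; Wd <- d[2L]; Cin <- d[3L]
  Ho <- (H - k) %/% stride + 1L
  Wo <- (Wd - k) %/% stride + 1L
  ri <- (seq_len(Ho) - 1L) * stride
  ci <- (seq_len(Wo) - 1L) * stride
  patches <- matrix(0, nrow = Ho * Wo, ncol = k * k * Cin)
  col <- 0L
  for (c0 in seq_len(Cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    col <- col + 1L
    patches[, col] <- img[outer(ri + di, ci + dj,
                                function(r, c) r + (c - 1L) * H) +
                          (c0 - 1L) * H * Wd]
  }
  out <- patches %*% W_k
  array(out, dim = c(Ho, Wo, ncol(W_k)))
}

avgPool <- function(x, k) {
  d <- dim(x)
  Ho <- d[1L] %/% k; Wo <- d[2L] %/% k
  out <- array(0, dim = c(Ho, Wo, d[3L]))
  for (c0 in seq_len(d[3L])) {
    m <- x[seq_len(Ho * k), seq_len(Wo * k), c0]
    m <- matrix(colMeans(matrix(m, nrow = k)), nrow = Ho)       # pool rows
    m <- t(matrix(colMeans(matrix(t(m), nrow = k)), nrow = Wo)) # pool cols
    out[, , c0] <- m
  }
  out
}

# Fixed-seed random convolutional backbone: conv(3x3, 1->8, stride 2),
# relu, conv(3x3, 8->16, stride 2), relu, 4x4 average pooling, flatten.
# 128x128 input -> 63x63x8 -> 31x31x16 -> 7x7x16 = 784 features.
tinyBackboneWeights <- function() {
  env <- .pkgCache
  if (is.null(env$tiny_backbone)) {
    env$tiny_backbone <- withSeed(190355L, list(
      W1 = matrix(stats::rnorm(9 * 8, sd = sqrt(2 / 9)), nrow = 9),
      W2 = matrix(stats::rnorm(9 * 8 * 16, sd = sqrt(2 / (9 * 8))), nrow = 9 * 8)
    ))
  }
  env$tiny_backbone
}

.pkgCache <- new.env(parent = emptyenv())

#' Extract frozen-backbone features from an image dataset
#'
#' @param ds an `ImageDataset` (128 x 128 images for the default
#'   backbone).
#' @param backbone `"tiny-random"` (shipped) — a fixed-seed random
#'   convolutional feature extractor whose weights never train.
#' @return n x 784 feature matrix.
#' @export
backboneFeatures <- function(ds, backbone = "tiny-random") {
  stopifnot(inherits(ds, "ImageDataset"))
  if (!identical(backbone, "tiny-random"))
    stop("only the 'tiny-random' backbone is available in this build")
  wts <- tinyBackboneWeights()
  n <- dim(ds$images)[1L]
  feats <- NULL
  for (i in seq_len(n)) {
    img <- array(ds$images[i, , ], dim = c(dim(ds$images)[2:3], 1L))
    h1 <- pmax(convStride(img, wts$W1, 3L, 2L), 0)
    h2 <- pmax(convStride(h1, wts$W2, 3L, 2L), 0)
    f <- as.numeric(avgPool(h2, 4L))
    if (is.null(feats)) feats <- matrix(0, nrow = n, ncol = length(f))
    feats[i, ] <- f
  }
  feats
}

# --- MLP head with batchnorm, two relu layers, dropout, softmax ---

adamStep <- function(state, g, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$w <- state$w - lr * mhat / (sqrt(vhat) + eps)
  state
}

newParam <- function(w) list(w = w, m = w * 0, v = w * 0)

#' Train the classifier head on frozen backbone features
#'
#' The head is batch normalization, two 1024-node relu dense layers,
#' 20% dropout and a 2-class softmax output, trained with cross-entropy
#' and the adam optimizer (initial learning rate 0.001) for 10 epochs at
#' batch size 4 — only the head trains; the backbone stays frozen.
#'
#' @param train an `ImageDataset`.
#' @param spec a `ModelSpec` of kind `"cnn_head"`.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param validation optional `ImageDataset` whose loss is recorded per
#'   epoch.
#' @return List of class `"cnnModel"` with the trained head, the backbone
#'   id and a `history` data.frame (per-epoch training and validation
#'   loss).
#' @export
fitCnnHead <- function(train, spec = modelSpec("cnn_head"), seed = NULL,
                       validation = NULL) {
  stopifnot(inherits(train, "ImageDataset"))
  if (length(unique(train$y)) < 2L) stop("need both classes to train")
  X <- backboneFeatures(train, spec$backbone)
  y <- train$y
  Xval <- if (!is.null(validation)) backboneFeatures(validation, spec$backbone)
  withSeed(seed, {
    d <- ncol(X); h <- spec$hidden
    par <- list(
      gamma = newParam(rep(1, d)), beta = newParam(rep(0, d)),
      W1 = newParam(matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)),
      b1 = newParam(rep(0, h)),
      W2 = newParam(matrix(stats::rnorm(h * h, sd = sqrt(2 / h)), h, h)),
      b2 = newParam(rep(0, h)),
      W3 = newParam(matrix(stats::rnorm(h * 2, sd = sqrt(2 / h)), h, 2)),
      b3 = newParam(rep(0, 2)))
    run_mean <- rep(0, d); run_var <- rep(1, d)
    eps <- 1e-5; mom <- 0.9
    t_step <- 0L
    n <- nrow(X)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    forward <- function(Xb, training, drop_mask = NULL) {
      if (training) {
        mu <- colMeans(Xb)
        va <- colMeans(sweep(Xb, 2, mu)^2)
      } else { mu <- run_mean; va <- run_var }
      xhat <- sweep(sweep(Xb, 2, mu), 2, sqrt(va + eps), "/")
      z0 <- sweep(sweep(xhat, 2, par$gamma$w, "*"), 2, par$beta$w, "+")
      a1 <- pmax(sweep(z0 %*% par$W1$w, 2, par$b1$w, "+"), 0)
      a2 <- pmax(sweep(a1 %*% par$W2$w, 2, par$b2$w, "+"), 0)
      a2d <- if (training && !is.null(drop_mask)) a2 * drop_mask else a2
      logits <- sweep(a2d %*% par$W3$w, 2, par$b3$w, "+")
      pr <- exp(logits - apply(logits, 1, max))
      pr <- pr / rowSums(pr)
      list(mu = mu, va = va, xhat = xhat, z0 = z0, a1 = a1, a2 = a2,
           a2d = a2d, prob = pr)
    }
    meanLoss <- function(Xb, yb) {
      f <- forward(Xb, training = FALSE)
      -mean(log(pmax(f$prob[cbind(seq_along(yb), yb + 1L)], 1e-12)))
    }
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = spec$batch_size)) {
        rows <- ord[b0:min(b0 + spec$batch_size - 1L, n)]
        if (length(rows) < 2L) next  # batch statistics need > 1 row
        Xb <- X[rows, , drop = FALSE]
        yb <- y[rows]
        m <- length(rows)
        mask <- matrix(stats::rbinom(m * h, 1L, 1 - spec$dropout), m, h) /
          (1 - spec$dropout)
        f <- forward(Xb, training = TRUE, drop_mask = mask)
        run_mean <- mom * run_mean + (1 - mom) * f$mu
        run_var <- mom * run_var + (1 - mom) * f$va
        Y1 <- cbind(1 - yb, yb)
        losses <- c(losses,
                    -mean(log(pmax(f$prob[cbind(seq_len(m), yb + 1L)], 1e-12))))
        dlog <- (f$prob - Y1) / m
        gW3 <- crossprod(f$a2d, dlog); gb3 <- colSums(dlog)
        da2 <- (dlog %*% t(par$W3$w)) * mask
        da2[f$a2 <= 0] <- 0
        gW2 <- crossprod(f$a1, da2); gb2 <- colSums(da2)
        da1 <- da2 %*% t(par$W2$w)
        da1[f$a1 <= 0] <- 0
        gW1 <- crossprod(f$z0, da1); gb1 <- colSums(da1)
        dz0 <- da1 %*% t(par$W1$w)
        ggamma <- colSums(dz0 * f$xhat); gbeta <- colSums(dz0)
        t_step <- t_step + 1L
        par$W3 <- adamStep(par$W3, gW3, spec$lr, t_step)
        par$b3 <- adamStep(par$b3, gb3, spec$lr, t_step)
        par$W2 <- adamStep(par$W2, gW2, spec$lr, t_step)
        par$b2 <- adamStep(par$b2, gb2, spec$lr, t_step)
        par$W1 <- adamStep(par$W1, gW1, spec$lr, t_step)
        par$b1 <- adamStep(par$b1, gb1, spec$lr, t_step)
        par$gamma <- adamStep(par$gamma, ggamma, spec$lr, t_step)
        par$beta <- adamStep(par$beta, gbeta, spec$lr, t_step)
      }
      val_loss <- if (!is.null(Xval)) {
        fv <- forward(Xval, training = FALSE)
        -mean(log(pmax(fv$prob[cbind(seq_along(validation$y),
                                     validation$y + 1L)], 1e-12)))
      } else NA_real_
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_loss = val_loss))
    }
    structure(list(par = lapply(par, `[[`, "w"), run_mean = run_mean,
                   run_var = run_var, eps = eps, backbone = spec$backbone,
                   history = history),
              class = "cnnModel")
  })
}

#' @export
predictModel.cnnModel <- function(model, newdata) {
  stopifnot(inherits(newdata, "ImageDataset"))
  X <- backboneFeatures(newdata, model$backbone)
  p <- model$par
  xhat <- sweep(sweep(X, 2, model$run_mean), 2,
                sqrt(model$run_var + model$eps), "/")
  z0 <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  a1 <- pmax(sweep(z0 %*% p$W1, 2, p$b1, "+"), 0)
  a2 <- pmax(sweep(a1 %*% p$W2, 2, p$b2, "+"), 0)
  logits <- sweep(a2 %*% p$W3, 2, p$b3, "+")
  pr <- exp(logits - apply(logits, 1, max))
  pr <- pr / rowSums(pr)
  as.numeric(pr[, 2L])
}
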