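## Feed-forward binary classifier: three fully connected ReLU layers with
## inverted dropout between layers and a sigmoid output, trained by Adam on
## binary cross-entropy with L2 regularisation.

mlp_init <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialisation, suited to ReLU
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout = 0, train = FALSE) {
  L <- length(par$W)
  A <- list(X); masks <- vector("list", L)
  H <- X
  for (l in seq_len(L - 1)) {
    Z <- sweep(H %*% par$W[[l]], 2, par$b[[l]], `+`)
    H <- pmax(Z, 0)
    if (train && dropout > 0) {
      m <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                  nrow(H), ncol(H))
      H <- H * m
      masks[[l]] <- m
    }
    A[[l + 1]] <- H
  }
  Zout <- sweep(H %*% par$W[[L]], 2, par$b[[L]], `+`)
  p <- stats::plogis(as.numeric(Zout))
  list(p = p, A = A, masks = masks)
}

#' Train the feed-forward transition network
#'
#' Fixed architecture: three fully connected hidden layers of 256 units with
#' ReLU activations, inverted dropout between layers, and a single sigmoid
#' output unit giving the transition probability. Training minimises binary
#' cross-entropy plus an L2 weight penalty with Adam on mini-batches. The
#' hyperparameter grid varies the regularisation strength, learning rate and
#' epoch count; when several combinations are given, the best by F1 on an
#' internal stratified 20% validation split is refit on all data.
#'
#' Continuous features are standardised internally (training means/SDs are
#' stored and re-applied at prediction).
#'
#' @param x Numeric feature data frame or matrix.
#' @param y Binary 0/1 labels.
#' @param grid Data frame or list of lists with columns/fields `reg`, `lr`,
#'   `epochs`. Default a single combination (reg 1e-4, lr 1e-3, 20 epochs).
#' @param hidden Hidden layer sizes (default `c(256, 256, 256)`).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param batch_size Mini-batch size.
#' @param seed RNG seed.
#' @return An object of class `dmt_mlp` with a `predict()` method returning
#'   probabilities in (0, 1).
#' @export
train_feedforward <- function(x, y, grid = NULL, hidden = c(256L, 256L, 256L),
                              dropout = 0.2, batch_size = 64L, seed = 1L) {
  if (dropout < 0 || dropout >= 1)
    stopf("dropout must be in [0,1): a rate of 1 drops every unit")
  if (length(unique(y)) < 2) stopf("training labels are single-class")
  X <- as.matrix(x); storage.mode(X) <- "double"
  if (is.null(grid)) grid <- list(list(reg = 1e-4, lr = 1e-3, epochs = 20L))
  if (is.data.frame(grid)) grid <- split(grid, seq_len(nrow(grid)))
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  set.seed(seed)
  if (length(grid) > 1) {
    # stratified 80/20 internal validation for grid selection
    val <- unlist(lapply(split(seq_along(y), y),
                         function(ix) sample(ix, max(1, round(0.2 * length(ix))))))
    best <- NULL; best_f1 <- -Inf
    for (g in grid) {
      par <- mlp_fit_one(Xs[-val, , drop = FALSE], y[-val], g, hidden,
                         dropout, batch_size)
      p <- mlp_forward(par, Xs[val, , drop = FALSE])$p
      f1 <- classification_metrics(y[val], p)$f1
      if (f1 > best_f1) { best_f1 <- f1; best <- g }
    }
    grid <- list(best)
  }
  g <- grid[[1]]
  par <- mlp_fit_one(Xs, y, g, hidden, dropout, batch_size)
  structure(list(par = par, center = ctr, scale = scl, config = g,
                 hidden = hidden, dropout = dropout,
                 features = colnames(X)),
            class = "dmt_mlp")
}

mlp_fit_one <- function(Xs, y, g, hidden, dropout, batch_size) {
  n <- nrow(Xs)
  par <- mlp_init(ncol(Xs), hidden)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(g$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, n)]
      Xb <- Xs[ix, , drop = FALSE]; yb <- y[ix]
      fw <- mlp_forward(par, Xb, dropout, train = TRUE)
      if (!all(is.finite(fw$p)))
        stopf("non-finite activations at epoch %d (lr=%g): reduce the learning rate",
              ep, g$lr)
      m <- length(ix)
      delta <- matrix((fw$p - yb) / m, m, 1)  # dL/dz_out for sigmoid + BCE
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in seq(L, 1)) {
        H <- fw$A[[l]]
        gW[[l]] <- crossprod(H, delta) + 2 * g$reg * par$W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(par$W[[l]])
          if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
          delta <- delta * (fw$A[[l]] > 0)
        }
      }
      t <- t + 1
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
        mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
        par$W[[l]] <- par$W[[l]] - g$lr * mhW / (sqrt(vhW) + eps)
        par$b[[l]] <- par$b[[l]] - g$lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  par
}

#' @export
predict.dmt_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  Xs <- scale(X, object$center, object$scale)
  p <- mlp_forward(object$par, Xs)$p
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
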