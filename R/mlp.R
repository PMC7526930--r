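#' Multi-layer perceptron configuration
#'
#' Defaults: one hidden layer of 10 sigmoid units, linear output, learning
#' rate 0.01, 500 epochs of seeded mini-batch gradient descent on squared
#' error. Inputs are expected on the \[0, 1\] scale; targets stay on the raw
#' 0–100 efficiency scale.
#'
#' @param hidden Hidden-layer size.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size (capped at the number of rows).
#' @param momentum Classical momentum coefficient in \[0, 1); at the default
#'   step size a plain first-order update moves too slowly to converge
#'   within the epoch budget, so velocity accumulation is on by default.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 10L, learning_rate = 0.01, epochs = 500L,
                       batch_size = 16L, momentum = 0.9, seed = 1L) {
  stopifnot(hidden >= 1, learning_rate > 0, epochs >= 1, batch_size >= 1,
            momentum >= 0, momentum < 1)
  structure(list(hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 momentum = momentum,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a multi-layer perceptron regressor
#'
#' Feed-forward network with one sigmoid hidden layer and a linear output
#' unit, trained by mini-batch gradient descent on mean squared error. The
#' output bias is initialized at the target mean so early updates fit
#' deviations, not the level. Fully deterministic given the config seed.
#'
#' @param x Feature matrix (rows scaled to \[0, 1\]).
#' @param y Target vector (efficiency, percent).
#' @param config An [mlp_config()].
#' @return Object of class `c("mlp_model", "regressor")` holding the weight
#'   matrices and the per-epoch training-loss trace.
#' @export
fit_mlp <- function(x, y, config = mlp_config()) {
  dat <- check_xy(x, y)
  x <- dat$x; y <- dat$y
  n <- nrow(x); d <- ncol(x); h <- config$hidden
  set.seed(config$seed)
  lim <- sqrt(6 / (d + h))
  w1 <- matrix(stats::runif(d * h, -lim, lim), d, h)
  b1 <- numeric(h)
  # zero output weights: the net starts at the target mean, so a constant
  # target is fit exactly from the first step
  w2 <- matrix(0, h, 1)
  b2 <- mean(y)
  bs <- min(config$batch_size, n)
  lr <- config$learning_rate
  mom <- config$momentum
  vw1 <- matrix(0, d, h); vb1 <- numeric(h)
  vw2 <- matrix(0, h, 1); vb2 <- 0
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- x[idx, , drop = FALSE]
      a1 <- sigmoid(xb %*% w1 + rep(b1, each = length(idx)))
      err <- (a1 %*% w2 + b2) - y[idx]          # batch x 1
      m <- length(idx)
      gw2 <- crossprod(a1, err) / m
      gb2 <- mean(err)
      delta <- (err %*% t(w2)) * a1 * (1 - a1)  # batch x h
      gw1 <- crossprod(xb, delta) / m
      gb1 <- colMeans(delta)
      vw2 <- mom * vw2 - lr * gw2; vb2 <- mom * vb2 - lr * gb2
      vw1 <- mom * vw1 - lr * gw1; vb1 <- mom * vb1 - lr * gb1
      w2 <- w2 + vw2; b2 <- b2 + vb2
      w1 <- w1 + vw1; b1 <- b1 + vb1
    }
    pred <- mlp_forward(x, w1, b1, w2, b2)
    losses[epoch] <- mean((pred - y)^2)
    if (!is.finite(losses[epoch])) {
      stop("MLP training diverged (non-finite loss); reduce learning_rate",
           call. = FALSE)
    }
  }
  structure(
    list(kind = "mlp", w1 = w1, b1 = b1, w2 = w2, b2 = b2,
         n_inputs = d, config = config, losses = losses),
    class = c("mlp_model", "regressor")
  )
}

mlp_forward <- function(x, w1, b1, w2, b2) {
  a1 <- sigmoid(x %*% w1 + rep(b1, each = nrow(x)))
  as.numeric(a1 %*% w2 + b2)
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- check_newdata(newdata, object$n_inputs)
  mlp_forward(x, object$w1, object$b1, object$w2, object$b2)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-1 sigmoid/linear, %d epochs, final MSE %.4g\n",
              x$n_inputs, x$config$hidden, x$config$epochs,
              utils::tail(x$losses, 1)))
  invisible(x)
}
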