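#' ANFIS (Takagi–Sugeno) configuration
#'
#' First-order Takagi–Sugeno fuzzy system with Gaussian membership
#' functions, product t-norm firing strengths, and linear rule consequents.
#' A grid partition over 11 inputs would need at least 2^11 rules, so the
#' rule base is generated by fuzzy clustering instead: one rule per k-means
#' cluster (4 by default), each with its own center and width vector.
#'
#' @param rules Number of fuzzy rules (clusters).
#' @param epochs Hybrid-learning epochs (consequents by least squares with
#'   premises fixed, premises by gradient descent, alternating).
#' @param premise_lr Initial gradient step for premise parameters; adapted
#'   (halved on a rejected step) so the recorded loss never increases.
#' @param ridge Ridge penalty on the consequent solve; the default (0.1)
#'   keeps the rules-x-(inputs+1) least-squares problem well conditioned on
#'   databases of tens of rows and is negligible at hundreds of rows.
#' @param seed Integer seed for the cluster initialization.
#' @return A list of class `anfis_config`.
#' @export
anfis_config <- function(rules = 4L, epochs = 100L, premise_lr = 0.05,
                         ridge = 0.1, seed = 1L) {
  stopifnot(rules >= 1, epochs >= 1, premise_lr > 0, ridge > 0)
  structure(list(rules = as.integer(rules), epochs = as.integer(epochs),
                 premise_lr = premise_lr, ridge = ridge,
                 seed = as.integer(seed)),
            class = "anfis_config")
}

# Normalized firing strengths, computed in log space so a sample far from
# every cluster renormalizes cleanly instead of dividing by zero.
anfis_firing <- function(x, centers, sigma) {
  n <- nrow(x); r <- nrow(centers)
  logw <- matrix(0, n, r)
  for (k in seq_len(r)) {
    dev <- sweep(x, 2, centers[k, ])
    logw[, k] <- -rowSums(sweep(dev^2, 2, 2 * sigma[k, ]^2, "/"))
  }
  shifted <- exp(logw - apply(logw, 1, max))
  list(wbar = shifted / rowSums(shifted), logw = logw)
}

# Weighted consequent design matrix: columns w_r * (x, 1) per rule.
anfis_design <- function(x, wbar) {
  n <- nrow(x); d <- ncol(x); r <- ncol(wbar)
  z <- matrix(0, n, r * (d + 1))
  for (k in seq_len(r)) {
    z[, (k - 1) * (d + 1) + seq_len(d + 1)] <- wbar[, k] * cbind(x, 1)
  }
  z
}

anfis_solve_consequents <- function(x, y, wbar, ridge) {
  z <- anfis_design(x, wbar)
  p <- ncol(z)
  aug <- rbind(z, sqrt(ridge) * diag(p))
  qr.coef(qr(aug), c(y, numeric(p)))
}

anfis_predict_inner <- function(x, centers, sigma, theta) {
  wbar <- anfis_firing(x, centers, sigma)$wbar
  list(pred = as.numeric(anfis_design(x, wbar) %*% theta), wbar = wbar)
}

# Rule outputs g_r(x) = a_r . x + b_r for every sample.
anfis_rule_outputs <- function(x, theta, r) {
  d <- ncol(x)
  vapply(seq_len(r), function(k) {
    coef <- theta[(k - 1) * (d + 1) + seq_len(d + 1)]
    as.numeric(cbind(x, 1) %*% coef)
  }, numeric(nrow(x)))
}

#' Fit a first-order Takagi–Sugeno ANFIS regressor
#'
#' Hybrid learning: with premises (Gaussian membership centers and widths)
#' fixed, the linear consequents have a closed-form least-squares solution;
#' premises are then moved one gradient step against the training MSE. A
#' premise step that would raise the loss is rejected and the step size is
#' halved, so the per-epoch loss trace is non-increasing by construction.
#'
#' @inheritParams fit_mlp
#' @param config An [anfis_config()].
#' @return Object of class `c("anfis_model", "regressor")` with the rule
#'   centers, widths, consequent coefficients and loss trace.
#' @export
fit_anfis <- function(x, y, config = anfis_config()) {
  dat <- check_xy(x, y)
  x <- dat$x; y <- dat$y
  n <- nrow(x); d <- ncol(x); r <- config$rules
  set.seed(config$seed)
  centers <- if (r == 1) {
    matrix(colMeans(x), 1, d)
  } else {
    distinct <- unique(x)
    if (nrow(distinct) < r) {
      stop("fewer distinct rows than fuzzy rules", call. = FALSE)
    }
    suppressWarnings(stats::kmeans(x, centers = r, nstart = 5, iter.max = 200))$centers
  }
  sigma <- matrix(pmax(apply(x, 2, stats::sd), 0.25), r, d, byrow = TRUE)
  lr <- config$premise_lr
  theta <- anfis_solve_consequents(
    x, y, anfis_firing(x, centers, sigma)$wbar, config$ridge)
  cur <- anfis_predict_inner(x, centers, sigma, theta)
  loss <- mean((cur$pred - y)^2)
  losses <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    g <- anfis_rule_outputs(x, theta, r)
    err <- cur$pred - y
    common <- err * cur$wbar * (g - cur$pred)   # n x r
    gc_ <- matrix(0, r, d); gs_ <- matrix(0, r, d)
    for (k in seq_len(r)) {
      dev <- sweep(x, 2, centers[k, ])          # x - c_k
      gc_[k, ] <- colSums(common[, k] * sweep(dev, 2, sigma[k, ]^2, "/")) * 2 / n
      gs_[k, ] <- colSums(common[, k] * sweep(dev^2, 2, sigma[k, ]^3, "/")) * 2 / n
    }
    new_centers <- centers - lr * gc_
    new_sigma <- pmax(sigma - lr * gs_, 0.05)
    new_theta <- anfis_solve_consequents(
      x, y, anfis_firing(x, new_centers, new_sigma)$wbar, config$ridge)
    new_cur <- anfis_predict_inner(x, new_centers, new_sigma, new_theta)
    new_loss <- mean((new_cur$pred - y)^2)
    if (is.finite(new_loss) && new_loss <= loss) {
      centers <- new_centers; sigma <- new_sigma
      theta <- new_theta; cur <- new_cur; loss <- new_loss
    } else {
      lr <- lr / 2
    }
    losses[epoch] <- loss
  }
  structure(
    list(kind = "anfis", centers = centers, sigma = sigma, theta = theta,
         n_inputs = d, config = config, losses = losses),
    class = c("anfis_model", "regressor")
  )
}

#' @export
predict.anfis_model <- function(object, newdata, ...) {
  x <- check_newdata(newdata, object$n_inputs)
  anfis_predict_inner(x, object$centers, object$sigma, object$theta)$pred
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("<anfis_model> %d Takagi-Sugeno rules, %d epochs, final MSE %.4g\n",
              nrow(x$centers), x$config$epochs, utils::tail(x$losses, 1)))
  invisible(x)
}
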