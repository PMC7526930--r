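#' Radial basis function network configuration
#'
#' Defaults: 15 Gaussian centers placed by seeded k-means, a common basis
#' width from the mean nearest-center distance, and ridge-regularized
#' linear output weights (penalty 1e-6).
#'
#' Two width rules are available. `"nearest"` (default) sets \eqn{\sigma}
#' to `width_factor` times the mean distance from each center to its
#' nearest other center, which keeps basis activations well scaled in any
#' input dimension. `"maxdist"` is the classical
#' \eqn{\sigma = d_{max}/\sqrt{2c}} rule (largest pairwise center
#' distance); it is appropriate for centers strung along one or two
#' dimensions but collapses to near-zero activations when 11-dimensional
#' centers are mutually far apart, producing huge ill-conditioned weights
#' and wild off-data predictions.
#'
#' @param centers Number of basis centers (must not exceed the number of
#'   distinct training rows).
#' @param width_rule `"nearest"` or `"maxdist"` (see above).
#' @param width_factor Multiplier on the rule's width.
#' @param ridge Ridge penalty on the output weights.
#' @param seed Integer seed for the k-means placement.
#' @param centers_matrix Optional explicit center matrix; bypasses k-means
#'   (used e.g. to place one center on every training point, in which case
#'   the network interpolates the data as ridge tends to zero).
#' @return A list of class `rbf_config`.
#' @export
rbf_config <- function(centers = 15L, width_rule = c("nearest", "maxdist"),
                       width_factor = 1, ridge = 1e-6, seed = 1L,
                       centers_matrix = NULL) {
  width_rule <- match.arg(width_rule)
  stopifnot(centers >= 1, ridge > 0, width_factor > 0)
  structure(list(centers = as.integer(centers), width_rule = width_rule,
                 width_factor = width_factor, ridge = ridge,
                 seed = as.integer(seed), centers_matrix = centers_matrix),
            class = "rbf_config")
}

# Basis width from the center geometry; degenerate layouts fall back to 1.
rbf_width <- function(centers, rule) {
  if (nrow(centers) < 2) return(1)
  d2 <- cross_dist2(centers, centers)
  sigma <- if (rule == "maxdist") {
    sqrt(max(d2)) / sqrt(2 * nrow(centers))
  } else {
    diag(d2) <- Inf
    mean(sqrt(apply(d2, 1, min)))
  }
  if (sigma > 0) sigma else 1
}

# Squared Euclidean cross-distances between rows of a and b.
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Fit a radial basis function network regressor
#'
#' Centers come from seeded k-means on the features; all bases share a
#' width set by the configured rule (see [rbf_config()]); output weights
#' (plus an intercept) solve a ridge-regularized least-squares problem in
#' closed form, so the recorded training loss is a single exact value.
#'
#' @inheritParams fit_mlp
#' @param config An [rbf_config()].
#' @return Object of class `c("rbf_model", "regressor")`.
#' @export
fit_rbf <- function(x, y, config = rbf_config()) {
  dat <- check_xy(x, y)
  x <- dat$x; y <- dat$y
  if (is.null(config$centers_matrix)) {
    distinct <- unique(x)
    if (config$centers > nrow(distinct)) {
      stop(sprintf(
        "degenerate training set: %d centers requested but only %d distinct rows",
        config$centers, nrow(distinct)), call. = FALSE)
    }
    centers <- if (config$centers == nrow(distinct)) {
      distinct
    } else {
      set.seed(config$seed)
      suppressWarnings(stats::kmeans(x, centers = config$centers, nstart = 5,
                                     iter.max = 200))$centers
    }
  } else {
    centers <- rbind(as.matrix(config$centers_matrix))
    if (ncol(centers) != ncol(x)) {
      stop("centers_matrix width does not match the features", call. = FALSE)
    }
  }
  c_n <- nrow(centers)
  sigma <- rbf_width(centers, config$width_rule) * config$width_factor
  phi <- cbind(exp(-cross_dist2(x, centers) / (2 * sigma^2)), 1)
  # ridge solve via the augmented least-squares system
  aug <- rbind(phi, sqrt(config$ridge) * diag(c_n + 1))
  w <- qr.coef(qr(aug), c(y, numeric(c_n + 1)))
  pred <- as.numeric(phi %*% w)
  structure(
    list(kind = "rbf", centers = centers, sigma = sigma, weights = w,
         n_inputs = ncol(x), config = config,
         losses = mean((pred - y)^2)),
    class = c("rbf_model", "regressor")
  )
}

#' @export
predict.rbf_model <- function(object, newdata, ...) {
  x <- check_newdata(newdata, object$n_inputs)
  phi <- cbind(exp(-cross_dist2(x, object$centers) / (2 * object$sigma^2)), 1)
  as.numeric(phi %*% object$weights)
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("<rbf_model> %d Gaussian centers, sigma %.4g, training MSE %.4g\n",
              nrow(x$centers), x$sigma, x$losses))
  invisible(x)
}
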