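#' Goodness-of-fit metrics for efficiency predictions
#'
#' Computes the three criteria used throughout the package to judge a model
#' on a data split: the coefficient of determination
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2} (one minus the ratio
#' of residual to total sum of squares, not a squared correlation), the root
#' mean square error, and the mean bias error \eqn{MBE = mean(\hat y - y)}
#' (positive when the model over-predicts). RMSE and MBE are in percentage
#' points of transformation efficiency.
#'
#' @param observed Numeric vector of observed efficiencies.
#' @param predicted Numeric vector of predictions, same length.
#' @param split Optional split label ("training", "testing", "validation").
#' @return One-row tibble: `split`, `r2`, `rmse`, `mbe`, `n`.
#' @examples
#' fit_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
fit_metrics <- function(observed, predicted, split = NA_character_) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have the same length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("need at least two observations", call. = FALSE)
  }
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("metrics require finite values", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("R-squared is undefined for constant observations; returning NA",
            call. = FALSE)
  }
  resid <- predicted - observed
  tibble::tibble(
    split = split,
    r2 = if (sst > 0) 1 - sum(resid^2) / sst else NA_real_,
    rmse = sqrt(mean(resid^2)),
    mbe = mean(resid),
    n = length(observed)
  )
}

# Shared input check for the regressor fitters.
check_xy <- function(x, y, min_rows = 2) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (nrow(x) < min_rows) {
    stop("need at least ", min_rows, " training rows", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("training data must be finite", call. = FALSE)
  }
  list(x = x, y = y)
}

# Check prediction input against a trained model's input width.
check_newdata <- function(x, d) {
  x <- rbind(as.matrix(x))
  storage.mode(x) <- "double"
  if (ncol(x) != d) {
    stop(sprintf("model expects %d feature columns, got %d", d, ncol(x)),
         call. = FALSE)
  }
  x
}
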