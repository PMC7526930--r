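#' Variable sensitivity error (VSE)
#'
#' RMSE of the ensemble when one input variable is "removed". Under the
#' default `"mean"` policy the variable's column is replaced by its
#' training-set mean (no retraining); `"identity"` replaces the column by
#' itself (a no-op, so VSE equals the full-model RMSE exactly — used to
#' calibrate the ratio); `"retrain"` refits the ensemble without the column.
#'
#' @param ensemble A `bagged_ensemble`.
#' @param x Evaluation features (scaled); by convention the full dataset.
#' @param y Observed efficiencies for `x`.
#' @param variable Name (or index) of the feature to remove.
#' @param policy `"mean"`, `"identity"`, or `"retrain"`.
#' @param train_x Features whose column means define the substitution value
#'   (defaults to `x`).
#' @param ... Passed to [fit_bagged_ensemble()] under the retrain policy.
#' @return The VSE (percentage points).
#' @export
variable_sensitivity <- function(ensemble, x, y, variable,
                                 policy = c("mean", "identity", "retrain"),
                                 train_x = x, ...) {
  policy <- match.arg(policy)
  x <- rbind(as.matrix(x))
  j <- if (is.character(variable)) match(variable, colnames(x)) else variable
  if (is.na(j) || j < 1 || j > ncol(x)) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (policy == "retrain") {
    refit <- fit_bagged_ensemble(train_x[, -j, drop = FALSE],
                                 y_train_for_retrain(ensemble, ...),
                                 B = ensemble$B, seed = ensemble$seed, ...)
    pred <- predict(refit, x[, -j, drop = FALSE])
  } else {
    xm <- x
    if (policy == "mean") xm[, j] <- mean(rbind(as.matrix(train_x))[, j])
    pred <- predict(ensemble, xm)
  }
  sqrt(mean((pred - y)^2))
}

# The retrain policy needs the original training targets; they are passed
# through ... as `retrain_y` to keep the common signature slim.
y_train_for_retrain <- function(ensemble, retrain_y = NULL, ...) {
  if (is.null(retrain_y)) {
    stop("retrain policy requires retrain_y (original training targets)",
         call. = FALSE)
  }
  retrain_y
}

#' Variable-sensitivity-ratio report
#'
#' For every input variable, computes the VSE (RMSE with that variable
#' removed), the VSR (VSE divided by the full-model RMSE with all inputs
#' available), and an importance rank: rank 1 is the largest VSR, ties
#' broken by the canonical variable order.
#'
#' @inheritParams variable_sensitivity
#' @param variables Variable names; defaults to the column names of `x`.
#' @return Tibble of class `sensitivity_report`: `variable`, `vse`, `vsr`,
#'   `rank`, with the full-model RMSE and policy as attributes.
#' @export
vsr_report <- function(ensemble, x, y, policy = c("mean", "identity", "retrain"),
                       train_x = x, variables = NULL, ...) {
  policy <- match.arg(policy)
  x <- rbind(as.matrix(x))
  if (is.null(variables)) variables <- colnames(x)
  if (is.null(variables)) variables <- paste0("x", seq_len(ncol(x)))
  full_rmse <- sqrt(mean((predict(ensemble, x) - y)^2))
  if (full_rmse == 0) {
    stop("full-model RMSE is zero; VSR is undefined for a degenerate fit",
         call. = FALSE)
  }
  vse <- vapply(seq_along(variables), function(j) {
    variable_sensitivity(ensemble, x, y, j, policy, train_x, ...)
  }, numeric(1))
  vsr <- vse / full_rmse
  rank <- integer(length(vsr))
  rank[order(-vsr, seq_along(vsr))] <- seq_along(vsr)
  out <- tibble::tibble(variable = variables, vse = vse, vsr = vsr,
                        rank = rank)
  structure(out, class = c("sensitivity_report", class(out)),
            full_rmse = full_rmse, policy = policy)
}

#' @rdname vsr_report
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @export
glance.sensitivity_report <- function(object, ...) {
  tibble::tibble(full_rmse = attr(object, "full_rmse"),
                 policy = attr(object, "policy"),
                 top_variable = object$variable[object$rank == 1])
}

#' Importance bar chart for a sensitivity report
#'
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @return A ggplot object of VSR by variable, ordered by rank.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$rank)
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vsr, y = .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Variable sensitivity ratio (VSE / full-model RMSE)",
                  y = NULL, title = "Input importance by sensitivity analysis") +
    ggplot2::theme_minimal()
}
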