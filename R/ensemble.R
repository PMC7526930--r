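#' Stack per-model predictions into an estimation matrix
#'
#' Evaluates every trained model on the same features and binds the
#' predictions column-wise: entry (i, j) is model j's estimate for row i.
#' This matrix is the input to fusion.
#'
#' @param models Named list of trained regressors (or bags of regressors;
#'   a bag contributes the mean over its refits).
#' @param x Feature matrix on the training encoding.
#' @return n x m numeric matrix with one column per model.
#' @export
stack_predictions <- function(models, x) {
  if (length(models) < 1) stop("need at least one model", call. = FALSE)
  cols <- lapply(models, function(m) {
    if (inherits(m, "regressor")) predict(m, x) else bag_predict(m, x)
  })
  lens <- lengths(cols)
  if (length(unique(lens)) != 1) {
    stop("models disagree on prediction length; were they trained on the ",
         "same encoding?", call. = FALSE)
  }
  out <- do.call(cbind, cols)
  colnames(out) <- if (!is.null(names(models))) names(models)
                   else paste0("model", seq_along(models))
  if (!all(is.finite(out))) stop("non-finite predictions", call. = FALSE)
  out
}

# Mean prediction over a bag (list) of refit models.
bag_predict <- function(bag, x) {
  n <- nrow(rbind(x))
  preds <- vapply(bag, function(m) predict(m, x), numeric(n))
  rowMeans(matrix(preds, nrow = n))
}

# Derive a per-refit seed from the ensemble seed (kept well below 2^31).
bag_seed <- function(seed, kind_index, b) {
  (seed %% 1000000L) * 1000L + kind_index * 101L + b
}

#' Fit the bagged three-member ensemble
#'
#' For each member kind (MLP, RBF network, ANFIS) draws `B` bootstrap
#' resamples of the training rows and refits the member on each; a member's
#' prediction is the mean over its `B` refits, and the fused prediction is
#' a convex combination of the member predictions, so it always lies inside
#' the members' min–max envelope.
#'
#' Under the default `"inverse_error"` fusion each member's weight is the
#' reciprocal of its out-of-bag mean squared error (each refit predicts the
#' training rows left out of its bootstrap sample), so the fusion leans on
#' the members that generalize best — fusing the members' best-resulted
#' outputs rather than treating unequal learners equally. `"uniform"` gives
#' the plain unweighted mean; it is also used whenever no out-of-bag rows
#' exist (`bag = FALSE`).
#'
#' @param x Training features (scaled).
#' @param y Training targets (efficiency, percent).
#' @param member_configs Named list with elements `mlp`, `rbf`, `anfis`
#'   giving each member's config; defaults to the package defaults.
#' @param B Bootstrap replicates per member (>= 1).
#' @param seed Integer seed driving resampling and every refit.
#' @param bag If `FALSE`, skip resampling and fit each member once on the
#'   full sample (degenerate bagging; the fusion is then the plain mean of
#'   the three single-model predictions).
#' @param fusion `"inverse_error"` (default) or `"uniform"`.
#' @return Object of class `bagged_ensemble` (fields: `members`, `weights`,
#'   `oob_mse`, `fusion`, `B`, `seed`).
#' @export
fit_bagged_ensemble <- function(x, y,
                                member_configs = list(
                                  mlp = mlp_config(),
                                  rbf = rbf_config(),
                                  anfis = anfis_config()),
                                B = 25L, seed = 1L, bag = TRUE,
                                fusion = c("inverse_error", "uniform")) {
  fusion <- match.arg(fusion)
  dat <- check_xy(x, y)
  x <- dat$x; y <- dat$y
  stopifnot(B >= 1)
  fitters <- list(mlp = fit_mlp, rbf = fit_rbf, anfis = fit_anfis)
  if (!all(names(member_configs) %in% names(fitters))) {
    stop("member_configs must be named among mlp/rbf/anfis", call. = FALSE)
  }
  n <- nrow(x)
  fitted <- purrr::imap(member_configs, function(cfg, kind) {
    kind_index <- match(kind, names(fitters))
    fits <- lapply(seq_len(B), function(b) {
      s <- bag_seed(seed, kind_index, b)
      if (bag) {
        idx <- NULL
        for (try in 1:20) {
          idx <- withr_seed(s + 7919L * try,
                            sample.int(n, n, replace = TRUE))
          if (nrow(unique(x[idx, , drop = FALSE])) >= 2) break
          idx <- NULL
        }
        if (is.null(idx)) {
          stop("could not draw a bootstrap sample with 2 distinct rows",
               call. = FALSE)
        }
      } else {
        idx <- seq_len(n)
      }
      cfg$seed <- s
      list(model = fitters[[kind]](x[idx, , drop = FALSE], y[idx], cfg),
           idx = idx)
    })
    # out-of-bag MSE: every refit predicts the rows its bootstrap missed
    oob_sum <- numeric(n); oob_cnt <- integer(n)
    if (bag) {
      for (f in fits) {
        out <- setdiff(seq_len(n), unique(f$idx))
        if (length(out) > 0) {
          oob_sum[out] <- oob_sum[out] +
            predict(f$model, x[out, , drop = FALSE])
          oob_cnt[out] <- oob_cnt[out] + 1L
        }
      }
    }
    covered <- oob_cnt > 0
    oob_mse <- if (any(covered)) {
      mean((oob_sum[covered] / oob_cnt[covered] - y[covered])^2)
    } else NA_real_
    list(bag = lapply(fits, `[[`, "model"), oob_mse = oob_mse)
  })
  members <- lapply(fitted, `[[`, "bag")
  oob_mse <- vapply(fitted, `[[`, numeric(1), "oob_mse")
  weights <- if (fusion == "inverse_error" && !anyNA(oob_mse)) {
    w <- 1 / pmax(oob_mse, 1e-12)
    w / sum(w)
  } else {
    rep(1 / length(members), length(members))
  }
  names(weights) <- names(members)
  structure(list(members = members, weights = weights, oob_mse = oob_mse,
                 fusion = fusion, B = as.integer(B), seed = as.integer(seed)),
            class = "bagged_ensemble")
}

#' Predict from a bagged ensemble
#'
#' @param object A `bagged_ensemble`.
#' @param newdata Feature matrix on the training encoding.
#' @param type `"fused"` (default) for the weighted mean across members,
#'   `"members"` for the per-member bagged predictions (n x m matrix).
#' @param ... Unused.
#' @return Numeric vector (fused) or matrix (members).
#' @export
predict.bagged_ensemble <- function(object, newdata,
                                    type = c("fused", "members"), ...) {
  type <- match.arg(type)
  n <- nrow(rbind(newdata))
  per_member <- vapply(object$members, function(bag) bag_predict(bag, newdata),
                       numeric(n))
  per_member <- matrix(per_member, nrow = n,
                       dimnames = list(NULL, names(object$members)))
  if (type == "members") per_member
  else as.numeric(per_member %*% object$weights)
}

#' @export
print.bagged_ensemble <- function(x, ...) {
  cat(sprintf("<bagged_ensemble> members: %s; B = %d bootstrap refits each\n",
              paste(names(x$members), collapse = ", "), x$B))
  cat(sprintf("  fusion %s; weights %s\n", x$fusion,
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = " ")))
  invisible(x)
}

#' Metrics for every member and the fused ensemble on the three splits
#'
#' @param ensemble A `bagged_ensemble`.
#' @param dataset An `encoded_dataset`.
#' @param split A `data_split` on the same dataset.
#' @return Tibble with one row per model x split: `model`, `split`, `r2`,
#'   `rmse`, `mbe`, `n` (the 12-cell performance table).
#' @export
ensemble_metrics <- function(ensemble, dataset, split) {
  splits <- list(training = split$training, testing = split$testing,
                 validation = split$validation)
  purrr::map_dfr(names(splits), function(sname) {
    idx <- splits[[sname]]
    xs <- dataset$features[idx, , drop = FALSE]
    ys <- dataset$targets[idx]
    members <- predict(ensemble, xs, type = "members")
    fused <- as.numeric(members %*% ensemble$weights)
    dplyr::bind_rows(
      purrr::map_dfr(colnames(members), function(m) {
        dplyr::mutate(fit_metrics(ys, members[, m], sname),
                      model = m, .before = 1)
      }),
      dplyr::mutate(fit_metrics(ys, fused, sname),
                    model = "ensemble", .before = 1)
    )
  })
}

#' @rdname predict.bagged_ensemble
#' @param x A `bagged_ensemble`.
#' @export
glance.bagged_ensemble <- function(x, ...) {
  tibble::tibble(members = length(x$members), B = x$B, seed = x$seed)
}
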