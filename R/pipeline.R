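#' Run the full modelling-optimization-sensitivity study
#'
#' Orchestrates every stage: ingest (packaged literature database or the
#' synthetic generator), resolve, encode, 70/20/10 split, bagged fitting of
#' the three members, fusion, metric evaluation on all splits, fruit-fly
#' optimization of the fused response surface over the 11 factors, and the
#' VSE/VSR importance ranking. Every source of randomness derives from
#' `seed`, so the same call is exactly reproducible.
#'
#' @param source `"table4"` for the packaged literature database, or
#'   `"synthetic"` for the generator.
#' @param seed Top-level integer seed.
#' @param path Database CSV (ignored for synthetic data).
#' @param synth A [synth_config()] used when `source = "synthetic"`; its
#'   seed is overridden by `seed`.
#' @param range_policy Range-cell resolution policy, see [resolve_records()].
#' @param member_configs Member configurations, see [fit_bagged_ensemble()].
#' @param B Bootstrap replicates per member.
#' @param foa A [foa_config()]; `dimensions` and `seed` are set internally.
#' @param sensitivity_policy Removal policy for the VSR report.
#' @param fractions Training/testing/validation fractions.
#' @param optimize Set `FALSE` to skip the FOA stage.
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `study_report`: list with `metrics` (12-row
#'   model x split tibble), `optimum` (decoded best protocol, its predicted
#'   efficiency, and the `foa_result`), `sensitivity` (the
#'   `sensitivity_report`), `split`, `encoded`, `ensemble`, `seed`,
#'   `source`, and `truth` (synthetic ground truth, if any).
#' @export
run_study <- function(source = c("table4", "synthetic"), seed = 1L,
                      path = transformation_db_path(),
                      synth = synth_config(),
                      range_policy = "midpoint",
                      member_configs = list(mlp = mlp_config(),
                                            rbf = rbf_config(),
                                            anfis = anfis_config()),
                      B = 25L,
                      foa = foa_config(),
                      sensitivity_policy = "mean",
                      fractions = c(0.70, 0.20, 0.10),
                      optimize = TRUE, quiet = TRUE) {
  source <- match.arg(source)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t1)
    out
  }
  truth <- NULL
  rows <- if (source == "table4") {
    stage("ingest+resolve", {
      resolve_records(load_database(path), range_policy)
    })
  } else {
    stage("synthesize", {
      synth$seed <- as.integer(seed)
      gen <- generate_synthetic(synth)
      truth <<- gen$truth
      gen$rows
    })
  }
  say("[data] %d rows", nrow(rows))
  encoded <- stage("encode", encode_features(rows))
  split <- stage("split", split_dataset(encoded, fractions, seed))
  xtr <- encoded$features[split$training, , drop = FALSE]
  ytr <- encoded$targets[split$training]
  ensemble <- stage("fit", fit_bagged_ensemble(xtr, ytr, member_configs,
                                               B = B, seed = seed))
  metrics <- stage("evaluate", ensemble_metrics(ensemble, encoded, split))
  optimum <- NULL
  if (optimize) {
    optimum <- stage("optimize", {
      bounds <- cbind(encoded$scaling$min, encoded$scaling$max)
      cat_spec <- list(dims = 1L, sizes = length(encoded$codebook))
      foa$dimensions <- nrow(bounds)
      foa$seed <- as.integer(seed)
      objective <- function(cand) {
        predict(ensemble, scale_features(cand, encoded$scaling))
      }
      res <- foa_optimize(objective, bounds, cat_spec, foa)
      inputs <- stats::setNames(as.list(res$best_inputs), encoded$feature_names)
      inputs$strain <- names(encoded$codebook)[
        match(res$best_inputs[1], encoded$codebook)]
      list(inputs = tibble::as_tibble(inputs),
           predicted_efficiency = res$best_value,
           foa = res)
    })
  }
  sensitivity <- stage("sensitivity", {
    vsr_report(ensemble, encoded$features, encoded$targets,
               policy = sensitivity_policy, train_x = xtr,
               retrain_y = if (sensitivity_policy == "retrain") ytr else NULL)
  })
  say("[total] %.2fs", proc.time()[["elapsed"]] - t0)
  structure(
    list(metrics = metrics, optimum = optimum, sensitivity = sensitivity,
         split = split, encoded = encoded, ensemble = ensemble,
         seed = as.integer(seed), source = source, truth = truth,
         version = as.character(utils::packageVersion("chrysfoa"))),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> source %s, seed %d\n", x$source, x$seed))
  ens_val <- dplyr::filter(x$metrics, .data$model == "ensemble",
                           .data$split == "validation")
  cat(sprintf("  ensemble validation: R2 %.3f, RMSE %.2f, MBE %.2f\n",
              ens_val$r2, ens_val$rmse, ens_val$mbe))
  if (!is.null(x$optimum)) {
    cat(sprintf("  FOA optimum: %.2f%% predicted efficiency (strain %s)\n",
                x$optimum$predicted_efficiency, x$optimum$inputs$strain))
  }
  top <- x$sensitivity$variable[x$sensitivity$rank == 1]
  cat(sprintf("  most sensitive input: %s\n", top))
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) x$metrics

#' @rdname run_study
#' @param object A `study_report`.
#' @export
glance.study_report <- function(object, ...) {
  ens <- dplyr::filter(object$metrics, .data$model == "ensemble")
  tibble::tibble(
    seed = object$seed,
    source = object$source,
    r2_training = ens$r2[ens$split == "training"],
    r2_validation = ens$r2[ens$split == "validation"],
    rmse_validation = ens$rmse[ens$split == "validation"],
    best_efficiency = if (is.null(object$optimum)) NA_real_
                      else object$optimum$predicted_efficiency,
    top_variable = object$sensitivity$variable[object$sensitivity$rank == 1]
  )
}

#' Repeat a study across seeds and summarize the distributions
#'
#' The literature database is small and the split is random, so a single
#' seed's metrics are noisy; the sweep is the package's reproduction mode.
#' Runs [run_study()] once per seed and returns every scalar of interest in
#' long form.
#'
#' @param seeds Integer vector of at least 2 seeds.
#' @param ... Passed to [run_study()].
#' @return Tibble of class `seed_sweep`: `seed`, `quantity`, `value`.
#' @export
seed_sweep <- function(seeds, ...) {
  stopifnot(length(seeds) >= 2)
  out <- purrr::map_dfr(seeds, function(s) {
    rep <- run_study(seed = s, ...)
    m <- tidyr::pivot_longer(rep$metrics, cols = c("r2", "rmse", "mbe"),
                             names_to = "metric", values_to = "value")
    m$quantity <- paste(m$model, m$split, m$metric, sep = "_")
    extra <- tibble::tibble(
      quantity = c("foa_best_efficiency", "strain_vsr", "strain_rank"),
      value = c(
        if (is.null(rep$optimum)) NA_real_ else rep$optimum$predicted_efficiency,
        rep$sensitivity$vsr[rep$sensitivity$variable == "strain"],
        as.numeric(rep$sensitivity$rank[rep$sensitivity$variable == "strain"])
      )
    )
    dplyr::bind_rows(m[, c("quantity", "value")], extra) |>
      dplyr::mutate(seed = s, .before = 1)
  })
  structure(out, class = c("seed_sweep", class(out)))
}

#' @rdname seed_sweep
#' @param sweep A `seed_sweep` tibble.
#' @export
summarise_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sweep), .data$quantity),
    median = stats::median(.data$value),
    iqr = stats::IQR(.data$value),
    n_seeds = dplyr::n(),
    .groups = "drop"
  )
}

#' Write a study report to disk as JSON and CSV tables
#'
#' Produces `report.json` plus three CSVs mirroring the study's result
#' tables — `table1.csv` (model x split metrics), `table2.csv` (the decoded
#' optimal protocol and its predicted efficiency), `table3.csv` (VSR and
#' rank per input) — and `convergence.csv` (best objective per generation).
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(metrics_table(report$metrics),
                   file.path(dir, "table1.csv"), row.names = FALSE)
  if (!is.null(report$optimum)) {
    opt <- dplyr::mutate(report$optimum$inputs,
                         efficiency_pct = report$optimum$predicted_efficiency)
    utils::write.csv(opt, file.path(dir, "table2.csv"), row.names = FALSE)
    utils::write.csv(tidy.foa_result(report$optimum$foa),
                     file.path(dir, "convergence.csv"), row.names = FALSE)
  }
  sens <- tibble::as_tibble(report$sensitivity)
  wide <- rbind(VSR = sens$vsr, Rank = sens$rank)
  colnames(wide) <- sens$variable
  utils::write.csv(data.frame(item = rownames(wide), wide,
                              check.names = FALSE),
                   file.path(dir, "table3.csv"), row.names = FALSE)
  payload <- list(
    seed = report$seed, source = report$source, version = report$version,
    metrics = report$metrics,
    optimum = if (is.null(report$optimum)) NULL else list(
      inputs = report$optimum$inputs,
      predicted_efficiency = report$optimum$predicted_efficiency,
      history = report$optimum$foa$history,
      evaluations = report$optimum$foa$evaluations
    ),
    sensitivity = tibble::as_tibble(report$sensitivity),
    full_model_rmse = attr(report$sensitivity, "full_rmse")
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

# Reshape the long metrics tibble into the classic model x (metric, split)
# table layout.
metrics_table <- function(metrics) {
  long <- tidyr::pivot_longer(metrics, cols = c("r2", "rmse", "mbe"),
                              names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(long,
                             id_cols = "model",
                             names_from = c("metric", "split"),
                             values_from = "value")
  wide
}

#' Predicted-versus-observed scatter plot
#'
#' @param observed,predicted Numeric vectors.
#' @param split Optional label used in the title.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_predicted_observed <- function(observed, predicted, split = NULL) {
  df <- tibble::tibble(observed = observed, predicted = predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed efficiency (%)",
                  y = "Predicted efficiency (%)",
                  title = paste(c("Predicted vs observed", split),
                                collapse = " — ")) +
    ggplot2::theme_minimal()
}
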