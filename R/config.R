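#' Export an encoded dataset and its encoding metadata
#'
#' Writes the resolved rows as CSV and the encoding metadata — the strain
#' codebook and the per-feature min/max used for scaling — as JSON, so an
#' encoding can be archived or applied elsewhere.
#'
#' @param dataset An `encoded_dataset`.
#' @param rows_path CSV destination for the resolved rows (NULL to skip).
#' @param meta_path JSON destination for the metadata (NULL to skip).
#' @return Invisibly, a list with the paths written.
#' @export
write_encoding <- function(dataset, rows_path = NULL, meta_path = NULL) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  if (!is.null(rows_path)) {
    utils::write.csv(dataset$rows, rows_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(schema = "chrysfoa-encoding/1",
           feature_names = dataset$feature_names,
           codebook = as.list(dataset$codebook),
           scaling = dataset$scaling),
      meta_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(list(rows = rows_path, meta = meta_path))
}

#' Read encoding metadata written by [write_encoding()]
#'
#' @param path JSON file.
#' @return List with `codebook` (named integer vector) and `scaling`
#'   (tibble), ready to pass to [encode_features()].
#' @export
read_encoding <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$schema, "chrysfoa-encoding/1")) {
    stop("unrecognized encoding schema in ", path, call. = FALSE)
  }
  list(codebook = stats::setNames(as.integer(unlist(l$codebook)),
                                  names(l$codebook)),
       scaling = tibble::as_tibble(l$scaling))
}

#' Read member-model configurations from a YAML file
#'
#' The file carries a `models:` section with one entry per member kind,
#' whose fields override that kind's config defaults, e.g.
#'
#' ```yaml
#' models:
#'   mlp: {hidden: 12, epochs: 300}
#'   rbf: {centers: 20}
#'   anfis: {rules: 5}
#' ```
#'
#' @param path YAML file.
#' @return Named list of configs suitable for [fit_bagged_ensemble()].
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read model configs", call. = FALSE)
  }
  spec <- yaml::read_yaml(path)
  if (is.null(spec$models)) stop("config lacks a 'models:' section",
                                 call. = FALSE)
  makers <- list(mlp = mlp_config, rbf = rbf_config, anfis = anfis_config)
  unknown <- setdiff(names(spec$models), names(makers))
  if (length(unknown) > 0) {
    stop("unknown model kind(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lapply(stats::setNames(nm = names(spec$models)), function(kind) {
    do.call(makers[[kind]], spec$models[[kind]] %||% list())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
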