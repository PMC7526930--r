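#' @importFrom rlang .data
NULL

# Canonical ordering of the eleven protocol factors. Selection antibiotics
# (kanamycin..geneticin) are dosed in mg/L, counter-selection antibiotics
# (vancomycin..ticarcillin) in ug/mL; od is unitless, ccp in days.
FACTOR_NAMES <- c(
  "strain", "od", "ccp",
  "kanamycin", "hygromycin", "paromomycin", "geneticin",
  "vancomycin", "cefotaxime", "carbenicillin", "ticarcillin"
)

CONCENTRATION_COLS <- FACTOR_NAMES[4:11]
ALLOWED_WAVELENGTHS <- c(540L, 550L, 600L, 660L)

#' Path to the packaged chrysanthemum transformation database
#'
#' Returns the location of the CSV transcription of the compiled literature
#' database of *Agrobacterium*-mediated chrysanthemum transformation studies
#' scored with the GUS reporter (49 studies, 11 protocol factors plus the
#' observed transformation efficiency).
#'
#' @return Path to the packaged CSV file.
#' @export
transformation_db_path <- function() {
  system.file("extdata", "chrysanthemum_gus_db.csv",
              package = "chrysfoa", mustWork = TRUE)
}

# Parse one raw cell into c(lo, hi). Accepts a single non-negative number,
# an a-b range (hyphen or en-dash), and tolerates a trailing "%".
# Returns NULL for absent cells ("-" or empty).
parse_cell <- function(text, row = NA, column = "") {
  text <- trimws(text)
  if (is.na(text) || text == "" || text == "-") return(NULL)
  text <- sub("%$", "", trimws(text))
  parts <- strsplit(text, "–|—|(?<=[0-9])-(?=[0-9.])", perl = TRUE)[[1]]
  parts <- trimws(parts)
  vals <- suppressWarnings(as.numeric(parts))
  bad <- length(vals) < 1 || length(vals) > 2 || anyNA(vals) || any(vals < 0)
  if (!bad && length(vals) == 2 && vals[1] > vals[2]) bad <- TRUE
  if (bad) {
    stop(sprintf("cannot parse cell '%s' (row %s, column '%s')",
                 text, row, column), call. = FALSE)
  }
  if (length(vals) == 1) vals <- c(vals, vals)
  vals
}

# Collapse c(lo, hi) to a single number under a range policy.
collapse_range <- function(vals, range_policy) {
  if (is.null(vals)) return(NULL)
  switch(range_policy,
         midpoint = mean(vals),
         min = vals[1],
         max = vals[2],
         stop("unknown range policy: ", range_policy, call. = FALSE))
}

#' Load the literature transformation database
#'
#' Reads a CSV in the packaged database dialect and validates every cell
#' without resolving it: strain cells may list several strains (semicolon
#' separated), and numeric cells may hold a single value or an a–b range.
#' Absent antibiotic doses, marked `"-"`, are kept as missing at this stage.
#'
#' @param path CSV file; defaults to the packaged database.
#' @return A tibble with one row per study: `strains` (list-column of strain
#'   labels), `od`, `ccp_days`, the eight antibiotic columns and
#'   `efficiency_pct` as raw text, `od_wavelength_nm` as integer, and
#'   `reference` (citation key).
#' @examples
#' db <- load_database()
#' nrow(db)
#' @export
load_database <- function(path = transformation_db_path()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  needed <- c("strains", "od", "od_wavelength_nm", "ccp_days",
              CONCENTRATION_COLS, "efficiency_pct", "reference")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("database file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(raw))) {
    strains <- trimws(strsplit(raw$strains[i], ";")[[1]])
    strains <- strains[strains != ""]
    if (length(strains) == 0) {
      stop(sprintf("row %d: empty strain cell", i), call. = FALSE)
    }
    wl <- suppressWarnings(as.integer(raw$od_wavelength_nm[i]))
    if (is.na(wl) || !wl %in% ALLOWED_WAVELENGTHS) {
      stop(sprintf("row %d: unknown OD wavelength '%s'",
                   i, raw$od_wavelength_nm[i]), call. = FALSE)
    }
    parse_cell(raw$od[i], i, "od")
    parse_cell(raw$ccp_days[i], i, "ccp_days")
    for (ab in CONCENTRATION_COLS) parse_cell(raw[[ab]][i], i, ab)
    eff <- parse_cell(raw$efficiency_pct[i], i, "efficiency_pct")
    if (is.null(eff)) {
      stop(sprintf("row %d: efficiency cell is absent", i), call. = FALSE)
    }
  }
  tibble::tibble(
    strains = lapply(raw$strains, function(s) {
      v <- trimws(strsplit(s, ";")[[1]]); v[v != ""]
    }),
    od = trimws(raw$od),
    od_wavelength_nm = as.integer(raw$od_wavelength_nm),
    ccp_days = trimws(raw$ccp_days),
    !!!stats::setNames(
      lapply(CONCENTRATION_COLS, function(ab) trimws(raw[[ab]])),
      CONCENTRATION_COLS
    ),
    efficiency_pct = trimws(raw$efficiency_pct),
    reference = trimws(raw$reference)
  )
}

#' Resolve raw literature records into numeric modelling rows
#'
#' Turns each validated record into one or more fully numeric rows:
#' range cells are collapsed under `range_policy` (default: arithmetic
#' midpoint, the least biased single-value summary of an a–b interval),
#' rows listing several *Agrobacterium* strains are expanded into one row per
#' strain with all other fields duplicated, and absent doses become a
#' concentration of zero (no compound applied is a zero dose, not a missing
#' measurement).
#'
#' @param records Tibble from [load_database()].
#' @param range_policy `"midpoint"` (default), `"min"`, or `"max"`.
#' @return Tibble of resolved rows: `strain` (character), the ten numeric
#'   factor columns, `efficiency_pct`, `od_wavelength_nm`, `reference`, and
#'   `record_id` (provenance: index of the source record).
#' @export
resolve_records <- function(records, range_policy = c("midpoint", "min", "max")) {
  range_policy <- match.arg(range_policy)
  rows <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    num <- function(col) {
      v <- collapse_range(parse_cell(rec[[col]], i, col), range_policy)
      if (is.null(v)) 0 else v
    }
    base <- tibble::tibble(
      od = num("od"),
      ccp = num("ccp_days"),
      !!!stats::setNames(lapply(CONCENTRATION_COLS, num), CONCENTRATION_COLS),
      efficiency_pct = num("efficiency_pct"),
      od_wavelength_nm = rec$od_wavelength_nm,
      reference = rec$reference,
      record_id = i
    )
    tibble::tibble(strain = rec$strains[[1]]) |>
      dplyr::bind_cols(base[rep(1, length(rec$strains[[1]])), ])
  })
  dplyr::relocate(rows, "strain")
}

#' Encode resolved rows into a scaled model matrix
#'
#' Builds the 11-column feature matrix used by every regressor: the strain
#' label becomes a single integer-coded column (codes assigned by first
#' appearance), and all eleven columns are min–max scaled to \[0, 1\]
#' using the extrema of the encoding data (stored, so new rows can be scaled
#' identically). Targets stay on the raw 0–100 efficiency scale, so model
#' errors read directly in percentage points.
#'
#' @param rows Resolved rows from [resolve_records()] (or the synthetic
#'   generator); must contain `strain`, the ten factor columns, and
#'   `efficiency_pct`.
#' @param codebook Optional named integer vector (label -> code) from a
#'   previous encoding; unseen strains are an error.
#' @param scaling Optional tibble (`feature`, `min`, `max`) from a previous
#'   encoding, applied instead of refitting extrema.
#' @return An object of class `encoded_dataset`: list with `features`
#'   (n x 11 scaled matrix), `targets`, `feature_names`, `codebook`,
#'   `scaling`, `provenance`, and `rows` (the input rows).
#' @export
encode_features <- function(rows, codebook = NULL, scaling = NULL) {
  stopifnot(nrow(rows) > 0)
  need <- c("strain", setdiff(FACTOR_NAMES, "strain"), "efficiency_pct")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) {
    stop("rows lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(codebook)) {
    labels <- unique(rows$strain)
    codebook <- stats::setNames(seq_along(labels) - 1L, labels)
  }
  unseen <- setdiff(unique(rows$strain), names(codebook))
  if (length(unseen) > 0) {
    stop("strain label(s) not in codebook: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  raw <- cbind(
    strain = as.numeric(codebook[rows$strain]),
    as.matrix(rows[, setdiff(FACTOR_NAMES, "strain")])
  )
  colnames(raw) <- FACTOR_NAMES
  if (is.null(scaling)) {
    scaling <- tibble::tibble(
      feature = FACTOR_NAMES,
      min = unname(apply(raw, 2, min)),
      max = unname(apply(raw, 2, max))
    )
  }
  features <- scale_features(raw, scaling)
  structure(
    list(
      features = features,
      targets = as.numeric(rows$efficiency_pct),
      feature_names = FACTOR_NAMES,
      codebook = codebook,
      scaling = scaling,
      provenance = if ("record_id" %in% names(rows)) rows$record_id
                   else seq_len(nrow(rows)),
      rows = rows
    ),
    class = "encoded_dataset"
  )
}

# Min-max scale a raw feature matrix (degenerate columns map to 0).
scale_features <- function(raw, scaling) {
  out <- raw
  for (j in seq_len(nrow(scaling))) {
    rng <- scaling$max[j] - scaling$min[j]
    out[, j] <- if (rng > 0) (raw[, j] - scaling$min[j]) / rng else 0
  }
  out
}

# Inverse of scale_features for a scaled matrix or vector.
unscale_features <- function(scaled, scaling) {
  scaled <- rbind(scaled)
  out <- scaled
  for (j in seq_len(nrow(scaling))) {
    rng <- scaling$max[j] - scaling$min[j]
    out[, j] <- scaled[, j] * rng + scaling$min[j]
  }
  out
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset> %d rows x %d features, %d strain codes\n",
              nrow(x$features), ncol(x$features), length(x$codebook)))
  cat("targets (efficiency %): range",
      sprintf("%.2f..%.2f\n", min(x$targets), max(x$targets)))
  invisible(x)
}

#' Split an encoded dataset into training, testing and validation sets
#'
#' Uniform random partition without replacement into 70/20/10 (by default)
#' with largest-remainder rounding; rounding ties favour training, then
#' testing, then validation.
#'
#' @param dataset An `encoded_dataset`, or a single integer row count.
#' @param fractions Length-3 numeric summing to 1 (training, testing,
#'   validation).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return Object of class `data_split`: list with integer index vectors
#'   `training`, `testing`, `validation`, plus `seed` and `fractions`.
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  n <- if (inherits(dataset, "encoded_dataset")) nrow(dataset$features)
       else as.integer(dataset)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three numbers summing to 1", call. = FALSE)
  }
  if (n < 10) stop("need at least 10 rows to split", call. = FALSE)
  sizes <- largest_remainder(n, fractions)
  perm <- withr_seed(seed, sample.int(n))
  structure(
    list(
      training = sort(perm[seq_len(sizes[1])]),
      testing = sort(perm[sizes[1] + seq_len(sizes[2])]),
      validation = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
      seed = as.integer(seed),
      fractions = fractions
    ),
    class = "data_split"
  )
}

# Largest-remainder apportionment; ties broken by position (training first).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    rem <- exact - sizes
    ord <- order(-rem, seq_along(rem))
    sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1
  }
  as.integer(sizes)
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> training %d / testing %d / validation %d (seed %d)\n",
              length(x$training), length(x$testing), length(x$validation),
              x$seed))
  invisible(x)
}

#' @rdname split_dataset
#' @param x A `data_split`.
#' @param ... Unused.
#' @export
tidy.data_split <- function(x, ...) {
  tibble::tibble(
    split = rep(c("training", "testing", "validation"),
                times = c(length(x$training), length(x$testing),
                          length(x$validation))),
    row = c(x$training, x$testing, x$validation)
  )
}
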