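#' Synthetic transformation-study generator configuration
#'
#' Emulates the statistical shape of the compiled literature database: one
#' categorical strain factor with additive level effects, ten non-negative
#' continuous factors on realistic dose ranges (several carrying no effect,
#' as most antibiotics are absent from any given study), and a smooth
#' unimodal response surface
#' \deqn{eff = base + strain_effect + \sum_j w_j \exp(-(v_j - o_j)^2 / 2\tau_j^2) + N(0, noise_sd)}
#' clipped to \[0, 100\]. The interior Gaussian-bump optimum mirrors the
#' assumption that an interior best protocol exists. Defaults: 500 rows,
#' five strain levels with effects 0/2/4/6/10 points, four active factors
#' with effect weights 18 (kanamycin), 12 (co-culture period), 9
#' (vancomycin) and 8 (paromomycin), bump widths of 20% of each range, and
#' 2 points of additive noise. The weights are set so that every active
#' factor's marginal contribution SD (about 2.5 to 5.6 points under uniform
#' sampling) exceeds the noise SD: each encoded effect is statistically
#' identifiable, none trivially so.
#'
#' @param n Number of rows (>= 20).
#' @param strain_levels Character vector of level labels.
#' @param strain_effects Additive effect (percentage points) per level.
#' @param factors Tibble with columns `name`, `low`, `high`, `optimum`
#'   (absolute units, inside the bounds), `weight` (>= 0, percentage
#'   points), `tau` (bump width, absolute units).
#' @param base Baseline efficiency (points).
#' @param noise_sd Additive Gaussian noise SD (points, >= 0).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = 500L,
                         strain_levels = paste0("S", 1:5),
                         strain_effects = c(0, 2, 4, 6, 10),
                         factors = default_synth_factors(),
                         base = 4, noise_sd = 2, seed = 1L) {
  stopifnot(n >= 20, length(strain_levels) == length(strain_effects),
            noise_sd >= 0, all(factors$weight >= 0),
            all(factors$optimum >= factors$low),
            all(factors$optimum <= factors$high),
            all(factors$tau > 0))
  structure(list(n = as.integer(n), strain_levels = strain_levels,
                 strain_effects = strain_effects, factors = factors,
                 base = base, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_synth_factors <- function() {
  f <- tibble::tribble(
    ~name,           ~low, ~high, ~opt_frac, ~weight,
    "od",             0.1,   2.2,      0.40,       0,
    "ccp",            0.5,   8.0,      0.45,      12,
    "kanamycin",      0,   100,        0.30,      18,
    "hygromycin",     0,    40,        0.50,       0,
    "paromomycin",    0,    50,        0.60,       8,
    "geneticin",      0,    30,        0.50,       0,
    "vancomycin",     0,   500,        0.35,       9,
    "cefotaxime",     0,   500,        0.50,       0,
    "carbenicillin",  0,   500,        0.50,       0,
    "ticarcillin",    0,   500,        0.50,       0
  )
  dplyr::mutate(f,
                optimum = .data$low + .data$opt_frac * (.data$high - .data$low),
                tau = 0.2 * (.data$high - .data$low)) |>
    dplyr::select("name", "low", "high", "optimum", "weight", "tau")
}

# Noiseless response surface for one or more rows.
synth_surface <- function(config, strain, factor_matrix) {
  factor_matrix <- rbind(factor_matrix)
  eff <- config$base +
    config$strain_effects[match(strain, config$strain_levels)]
  for (j in seq_len(nrow(config$factors))) {
    fj <- config$factors[j, ]
    eff <- eff + fj$weight *
      exp(-(factor_matrix[, j] - fj$optimum)^2 / (2 * fj$tau^2))
  }
  as.numeric(eff)
}

#' Generate a synthetic transformation dataset with known ground truth
#'
#' @param config A [synth_config()].
#' @return List with `rows` (tibble in the resolved-row schema: `strain`,
#'   the ten factor columns, `efficiency_pct`, `record_id`) and `truth`
#'   (list: `optimum` from [true_optimum()], `effect_sd` per variable,
#'   `effect_order` from strongest to weakest, `dominant`, `surface` (the
#'   noiseless evaluator), and `clip_rate`).
#' @export
generate_synthetic <- function(config) {
  withr_seed(config$seed, {
    n <- config$n
    strain <- sample(config$strain_levels, n, replace = TRUE)
    fm <- vapply(seq_len(nrow(config$factors)), function(j) {
      stats::runif(n, config$factors$low[j], config$factors$high[j])
    }, numeric(n))
    colnames(fm) <- config$factors$name
    noiseless <- synth_surface(config, strain, fm)
    eff <- noiseless + stats::rnorm(n, 0, config$noise_sd)
    clipped <- pmin(pmax(eff, 0), 100)
    rows <- tibble::tibble(strain = strain) |>
      dplyr::bind_cols(tibble::as_tibble(fm)) |>
      dplyr::mutate(efficiency_pct = clipped, record_id = dplyr::row_number())
    truth <- list(
      optimum = true_optimum(config),
      effect_sd = synth_effect_sd(config),
      surface = function(strain, factors) synth_surface(config, strain, factors),
      clip_rate = mean(eff != clipped)
    )
    truth$effect_order <- names(sort(truth$effect_sd, decreasing = TRUE))
    truth$dominant <- truth$effect_order[1]
    list(rows = rows, truth = truth)
  })
}

# Standard deviation of each variable's contribution under uniform sampling
# (strain: over levels; factors: dense-grid quadrature of the bump).
synth_effect_sd <- function(config) {
  sds <- c(strain = stats::sd(config$strain_effects) *
             sqrt((length(config$strain_effects) - 1) /
                    length(config$strain_effects)))
  for (j in seq_len(nrow(config$factors))) {
    fj <- config$factors[j, ]
    grid <- seq(fj$low, fj$high, length.out = 2001)
    contrib <- fj$weight * exp(-(grid - fj$optimum)^2 / (2 * fj$tau^2))
    sds[fj$name] <- sqrt(mean((contrib - mean(contrib))^2))
  }
  sds
}

#' Analytic optimum of the noiseless synthetic surface
#'
#' The surface is additive, so its argmax is the best strain level together
#' with each active factor at its bump center; factors with zero weight do
#' not affect the response and are reported at their range midpoint.
#'
#' @param config A [synth_config()].
#' @return List: `strain`, `factors` (named vector of argmax values),
#'   `value` (the maximum noiseless efficiency), and `active` (names of
#'   factors with positive weight).
#' @export
true_optimum <- function(config) {
  best_level <- config$strain_levels[which.max(config$strain_effects)]
  vals <- ifelse(config$factors$weight > 0, config$factors$optimum,
                 (config$factors$low + config$factors$high) / 2)
  names(vals) <- config$factors$name
  list(strain = best_level,
       factors = vals,
       value = config$base + max(config$strain_effects) +
         sum(config$factors$weight),
       active = config$factors$name[config$factors$weight > 0])
}
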