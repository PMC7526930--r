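#' Fruit-fly optimization algorithm configuration
#'
#' Defaults follow the study configuration: 100 generations, 10 flies, a
#' random flight range of \[-10, 10\] added to the swarm axis each
#' generation, and initial axis coordinates drawn uniformly from \[0, 1\].
#' Each decision variable gets its own (x, y) coordinate pair — the standard
#' multi-dimensional extension of the scalar algorithm.
#'
#' @param maxgen Number of generations.
#' @param sizepop Number of flies per generation.
#' @param fr Flight range, a symmetric interval about 0.
#' @param axis_init Interval the initial axis is drawn from.
#' @param dimensions Number of decision variables.
#' @param seed Integer seed.
#' @return A list of class `foa_config`.
#' @export
foa_config <- function(maxgen = 100L, sizepop = 10L, fr = c(-10, 10),
                       axis_init = c(0, 1), dimensions = 11L, seed = 1L) {
  stopifnot(maxgen >= 1, sizepop >= 1, dimensions >= 1,
            length(fr) == 2, length(axis_init) == 2)
  if (abs(fr[1] + fr[2]) > 1e-9) {
    stop("flight range must be symmetric about 0", call. = FALSE)
  }
  structure(list(maxgen = as.integer(maxgen), sizepop = as.integer(sizepop),
                 fr = fr, axis_init = axis_init,
                 dimensions = as.integer(dimensions), seed = as.integer(seed)),
            class = "foa_config")
}

#' Smell-concentration decision value
#'
#' The reciprocal of a fly's distance from the origin,
#' \eqn{S = 1/\sqrt{x^2 + y^2}}; distances below 1e-12 are clamped so the
#' value stays finite.
#'
#' @param x_coord,y_coord Numeric coordinates (vectorized).
#' @return Numeric decision values.
#' @examples
#' smell_decision_value(3, 4)  # 1/5
#' @export
smell_decision_value <- function(x_coord, y_coord) {
  1 / pmax(sqrt(x_coord^2 + y_coord^2), 1e-12)
}

#' Initialize a fruit-fly swarm
#'
#' Draws the per-dimension axis uniformly from the configured initial
#' interval; no fitness is evaluated yet and the generation counter is 0.
#'
#' @param config A [foa_config()]. The caller controls the RNG state (set a
#'   seed before calling, or use [foa_optimize()] which seeds everything).
#' @return Object of class `foa_swarm`.
#' @export
init_swarm <- function(config) {
  d <- config$dimensions
  structure(
    list(
      axis_x = stats::runif(d, config$axis_init[1], config$axis_init[2]),
      axis_y = stats::runif(d, config$axis_init[1], config$axis_init[2]),
      best_smell = -Inf,
      best_candidate = NULL,
      generation = 0L,
      history = numeric(0),
      evaluations = 0L
    ),
    class = "foa_swarm"
  )
}

#' Decode smell-concentration values into candidate inputs
#'
#' Continuous dimensions map linearly: `low + clamp01(s) * (high - low)`
#' (the decision-value magnitude at unit distance, S = 1, marks the top of
#' the range). Categorical dimensions round to the nearest valid integer
#' code and clamp into the codebook.
#'
#' @param s Matrix (flies x dimensions) or vector of decision values.
#' @param bounds Two-column matrix (low, high) with one row per dimension.
#' @param categorical_spec Optional named list: `dims` (indices of
#'   categorical dimensions) and `sizes` (codebook size per such dimension;
#'   codes run 0..size-1).
#' @return Matrix of decoded candidates in original units.
#' @export
decode_candidate <- function(s, bounds, categorical_spec = NULL) {
  s <- rbind(s)
  bounds <- rbind(bounds)
  if (any(bounds[, 1] > bounds[, 2])) {
    stop("bounds must satisfy low <= high", call. = FALSE)
  }
  scaled <- pmin(pmax(s, 0), 1)
  cand <- sweep(scaled, 2, bounds[, 2] - bounds[, 1], "*")
  cand <- sweep(cand, 2, bounds[, 1], "+")
  if (!is.null(categorical_spec)) {
    for (j in seq_along(categorical_spec$dims)) {
      dim_j <- categorical_spec$dims[j]
      k <- categorical_spec$sizes[j]
      cand[, dim_j] <- pmin(pmax(round(cand[, dim_j]), 0), k - 1)
    }
  }
  cand
}

#' Advance the swarm one generation
#'
#' Every fly flies from the axis with a uniform random offset in the flight
#' range (per dimension), its smell-concentration decision value is decoded
#' into a candidate, and the objective ("smell concentration") is evaluated.
#' The best fly (ties: lowest index) replaces the incumbent only if it
#' improves on it, and the axis moves to that fly's coordinates — so the
#' best-smell trace never decreases. Non-finite objective values exclude a
#' fly from the argmax.
#'
#' @param swarm A `foa_swarm`.
#' @param objective Function taking a decoded candidate matrix (flies x
#'   dimensions) and returning one finite value per row (maximized).
#' @param bounds,categorical_spec See [decode_candidate()].
#' @param config A [foa_config()].
#' @return The updated `foa_swarm`.
#' @export
foa_step <- function(swarm, objective, bounds, categorical_spec = NULL,
                     config) {
  p <- config$sizepop; d <- config$dimensions
  x <- rep(swarm$axis_x, each = p) +
    matrix(stats::runif(p * d, config$fr[1], config$fr[2]), p, d)
  y <- rep(swarm$axis_y, each = p) +
    matrix(stats::runif(p * d, config$fr[1], config$fr[2]), p, d)
  s <- smell_decision_value(x, y)
  cand <- decode_candidate(s, bounds, categorical_spec)
  smell <- as.numeric(objective(cand))
  if (length(smell) != p) {
    stop("objective must return one value per fly", call. = FALSE)
  }
  smell[!is.finite(smell)] <- -Inf
  best_index <- which.max(smell)
  if (length(best_index) == 1 && smell[best_index] > swarm$best_smell) {
    swarm$best_smell <- smell[best_index]
    swarm$best_candidate <- cand[best_index, ]
    swarm$axis_x <- x[best_index, ]
    swarm$axis_y <- y[best_index, ]
  }
  swarm$evaluations <- swarm$evaluations + p
  swarm$generation <- swarm$generation + 1L
  swarm$history <- c(swarm$history, swarm$best_smell)
  swarm
}

#' Maximize an objective with the fruit-fly optimization algorithm
#'
#' Runs [init_swarm()] followed by `maxgen` generations of [foa_step()],
#' for exactly `maxgen * sizepop` objective evaluations. Identical seed,
#' objective and bounds give an identical result.
#'
#' @inheritParams foa_step
#' @param config A [foa_config()]; its `dimensions` must match `bounds`.
#' @return Object of class `foa_result`: `best_inputs` (decoded optimum),
#'   `best_value`, `history` (best objective per generation, non-decreasing),
#'   `evaluations`, and the config.
#' @export
foa_optimize <- function(objective, bounds, categorical_spec = NULL,
                         config = foa_config()) {
  bounds <- rbind(bounds)
  if (nrow(bounds) != config$dimensions) {
    stop("bounds rows must equal config$dimensions", call. = FALSE)
  }
  withr_seed(config$seed, {
    swarm <- init_swarm(config)
    for (gen in seq_len(config$maxgen)) {
      swarm <- foa_step(swarm, objective, bounds, categorical_spec, config)
    }
    structure(
      list(best_inputs = swarm$best_candidate,
           best_value = swarm$best_smell,
           history = swarm$history,
           evaluations = swarm$evaluations,
           config = config),
      class = "foa_result"
    )
  })
}

#' @export
print.foa_result <- function(x, ...) {
  cat(sprintf("<foa_result> best value %.4f after %d evaluations (%d generations)\n",
              x$best_value, x$evaluations, length(x$history)))
  invisible(x)
}

#' @rdname foa_optimize
#' @param x A `foa_result`.
#' @param ... Unused.
#' @export
tidy.foa_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history), best_value = x$history)
}

#' @rdname foa_optimize
#' @param object A `foa_result`.
#' @export
glance.foa_result <- function(object, ...) {
  tibble::tibble(best_value = object$best_value,
                 evaluations = object$evaluations,
                 generations = length(object$history))
}

#' Convergence trace plot for an FOA run
#'
#' @param object A `foa_result`.
#' @param ... Unused.
#' @return A ggplot object showing the best objective value per generation.
#' @export
autoplot.foa_result <- function(object, ...) {
  ggplot2::ggplot(tidy.foa_result(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best predicted efficiency (%)",
                  title = "Fruit-fly optimization convergence") +
    ggplot2::theme_minimal()
}
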