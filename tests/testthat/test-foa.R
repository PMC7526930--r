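test_that("smell-concentration decision values follow S = 1/dist", {
  expect_equal(smell_decision_value(3, 4), 0.2)
  expect_equal(smell_decision_value(1, 0), 1)
  expect_equal(smell_decision_value(10, 10), 1 / sqrt(200))
  # the epsilon floor keeps S finite at the origin
  expect_true(is.finite(smell_decision_value(0, 0)))
})

test_that("swarm initialization is seeded, in range, and unevaluated", {
  cfg <- foa_config(dimensions = 11, seed = 7)
  s1 <- withr::with_seed(7, init_swarm(cfg))
  s2 <- withr::with_seed(7, init_swarm(cfg))
  expect_identical(s1, s2)
  expect_length(s1$axis_x, 11)
  expect_true(all(s1$axis_x >= 0 & s1$axis_x <= 1))
  expect_true(all(s1$axis_y >= 0 & s1$axis_y <= 1))
  expect_equal(s1$generation, 0L)
  expect_equal(s1$evaluations, 0L)
})

test_that("candidates decode linearly with clamping and integer codes", {
  b <- rbind(c(0, 100))
  expect_equal(as.numeric(decode_candidate(0.5, b)), 50)
  expect_equal(as.numeric(decode_candidate(1.7, rbind(c(0, 10)))), 10)
  expect_equal(as.numeric(decode_candidate(-0.2, rbind(c(0, 10)))), 0)
  cat5 <- list(dims = 1L, sizes = 5L)
  expect_equal(as.numeric(decode_candidate(2.6 / 4, rbind(c(0, 4)), cat5)), 3)
  expect_error(decode_candidate(0.5, rbind(c(5, 1))), "low <= high")
})

test_that("a step keeps the incumbent on flat or worsening landscapes", {
  cfg <- foa_config(maxgen = 30, sizepop = 5, dimensions = 2, seed = 1)
  flat <- foa_optimize(function(cand) rep(1, nrow(cand)),
                       bounds = rbind(c(0, 1), c(0, 1)), config = cfg)
  expect_equal(flat$history, rep(1, 30))
  # ties at the argmax resolve to the lowest fly index
  smells <- c(1, 3, 3)
  expect_equal(which.max(smells), 2)
})

test_that("the optimizer spends exactly maxgen x sizepop evaluations", {
  counter <- 0
  obj <- function(cand) { counter <<- counter + nrow(cand); rowSums(cand) }
  res <- foa_optimize(obj, bounds = rbind(c(0, 1), c(0, 1)),
                      config = foa_config(dimensions = 2, seed = 3))
  expect_equal(counter, 100 * 10)
  expect_equal(res$evaluations, 1000)
  expect_length(res$history, 100)
})

test_that("the best-smell history never decreases and runs are reproducible", {
  obj <- function(cand) -rowSums((cand - 0.3)^2)
  cfg <- foa_config(dimensions = 2, seed = 7)
  r1 <- foa_optimize(obj, rbind(c(0, 1), c(0, 1)), config = cfg)
  r2 <- foa_optimize(obj, rbind(c(0, 1), c(0, 1)), config = cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$history) >= 0))
  # non-finite objective values exclude the fly instead of propagating
  bad <- foa_optimize(function(cand) ifelse(cand[, 1] > 0.5, NaN, cand[, 1]),
                      rbind(c(0, 1)), config = foa_config(dimensions = 1, seed = 2))
  expect_true(is.finite(bad$best_value))
  expect_lte(bad$best_inputs[1], 0.5)
})

test_that("a categorical-only search matches exhaustive enumeration", {
  payoff <- c(2, 5, 3, 9, 1)   # five strain codes, best is code 3
  obj <- function(cand) payoff[cand[, 1] + 1]
  hits <- vapply(1:20, function(s) {
    r <- foa_optimize(obj, rbind(c(0, 4)),
                      categorical_spec = list(dims = 1L, sizes = 5L),
                      config = foa_config(dimensions = 1, seed = s))
    r$best_inputs[1] == which.max(payoff) - 1
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("result tidiers expose the convergence trace", {
  r <- foa_optimize(function(cand) rowSums(cand), rbind(c(0, 1)),
                    config = foa_config(maxgen = 20, dimensions = 1, seed = 1))
  td <- tidy(r)
  expect_equal(nrow(td), 20)
  expect_named(td, c("generation", "best_value"))
  expect_s3_class(autoplot(r), "ggplot")
  expect_equal(glance(r)$evaluations, 200)
})
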