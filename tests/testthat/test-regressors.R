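test_that("every fitter is bitwise reproducible under a fixed seed", {
  set.seed(5)
  x <- matrix(runif(60 * 2), 60, 2)
  y <- 3 * x[, 1] - x[, 2] + rnorm(60, 0, 0.1)
  for (fitter in list(
    function() fit_mlp(x, y, mlp_config(epochs = 50, seed = 9)),
    function() fit_rbf(x, y, rbf_config(centers = 8, seed = 9)),
    function() fit_anfis(x, y, anfis_config(rules = 3, epochs = 10, seed = 9))
  )) {
    a <- fitter(); b <- fitter()
    expect_identical(a[setdiff(names(a), "config")],
                     b[setdiff(names(b), "config")])
  }
})

test_that("MLP learns simple targets and records a decreasing loss", {
  set.seed(1)
  x <- matrix(runif(50), 50, 1)
  # constant target is represented exactly from the first step
  m <- fit_mlp(x, rep(7, 50), mlp_config(seed = 3))
  expect_lt(max(abs(predict(m, x) - 7)), 1e-2)
  # y = 2x is learned well within the default budget
  y <- 2 * x[, 1]
  m <- fit_mlp(x, y, mlp_config(seed = 3))
  expect_lt(sqrt(mean((predict(m, x) - y)^2)), 0.05 * diff(range(y)))
  expect_length(m$losses, 500)
  expect_lt(m$losses[length(m$losses)], m$losses[1])
  # divergence is reported, not returned
  expect_error(fit_mlp(x, 100 * y, mlp_config(learning_rate = 50, seed = 1)),
               "learning_rate")
})

test_that("RBF interpolates exactly with one center per point", {
  x <- matrix(1:5 / 5, 5, 1)
  y <- c(3, 1, 4, 1, 5)
  m <- fit_rbf(x, y, rbf_config(ridge = 1e-10, centers_matrix = x))
  expect_lt(max(abs(predict(m, x) - y)), 1e-6)
  # the Gaussian basis is 1 at its center
  expect_equal(exp(-0 / (2 * m$sigma^2)), 1)
})

test_that("RBF weights equal the explicit ridge normal-equations solution", {
  set.seed(2)
  x <- matrix(runif(80 * 2), 80, 2)
  y <- sin(2 * pi * x[, 1]) + x[, 2]
  m <- fit_rbf(x, y, rbf_config(centers = 10, ridge = 1e-4, seed = 2))
  phi <- cbind(exp(-chrysfoa:::cross_dist2(x, m$centers) / (2 * m$sigma^2)), 1)
  oracle <- solve(crossprod(phi) + 1e-4 * diag(ncol(phi)), crossprod(phi, y))
  expect_equal(as.numeric(m$weights), as.numeric(oracle), tolerance = 1e-8)
})

test_that("RBF fits smooth 1-D and linear 3-D surfaces", {
  x <- matrix(seq(0, 1, length.out = 100), 100, 1)
  y <- sin(2 * pi * x[, 1])
  m <- fit_rbf(x, y, rbf_config(centers = 15, seed = 1))
  xt <- matrix(withr::with_seed(4, runif(50)), 50, 1)
  expect_lt(sqrt(mean((predict(m, xt) - sin(2 * pi * xt[, 1]))^2)), 0.1)
  # a noiseless linear response surface is recovered with R2 > 0.99
  set.seed(42)
  x3 <- matrix(runif(500 * 3), 500, 3)
  y3 <- 10 + 20 * x3[, 1] + 10 * x3[, 2] + 5 * x3[, 3]
  m3 <- fit_rbf(x3[1:350, ], y3[1:350],
                rbf_config(centers = 30, width_factor = 2, seed = 1))
  expect_gt(fit_metrics(y3[351:500], predict(m3, x3[351:500, ]))$r2, 0.99)
})

test_that("RBF degeneracy and shape errors are explicit", {
  x <- matrix(rep(c(0.1, 0.9), each = 6), 12, 1)
  expect_error(fit_rbf(x, rnorm(12), rbf_config(centers = 5)), "distinct")
  m <- fit_rbf(matrix(runif(20), 10, 2), rnorm(10), rbf_config(centers = 4))
  expect_error(predict(m, matrix(0.5, 1, 3)), "feature columns")
})

test_that("ANFIS forward pass follows Takagi-Sugeno defuzzification", {
  # single rule with consequent y = 3 predicts 3 everywhere
  one <- structure(
    list(kind = "anfis", centers = matrix(0.5, 1, 1),
         sigma = matrix(1, 1, 1), theta = c(0, 3), n_inputs = 1L,
         config = anfis_config(rules = 1), losses = 0),
    class = c("anfis_model", "regressor"))
  expect_equal(predict(one, matrix(c(0, 0.3, 1), 3, 1)), rep(3, 3))
  # two rules, normalized memberships 0.2/0.8, consequents 10 and 20 -> 18
  two <- structure(
    list(kind = "anfis",
         centers = matrix(c(sqrt(2 * log(4)), 0), 2, 1),
         sigma = matrix(1, 2, 1), theta = c(0, 10, 0, 20), n_inputs = 1L,
         config = anfis_config(rules = 2), losses = 0),
    class = c("anfis_model", "regressor"))
  expect_equal(predict(two, matrix(0, 1, 1)), 0.2 * 10 + 0.8 * 20,
               tolerance = 1e-12)
})

test_that("ANFIS firing strengths renormalize to one for every sample", {
  set.seed(3)
  x <- matrix(runif(200 * 4), 200, 4)
  centers <- matrix(runif(3 * 4), 3, 4)
  sigma <- matrix(0.3, 3, 4)
  wbar <- chrysfoa:::anfis_firing(x, centers, sigma)$wbar
  expect_equal(rowSums(wbar), rep(1, 200), tolerance = 1e-12)
  # a sample far from every cluster still renormalizes cleanly
  far <- chrysfoa:::anfis_firing(matrix(50, 1, 4), centers, sigma)$wbar
  expect_equal(sum(far), 1, tolerance = 1e-12)
})

test_that("ANFIS learns an additive surface with a monotone loss trace", {
  set.seed(6)
  x <- matrix(runif(200 * 2), 200, 2)
  y <- x[, 1] + x[, 2]
  m <- fit_anfis(x, y, anfis_config(rules = 4, ridge = 1e-8, seed = 6))
  xt <- matrix(runif(100), 50, 2)
  expect_lt(sqrt(mean((predict(m, xt) - rowSums(xt))^2)),
            0.05 * diff(range(y)))
  expect_true(all(diff(m$losses) <= 1e-9))
})

test_that("trained models survive a JSON round trip with identical output", {
  set.seed(8)
  x <- matrix(runif(40 * 2), 40, 2)
  y <- x[, 1] - 2 * x[, 2]
  for (m in list(fit_mlp(x, y, mlp_config(epochs = 30, seed = 1)),
                 fit_rbf(x, y, rbf_config(centers = 6, seed = 1)),
                 fit_anfis(x, y, anfis_config(rules = 2, epochs = 5, seed = 1)))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    back <- read_model(path)
    expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
  }
})
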