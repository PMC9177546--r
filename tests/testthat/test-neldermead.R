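# Simplex optimizer and the calibration layer on top of it.

test_that("the weighted SSE objective behaves like a normal likelihood", {
  spec <- objective_spec(c(BOD = 24.8, TN = 12.9, TSS = 29.5),
                         codes = "X52")
  ev <- stub_evaluator()
  expect_equal(objective_wsse(c(X52 = 0.666), spec, ev), 0)
  # residuals (1, 2) with sigma (1, 2) -> 1 + 1 = 2
  spec2 <- objective_spec(c(BOD = 1, TN = 2), sigma = c(BOD = 1, TN = 2),
                          codes = "X52")
  ev0 <- stub_evaluator(c(BOD = 0, TN = 0, TSS = 0))
  expect_equal(objective_wsse(c(X52 = 0.6), spec2, ev0), 2)
  # doubling every sigma divides the objective by four
  spec4 <- objective_spec(c(BOD = 1, TN = 2), sigma = c(BOD = 2, TN = 4),
                          codes = "X52")
  expect_equal(objective_wsse(c(X52 = 0.6), spec4, ev0), 0.5)
  # symmetric in residual sign
  evp <- stub_evaluator(c(BOD = 2, TN = 4, TSS = 0))
  evm <- stub_evaluator(c(BOD = 0, TN = 0, TSS = 0))
  expect_equal(objective_wsse(c(X52 = 0.6), spec2, evp),
               objective_wsse(c(X52 = 0.6), spec2, evm))
  # failed evaluations draw the penalty
  evna <- stub_evaluator(c(BOD = NA_real_, TN = 1, TSS = 1))
  expect_equal(objective_wsse(c(X52 = 0.6), spec2, evna), spec2$penalty)
  expect_error(objective_spec(c(BOD = 1), sigma = c(BOD = 0), codes = "X52"),
               "positive")
})

test_that("simplex minimization solves standard benchmarks", {
  r <- nelder_mead(function(x) (x - 2)^2, 0)
  expect_lt(abs(r$par - 2), 1e-6)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r2 <- nelder_mead(rosen, c(-1.2, 1), control = list(max_iter = 2000))
  expect_lt(r2$value, 1e-8)
  expect_equal(unname(r2$par), c(1, 1), tolerance = 1e-4)
  expect_true(r2$converged)
})

test_that("convex quadratics are solved from random starts in <= 4 dims", {
  set.seed(17)
  target <- c(1, -2, 3, 0.5)
  w <- c(1, 4, 0.5, 2)
  f <- function(x) sum(w * (x - target)^2)
  for (i in 1:10) {
    r <- nelder_mead(f, runif(4, -5, 5), control = list(max_iter = 4000))
    expect_lt(max(abs(r$par - target)), 1e-6)
  }
})

test_that("best value is non-increasing and bounds are respected", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r <- nelder_mead(rosen, c(-1.2, 1), control = list(max_iter = 1500))
  expect_true(all(diff(r$trace$best) <= 1e-14))
  expect_setequal(unique(r$trace$move) %in%
                    c("reflect", "expand", "contract", "shrink"), TRUE)
  # box constraints: unconstrained minimum (2) outside the box
  rb <- nelder_mead(function(x) (x - 2)^2, 0.5, lower = 0, upper = 1)
  expect_lt(abs(rb$par - 1), 1e-6)
  expect_true(rb$par <= 1)
  expect_error(nelder_mead(function(x) x^2, 5, lower = 0, upper = 1),
               "outside bounds")
  # iteration cap is reported, not hidden
  rc <- nelder_mead(rosen, c(-1.2, 1), control = list(max_iter = 3))
  expect_false(rc$converged)
  expect_equal(rc$termination, "max_iter")
})

test_that("calibration recovers identifiable parameters from synthetic data", {
  reg <- ifas_registry()
  cfg <- plant_config()
  ev <- pilot_evaluator(cfg, reg)
  theta <- c(X52 = 0.60, X53 = 0.50)
  obs <- generate_synthetic_observation(ev, theta, sigma = 0, seed = 1)
  res <- calibrate(ev, obs$observed, names(theta), reg)
  est <- stats::setNames(res$parameters$estimated, res$parameters$code)
  expect_lt(max(abs(est - theta) / theta), 0.01)
  expect_true(all(est >= reg$low[match(names(theta), reg$code)] &
                  est <= reg$high[match(names(theta), reg$code)]))
  # noisy observations: median error over seeds within 5% of the range
  rng_w <- (reg$high - reg$low)[match(names(theta), reg$code)]
  errs <- sapply(1:6, function(s) {
    o <- generate_synthetic_observation(ev, theta, sigma = 0.02, seed = s)
    r <- calibrate(ev, o$observed, names(theta), reg)
    abs(stats::setNames(r$parameters$estimated, r$parameters$code) - theta) / rng_w
  })
  expect_lt(max(apply(errs, 1, median)), 0.05)
})

test_that("calibrating against the model's own defaults needs no adjustment", {
  reg <- ifas_registry()
  ev <- pilot_evaluator(plant_config(), reg)
  obs <- ev()  # outputs at defaults
  res <- calibrate(ev, obs, c("X52", "X53"), reg)
  expect_lt(max(res$parameters$adjustment), 1e-3)
  expect_lt(res$objective, 1e-10)
})

test_that("bookkeeping tables report absolute adjustments and deviations", {
  tab <- calibration_table(c(X16 = 0.51, X12 = 0.39))
  expect_equal(tab$default, c(0.62, 0.48))
  expect_equal(tab$adjustment, c(0.11, 0.09))
  dev <- deviation_table(c(BOD = 24.8, TN = 12.9), c(TN = 14.2, BOD = 28.4))
  expect_equal(dev$deviation, c(3.6, 1.3))
  ev_bad <- function(params = NULL, ...) c(BOD = NA_real_, TN = NA, TSS = NA)
  expect_error(calibrate(ev_bad, c(BOD = 1, TN = 1, TSS = 1), "X52"),
               "defaults")
})
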