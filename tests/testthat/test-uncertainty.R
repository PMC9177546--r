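# Monte-Carlo uncertainty propagation and the GUM-style shape rules.

test_that("standard uncertainties follow the PDF shape rules", {
  # uniform over the aerobic-yield literature range 0.63..0.69 (a = 0.03)
  expect_equal(std_from_pdf(pdf_spec("X52", "uniform", low = 0.63, high = 0.69)),
               0.03 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(std_from_pdf(pdf_spec("X52", "uniform",
                                           low = 0.63, high = 0.69)), 7),
               0.0173205)
  expect_equal(std_from_pdf(pdf_spec("p", "triangular", center = 0, a = 0.6)),
               0.6 / sqrt(6), tolerance = 1e-12)
  expect_equal(round(std_from_pdf(pdf_spec("p", "triangular", center = 0, a = 0.6)), 7),
               0.2449490)
  expect_equal(std_from_pdf(pdf_spec("p", "normal", center = 2, sd = 1)), 1)
  expect_equal(std_from_pdf(pdf_spec("p", "normal", center = 2, sd = 99),
                            samples = NULL), 99)
  sn <- pdf_spec("p", "normal", center = 2, sd = 1)
  sn$sd <- NULL
  expect_equal(std_from_pdf(sn, samples = c(1, 2, 3)), 1)
  expect_error(std_from_pdf(sn, samples = 2), "samples")
  expect_error(pdf_spec("p", "uniform", center = 1, a = 0), "positive")
  expect_error(pdf_spec("p", "normal", center = 1, sd = -1), "sd")
})

test_that("expanded uncertainty is the exact coverage identity", {
  expect_equal(expanded_uncertainty(0.67), 1.3132)
  expect_equal(expanded_uncertainty(2.16), 4.2336)
  expect_equal(expanded_uncertainty(0), 0)
  u <- c(0.1, 2.3, 11)
  expect_equal(expanded_uncertainty(u) / u, rep(1.96, 3))
  expect_error(expanded_uncertainty(-0.1), ">= 0")
})

test_that("MC propagation reproduces closed-form uncertainties", {
  # identity model: U_c -> a / sqrt(3)
  evi <- function(params = NULL, ...) c(Y = unname(params["p"]))
  spec <- pdf_spec("p", "uniform", center = 1, a = 0.3)
  res <- mc_propagate(evi, list(spec), n = 1e5, seed = 42)
  expect_equal(res$table$U_c, 0.3 / sqrt(3), tolerance = 0.01)
  expect_equal(res$table$U_e, 1.96 * res$table$U_c)  # exact identity
  expect_equal(res$table$mean, 1, tolerance = 0.005)
  # constant model: zero uncertainty
  resc <- mc_propagate(stub_evaluator(), list(spec), n = 2000, seed = 1)
  expect_equal(resc$table$U_c, c(0, 0, 0))
  # additive independent uniforms: variances add
  eva <- function(params = NULL, ...) c(Y = unname(params["a"] + params["b"]))
  specs <- list(pdf_spec("a", "uniform", center = 0, a = 0.5),
                pdf_spec("b", "uniform", center = 0, a = 0.2))
  resa <- mc_propagate(eva, specs, n = 5e4, seed = 7)
  expect_equal(resa$table$U_c^2, 0.5^2 / 3 + 0.2^2 / 3, tolerance = 0.02)
})

test_that("MC error decays with sample size and seeds reproduce exactly", {
  evi <- function(params = NULL, ...) c(Y = unname(params["p"]))
  spec <- pdf_spec("p", "uniform", center = 0, a = 1)
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    e <- vapply(1:5, function(s)
      mc_propagate(evi, list(spec), n = n, seed = s)$table$U_c, numeric(1))
    mean(abs(e - 1 / sqrt(3)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  r1 <- mc_propagate(evi, list(spec), n = 5000, seed = 3)
  r2 <- mc_propagate(evi, list(spec), n = 5000, seed = 3)
  expect_identical(r1$samples, r2$samples)
})

test_that("propagation guards its preconditions", {
  evi <- function(params = NULL, ...) c(Y = unname(params["p"]))
  expect_error(mc_propagate(evi, list(), n = 100), "no PDF")
  # evaluator failing for >1% of draws aborts with diagnostics
  ev_flaky <- function(params = NULL, ...)
    if (params[["p"]] > 0.5) c(Y = NA_real_) else c(Y = 1)
  spec <- pdf_spec("p", "uniform", center = 0.5, a = 0.5)
  expect_error(mc_propagate(ev_flaky, list(spec), n = 500, seed = 1),
               "converge")
})

test_that("bundled literature ranges load as uniform PDF specs", {
  specs <- read_pdf_specs()
  codes <- vapply(specs, `[[`, character(1), "code")
  expect_setequal(codes, c("X52", "X53", "X16", "X12"))
  x12 <- specs[[match("X12", codes)]]
  expect_equal(c(x12$low, x12$high), c(0.375, 0.48))
  expect_equal(std_from_pdf(specs[[match("X52", codes)]]), 0.03 / sqrt(3),
               tolerance = 1e-9)
})

test_that("synthetic observations are reproducible and noise-controlled", {
  ev <- pilot_evaluator()
  theta <- c(X52 = 0.6)
  o0 <- generate_synthetic_observation(ev, theta, sigma = 0, seed = 5)
  expect_identical(o0$observed, o0$truth)       # sigma = 0 is exact
  o1 <- generate_synthetic_observation(ev, theta, sigma = 0.05, seed = 5)
  o2 <- generate_synthetic_observation(ev, theta, sigma = 0.05, seed = 5)
  expect_identical(o1$observed, o2$observed)    # same seed, same observation
  o3 <- generate_synthetic_observation(ev, theta, sigma = 0.05, seed = 6)
  expect_false(identical(o1$observed, o3$observed))
  expect_true(all(o1$observed >= 0))
})
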