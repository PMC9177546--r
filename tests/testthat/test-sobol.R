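# Variance-based decomposition: design layout, estimators against closed
# forms, bootstrap intervals, influence flags.

test_that("Saltelli designs have the prescribed block structure", {
  d <- saltelli_sample(unit_ranges(4), n = 8, second_order = TRUE, seed = 1)
  expect_equal(nrow(d$X), 8 * (2 * 4 + 2))   # n (2k + 2)
  d1 <- saltelli_sample(unit_ranges(4), n = 8, second_order = FALSE, seed = 1)
  expect_equal(nrow(d1$X), 8 * (4 + 2))      # n (k + 2)
  expect_true(all(d$X >= 0 & d$X <= 1))
  # physical ranges honoured: default 0.666 spans 0.333..0.999 at +/-50%
  reg <- ifas_registry()
  dr <- saltelli_sample(reg[reg$code %in% c("X52", "X53"), ], n = 16, seed = 2)
  x52 <- dr$X[, "X52"]
  expect_true(all(x52 >= 0.333 & x52 <= 0.999))
  expect_gt(diff(range(x52)), 0.5)
  expect_warning(saltelli_sample(unit_ranges(3), n = 10, seed = 1), "power of two")
  expect_error(saltelli_sample(cbind(low = c(0, 1), high = c(1, 1)), n = 8),
               "empty")
  a <- saltelli_sample(unit_ranges(5), n = 32, seed = 7)
  b <- saltelli_sample(unit_ranges(5), n = 32, seed = 7)
  expect_identical(a$X, b$X)
})

test_that("indices isolate a single active factor", {
  d <- saltelli_sample(unit_ranges(3), n = 1024, seed = 3)
  res <- sobol_indices(d$X01[, 1], d, boot = 150, seed = 4)
  expect_gt(res$table$S1[1], 0.95)
  expect_gt(res$table$ST[1], 0.95)
  expect_lt(max(abs(res$table$S1[2:3])), 0.05)
  expect_lt(max(res$table$ST[2:3]), 0.05)
})

test_that("additive two-factor model splits variance evenly", {
  d <- saltelli_sample(unit_ranges(2), n = 2048, second_order = TRUE, seed = 5)
  y <- d$X01[, 1] + d$X01[, 2]
  res <- sobol_indices(y, d, boot = 150, seed = 6)
  expect_equal(res$table$S1, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(res$table$ST, res$table$S1, tolerance = 0.05)
  expect_lt(abs(res$S2[1, 2]), 0.05)
  # analytic total variance of x1 + x2, x ~ U(0,1): 1/6
  expect_equal(res$V, 1 / 6, tolerance = 0.05)
})

test_that("Ishigami indices match closed forms within bootstrap error", {
  d <- saltelli_sample(cbind(low = rep(-pi, 3), high = rep(pi, 3)),
                       n = 2^13, second_order = TRUE, seed = 7)
  res <- sobol_indices(ishigami(d$X), d, boot = 200, seed = 8)
  tr <- ishigami_truth()
  expect_lt(max(abs(res$table$S1 - tr$S1) / pmax(res$table$S1_se, 1e-3)), 3)
  expect_lt(max(abs(res$table$ST - tr$ST) / pmax(res$table$ST_se, 1e-3)), 3)
  # the x1:x3 interaction is the only appreciable second-order term
  expect_equal(res$S2[1, 3], tr$ST[3], tolerance = 0.1)
  expect_lt(abs(res$S2[1, 2]), 0.05)
})

test_that("total-order consistency: ST ~ S1 + sum of pairwise terms", {
  d <- saltelli_sample(unit_ranges(2), n = 2^12, second_order = TRUE, seed = 9)
  y <- d$X01[, 1] * d$X01[, 2]   # pure pairwise interaction model
  res <- sobol_indices(y, d, boot = 150, seed = 10)
  expect_equal(res$table$ST[1], res$table$S1[1] + res$S2[1, 2], tolerance = 0.08)
})

test_that("additive ST - S1 gap shrinks with the sample size", {
  gaps <- vapply(c(256, 1024, 4096), function(n) {
    d <- saltelli_sample(unit_ranges(2), n = n, second_order = FALSE, seed = 11)
    res <- sobol_indices(d$X01[, 1] + d$X01[, 2], d, boot = 100, seed = 12)
    max(abs(res$table$ST - res$table$S1))
  }, numeric(1))
  expect_lt(gaps[3], gaps[1])
  expect_lt(gaps[3], 0.02)
})

test_that("bootstrap intervals behave and degenerate cases error", {
  d <- saltelli_sample(unit_ranges(2), n = 256, seed = 13)
  expect_error(sobol_indices(rep(1, nrow(d$X)), d, boot = 100), "zero total")
  y <- d$X01[, 1] + 0.3 * d$X01[, 2]
  r1 <- sobol_indices(y, d, boot = 150, seed = 14)
  r2 <- sobol_indices(y, d, boot = 150, seed = 14)
  expect_identical(r1$table, r2$table)   # seeded bootstrap determinism
  expect_true(all(r1$table$S1_lo <= r1$table$S1_hi))
  expect_error(bootstrap_ci(y, d, reps = 1), "at least 2")
})

test_that("bootstrap CIs cover the true first-order index", {
  hits <- 0
  for (s in 1:25) {
    d <- saltelli_sample(unit_ranges(2), n = 1024, second_order = FALSE, seed = s)
    res <- sobol_indices(d$X01[, 1] + d$X01[, 2], d, boot = 100, seed = s + 1000)
    if (res$table$S1_lo[1] <= 0.5 && 0.5 <= res$table$S1_hi[1]) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.8)
})

test_that("influence and interaction flags follow the 0.05 threshold", {
  tab <- data.frame(factor = c("a", "b", "c"),
                    S1 = c(0.10, 0.049, 0.90), S1_se = 0, S1_lo = 0, S1_hi = 0,
                    ST = c(0.20, 0.049, 0.93), ST_se = 0, ST_lo = 0, ST_hi = 0)
  res <- structure(list(table = tab, S2 = NULL, V = 1, f0 = 0, n = 10, k = 3,
                        level = 0.95, boot = 0,
                        estimators = c(S1 = "x", ST = "x", S2 = "x")),
                   class = "sobol_result")
  fl <- flag_influential_sobol(res, 0.05)
  expect_setequal(fl$influential, c("a", "c"))          # 0.049 excluded
  expect_true(fl$table$interacting[1])                  # ST - S1 = 0.10
  expect_false(fl$table$interacting[3])                 # gap 0.03
  expect_true(fl$table$influential[fl$table$ST == 0.20])
})
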