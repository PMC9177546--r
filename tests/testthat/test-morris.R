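# Method-of-Morris: design bookkeeping, elementary effects, summaries,
# normalization and screening.

test_that("trajectory designs satisfy the Morris construction", {
  d <- sample_morris_design(unit_ranges(2), r = 1, p = 4, seed = 1)
  expect_equal(nrow(d$X), 3)           # r * (k + 1)
  expect_equal(d$delta, 2 / 3)         # p / (2 (p - 1))
  for (r in c(3, 7)) {
    k <- 5
    d <- sample_morris_design(unit_ranges(k), r = r, p = 4, seed = r)
    expect_equal(nrow(d$X01), r * (k + 1))
    # all coordinates on the p-level grid
    expect_true(all(abs(d$X01 * 3 - round(d$X01 * 3)) < 1e-12))
    for (t in seq_len(r)) {
      rows <- (t - 1) * (k + 1) + seq_len(k + 1)
      difs <- diff(d$X01[rows, ])
      # consecutive rows differ in exactly one coordinate, by +/- delta
      expect_true(all(rowSums(difs != 0) == 1))
      expect_true(all(abs(difs[difs != 0]) - d$delta < 1e-12))
      # each factor moves exactly once per trajectory
      expect_equal(sort(apply(difs != 0, 1, which)), seq_len(k))
    }
  }
  expect_error(sample_morris_design(unit_ranges(2), r = 1, p = 1), "levels")
  expect_error(sample_morris_design(cbind(low = 1, high = 1), r = 1), "empty|two factors")
})

test_that("designs are reproducible under a fixed seed", {
  a <- sample_morris_design(unit_ranges(6), r = 4, p = 4, seed = 99)
  b <- sample_morris_design(unit_ranges(6), r = 4, p = 4, seed = 99)
  expect_identical(a$X, b$X)
  expect_identical(a$steps, b$steps)
})

test_that("elementary effects are exact for linear models", {
  d <- sample_morris_design(unit_ranges(3), r = 6, p = 4, seed = 5)
  # constant model
  expect_true(all(elementary_effects(d, rep(4.2, nrow(d$X))) == 0))
  # unit-coordinate identity
  ee1 <- elementary_effects(d, d$X01[, 1])
  expect_equal(unname(ee1[, 1]), rep(1, 6))
  expect_true(all(ee1[, 2:3] == 0))
  # linearity makes the finite difference exact
  ee <- elementary_effects(d, 3 * d$X01[, 1] + 5 * d$X01[, 2])
  expect_equal(unname(colMeans(ee)), c(3, 5, 0))
  expect_lt(max(apply(ee, 2, sd)), 1e-12)
  expect_error(elementary_effects(d, 1:5), "per design row")
})

test_that("non-finite outputs drop whole trajectories with a cap", {
  d <- sample_morris_design(unit_ranges(2), r = 10, p = 4, seed = 2)
  y <- 2 * d$X01[, 1]
  y[4] <- NA  # poisons trajectory 2
  expect_message(ee <- elementary_effects(d, y), "dropped")
  expect_equal(nrow(ee), 9)
  expect_equal(attr(ee, "n_dropped"), 1)
  y[seq(1, 30, by = 3)] <- Inf
  expect_error(suppressMessages(elementary_effects(d, y)), "20%")
})

test_that("summary statistics follow the elementary-effect definitions", {
  # sign cancellation: mu vanishes, mu* does not
  s <- morris_summary(cbind(a = c(1, -1), b = c(1, 1)))
  expect_equal(s$mu, c(0, 1))
  expect_equal(s$mu_star, c(1, 1))
  # constant effects: sigma = 0, B = |c|
  s2 <- morris_summary(cbind(a = c(-2, -2, -2), b = c(1, 1, 1)))
  expect_equal(s2$sigma, c(0, 0))
  expect_equal(s2$B, c(2, 1))
  expect_equal(s2$polarity, c("-", "+"))
  # hand arithmetic: EE = {2, 4}
  s3 <- morris_summary(cbind(a = c(2, 4), b = c(0, 0)))
  expect_equal(s3$mu[1], 3)
  expect_equal(s3$mu_star[1], 3)
  expect_equal(s3$sigma[1], sqrt(2))
  expect_equal(s3$B[1], sqrt(11))
  expect_error(morris_summary(cbind(a = 1, b = 2)), "at least two")
})

test_that("mu* is invariant to flipping a factor's sign; polarity is not", {
  d <- sample_morris_design(unit_ranges(2), r = 20, p = 4, seed = 31)
  f <- function(s) s * 4 * d$X01[, 1] + 2 * d$X01[, 2]^2
  s_pos <- morris_summary(elementary_effects(d, f(1)))
  s_neg <- morris_summary(elementary_effects(d, f(-1)))
  expect_equal(s_pos$mu_star, s_neg$mu_star)
  expect_equal(s_pos$sigma, s_neg$sigma)
  expect_equal(s_pos$B, s_neg$B)
  expect_equal(s_pos$polarity[1], "+")
  expect_equal(s_neg$polarity[1], "-")
})

test_that("min-max normalization maps extremes to 0 and 1", {
  expect_equal(normalize_scores(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(normalize_scores(c(7, 3)), c(1, 0))
  set.seed(8)
  x <- rnorm(50)
  z <- normalize_scores(x)
  expect_equal(z[which.min(x)], 0)
  expect_equal(z[which.max(x)], 1)
  expect_true(all(z >= 0 & z <= 1))
  expect_error(normalize_scores(rep(2, 4)), "distinct")
})

test_that("screening applies the inclusive 0.1 threshold and top-k forwarding", {
  set.seed(9)
  k <- 68
  d <- sample_morris_design(unit_ranges(k), r = 8, p = 4, seed = 10)
  beta <- c(10, 8, 6, 5, 4, rep(0.05, k - 5))
  y <- as.numeric(d$X01 %*% beta)
  res <- morris_summary(elementary_effects(d, y))
  scr <- screen_influential(res, threshold = 0.1, top_k = 10)
  expect_length(scr$top, 10)
  expect_true(all(paste0("x", 1:5) %in% scr$influential))
  # the maximal factor is always included; boundary cases are inclusive
  expect_true(res$factor[which.max(res$z_mu_star)] %in% scr$influential)
  tab <- scr$table
  expect_true(all(tab$selected == (tab$z_mu_star >= 0.1)))
  expect_false(any(tab$z_mu_star[!tab$selected] >= 0.1))
})

test_that("additive linear models rank by |coefficient x range width|", {
  rng <- cbind(low = c(0, 0, 0), high = c(1, 4, 2))
  d <- sample_morris_design(rng, r = 10, p = 4, seed = 12)
  y <- 5 * d$X[, 1] + 2 * d$X[, 2] + 3 * d$X[, 3]  # physical-range widths 1, 4, 2
  s <- morris_summary(elementary_effects(d, y))
  expect_lt(max(s$sigma), 1e-10)
  # range-scaled effects: 5*1 = 5, 2*4 = 8, 3*2 = 6
  expect_equal(s$factor[order(-s$B)], c("x2", "x3", "x1"))
})
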