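# Variance-based (Sobol) sensitivity decomposition on Saltelli-type designs.
#
# Estimators (recorded in the result metadata): Saltelli-2010 for first-order
# indices, Jansen for total-order, Saltelli-2002 cross-matrix for closed
# second-order indices. Sampling uses a seeded Latin-hypercube (variance
# reduction over plain pseudo-random draws) over the declared factor ranges.

#' Saltelli-type sampling design
#'
#' Builds the radial evaluation blocks for first-, total- and (optionally)
#' second-order index estimation: base matrices A and B, the cross matrices
#' AB_i (A with column i from B) and, when `second_order`, BA_i. Total row
#' count is `n * (k + 2)`, or `n * (2k + 2)` with second-order blocks.
#'
#' @param ranges factor ranges as in [sample_morris_design()]; for a
#'   parameter registry, `low`/`high` (+/-50% of defaults) are used.
#' @param n base sample size (a power of two is recommended; other values
#'   draw a warning).
#' @param second_order include the BA_i blocks for second-order estimation.
#' @param seed RNG seed.
#' @param method `"lhs"` (default, seeded Latin hypercube) or `"random"`.
#' @return A `saltelli_design`: physical evaluation matrix `X` (all blocks
#'   stacked), unit-coordinate `X01`, block layout, `n`, `k`, factor codes.
#' @export
#' @examples
#' d <- saltelli_sample(cbind(low = rep(0, 4), high = rep(1, 4)), n = 8)
#' nrow(d$X)  # 8 * (2*4 + 2) = 80
saltelli_sample <- function(ranges, n, second_order = TRUE, seed = NULL,
                            method = c("lhs", "random")) {
  method <- match.arg(method)
  rng <- as_ranges(ranges)
  k <- nrow(rng)
  if (k < 2) stop_ifas("need at least two factors for a Sobol decomposition")
  if (n < 2) stop_ifas("base sample size n must be >= 2")
  if (abs(log2(n) - round(log2(n))) > 1e-9)
    warning("base sample size n = ", n, " is not a power of two")
  U <- with_seed(seed, {
    if (method == "lhs") lhs::randomLHS(n, 2 * k) else
      matrix(stats::runif(n * 2 * k), n, 2 * k)
  })
  A <- U[, seq_len(k), drop = FALSE]
  B <- U[, k + seq_len(k), drop = FALSE]
  blocks <- list(A = A, B = B)
  for (i in seq_len(k)) {
    AB <- A; AB[, i] <- B[, i]
    blocks[[paste0("AB", i)]] <- AB
  }
  if (second_order) {
    for (i in seq_len(k)) {
      BA <- B; BA[, i] <- A[, i]
      blocks[[paste0("BA", i)]] <- BA
    }
  }
  X01 <- do.call(rbind, blocks)
  colnames(X01) <- rownames(rng)
  X <- sweep(sweep(X01, 2, rng$high - rng$low, "*"), 2, rng$low, "+")
  # warm-start map for model evaluation: each cross-matrix row differs from
  # its base row (A for AB_i, B for BA_i) in one coordinate
  warm_from <- rep(NA_integer_, nrow(X01))
  for (b in seq_along(blocks)[-(1:2)]) {
    base_off <- if (startsWith(names(blocks)[b], "AB")) 0L else n
    warm_from[(b - 1L) * n + seq_len(n)] <- base_off + seq_len(n)
  }
  structure(list(X = X, X01 = X01, block_names = names(blocks), n = n, k = k,
                 second_order = second_order, codes = rownames(rng),
                 ranges = rng, seed = seed, method = method,
                 warm_from = warm_from),
            class = "saltelli_design")
}

#' Drop failed base rows from an evaluated Saltelli design
#'
#' A model evaluation that does not converge poisons one base index across
#' all blocks; that index is removed consistently from every block (the
#' analogue of dropping a Morris trajectory). More than 1% dropped is an
#' error: the model, not the design, is then the problem.
#'
#' @param y outputs over the stacked design rows (may contain `NA`).
#' @param design the [saltelli_sample()] that produced them.
#' @param max_fail_rate abort threshold on the dropped fraction.
#' @return list: pruned `y`, adjusted `design`, `n_dropped`.
#' @export
prune_failed_rows <- function(y, design, max_fail_rate = 0.01) {
  stopifnot(inherits(design, "saltelli_design"))
  nb <- length(design$block_names)
  ymat <- matrix(y, nrow = design$n, ncol = nb)
  bad <- which(apply(ymat, 1, function(r) any(!is.finite(r))))
  if (!length(bad))
    return(list(y = y, design = design, n_dropped = 0L))
  if (length(bad) / design$n > max_fail_rate)
    stop_ifas(sprintf("%d of %d base rows failed to evaluate (> %.0f%%)",
                      length(bad), design$n, 100 * max_fail_rate))
  design$n <- design$n - length(bad)
  list(y = as.numeric(ymat[-bad, , drop = FALSE]), design = design,
       n_dropped = length(bad))
}

design_blocks <- function(design, y) {
  n <- design$n
  if (length(y) != n * length(design$block_names))
    stop_ifas("output length ", length(y), " does not match design rows ",
              n * length(design$block_names))
  split(y, rep(design$block_names, each = n))
}

# core estimators on one (resampled) index set
sobol_estimates <- function(yA, yB, yAB, yBA = NULL) {
  k <- ncol(yAB)
  y0 <- c(yA, yB)
  f0 <- mean(y0)
  V <- stats::var(y0)
  S1 <- vapply(seq_len(k), function(i) mean(yB * (yAB[, i] - yA)) / V, numeric(1))
  ST <- vapply(seq_len(k), function(i) mean((yA - yAB[, i])^2) / (2 * V), numeric(1))
  S2 <- NULL
  if (!is.null(yBA)) {
    S2 <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      closed <- (mean(yBA[, i] * yAB[, j]) - f0^2) / V
      S2[i, j] <- S2[j, i] <- closed - S1[i] - S1[j]
    }
  }
  list(S1 = S1, ST = ST, S2 = S2, V = V, f0 = f0)
}

#' Sobol sensitivity indices from evaluated design blocks
#'
#' First-order (share of output variance a factor explains alone),
#' total-order (the factor plus all its interactions) and, when the design
#' carries second-order blocks, pairwise interaction indices — each with
#' percentile bootstrap confidence intervals over resampled base rows.
#'
#' @param y model outputs, one per design row (stacked blocks).
#' @param design the [saltelli_sample()] that produced them.
#' @param boot bootstrap replicates (default 200; >= 100 recommended).
#' @param level confidence level (default 0.95).
#' @param seed bootstrap RNG seed.
#' @return A `sobol_result`: per-factor table (`S1`, `ST`, standard errors,
#'   CI bounds), second-order matrix `S2` (+ `S2_se`), total variance `V`,
#'   mean `f0`, estimator metadata.
#' @export
sobol_indices <- function(y, design, boot = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(design, "saltelli_design"))
  if (any(!is.finite(y))) stop_ifas("non-finite model outputs in design evaluation")
  b <- design_blocks(design, y)
  k <- design$k; n <- design$n
  yA <- b$A; yB <- b$B
  yAB <- vapply(seq_len(k), function(i) b[[paste0("AB", i)]], numeric(n))
  yBA <- if (design$second_order)
    vapply(seq_len(k), function(i) b[[paste0("BA", i)]], numeric(n)) else NULL
  if (stats::var(c(yA, yB)) <= 0)
    stop_ifas("zero total output variance: indices undefined")
  est <- sobol_estimates(yA, yB, yAB, yBA)
  ci <- bootstrap_ci(y, design, level = level, reps = boot, seed = seed)
  tab <- data.frame(factor = design$codes,
                    S1 = est$S1, S1_se = ci$S1_se,
                    S1_lo = ci$S1_lo, S1_hi = ci$S1_hi,
                    ST = est$ST, ST_se = ci$ST_se,
                    ST_lo = ci$ST_lo, ST_hi = ci$ST_hi,
                    stringsAsFactors = FALSE)
  res <- list(table = tab, S2 = est$S2, S2_se = ci$S2_se, V = est$V,
              f0 = est$f0, n = n, k = k, level = level, boot = boot,
              estimators = c(S1 = "Saltelli2010", ST = "Jansen",
                             S2 = "Saltelli2002-cross"))
  class(res) <- "sobol_result"
  res
}

#' Percentile bootstrap confidence intervals for Sobol indices
#'
#' Resamples the `n` base rows with replacement (consistently across all
#' design blocks), re-estimates the indices, and reports per-index standard
#' errors and percentile intervals.
#'
#' @inheritParams sobol_indices
#' @param reps bootstrap replicates (>= 2; >= 100 recommended).
#' @export
bootstrap_ci <- function(y, design, level = 0.95, reps = 200, seed = NULL) {
  if (reps < 2) stop_ifas("need at least 2 bootstrap replicates")
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  b <- design_blocks(design, y)
  k <- design$k; n <- design$n
  yA <- b$A; yB <- b$B
  yAB <- vapply(seq_len(k), function(i) b[[paste0("AB", i)]], numeric(n))
  yBA <- if (design$second_order)
    vapply(seq_len(k), function(i) b[[paste0("BA", i)]], numeric(n)) else NULL
  S1r <- matrix(NA_real_, reps, k)
  STr <- matrix(NA_real_, reps, k)
  S2r <- if (!is.null(yBA)) array(NA_real_, c(reps, k, k)) else NULL
  with_seed(seed, {
    for (r in seq_len(reps)) {
      ix <- sample.int(n, n, replace = TRUE)
      e <- sobol_estimates(yA[ix], yB[ix], yAB[ix, , drop = FALSE],
                           if (!is.null(yBA)) yBA[ix, , drop = FALSE])
      S1r[r, ] <- e$S1; STr[r, ] <- e$ST
      if (!is.null(S2r)) S2r[r, , ] <- e$S2
    }
  })
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  q1 <- qs(S1r); qt <- qs(STr)
  list(S1_se = apply(S1r, 2, stats::sd), ST_se = apply(STr, 2, stats::sd),
       S1_lo = q1[1, ], S1_hi = q1[2, ], ST_lo = qt[1, ], ST_hi = qt[2, ],
       S2_se = if (!is.null(S2r)) apply(S2r, c(2, 3), stats::sd),
       level = level, reps = reps)
}

#' Flag influential and interacting factors
#'
#' Influence: total-order index at or above the threshold. Interaction: the
#' total-minus-first-order gap, or any pairwise second-order index, at or
#' above the same threshold. Small negative index estimates (Monte-Carlo
#' noise) are reported as-is; values below `-threshold` are flagged.
#'
#' @param result a [sobol_indices()] result.
#' @param threshold influence threshold on total-order indices (default 0.05).
#' @return list: `influential` codes, annotated `table` with `influential`,
#'   `interacting` and `suspect_negative` flags, and the pairwise interaction
#'   matrix `pairs` for chord-style plots.
#' @export
flag_influential_sobol <- function(result, threshold = 0.05) {
  stopifnot(inherits(result, "sobol_result"))
  tab <- result$table
  tab$influential <- tab$ST >= threshold
  gap <- tab$ST - tab$S1
  s2max <- if (!is.null(result$S2))
    apply(result$S2, 1, function(r) max(r, na.rm = TRUE)) else rep(-Inf, nrow(tab))
  tab$interacting <- gap >= threshold | s2max >= threshold
  tab$suspect_negative <- pmin(tab$S1, tab$ST) < -threshold
  list(influential = tab$factor[tab$influential], table = tab,
       pairs = result$S2, threshold = threshold)
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> k = %d factors, n = %d base samples (V = %.4g)\n",
              x$k, x$n, x$V))
  cat(sprintf("estimators: S1 %s, ST %s, S2 %s; %g%% bootstrap CIs (%d reps)\n",
              x$estimators["S1"], x$estimators["ST"], x$estimators["S2"],
              100 * x$level, x$boot))
  print.data.frame(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
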