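# Method-of-Morris elementary-effects screening.
#
# Elementary effects are computed in unit-hypercube coordinates, so mu* is
# range-scaled and directly comparable across factors with different units.

#' Sample a Morris trajectory design
#'
#' Classic one-at-a-time trajectories: each of the `r` trajectories starts at
#' a random point on the `p`-level grid and moves each factor once, in random
#' order, by the standard perturbation `delta = p / (2 * (p - 1))`, giving
#' `r * (k + 1)` model evaluations in total.
#'
#' @param ranges two-column matrix or data frame (`low`, `high`) with one row
#'   per factor (rownames/`code` column used as factor codes), or a
#'   [ifas_registry()] whose `low`/`high` columns are used.
#' @param r number of trajectories.
#' @param p number of grid levels (even; default 4).
#' @param seed RNG seed for reproducible designs.
#' @return A `morris_design`: unit-coordinate matrix `X01`, physical matrix
#'   `X`, step bookkeeping (`trajectory`, `factor`, `delta` per move), and the
#'   design constants `r`, `k`, `p`, `delta`.
#' @export
#' @examples
#' d <- sample_morris_design(cbind(low = c(0, 0), high = c(1, 1)), r = 1, seed = 1)
#' nrow(d$X)  # (k + 1) rows per trajectory = 3
sample_morris_design <- function(ranges, r, p = 4, seed = NULL) {
  rng <- as_ranges(ranges)
  k <- nrow(rng)
  if (r < 1 || k < 1) stop_ifas("need r >= 1 trajectories and k >= 1 factors")
  if (p < 2) stop_ifas("grid levels p must be >= 2")
  if (p %% 2 != 0) warning("odd p gives an asymmetric step distribution; even p is standard")
  delta <- p / (2 * (p - 1))
  base_levels <- (seq_len(p) - 1) / (p - 1)
  X01 <- matrix(NA_real_, r * (k + 1), k)
  steps <- data.frame(trajectory = integer(r * k), step = integer(r * k),
                      factor = integer(r * k), delta = numeric(r * k))
  with_seed(seed, {
    for (t in seq_len(r)) {
      dir <- sample(c(delta, -delta), k, replace = TRUE)
      # base levels restricted so the perturbed coordinate stays in [0, 1]
      x <- vapply(dir, function(d) {
        ok <- base_levels[base_levels + d >= -1e-12 & base_levels + d <= 1 + 1e-12]
        ok[sample.int(length(ok), 1)]
      }, numeric(1))
      ord <- sample.int(k)
      row0 <- (t - 1) * (k + 1)
      X01[row0 + 1, ] <- x
      for (s in seq_len(k)) {
        j <- ord[s]
        x[j] <- min(max(x[j] + dir[j], 0), 1)
        X01[row0 + s + 1, ] <- x
        ix <- (t - 1) * k + s
        steps$trajectory[ix] <- t; steps$step[ix] <- s
        steps$factor[ix] <- j; steps$delta[ix] <- dir[j]
      }
    }
  })
  colnames(X01) <- rownames(rng)
  X <- sweep(sweep(X01, 2, rng$high - rng$low, "*"), 2, rng$low, "+")
  structure(list(X01 = X01, X = X, steps = steps, r = r, k = k, p = p,
                 delta = delta, ranges = rng, seed = seed),
            class = "morris_design")
}

as_ranges <- function(ranges) {
  if (inherits(ranges, "parameter_registry"))
    return(data.frame(low = ranges$low, high = ranges$high,
                      row.names = ranges$code))
  rng <- as.data.frame(ranges)
  if (!all(c("low", "high") %in% names(rng))) {
    stopifnot(ncol(rng) >= 2)
    names(rng)[1:2] <- c("low", "high")
  }
  if (is.null(rownames(rng)) || identical(rownames(rng), as.character(seq_len(nrow(rng)))))
    if (!is.null(rng$code)) rownames(rng) <- rng$code
    else rownames(rng) <- paste0("x", seq_len(nrow(rng)))
  if (any(rng$high <= rng$low)) stop_ifas("empty factor range(s)")
  rng[, c("low", "high")]
}

#' Elementary effects from evaluated design rows
#'
#' One finite-difference elementary effect per factor per trajectory,
#' computed in unit-hypercube coordinates and sign-corrected for negative
#' steps: `EE = (y_after - y_before) / delta_signed`.
#'
#' @param design a [sample_morris_design()].
#' @param y numeric vector of model outputs, one per design row. Trajectories
#'   containing non-finite outputs are dropped (with a message) and counted
#'   in `attr(, "n_dropped")`; more than 20% dropped is an error.
#' @return `r x k` matrix of elementary effects.
#' @export
elementary_effects <- function(design, y) {
  stopifnot(inherits(design, "morris_design"))
  r <- design$r; k <- design$k
  if (length(y) != r * (k + 1))
    stop_ifas("need one output per design row (", r * (k + 1), "), got ", length(y))
  ee <- matrix(NA_real_, r, k, dimnames = list(NULL, colnames(design$X01)))
  bad <- logical(r)
  for (t in seq_len(r)) {
    rows <- (t - 1) * (k + 1) + seq_len(k + 1)
    yt <- y[rows]
    if (any(!is.finite(yt))) { bad[t] <- TRUE; next }
    st <- design$steps[design$steps$trajectory == t, ]
    ee[t, st$factor] <- (yt[st$step + 1] - yt[st$step]) / st$delta
  }
  if (any(bad)) {
    message(sum(bad), " of ", r, " trajectories dropped (non-finite outputs)")
    if (mean(bad) > 0.2)
      stop_ifas("more than 20% of trajectories dropped; refusing to summarize")
    ee <- ee[!bad, , drop = FALSE]
  }
  attr(ee, "n_dropped") <- sum(bad)
  ee
}

#' Summarize elementary effects per factor
#'
#' Computes the Morris statistics: mean `mu`, absolute mean `mu_star` (robust
#' to sign cancellation in non-monotonic responses), sample standard
#' deviation `sigma` (divisor r-1), the rank score `B = sqrt(mu_star^2 +
#' sigma^2)`, polarity (sign of `mu`), min-max normalized `mu_star` and `B`,
#' and a coarse category: negligible (low normalized mu*), linear/additive
#' (influential with low normalized sigma) or nonlinear/interacting (high
#' normalized sigma).
#'
#' @param ee elementary-effects matrix from [elementary_effects()].
#' @param threshold normalization threshold used for the categories (0.1).
#' @return A `morris_result` data frame, one row per factor, ordered as the
#'   input columns, with ranks by `B`.
#' @export
#' @examples
#' ee <- cbind(a = c(2, 4), b = c(1, 1))
#' morris_summary(ee)$mu_star  # 3, 1
morris_summary <- function(ee, threshold = 0.1) {
  if (nrow(ee) < 2)
    stop_ifas("need at least two elementary effects per factor for sigma")
  mu <- colMeans(ee)
  mu_star <- colMeans(abs(ee))
  sigma <- apply(ee, 2, stats::sd)
  B <- sqrt(mu_star^2 + sigma^2)
  polarity <- ifelse(mu > 0, "+", ifelse(mu < 0, "-", "0"))
  z_mu_star <- tryCatch(normalize_scores(mu_star), error = function(e) rep(NA_real_, length(mu_star)))
  z_B <- tryCatch(normalize_scores(B), error = function(e) rep(NA_real_, length(B)))
  z_sigma <- tryCatch(normalize_scores(sigma), error = function(e) rep(NA_real_, length(sigma)))
  category <- ifelse(is.na(z_mu_star), NA_character_,
              ifelse(z_sigma >= threshold, "nonlinear/interacting",
              ifelse(z_mu_star >= threshold, "linear-additive", "negligible")))
  out <- data.frame(factor = colnames(ee), mu = mu, mu_star = mu_star,
                    sigma = sigma, B = B, polarity = polarity,
                    z_mu_star = z_mu_star, z_B = z_B, category = category,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$rank <- rank(-out$B, ties.method = "first")
  attr(out, "r") <- nrow(ee)
  class(out) <- c("morris_result", "data.frame")
  out
}

#' Min-max normalization to the unit interval
#'
#' Affine rescaling `z = (x - min x) / (max x - min x)`; the minimum maps to
#' 0 and the maximum to 1.
#'
#' @param values numeric vector with at least two distinct values.
#' @export
#' @examples
#' normalize_scores(c(1, 2, 3))  # 0, 0.5, 1
normalize_scores <- function(values) {
  if (length(values) < 2 || max(values) - min(values) <= 0)
    stop_ifas("normalization undefined: need at least two distinct values")
  (values - min(values)) / (max(values) - min(values))
}

#' Screen influential factors from a Morris summary
#'
#' Influential set: normalized mu* at or above the threshold (inclusive).
#' Separately, the `top_k` factors ranked by `B` (ties broken by mu*, then by
#' input order) are forwarded to the variance-based stage.
#'
#' @param result a [morris_summary()].
#' @param threshold normalized mu* influence threshold (default 0.1).
#' @param top_k number of factors to forward (default 10).
#' @return list: `influential` codes, `top` codes (length `min(top_k, k)`),
#'   and the annotated `table` with `selected`/`forwarded` flags.
#' @export
screen_influential <- function(result, threshold = 0.1, top_k = 10) {
  stopifnot(inherits(result, "morris_result"))
  if (all(is.na(result$z_mu_star)))
    stop_ifas("normalized scores unavailable (all mu* equal)")
  tab <- as.data.frame(result)
  tab$selected <- !is.na(tab$z_mu_star) & tab$z_mu_star >= threshold
  ord <- order(-tab$B, -tab$mu_star, seq_len(nrow(tab)))
  top <- tab$factor[ord[seq_len(min(top_k, nrow(tab)))]]
  tab$forwarded <- tab$factor %in% top
  list(influential = tab$factor[tab$selected], top = top, table = tab,
       threshold = threshold, top_k = top_k)
}

#' @export
print.morris_result <- function(x, n = 10, ...) {
  cat(sprintf("<morris_result> %d factors, r = %s trajectories\n",
              nrow(x), attr(x, "r") %||% "?"))
  ord <- order(x$rank)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more factors\n")
  invisible(x)
}
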