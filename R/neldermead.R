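# Nelder-Mead simplex parameter estimation against observed effluent quality.

#' Weighted sum-of-squares calibration objective
#'
#' The negative log-likelihood (up to constants) of independent normal
#' observation errors: `sum(((y_j(theta) - t_j) / sigma_j)^2)` over the
#' assessed effluent outputs. Zero iff the model hits every target exactly;
#' symmetric in residual sign. Evaluations where the model fails to converge
#' receive a large penalty value.
#'
#' @param params named parameter (sub)vector to evaluate.
#' @param objective an [objective_spec()].
#' @param evaluator model evaluator with the [ifas_evaluator()] contract.
#' @return scalar objective value (>= 0).
#' @export
objective_wsse <- function(params, objective, evaluator) {
  stopifnot(inherits(objective, "objective_spec"))
  y <- evaluator(params)
  y <- y[names(objective$targets)]
  if (any(!is.finite(y))) return(objective$penalty)
  sum(((y - objective$targets) / objective$sigma)^2)
}

#' Calibration objective specification
#'
#' @param targets named numeric of observed outputs (mg/L), e.g.
#'   `c(BOD = 31, TN = 14, TSS = 37)`.
#' @param sigma named numeric of per-target scales (mg/L). Defaults to the
#'   reported spread where one is given, else 5% of the target (the
#'   likelihood needs a scale; reported spreads are the least arbitrary
#'   source).
#' @param codes parameter codes to calibrate (non-empty).
#' @param penalty objective value substituted for failed model evaluations.
#' @export
objective_spec <- function(targets, sigma = NULL, codes, penalty = 1e12) {
  stopifnot(is.numeric(targets), !is.null(names(targets)), length(codes) >= 1)
  if (is.null(sigma)) sigma <- 0.05 * targets
  sigma <- sigma[names(targets)]
  fill <- !is.finite(sigma) | is.na(sigma)
  sigma[fill] <- 0.05 * targets[fill]
  if (any(sigma <= 0)) stop_ifas("objective scales sigma must be positive")
  structure(list(targets = targets, sigma = sigma, codes = codes,
                 penalty = penalty), class = "objective_spec")
}

#' Nelder-Mead simplex minimization
#'
#' From-scratch simplex search with the standard coefficients (reflection
#' alpha = 1, expansion gamma = 2, contraction beta = 0.5, shrink delta =
#' 0.5) and box constraints imposed by projecting proposed vertices onto the
#' bounds. Terminates when the relative vertex spread falls below `tol_x`,
#' the value spread below `tol_f`, or at the iteration cap (result returned,
#' flagged not converged).
#'
#' @param f objective function of a numeric vector.
#' @param x0 start point (within bounds).
#' @param lower,upper box constraints (recycled; default unbounded).
#' @param control list: `alpha`, `gamma`, `beta`, `delta`, `tol_x` (1e-8),
#'   `tol_f` (1e-12), `max_iter` (150 * dimension), `step` (initial simplex
#'   step per coordinate; default 5% of the box width or of `max(1, |x0|)`).
#' @return list: `par`, `value`, `iterations`, `evaluations`, `converged`,
#'   `termination`, `trace` (best value + move per iteration), `simplex`.
#' @export
#' @examples
#' nelder_mead(function(x) (x - 2)^2, 0)$par  # ~2
nelder_mead <- function(f, x0, lower = -Inf, upper = Inf, control = list()) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(x0 < lower | x0 > upper)) stop_ifas("start point outside bounds")
  alpha <- control$alpha %||% 1
  gamma <- control$gamma %||% 2
  beta <- control$beta %||% 0.5
  delta <- control$delta %||% 0.5
  tol_x <- control$tol_x %||% 1e-8
  tol_f <- control$tol_f %||% 1e-12
  max_iter <- control$max_iter %||% (150 * n)
  clamp <- function(x) pmin(pmax(x, lower), upper)

  width <- ifelse(is.finite(upper - lower), upper - lower, NA)
  step <- control$step %||% ifelse(is.na(width), 0.05 * pmax(1, abs(x0)), 0.05 * width)
  step <- rep_len(step, n)
  V <- matrix(rep(x0, n + 1), ncol = n, byrow = TRUE)
  for (j in seq_len(n)) {
    xj <- x0[j] + step[j]
    if (xj > upper[j]) xj <- x0[j] - step[j]
    if (xj < lower[j])  # squeezed against both bounds: tiny inward step
      xj <- x0[j] + 0.00025 * ifelse(is.na(width[j]), 1, width[j]) *
        (if (x0[j] + step[j] > upper[j]) -1 else 1)
    V[j + 1, j] <- min(max(xj, lower[j]), upper[j])
  }
  fv <- apply(V, 1, f)
  evals <- n + 1
  trace <- data.frame(iteration = integer(0), best = numeric(0),
                      move = character(0), stringsAsFactors = FALSE)
  it <- 0
  termination <- "max_iter"
  while (it < max_iter) {
    it <- it + 1
    ord <- order(fv)
    V <- V[ord, , drop = FALSE]; fv <- fv[ord]
    spread_x <- max(abs(sweep(V, 2, V[1, ], "-")) /
                      pmax(1, abs(matrix(V[1, ], n + 1, n, byrow = TRUE))))
    spread_f <- abs(fv[n + 1] - fv[1]) / max(1, abs(fv[1]))
    if (spread_x < tol_x) { termination <- "tol_x"; break }
    # value spread alone can vanish on a simplex straddling a symmetric
    # minimum; only accept it once the simplex is also geometrically small
    if (spread_f < tol_f && spread_x < 1e-4) { termination <- "tol_f"; break }
    centroid <- colMeans(V[seq_len(n), , drop = FALSE])
    xr <- clamp(centroid + alpha * (centroid - V[n + 1, ]))
    fr <- f(xr); evals <- evals + 1
    move <- "reflect"
    if (fr < fv[1]) {
      xe <- clamp(centroid + gamma * (xr - centroid))
      fe <- f(xe); evals <- evals + 1
      if (fe < fr) { V[n + 1, ] <- xe; fv[n + 1] <- fe; move <- "expand" }
      else { V[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      V[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      if (fr < fv[n + 1]) { # outside contraction
        xc <- clamp(centroid + beta * (xr - centroid))
      } else {              # inside contraction
        xc <- clamp(centroid - beta * (centroid - V[n + 1, ]))
      }
      fc <- f(xc); evals <- evals + 1
      if (fc < min(fr, fv[n + 1])) {
        V[n + 1, ] <- xc; fv[n + 1] <- fc; move <- "contract"
      } else {
        for (i in 2:(n + 1)) {
          V[i, ] <- clamp(V[1, ] + delta * (V[i, ] - V[1, ]))
          fv[i] <- f(V[i, ])
        }
        evals <- evals + n
        move <- "shrink"
      }
    }
    trace <- rbind(trace, data.frame(iteration = it, best = min(fv),
                                     move = move, stringsAsFactors = FALSE))
  }
  ord <- order(fv)
  list(par = stats::setNames(V[ord[1], ], names(x0)), value = fv[ord[1]],
       iterations = it, evaluations = evals,
       converged = termination != "max_iter", termination = termination,
       trace = trace, simplex = V[ord, , drop = FALSE])
}

#' Calibrate influential parameters against observed effluent quality
#'
#' Joint Nelder-Mead estimation of the selected parameter subset, starting
#' from the registry defaults, minimizing the normal-error weighted
#' sum-of-squares between model outputs and observed BOD/TN/TSS.
#'
#' @param evaluator model evaluator ([ifas_evaluator()]).
#' @param observed named numeric of observed effluent composites.
#' @param codes parameter codes to estimate (typically the Sobol-influential
#'   set).
#' @param registry parameter registry (bounds and defaults).
#' @param sigma optional per-target scales (see [objective_spec()]).
#' @param control [nelder_mead()] control list.
#' @return A `calibration_result`: per-parameter table (`default`,
#'   `estimated`, `adjustment` = |estimated - default|), achieved outputs,
#'   residuals and absolute deviations per output, final objective,
#'   iteration trace and termination reason.
#' @export
calibrate <- function(evaluator, observed, codes, registry = ifas_registry(),
                      sigma = NULL, control = list()) {
  stopifnot(all(codes %in% registry$code))
  spec <- objective_spec(observed, sigma, codes)
  ix <- match(codes, registry$code)
  x0 <- stats::setNames(registry$default[ix], codes)
  y0 <- evaluator(x0)
  if (any(!is.finite(y0)))
    stop_ifas("model evaluation failed at registry defaults")
  fobj <- function(x) objective_wsse(stats::setNames(x, codes), spec, evaluator)
  fit <- nelder_mead(fobj, x0, lower = registry$low[ix],
                     upper = registry$high[ix], control = control)
  est <- stats::setNames(fit$par, codes)
  achieved <- evaluator(est)[names(spec$targets)]
  tab <- calibration_table(est, registry)
  dev <- deviation_table(achieved, spec$targets)
  out <- list(parameters = tab, achieved = achieved,
              observed = spec$targets, sigma = spec$sigma,
              residuals = achieved - spec$targets,
              deviation = stats::setNames(dev$deviation, dev$output),
              objective = fit$value, termination = fit$termination,
              converged = fit$converged, iterations = fit$iterations,
              evaluations = fit$evaluations, trace = fit$trace)
  class(out) <- "calibration_result"
  out
}

#' Default-vs-estimated bookkeeping table
#'
#' The reporting convention used for calibration results: one row per
#' estimated parameter with its registry default and the absolute adjustment
#' `|estimated - default|`.
#'
#' @param estimated named numeric of estimated parameter values.
#' @param registry parameter registry supplying names, units and defaults.
#' @export
#' @examples
#' calibration_table(c(X16 = 0.51, X12 = 0.39))$adjustment  # 0.11, 0.09
calibration_table <- function(estimated, registry = ifas_registry()) {
  codes <- names(estimated)
  ix <- match(codes, registry$code)
  if (anyNA(ix)) stop_ifas("unknown parameter code(s) in estimates")
  data.frame(code = codes, name = registry$name[ix], units = registry$units[ix],
             default = registry$default[ix], estimated = as.numeric(estimated),
             adjustment = abs(as.numeric(estimated) - registry$default[ix]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Model-vs-observed deviation table
#'
#' @param predicted named numeric of model outputs (mg/L).
#' @param observed named numeric of observed values over the same outputs.
#' @return data frame with absolute deviations `|predicted - observed|`.
#' @export
#' @examples
#' deviation_table(c(BOD = 24.8, TN = 12.9), c(BOD = 28.4, TN = 14.2))
deviation_table <- function(predicted, observed) {
  outs <- names(predicted)
  data.frame(output = outs, predicted = as.numeric(predicted),
             observed = as.numeric(observed[outs]),
             deviation = abs(as.numeric(predicted) - as.numeric(observed[outs])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s after %d iterations (objective %.4g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$objective))
  print.data.frame(x$parameters, digits = 4, row.names = FALSE)
  dev <- data.frame(output = names(x$observed), observed = x$observed,
                    model = x$achieved, deviation = x$deviation)
  print.data.frame(dev, digits = 4, row.names = FALSE)
  invisible(x)
}
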