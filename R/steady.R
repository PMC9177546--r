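# Steady-state mass balances of the hybrid reactor + ideal clarifier and the
# damped-Newton solver that all pipeline stages drive.

# Transport bookkeeping: completely mixed reactor, dilution rate D = Q/V for
# solubles; suspended particulates leave at 1/SRT (wastage + clarifier
# escape combined, SRT being the total solids residence time); attached
# pools are fully retained and exchange with the suspended phase through the
# attach/detach process rows of the Gujer matrix.
transport_indices <- function() {
  nm <- ifas_state_names()
  list(soluble = which(nm %in% c("S_S", "S_I", "S_NH", "S_ND",
                                 "S_NO2", "S_NO3", "S_N2")),
       particulate = which(nm %in% c("X_S", "X_I", "X_ND",
                                     "X_BH", "X_BA1", "X_BA2")),
       attached = which(startsWith(nm, "XF_")))
}

#' Right-hand side of the reduced-model mass balances
#'
#' Returns `function(x)` computing d(state)/dt in mg/L/d for the 16 state
#' variables, given a fixed influent, plant configuration and parameter
#' vector. Used by the steady-state solver; also convenient for driving an
#' external time integrator when cross-checking the solver.
#'
#' @param influent an [fractionate_influent()] state (influent concentrations).
#' @param config [plant_config()].
#' @param params full named parameter vector.
#' @param registry parameter registry.
#' @export
ifas_rhs <- function(influent, config, params, registry = ifas_registry()) {
  pp <- model_constants(params, registry)
  Smat <- ifas_stoichiometry(params, registry)
  St <- t(Smat[, ifas_state_names()])     # components x processes
  kern <- rate_kernel(pp, config)
  idx <- transport_indices()
  D <- (config$flow_m3h * 24) / config$volume_m3   # 1/d
  srt <- config$srt_d
  xin <- as.numeric(influent)[seq_len(16)]
  function(x) {
    dx <- numeric(16)
    dx[idx$soluble] <- D * (xin[idx$soluble] - x[idx$soluble])
    dx[idx$particulate] <- D * xin[idx$particulate] - x[idx$particulate] / srt
    dx + as.numeric(St %*% kern(x))
  }
}

default_initial_state <- function(influent, config, params,
                                  registry = ifas_registry()) {
  pp <- model_constants(params, registry)
  x <- stats::setNames(numeric(16), ifas_state_names())
  xin <- as.numeric(influent)
  names(xin) <- ifas_state_names()
  hrt_d <- config$volume_m3 / (config$flow_m3h * 24)
  conc <- config$srt_d / hrt_d
  codb <- xin["S_S"] + xin["X_S"]
  if (codb > 0) {
    x["X_BH"] <- 0.5 * pp$Y_H_aer * codb * conc / (1 + pp$b_H * config$srt_d)
    x["X_BA1"] <- 20; x["X_BA2"] <- 10
    x["XF_BH"] <- 0.25 * config$attached_capacity_gm3
    x["XF_BA1"] <- 0.05 * config$attached_capacity_gm3
    x["XF_BA2"] <- 0.02 * config$attached_capacity_gm3
    x["S_S"] <- min(2, xin["S_S"])
    x["X_S"] <- 0.1 * xin["X_S"] * conc
    x["S_NH"] <- 1
    x["S_ND"] <- 0.5
    x["S_NO2"] <- 0.5
    x["S_NO3"] <- 5
    x["S_N2"] <- 5
  }
  x["S_I"] <- xin["S_I"]
  x["X_I"] <- xin["X_I"] * conc
  x["X_ND"] <- 0.2 * xin["X_ND"] * conc
  pmax(as.numeric(x), 0)
}

# residual convergence test: componentwise absolute tolerance, relaxed in
# proportion to the state magnitude above 1 mg/L (see methods vignette).
residual_ok <- function(f, x, tol) all(abs(f) <= tol * pmax(1, abs(x)))

numeric_jacobian <- function(fn, x, f0) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (fn(xp) - f0) / h
  }
  J
}

#' Solve the reduced IFAS model to steady state
#'
#' Damped Newton iteration with positivity projection on the algebraic mass
#' balances, falling back to implicit-Euler pseudo-transient continuation when
#' a Newton step stalls. Washout (a biomass pool converging to zero) is a
#' valid steady state, not an error.
#'
#' @inheritParams ifas_rhs
#' @param control list: `tol` (componentwise residual tolerance, default
#'   1e-10, scaled by `max(1, |x|)`), `max_iter` (Newton cap, default 500),
#'   `x0` (optional warm-start state).
#' @return A `steady_state` object: `state` (named concentrations),
#'   `effluent` (concentrations after the ideal clarifier), `residual_norm`,
#'   `converged`, `iterations`, `residual_trace`, plus the inputs needed by
#'   downstream summaries.
#' @export
#' @examples
#' inf <- fractionate_influent(composite_measurements(cod = 626, nh3 = 33.7,
#'                                                    tkn = 44.2, tn = 46.7))
#' ss <- solve_steady_state(inf, plant_config(), default_params())
#' ss$converged
solve_steady_state <- function(influent, config, params,
                               registry = ifas_registry(), control = list()) {
  tol <- control$tol %||% 1e-10
  max_iter <- control$max_iter %||% 500
  fn <- ifas_rhs(influent, config, params, registry)
  iters <- 0L         # all linearized steps (Newton + continuation)
  newton_iters <- 0L  # Newton steps only, capped by max_iter
  trace <- numeric(0)

  newton <- function(x, budget) {
    f <- fn(x)
    it <- 0
    while (it < budget && !residual_ok(f, x, tol)) {
      it <- it + 1
      J <- numeric_jacobian(fn, x, f)
      dx <- tryCatch(solve(J, -f), error = function(e) NULL)
      accepted <- FALSE
      if (!is.null(dx)) {
        n0 <- max(abs(f))
        lam <- 1
        for (k in 1:9) {
          xt <- pmax(x + lam * dx, 0)
          ft <- fn(xt)
          if (max(abs(ft)) < n0 * (1 - 1e-4 * lam) || residual_ok(ft, xt, tol)) {
            x <- xt; f <- ft; accepted <- TRUE
            break
          }
          lam <- lam / 2
        }
      }
      trace <<- c(trace, max(abs(f)))
      if (!accepted) break
    }
    iters <<- iters + it
    newton_iters <<- newton_iters + it
    list(x = x, f = f, ok = residual_ok(f, x, tol))
  }

  # linearized implicit-Euler pseudo-transient continuation: follows the
  # attracting trajectory so that starts land in the basin of a stable root.
  # dt stays below the biological timescale: with a positive eigenvalue
  # lambda (an unstable mode, e.g. washout with ample substrate) the step
  # amplification 1/(1 - lambda dt) only tracks the growing mode while
  # lambda dt < 1, so large dt would collapse onto the unstable root.
  ptc <- function(x, steps, dt_max = 2) {
    f <- fn(x)
    dt <- 1e-3
    for (k in seq_len(steps)) {
      J <- numeric_jacobian(fn, x, f)
      A <- diag(length(x)) / dt - J
      dxp <- tryCatch(solve(A, f), error = function(e) NULL)
      accepted <- FALSE
      if (!is.null(dxp)) {
        xt <- pmax(x + dxp, 0)
        ft <- fn(xt)
        # guarded step: a residual blow-up means dt outruns the local
        # dynamics (e.g. an unstable mode with lambda dt > 1) — shrink dt
        if (all(is.finite(ft)) && max(abs(ft)) <= 1.2 * max(abs(f)) + 1e-12) {
          x <- xt; f <- ft
          dt <- min(dt * 1.7, dt_max)
          accepted <- TRUE
        }
      }
      if (!accepted) dt <- dt / 4
      iters <<- iters + 1L
      if (residual_ok(f, x, tol)) break
    }
    x
  }

  # any eigenvalue of the Jacobian with positive real part marks an
  # unstable root (e.g. washout with ample substrate): not the operating
  # steady state the plant would settle into
  unstable <- function(x) {
    J <- numeric_jacobian(fn, x, fn(x))
    max(Re(eigen(J, only.values = TRUE)$values)) > 1e-8
  }

  # Newton with a pseudo-transient rescue if it stalls; the iteration cap
  # applies to Newton steps (continuation phases are bounded by their fixed
  # step counts)
  solve_from <- function(x) {
    res <- newton(x, max_iter - newton_iters)
    if (!res$ok && newton_iters < max_iter) {
      x <- ptc(res$x, 80)
      res <- newton(x, max_iter - newton_iters)
    }
    if (!res$ok && newton_iters < max_iter) {
      # a slow marginal mode (e.g. near a washout fold) stalls both Newton
      # and modest-dt continuation; guarded long steps converge it — the
      # residual guard rejects any step whose dt outruns an unstable mode
      x <- ptc(res$x, 150, dt_max = 1e5)
      res <- newton(x, max_iter - newton_iters)
    }
    res
  }

  warm <- !is.null(control$x0)
  x <- if (warm) pmax(as.numeric(control$x0), 0)
       else default_initial_state(influent, config, params, registry)
  if (!warm) x <- ptc(x, 60)
  res <- solve_from(x)
  tries <- 0
  while (res$ok && tries < 3 && newton_iters < max_iter && unstable(res$x)) {
    # converged onto an unstable root: reseed the washed-out pools and
    # follow the transient with small steps until a stable basin is reached
    tries <- tries + 1
    x <- res$x
    zero_bio <- intersect(which(x < 1e-3),
                          which(ifas_state_names() %in%
                                c("X_BH", "X_BA1", "X_BA2",
                                  "XF_BH", "XF_BA1", "XF_BA2")))
    x[zero_bio] <- 10
    x <- ptc(x, 200, dt_max = 0.1)
    x <- ptc(x, 60)
    res <- solve_from(x)
  }
  converged <- res$ok && !(tries == 3 && unstable(res$x))
  state <- stats::setNames(res$x, ifas_state_names())
  f <- res$f
  it <- iters
  structure(list(state = state,
                 effluent = clarified_effluent(state, config),
                 residual_norm = max(abs(f)),
                 residual_trace = trace,
                 converged = converged,
                 iterations = it,
                 influent = influent, config = config,
                 params = params, registry = registry),
            class = "steady_state")
}

#' Ideal point-settler split of mixed-liquor solids
#'
#' A non-settleable fraction `f_ns` of the mixed-liquor solids escapes with
#' the clarifier effluent; the remainder is routed to the underflow
#' (RAS/WAS). Solids are conserved exactly.
#'
#' @param mlss mixed-liquor solids concentration(s), mg/L.
#' @param config [plant_config()] supplying `f_ns`.
#' @return list with `effluent` and `underflow` concentrations.
#' @export
#' @examples
#' clarifier_split(2000, plant_config(f_ns = 0.01))$effluent  # 20
clarifier_split <- function(mlss, config = plant_config()) {
  if (any(mlss < 0)) stop_ifas("MLSS must be non-negative")
  eff <- config$f_ns * mlss
  list(effluent = eff, underflow = mlss - eff)
}

# Effluent-side concentrations: solubles pass, particulates attenuated by
# the clarifier, attached pools never leave.
clarified_effluent <- function(state, config) {
  idx <- transport_indices()
  eff <- state
  eff[idx$particulate] <- clarifier_split(state[idx$particulate], config)$effluent
  eff[idx$attached] <- 0
  eff
}

#' Composite effluent summary (BOD, TN, TSS)
#'
#' Maps the clarified effluent state onto the three composite determinands
#' assessed during calibration: BOD as `f_bod` times the biodegradable COD
#' escaping (readily biodegradable substrate plus non-settled slowly
#' biodegradable substrate and active biomass), TN as the sum of all
#' dissolved nitrogen species (dinitrogen excluded) plus the nitrogen bound
#' in escaping particulates, and TSS from escaping particulate COD via the
#' COD:VSS and VSS/TSS factors.
#'
#' @param steady a converged [solve_steady_state()] result.
#' @param config [plant_config()]; defaults to the configuration stored in
#'   `steady`.
#' @return Named numeric `c(BOD, TN, TSS)` (mg/L), class `effluent_summary`,
#'   with a `components` attribute itemizing the TN constituents.
#' @export
effluent_summary <- function(steady, config = steady$config) {
  eff <- steady$effluent
  p <- model_constants(steady$params, steady$registry)
  biomass <- eff[["X_BH"]] + eff[["X_BA1"]] + eff[["X_BA2"]]
  bod <- config$f_bod * (eff[["S_S"]] + eff[["X_S"]] + biomass)
  tn_parts <- c(S_NH = eff[["S_NH"]], S_ND = eff[["S_ND"]],
                S_NO2 = eff[["S_NO2"]], S_NO3 = eff[["S_NO3"]],
                X_ND = eff[["X_ND"]], biomass_N = p$i_XB * biomass)
  part_cod <- eff[["X_S"]] + eff[["X_I"]] + biomass
  tss <- part_cod / config$cod_vss / config$vss_tss
  structure(c(BOD = bod, TN = sum(tn_parts), TSS = tss),
            components = tn_parts, class = c("effluent_summary", "numeric"))
}

#' Model evaluator: parameter vector in, effluent composites out
#'
#' Builds the evaluator contract consumed by every pipeline stage: a function
#' taking a full or partial named parameter vector (unspecified codes stay at
#' the base values) and returning `c(BOD, TN, TSS)`. The closure keeps the
#' last converged state as a warm start, which speeds up design evaluation by
#' an order of magnitude; pass `warm = FALSE` for a cold solve.
#'
#' @inheritParams ifas_rhs
#' @param base full parameter vector providing values for codes a call does
#'   not override (default: registry defaults).
#' @param control solver control list (see [solve_steady_state()]).
#' @return function `(params, warm = TRUE, detail = FALSE)`; with
#'   `detail = TRUE` the full `steady_state` object is returned. Evaluations
#'   that do not converge return `NA` composites and increment the counter
#'   reported by `attr(evaluator, "failures")()`.
#' @export
ifas_evaluator <- function(influent, config, registry = ifas_registry(),
                           base = default_params(registry), control = list()) {
  force(influent); force(config); force(registry); force(base); force(control)
  last <- NULL
  failures <- 0L
  ev <- function(params = NULL, warm = TRUE, detail = FALSE, x0 = NULL) {
    p <- base
    if (!is.null(params)) {
      unknown <- setdiff(names(params), registry$code)
      if (length(unknown))
        stop_ifas("unknown parameter code(s): ", paste(unknown, collapse = ", "))
      p[names(params)] <- params
    }
    ctl <- control
    if (!is.null(x0)) ctl$x0 <- x0
    else if (warm && !is.null(last)) ctl$x0 <- last
    ss <- solve_steady_state(influent, config, p, registry, ctl)
    if (!ss$converged && !is.null(ctl$x0)) {
      # cold retry with a larger Newton budget
      ctl$x0 <- NULL
      ctl$max_iter <- max(control$max_iter %||% 500, 2000)
      ss <- solve_steady_state(influent, config, p, registry, ctl)
    }
    if (ss$converged) last <<- ss$state else failures <<- failures + 1L
    if (detail) return(ss)
    if (!ss$converged) return(c(BOD = NA_real_, TN = NA_real_, TSS = NA_real_))
    out <- effluent_summary(ss, config)
    attributes(out) <- list(names = names(out))
    out
  }
  attr(ev, "failures") <- function() failures
  attr(ev, "reset") <- function() { last <<- NULL; failures <<- 0L; invisible(NULL) }
  ev
}

#' Evaluate a design matrix of parameter points
#'
#' Runs the evaluator over the rows of a design matrix (columns named by
#' parameter code), warm-starting consecutive solves. When the design carries
#' structure (e.g. the cross-matrix rows of a Saltelli scheme differ from a
#' base row in a single coordinate), `warm_from` names, per row, an earlier
#' row whose converged state seeds the solve — this keeps the solver on the
#' same stable branch and is considerably faster than chaining scattered
#' rows. Non-converged rows are returned as `NA` and counted.
#'
#' @param evaluator an [ifas_evaluator()] (or any function with its contract;
#'   `warm_from` requires the full [ifas_evaluator()] interface).
#' @param X numeric matrix, one row per parameter point.
#' @param warm_from optional integer vector: `warm_from[i] < i` is the row
#'   whose solution warm-starts row `i` (`NA` = chain from the previous row).
#' @return matrix of outputs (one row per design row) with attribute
#'   `n_failed`.
#' @export
evaluate_design <- function(evaluator, X, warm_from = NULL) {
  codes <- colnames(X)
  if (is.null(warm_from)) {
    y1 <- evaluator(stats::setNames(X[1, ], codes))
    out <- matrix(NA_real_, nrow(X), length(y1),
                  dimnames = list(NULL, names(y1) %||% paste0("y", seq_along(y1))))
    out[1, ] <- y1
    for (i in seq_len(nrow(X))[-1]) {
      out[i, ] <- evaluator(stats::setNames(X[i, ], codes))
    }
  } else {
    stopifnot(length(warm_from) == nrow(X))
    states <- vector("list", nrow(X))
    out <- matrix(NA_real_, nrow(X), 3, dimnames = list(NULL, c("BOD", "TN", "TSS")))
    for (i in seq_len(nrow(X))) {
      x0 <- if (!is.na(warm_from[i])) states[[warm_from[i]]]
      ss <- evaluator(stats::setNames(X[i, ], codes), detail = TRUE, x0 = x0)
      if (ss$converged) {
        states[[i]] <- ss$state
        out[i, ] <- as.numeric(effluent_summary(ss))
      }
    }
  }
  failed <- sum(!stats::complete.cases(out))
  attr(out, "n_failed") <- failed
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> converged: %s in %d iterations (max residual %.2e)\n",
              x$converged, x$iterations, x$residual_norm))
  print(round(x$state, 3))
  invisible(x)
}

#' @export
print.effluent_summary <- function(x, ...) {
  cat(sprintf("<effluent_summary> BOD %.2f, TN %.2f, TSS %.2f mg/L\n",
              x[["BOD"]], x[["TN"]], x[["TSS"]]))
  invisible(x)
}
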