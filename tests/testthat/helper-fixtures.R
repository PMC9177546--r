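# Shared builders for the test suite. Everything is generated in code; the
# only files read are the package's own bundled fixtures.

pilot_influent_composites <- function() {
  composite_measurements(cod = 627, bod = 306, tss = 384,
                         nh3 = 33.7, tkn = 44.2, tn = 46.7)
}

pilot_influent <- function(config = plant_config()) {
  fractionate_influent(pilot_influent_composites(), config = config)
}

pilot_evaluator <- function(config = plant_config(), registry = ifas_registry(),
                            base = default_params(registry)) {
  ifas_evaluator(pilot_influent(config), config, registry, base = base)
}

# Ishigami benchmark (a = 7, b = 0.1) and its closed-form Sobol indices
ishigami <- function(X, a = 7, b = 0.1)
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])

ishigami_truth <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * pi^8 * b^2 / 225
  V <- V1 + V2 + V13
  list(S1 = c(V1 / V, V2 / V, 0),
       ST = c((V1 + V13) / V, V2 / V, V13 / V), V = V)
}

unit_ranges <- function(k) cbind(low = rep(0, k), high = rep(1, k))

# constant-output stub honouring the evaluator contract
stub_evaluator <- function(out = c(BOD = 24.8, TN = 12.9, TSS = 29.5))
  function(params = NULL, ...) out

# Independent steady-state oracle: brute-force time integration of the same
# mass balances until the scaled derivative vanishes. Slow pools (marginal
# nitrifier or biofilm inventories) can need several thousand days.
ode_steady_oracle <- function(influent, config, params,
                              registry = ifas_registry(),
                              chunk_d = 5000, max_d = 1e5) {
  rhs <- ifas_rhs(influent, config, params, registry)
  y <- ifascal:::default_initial_state(influent, config, params, registry)
  t <- 0
  repeat {
    out <- deSolve::ode(y, c(0, chunk_d),
                        func = function(t, y, pr) list(rhs(y)), parms = NULL,
                        rtol = 1e-12, atol = 1e-10, maxsteps = 1e7)
    y <- pmax(as.numeric(out[2, -1]), 0)
    t <- t + chunk_d
    if (max(abs(rhs(y)) / pmax(1, y)) < 1e-9 || t >= max_d) break
  }
  y
}

# relative deviation with a 1e-3 mg/L (1 ug/L) floor: concentrations below
# the floor are numerically washed out on both sides
max_rel_dev <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-3))
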