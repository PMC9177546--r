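# Synthetic-observation generator: "observed" effluent targets produced from
# known true parameter values, so calibration recovery is testable without
# plant data.

#' Generate a synthetic effluent observation
#'
#' Evaluates the model at a known true parameter point `theta_star` and adds
#' independent normal noise per output (truncated at zero), emulating the
#' structure of a pilot-plant effluent characterization (three composite
#' outputs with reported spreads). With `sigma = 0` the observation equals
#' the model output exactly, which makes full-pipeline parameter recovery an
#' exact self-consistency check.
#'
#' @param evaluator model evaluator ([ifas_evaluator()]).
#' @param theta_star named parameter (sub)vector of true values.
#' @param sigma noise standard deviation per output: scalar (interpreted as a
#'   fraction of each output when `relative = TRUE`, mg/L otherwise) or named
#'   vector over outputs.
#' @param seed RNG seed; regeneration with the same seed reproduces the
#'   observation exactly.
#' @param relative interpret a scalar `sigma` as a fraction of each output.
#' @return A `synthetic_observation`: `observed` (named numeric), `truth`
#'   (model output without noise), `theta_star`, `sigma`, `seed`.
#' @export
generate_synthetic_observation <- function(evaluator, theta_star, sigma = 0,
                                           seed = NULL, relative = TRUE) {
  truth <- evaluator(theta_star)
  if (any(!is.finite(truth)))
    stop_ifas("model does not converge at theta_star")
  sd_abs <- if (length(sigma) == 1 && relative) sigma * truth
            else rep_len(sigma, length(truth))
  observed <- with_seed(seed, pmax(truth + stats::rnorm(length(truth), 0, ifelse(sd_abs > 0, sd_abs, 0)), 0))
  names(observed) <- names(truth)
  structure(list(observed = observed, truth = truth, theta_star = theta_star,
                 sigma = sd_abs, seed = seed),
            class = "synthetic_observation")
}

#' @export
print.synthetic_observation <- function(x, ...) {
  cat("<synthetic_observation>\n")
  print.data.frame(data.frame(output = names(x$observed), truth = x$truth,
                              observed = x$observed, sigma = x$sigma),
                   digits = 4, row.names = FALSE)
  invisible(x)
}
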