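# Monte-Carlo uncertainty propagation with GUM-style coverage factors.

#' Probability-density specification for an uncertain parameter
#'
#' Uniform and triangular shapes are parameterized by a center and half-width
#' `a` (typically from literature ranges); the normal shape by center and
#' standard deviation `sd`.
#'
#' @param code parameter code.
#' @param shape one of `"uniform"`, `"normal"`, `"triangular"`.
#' @param low,high distribution limits (uniform/triangular), or omit and give
#'   `center` + `a`.
#' @param center distribution center (defaults to midpoint of `low`/`high`).
#' @param a half-width (defaults to `(high - low) / 2`).
#' @param sd standard deviation (normal only).
#' @param source free-text provenance note (e.g. a literature citation key).
#' @export
#' @examples
#' pdf_spec("X52", "uniform", low = 0.63, high = 0.69)  # a = 0.03
pdf_spec <- function(code, shape = c("uniform", "normal", "triangular"),
                     low = NULL, high = NULL, center = NULL, a = NULL,
                     sd = NULL, source = NA_character_) {
  shape <- match.arg(shape)
  if (is.null(a) && !is.null(low) && !is.null(high)) a <- (high - low) / 2
  if (is.null(center) && !is.null(low) && !is.null(high)) center <- (low + high) / 2
  if (shape %in% c("uniform", "triangular")) {
    if (is.null(a) || a <= 0) stop_ifas("half-width a must be positive")
  } else {
    if (is.null(sd) || sd <= 0) stop_ifas("normal pdf needs sd > 0")
  }
  if (is.null(center)) stop_ifas("center is required")
  structure(list(code = code, shape = shape, center = center, a = a,
                 low = low %||% (center - a), high = high %||% (center + a),
                 sd = sd, source = source), class = "pdf_spec")
}

#' Standard uncertainty implied by a PDF shape
#'
#' Uniform: `a / sqrt(3)`; triangular: `a / sqrt(6)`; normal: the sample
#' standard deviation (divisor n-1) of the supplied observations.
#'
#' @param spec a [pdf_spec()].
#' @param samples observations (required for the normal shape when the spec
#'   carries no `sd`).
#' @export
#' @examples
#' std_from_pdf(pdf_spec("X52", "uniform", low = 0.63, high = 0.69))  # 0.0173205
std_from_pdf <- function(spec, samples = NULL) {
  stopifnot(inherits(spec, "pdf_spec"))
  switch(spec$shape,
    uniform = spec$a / sqrt(3),
    triangular = spec$a / sqrt(6),
    normal = {
      if (!is.null(spec$sd)) spec$sd
      else {
        if (is.null(samples) || length(samples) < 2)
          stop_ifas("normal pdf needs sd or >= 2 samples")
        stats::sd(samples)
      }
    })
}

sample_pdf <- function(spec, n) {
  switch(spec$shape,
    uniform = stats::runif(n, spec$center - spec$a, spec$center + spec$a),
    normal = stats::rnorm(n, spec$center, spec$sd),
    triangular = {
      # inverse-CDF of the symmetric triangular distribution on center +/- a
      u <- stats::runif(n)
      lo <- spec$center - spec$a; hi <- spec$center + spec$a
      ifelse(u < 0.5, lo + spec$a * sqrt(2 * u), hi - spec$a * sqrt(2 * (1 - u)))
    })
}

#' Read PDF specifications from CSV
#'
#' Columns: `code`, `shape`, `low`, `high`, optional `center`, `sd`,
#' `source`. The bundled fixture carries the literature uncertainty ranges of
#' the four headline parameters.
#'
#' @param path CSV file; default the bundled literature fixture.
#' @return list of [pdf_spec()].
#' @export
read_pdf_specs <- function(path = system.file("extdata", "literature_pdfs.csv",
                                              package = "ifascal")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    pdf_spec(tab$code[i], tab$shape[i], low = tab$low[i], high = tab$high[i],
             sd = if ("sd" %in% names(tab) && is.finite(tab$sd[i])) tab$sd[i],
             source = if ("source" %in% names(tab)) tab$source[i] else NA))
}

#' Monte-Carlo propagation of parameter uncertainty
#'
#' Draws `n` pseudo-random parameter sets from the assigned PDFs (inputs
#' independent), evaluates the model for each, and summarizes every output by
#' its mean, combined standard uncertainty `U_c` (sample standard deviation)
#' and expanded uncertainty `U_e = k * U_c`.
#'
#' @param evaluator model evaluator; parameters not covered by `specs` stay
#'   at the evaluator's base (calibrated) values.
#' @param specs list of [pdf_spec()] covering the influential parameters.
#' @param n Monte-Carlo sample size (default 1e5).
#' @param seed RNG seed.
#' @param coverage coverage factor k for the expanded uncertainty (1.96 for a
#'   95% coverage interval).
#' @param bins histogram bin count for the exported output PDFs.
#' @param max_fail_rate abort when the share of non-converged evaluations
#'   exceeds this (default 1%).
#' @return An `uncertainty_result`: per-output table (`mean`, `U_c`, `U_e`,
#'   `k`), raw `samples` (inputs and outputs), histograms, `n`, `seed`.
#' @export
mc_propagate <- function(evaluator, specs, n = 1e5, seed = NULL,
                         coverage = 1.96, bins = 50, max_fail_rate = 0.01) {
  if (length(specs) == 0) stop_ifas("no PDF specifications supplied")
  if (inherits(specs, "pdf_spec")) specs <- list(specs)
  codes <- vapply(specs, `[[`, character(1), "code")
  X <- with_seed(seed, {
    m <- vapply(specs, sample_pdf, numeric(n), n = n)
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    m
  })
  colnames(X) <- codes
  Y <- evaluate_design(evaluator, X)
  fail <- attr(Y, "n_failed")
  if (fail / n > max_fail_rate)
    stop_ifas(sprintf("model failed to converge for %.1f%% of samples", 100 * fail / n))
  ok <- stats::complete.cases(Y)
  outs <- colnames(Y)
  tab <- data.frame(output = outs,
                    mean = colMeans(Y[ok, , drop = FALSE]),
                    U_c = apply(Y[ok, , drop = FALSE], 2, stats::sd),
                    row.names = NULL)
  tab$U_e <- expanded_uncertainty(tab$U_c, coverage)
  tab$k <- coverage
  hist_list <- lapply(outs, function(o) {
    h <- graphics::hist(Y[ok, o], breaks = bins, plot = FALSE)
    data.frame(mid = h$mids, density = h$density, count = h$counts)
  })
  names(hist_list) <- outs
  structure(list(table = tab, samples = list(inputs = X, outputs = Y),
                 histograms = hist_list, n = n, n_failed = fail,
                 coverage = coverage, seed = seed, codes = codes),
            class = "uncertainty_result")
}

#' Expanded uncertainty from a combined standard uncertainty
#'
#' `U_e = k * U_c` with coverage factor `k = 1.96` for a 95% coverage
#' interval.
#'
#' @param u_c combined standard uncertainty (>= 0).
#' @param k coverage factor.
#' @export
#' @examples
#' expanded_uncertainty(0.67)  # 1.3132 (~1.31)
#' expanded_uncertainty(2.16)  # 4.2336 (~4.23)
expanded_uncertainty <- function(u_c, k = 1.96) {
  if (any(u_c < 0)) stop_ifas("combined standard uncertainty must be >= 0")
  k * u_c
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> n = %d Monte-Carlo samples over {%s} (%d failed)\n",
              x$n, paste(x$codes, collapse = ", "), x$n_failed))
  tab <- x$table
  tab$interval <- sprintf("%.3g +/- %.3g", tab$mean, tab$U_e)
  print.data.frame(tab, digits = 4, row.names = FALSE)
  invisible(x)
}
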