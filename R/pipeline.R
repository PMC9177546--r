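# Orchestration of the full calibration workflow:
# screen (Morris) -> decompose (Sobol) -> estimate (Nelder-Mead) ->
# quantify uncertainty (Monte-Carlo) -> validate across DO regimes.

#' Paths to the bundled pilot-plant fixtures
#'
#' @return list of file paths: characterization tables and plant configs per
#'   DO regime (calibration 2.5 mg/L; validation 0.5 and 4.5 mg/L), parameter
#'   registry, literature PDF ranges.
#' @export
ifas_fixture_paths <- function() {
  ext <- function(f) system.file("extdata", f, package = "ifascal", mustWork = TRUE)
  list(characterization = c(do25 = ext("characterization_do25.csv"),
                            do05 = ext("characterization_do05.csv"),
                            do45 = ext("characterization_do45.csv")),
       plant = c(do25 = ext("plant_do25.yaml"),
                 do05 = ext("plant_do05.yaml"),
                 do45 = ext("plant_do45.yaml")),
       registry = ext("parameter_registry.csv"),
       pdfs = ext("literature_pdfs.csv"))
}

#' Load the bundled (or user-supplied) fixtures
#'
#' @param paths a list shaped like [ifas_fixture_paths()].
#' @return list: `regimes` (named list with `composites`, `config` per DO
#'   regime; `do25` is the calibration regime), `registry`, `pdf_specs`.
#' @export
load_fixtures <- function(paths = ifas_fixture_paths()) {
  regs <- names(paths$characterization)
  regimes <- lapply(regs, function(r) {
    ch <- read_characterization(paths$characterization[[r]])
    cfg <- read_plant_config(paths$plant[[r]])
    list(name = r, composites = ch, config = cfg)
  })
  names(regimes) <- regs
  list(regimes = regimes,
       registry = read_registry(paths$registry),
       pdf_specs = read_pdf_specs(paths$pdfs))
}

#' Pipeline settings
#'
#' Stage settings with desk-scale defaults; `r = 100` trajectories and
#' `mc_n = 1e5` reproduce the full field-study scale, smaller values keep test
#' runs fast.
#'
#' @param r Morris trajectories. @param p Morris grid levels.
#' @param morris_threshold normalized mu* influence threshold.
#' @param top_k factors forwarded per output to the Sobol stage.
#' @param sobol_n Saltelli base sample size. @param second_order include
#'   second-order blocks. @param sobol_threshold total-order influence
#'   threshold. @param boot bootstrap replicates.
#' @param mc_n Monte-Carlo sample size for uncertainty propagation.
#' @param nm_control [nelder_mead()] control list.
#' @param seed master seed; every stage derives its own stream from it.
#' @param observed optional named effluent targets overriding the fixture
#'   effluent (e.g. a [generate_synthetic_observation()]'s `observed`).
#' @param subset optional parameter codes overriding the Sobol-influential
#'   calibration subset.
#' @export
pipeline_settings <- function(r = 100, p = 4, morris_threshold = 0.1,
                              top_k = 10, sobol_n = 512, second_order = TRUE,
                              sobol_threshold = 0.05, boot = 200,
                              mc_n = 1e4, nm_control = list(), seed = 1,
                              observed = NULL, subset = NULL) {
  stopifnot(morris_threshold > 0, morris_threshold < 1,
            sobol_threshold > 0, sobol_threshold < 1)
  list(r = r, p = p, morris_threshold = morris_threshold, top_k = top_k,
       sobol_n = sobol_n, second_order = second_order,
       sobol_threshold = sobol_threshold, boot = boot, mc_n = mc_n,
       nm_control = nm_control, seed = seed, observed = observed,
       subset = subset)
}

#' Run the full automated-calibration pipeline
#'
#' Screens all registry parameters with the Method of Morris per output
#' (BOD/TN/TSS), forwards each output's top factors to a variance-based Sobol
#' decomposition, takes the union of Sobol-influential parameters (total
#' order >= threshold) as the calibration subset, estimates it jointly by
#' Nelder-Mead against the observed effluent, propagates the literature
#' uncertainty of the calibrated parameters by Monte Carlo, and validates the
#' calibrated model under all bundled DO regimes.
#'
#' @param fixtures [load_fixtures()] output.
#' @param settings [pipeline_settings()].
#' @return An `ifas_pipeline` result with one element per stage plus
#'   evaluation counts and the seeds used.
#' @export
run_pipeline <- function(fixtures = load_fixtures(),
                         settings = pipeline_settings()) {
  reg <- fixtures$registry
  cal <- fixtures$regimes$do25 %||% fixtures$regimes[[1]]
  influent <- fractionate_influent(cal$composites$influent, config = cal$config)
  evaluator <- ifas_evaluator(influent, cal$config, reg)
  seeds <- list(morris = derive_seed(settings$seed, 101),
                sobol = stats::setNames(lapply(1:3, function(i)
                  derive_seed(settings$seed, 200 + i)), c("BOD", "TN", "TSS")),
                boot = derive_seed(settings$seed, 301),
                mc = derive_seed(settings$seed, 401))
  counts <- list()

  # --- Morris screening over the full registry, one evaluation set shared
  #     by all three outputs
  design <- sample_morris_design(reg, r = settings$r, p = settings$p,
                                 seed = seeds$morris)
  Y <- evaluate_design(evaluator, design$X)
  counts$morris <- nrow(design$X)
  outputs <- colnames(Y)
  morris <- lapply(outputs, function(o) {
    ee <- elementary_effects(design, Y[, o])
    morris_summary(ee, threshold = settings$morris_threshold)
  })
  names(morris) <- outputs
  screening <- lapply(morris, screen_influential,
                      threshold = settings$morris_threshold,
                      top_k = settings$top_k)

  # --- Sobol decomposition per output on that output's forwarded factors
  sobol <- list(); flags <- list()
  counts$sobol <- stats::setNames(numeric(length(outputs)), outputs)
  for (o in outputs) {
    codes <- screening[[o]]$top
    sub <- reg[match(codes, reg$code), ]
    sd_ <- saltelli_sample(sub, n = settings$sobol_n,
                           second_order = settings$second_order,
                           seed = seeds$sobol[[o]])
    Yo <- evaluate_design(evaluator, sd_$X, warm_from = sd_$warm_from)[, o]
    counts$sobol[o] <- nrow(sd_$X)
    pruned <- prune_failed_rows(Yo, sd_)
    res <- sobol_indices(pruned$y, pruned$design, boot = settings$boot,
                         seed = seeds$boot)
    res$n_dropped <- pruned$n_dropped
    sobol[[o]] <- res
    flags[[o]] <- flag_influential_sobol(res, settings$sobol_threshold)
  }

  influential <- unique(unlist(lapply(flags, `[[`, "influential")))
  # deterministic registry order
  influential <- reg$code[reg$code %in% influential]

  # --- joint Nelder-Mead calibration of the influential set
  observed <- settings$observed %||% {
    eff <- cal$composites$effluent$value
    c(BOD = eff[["bod"]], TN = eff[["tn"]], TSS = eff[["tss"]])
  }
  sigma <- {
    sp <- cal$composites$effluent$spread
    s <- c(BOD = sp[["bod"]], TN = sp[["tn"]], TSS = sp[["tss"]])
    if (!is.null(settings$observed)) s[] <- NA
    s
  }
  subset <- settings$subset %||% influential
  if (length(subset) == 0)
    stop_ifas("no influential parameters found to calibrate")
  calibration <- calibrate(evaluator, observed, subset, reg, sigma = sigma,
                           control = settings$nm_control)

  # --- Monte-Carlo uncertainty of the calibrated parameters
  calibrated <- default_params(reg)
  calibrated[calibration$parameters$code] <- calibration$parameters$estimated
  cal_eval <- ifas_evaluator(influent, cal$config, reg, base = calibrated)
  lit <- fixtures$pdf_specs
  lit_codes <- vapply(lit, `[[`, character(1), "code")
  specs <- lapply(subset, function(code) {
    i <- match(code, lit_codes)
    if (!is.na(i)) lit[[i]]
    else {
      # no literature range: fall back to the registry screening range
      j <- match(code, reg$code)
      pdf_spec(code, "uniform", low = reg$low[j], high = reg$high[j],
               source = "registry screening range (no literature values)")
    }
  })
  uncertainty <- mc_propagate(cal_eval, specs, n = settings$mc_n,
                              seed = seeds$mc)
  counts$mc <- settings$mc_n

  validation <- validate_regimes(calibrated, fixtures)

  structure(list(morris = morris, screening = screening, sobol = sobol,
                 sobol_flags = flags, influential = influential,
                 subset = subset, observed = observed,
                 calibration = calibration, calibrated_params = calibrated,
                 uncertainty = uncertainty, validation = validation,
                 counts = counts, seeds = seeds, settings = settings,
                 design = design),
            class = "ifas_pipeline")
}

#' Validate calibrated parameters across DO regimes
#'
#' Re-runs the model with the calibrated parameter vector under each regime's
#' influent and operating configuration and tabulates predicted vs reported
#' effluent composites with absolute deviations.
#'
#' @param params full (calibrated) parameter vector.
#' @param fixtures [load_fixtures()] output.
#' @param registry parameter registry (default: the fixtures' registry).
#' @return data frame: one row per regime x output with `predicted`,
#'   `reported`, `deviation`.
#' @export
validate_regimes <- function(params, fixtures, registry = fixtures$registry) {
  rows <- lapply(fixtures$regimes, function(rg) {
    influent <- fractionate_influent(rg$composites$influent, config = rg$config)
    ev <- ifas_evaluator(influent, rg$config, registry, base = params)
    pred <- ev()
    eff <- rg$composites$effluent$value
    rep_ <- c(BOD = eff[["bod"]], TN = eff[["tn"]], TSS = eff[["tss"]])
    cbind(data.frame(regime = rg$name, do_mgl = rg$config$do_mgl),
          deviation_table(pred, rep_))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Export pipeline reports to disk
#'
#' Writes deterministic plain-text artifacts: per-output Morris tables and
#' Morris-plot coordinates, Sobol index tables and pairwise interaction
#' matrices, the default-vs-estimated calibration table, per-output
#' uncertainty summaries and histogram data, the validation table, and a JSON
#' run manifest (versions, seeds, thresholds, evaluation counts).
#'
#' @param result an [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
export_reports <- function(result, outdir) {
  stopifnot(inherits(result, "ifas_pipeline"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  for (o in names(result$morris)) {
    tab <- result$screening[[o]]$table
    wcsv(tab, sprintf("morris_%s.csv", o))
    wcsv(tab[, c("factor", "mu_star", "sigma")], sprintf("morris_plot_%s.csv", o))
    s <- result$sobol[[o]]
    wcsv(result$sobol_flags[[o]]$table, sprintf("sobol_%s.csv", o))
    if (!is.null(s$S2)) {
      m <- s$S2; dimnames(m) <- list(s$table$factor, s$table$factor)
      utils::write.csv(m, file.path(outdir, sprintf("sobol_s2_%s.csv", o)))
    }
    h <- result$uncertainty$histograms[[o]]
    if (!is.null(h)) wcsv(h, sprintf("uncertainty_hist_%s.csv", o))
  }
  wcsv(result$calibration$parameters, "calibration.csv")
  wcsv(deviation_table(result$calibration$achieved, result$observed),
       "deviation.csv")
  wcsv(result$uncertainty$table, "uncertainty.csv")
  wcsv(result$validation, "validation.csv")
  manifest <- list(
    package = "ifascal",
    version = as.character(utils::packageVersion("ifascal")),
    r_version = as.character(getRversion()),
    seed = result$settings$seed,
    stage_seeds = result$seeds,
    thresholds = list(morris = result$settings$morris_threshold,
                      sobol = result$settings$sobol_threshold),
    settings = result$settings[c("r", "p", "top_k", "sobol_n",
                                 "second_order", "boot", "mc_n")],
    evaluation_counts = result$counts,
    influential = result$influential,
    calibrated_subset = result$subset)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' @export
print.ifas_pipeline <- function(x, ...) {
  cat("<ifas_pipeline>\n")
  cat(sprintf("  Morris: %d evaluations (r = %d, k = %d)\n",
              x$counts$morris, x$settings$r, x$design$k))
  cat(sprintf("  Sobol: %s evaluations/output; influential: %s\n",
              paste(x$counts$sobol, collapse = "/"),
              paste(x$influential, collapse = ", ")))
  cat(sprintf("  Calibrated subset: %s\n", paste(x$subset, collapse = ", ")))
  print(x$calibration)
  cat("  Uncertainty:\n")
  print(x$uncertainty$table, digits = 4)
  cat("  Validation:\n")
  print(x$validation, digits = 4)
  invisible(x)
}
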