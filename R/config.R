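#' Plant operating configuration
#'
#' Bundles the reactor geometry, hydraulics and the conversion factors that
#' map model state variables onto composite effluent determinands. Defaults
#' describe the pilot-scale hybrid (suspended + attached growth) reactor used
#' throughout: 20 m3 aerated tank fed at 1.8 m3/h (HRT 11.1 h).
#'
#' @param volume_m3 reactor volume (m3).
#' @param flow_m3h influent flow Q (m3/h).
#' @param srt_d solids retention time (d); governs wastage of all suspended
#'   particulates.
#' @param ras_ratio return activated sludge ratio (multiples of Q).
#' @param ras_m3h absolute RAS flow (m3/h). The source tables report both an
#'   absolute flow and a ratio that disagree slightly; both are stored and the
#'   absolute flow is authoritative where one is needed.
#' @param was_m3d waste activated sludge flow (m3/d), informational (wastage
#'   is SRT-controlled).
#' @param do_mgl bulk dissolved-oxygen setpoint (mgO2/L), held fixed.
#' @param temp_c bulk liquid temperature (deg C), informational (kinetics are
#'   not temperature-corrected).
#' @param mlss_mgl target mixed-liquor suspended solids (mg/L), informational.
#' @param media_fill volume fraction occupied by biofilm carrier media.
#' @param attached_capacity_gm3 maximum attached-biomass inventory expressed
#'   per unit reactor volume (gCOD/m3); attachment and attached growth vanish
#'   as the inventory approaches this cap.
#' @param biofilm_do_factor fraction of the bulk DO seen by the attached
#'   biomass (crude stand-in for oxygen penetration limits of a biofilm).
#' @param f_ns non-settleable fraction of mixed-liquor solids escaping with
#'   the clarifier effluent (ideal point-settler).
#' @param f_bod BOD5 per unit biodegradable COD (gBOD/gCOD).
#' @param cod_vss COD content of volatile suspended solids (gCOD/gVSS).
#' @param vss_tss VSS/TSS ratio of the sludge (-).
#' @return A validated `plant_config` list.
#' @export
#' @examples
#' cfg <- plant_config()
#' hrt_hours(cfg)  # 11.1
plant_config <- function(volume_m3 = 20, flow_m3h = 1.8, srt_d = 11,
                         ras_ratio = 2.5, ras_m3h = 3.7, was_m3d = 2.2,
                         do_mgl = 2.5, temp_c = 26, mlss_mgl = 2000,
                         media_fill = 0.005, attached_capacity_gm3 = 2000,
                         biofilm_do_factor = 0.2, f_ns = 0.005,
                         f_bod = 0.66, cod_vss = 1.48, vss_tss = 0.63) {
  cfg <- list(volume_m3 = volume_m3, flow_m3h = flow_m3h, srt_d = srt_d,
              ras_ratio = ras_ratio, ras_m3h = ras_m3h, was_m3d = was_m3d,
              do_mgl = do_mgl, temp_c = temp_c, mlss_mgl = mlss_mgl,
              media_fill = media_fill,
              attached_capacity_gm3 = attached_capacity_gm3,
              biofilm_do_factor = biofilm_do_factor, f_ns = f_ns,
              f_bod = f_bod, cod_vss = cod_vss, vss_tss = vss_tss)
  validate_plant_config(cfg)
  class(cfg) <- "plant_config"
  cfg
}

validate_plant_config <- function(cfg) {
  pos <- c("volume_m3", "flow_m3h", "srt_d", "ras_ratio", "ras_m3h",
           "attached_capacity_gm3", "cod_vss")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_ifas("plant_config field '", f, "' must be strictly positive")
  for (f in c("f_ns", "f_bod", "vss_tss", "biofilm_do_factor", "media_fill"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop_ifas("plant_config field '", f, "' must lie in (0, 1]")
  if (cfg$do_mgl < 0) stop_ifas("DO setpoint must be non-negative")
  invisible(cfg)
}

#' Hydraulic retention time
#'
#' @param cfg a [plant_config()].
#' @return HRT in hours (volume / flow).
#' @export
hrt_hours <- function(cfg) cfg$volume_m3 / cfg$flow_m3h

#' Read a plant configuration from YAML
#'
#' One file per DO regime; keys mirror the arguments of [plant_config()].
#'
#' @param path YAML file.
#' @export
read_plant_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(plant_config))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop_ifas("unknown plant config keys in ", path, ": ",
              paste(extra, collapse = ", "))
  do.call(plant_config, y)
}

#' @export
print.plant_config <- function(x, ...) {
  cat(sprintf(paste0("<plant_config> V = %g m3, Q = %g m3/h (HRT %.1f h), ",
                     "SRT = %g d, DO = %g mg/L, T = %g C\n"),
              x$volume_m3, x$flow_m3h, hrt_hours(x), x$srt_d, x$do_mgl, x$temp_c))
  invisible(x)
}
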