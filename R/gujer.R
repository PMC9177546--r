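# Reduced IFAS biokinetics: every stand-in equation (process stoichiometry
# and rate laws) lives in this file so the whole kinetic core can be audited
# in one place.
#
# Components (columns). Concentrations in mgCOD/L or mgN/L of reactor volume:
#   S_S   readily biodegradable substrate        S_I  soluble inerts
#   X_S   slowly biodegradable substrate         X_I  particulate inerts
#   S_NH  ammonia-N        S_ND soluble organic N    X_ND particulate organic N
#   S_NO2 nitrite-N        S_NO3 nitrate-N           S_N2 dinitrogen (dissolved)
#   X_BH  suspended heterotrophs   X_BA1 suspended AOB   X_BA2 suspended NOB
#   XF_BH/XF_BA1/XF_BA2 attached (biofilm) counterparts, fully retained
#   S_O   bulk dissolved oxygen: fixed setpoint, carried as a bookkeeping
#         column for the COD continuity check and oxygen-demand reporting.
#
# Electron-equivalent conversions (gCOD per gN, exact fractions so that the
# per-process continuity checks close to machine precision):
#   NO3- -> N2: 40/14 = 2.857 ("2.86"); NO2- -> N2: 24/14 = 1.714 ("1.71");
#   NH4+ -> NO2-: 48/14 = 3.429; NO2- -> NO3-: 16/14 = 1.143.

COD_PER_NO3 <- 40 / 14   # denitrification from nitrate
COD_PER_NO2 <- 24 / 14   # denitrification from nitrite
COD_PER_AOB <- 48 / 14   # ammonia -> nitrite oxygen demand
COD_PER_NOB <- 16 / 14   # nitrite -> nitrate oxygen demand
K_NH_SYN <- 0.05         # fixed nutrient switch for biomass synthesis (mgN/L)

ifas_process_names <- function() {
  g <- c("het_growth_aer", "het_growth_anx_no3", "het_growth_anx_no2",
         "het_decay", "aob_growth", "nob_growth", "aob_decay", "nob_decay")
  c(paste0(g, "_susp"),
    "hydrolysis", "hydrolysis_orgN", "ammonification",
    paste0(g, "_att"),
    "attach_H", "detach_H", "attach_AOB", "detach_AOB",
    "attach_NOB", "detach_NOB")
}

#' Stoichiometric (Gujer) matrix of the reduced IFAS model
#'
#' One row per process, one column per component (the 16 state variables plus
#' a bookkeeping dissolved-oxygen column). Yields and fractions are taken
#' from the supplied parameter vector. Every row conserves COD (counting
#' oxygen as negative COD and NOx-N at its electron-accepting equivalents)
#' and nitrogen exactly; see [continuity_check()].
#'
#' @param params full named parameter vector (codes).
#' @param registry parameter registry resolving codes to model roles.
#' @return numeric matrix `processes x components`.
#' @export
ifas_stoichiometry <- function(params, registry = ifas_registry()) {
  p <- model_constants(params, registry)
  comp <- c(ifas_state_names(), "S_O")
  proc <- ifas_process_names()
  S <- matrix(0, length(proc), length(comp), dimnames = list(proc, comp))

  grow <- function(rowname, biomass_col) {
    # aerobic heterotrophic growth on S_S
    S[rowname[1], c("S_S", "S_O", "S_NH", biomass_col)] <<-
      c(-1 / p$Y_H_aer, -(1 - p$Y_H_aer) / p$Y_H_aer, -p$i_XB, 1)
    # anoxic growth on nitrate (denitrification to N2)
    nno3 <- (1 - p$Y_H_anx) / (COD_PER_NO3 * p$Y_H_anx)
    S[rowname[2], c("S_S", "S_NO3", "S_N2", "S_NH", biomass_col)] <<-
      c(-1 / p$Y_H_anx, -nno3, nno3, -p$i_XB, 1)
    # anoxic growth on nitrite (denitrification to N2)
    nno2 <- (1 - p$Y_H_anx) / (COD_PER_NO2 * p$Y_H_anx)
    S[rowname[3], c("S_S", "S_NO2", "S_N2", "S_NH", biomass_col)] <<-
      c(-1 / p$Y_H_anx, -nno2, nno2, -p$i_XB, 1)
  }
  decay <- function(rowname, biomass_col) {
    S[rowname, c(biomass_col, "X_S", "X_I", "X_ND")] <<-
      c(-1, 1 - p$f_U, p$f_U, p$i_XB)
  }
  nitrify <- function(rownames, b1, b2) {
    S[rownames[1], c("S_NH", "S_NO2", "S_O", b1)] <<-
      c(-1 / p$Y_AOB - p$i_XB, 1 / p$Y_AOB, -(COD_PER_AOB - p$Y_AOB) / p$Y_AOB, 1)
    S[rownames[2], c("S_NO2", "S_NO3", "S_NH", "S_O", b2)] <<-
      c(-1 / p$Y_NOB, 1 / p$Y_NOB, -p$i_XB, -(COD_PER_NOB - p$Y_NOB) / p$Y_NOB, 1)
  }

  grow(c("het_growth_aer_susp", "het_growth_anx_no3_susp", "het_growth_anx_no2_susp"), "X_BH")
  decay("het_decay_susp", "X_BH")
  nitrify(c("aob_growth_susp", "nob_growth_susp"), "X_BA1", "X_BA2")
  decay("aob_decay_susp", "X_BA1")
  decay("nob_decay_susp", "X_BA2")

  S["hydrolysis", c("X_S", "S_S")] <- c(-1, 1)
  S["hydrolysis_orgN", c("X_ND", "S_ND")] <- c(-1, 1)
  S["ammonification", c("S_ND", "S_NH")] <- c(-1, 1)

  grow(c("het_growth_aer_att", "het_growth_anx_no3_att", "het_growth_anx_no2_att"), "XF_BH")
  decay("het_decay_att", "XF_BH")
  nitrify(c("aob_growth_att", "nob_growth_att"), "XF_BA1", "XF_BA2")
  decay("aob_decay_att", "XF_BA1")
  decay("nob_decay_att", "XF_BA2")

  # physical exchange between suspended and attached pools
  S["attach_H", c("X_BH", "XF_BH")] <- c(-1, 1)
  S["detach_H", c("XF_BH", "X_BH")] <- c(-1, 1)
  S["attach_AOB", c("X_BA1", "XF_BA1")] <- c(-1, 1)
  S["detach_AOB", c("XF_BA1", "X_BA1")] <- c(-1, 1)
  S["attach_NOB", c("X_BA2", "XF_BA2")] <- c(-1, 1)
  S["detach_NOB", c("XF_BA2", "X_BA2")] <- c(-1, 1)
  S
}

# Conservation weights for the continuity check.
continuity_weights <- function() {
  comp <- c(ifas_state_names(), "S_O")
  cod <- stats::setNames(numeric(length(comp)), comp)
  cod[c("S_S", "S_I", "X_S", "X_I", "X_BH", "X_BA1", "X_BA2",
        "XF_BH", "XF_BA1", "XF_BA2")] <- 1
  cod["S_O"] <- -1
  cod["S_NO3"] <- -64 / 14  # electron equivalents relative to NH4-N reference
  cod["S_NO2"] <- -48 / 14
  cod["S_N2"] <- -24 / 14
  nw <- stats::setNames(numeric(length(comp)), comp)
  nw[c("S_NH", "S_ND", "X_ND", "S_NO2", "S_NO3", "S_N2")] <- 1
  list(cod = cod, nitrogen = nw)
}

#' Per-process mass-continuity check
#'
#' Verifies that every row of the stoichiometric matrix conserves COD
#' (oxygen counted negative, NOx at electron-accepting equivalents relative
#' to ammonia) and nitrogen, except that the nitrogen weight of biomass is
#' its nitrogen content i_XB.
#'
#' @inheritParams ifas_stoichiometry
#' @return data frame of per-process COD and N column sums (all ~0).
#' @export
continuity_check <- function(params, registry = ifas_registry()) {
  p <- model_constants(params, registry)
  S <- ifas_stoichiometry(params, registry)
  w <- continuity_weights()
  nw <- w$nitrogen
  nw[c("X_BH", "X_BA1", "X_BA2", "XF_BH", "XF_BA1", "XF_BA2")] <- p$i_XB
  data.frame(process = rownames(S),
             cod = as.numeric(S %*% w$cod[colnames(S)]),
             nitrogen = as.numeric(S %*% nw[colnames(S)]))
}

# Fast internal rate kernel; `pp` is the role-named constant list and `env`
# carries DO, biofilm DO factor and the attached capacity. Exposed publicly
# through process_rates().
rate_kernel <- function(pp, env) {
  force(pp); force(env)
  SO <- env$do_mgl
  SOb <- env$do_mgl * env$biofilm_do_factor
  cap <- env$attached_capacity_gm3
  function(x) {
    x <- pmax(x, 0)
    S_S <- x[1]; X_S <- x[3]; S_NH <- x[5]; S_ND <- x[6]; X_ND <- x[7]
    S_NO2 <- x[8]; S_NO3 <- x[9]
    X_BH <- x[11]; X_BA1 <- x[12]; X_BA2 <- x[13]
    XF_BH <- x[14]; XF_BA1 <- x[15]; XF_BA2 <- x[16]

    MS <- S_S / (pp$K_S + S_S)
    MNH_syn <- S_NH / (K_NH_SYN + S_NH)
    MNO3 <- S_NO3 / (pp$K_NO3 + S_NO3)
    MNO2 <- S_NO2 / (pp$K_NO2 + S_NO2)
    MNH <- S_NH / (pp$K_NH + S_NH)
    MNO2n <- S_NO2 / (pp$K_NO2_NOB + S_NO2)

    bio_rates <- function(O2, scale, BH, BA1, BA2) {
      MO <- O2 / (pp$K_OH + O2)
      IO <- pp$K_O_den / (pp$K_O_den + O2)
      MOA <- O2 / (pp$K_OA + O2)
      c(pp$mu_H * MS * MO * MNH_syn * scale * BH,
        pp$mu_H * MS * IO * MNO3 * MNH_syn * scale * BH,
        pp$eta_NO2 * pp$mu_H * MS * IO * MNO2 * MNH_syn * scale * BH,
        pp$b_H * BH,
        pp$mu_AOB * MNH * MOA * scale * BA1,
        pp$mu_NOB * MNO2n * MOA * MNH_syn * scale * BA2,
        pp$b_A * BA1,
        pp$b_A * BA2)
    }

    XF_tot <- XF_BH + XF_BA1 + XF_BA2
    L <- max(0, 1 - XF_tot / cap)  # remaining media capacity

    XBH_tot <- X_BH + XF_BH
    ratio <- if (XBH_tot > 0) X_S / XBH_tot else 0
    hyd <- pp$k_h * ratio / (pp$K_X + ratio) * XBH_tot
    hyd_n <- if (X_S > 0) hyd * X_ND / X_S else 0
    ammon <- pp$k_a * S_ND * XBH_tot

    c(bio_rates(SO, 1, X_BH, X_BA1, X_BA2),
      hyd, hyd_n, ammon,
      bio_rates(SOb, L, XF_BH, XF_BA1, XF_BA2),
      pp$k_att * X_BH * L, pp$k_det * XF_BH,
      pp$k_att * X_BA1 * L, pp$k_det * XF_BA1,
      pp$k_att * X_BA2 * L, pp$k_det * XF_BA2)
  }
}

#' Process rates of the reduced model
#'
#' Monod-type rate laws for the biological processes plus the physical
#' attachment/detachment exchange. Attached-biomass growth sees a reduced
#' dissolved oxygen (`biofilm_do_factor * DO`, emulating diffusion limitation)
#' and is throttled by the remaining media capacity. All rates are
#' non-negative (mg/L/d).
#'
#' @param state named state vector (see [ifas_state_names()]).
#' @param params full named parameter vector.
#' @param config [plant_config()] supplying DO and media properties.
#' @param registry parameter registry.
#' @return named rate vector, one entry per process row of
#'   [ifas_stoichiometry()].
#' @export
process_rates <- function(state, params, config = plant_config(),
                          registry = ifas_registry()) {
  if (any(state < 0)) stop_ifas("negative concentration in state vector")
  x <- stats::setNames(numeric(16), ifas_state_names())
  if (is.null(names(state))) {
    if (length(state) != 16) stop_ifas("unnamed state must have length 16")
    x[] <- state
  } else {
    x[names(state)] <- state
  }
  pp <- model_constants(params, registry)
  kern <- rate_kernel(pp, config)
  stats::setNames(kern(as.numeric(x)), ifas_process_names())
}
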