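#' Rim-structured tumor growth model
#'
#' A compact Greenspan-style surrogate for EGFR-mutant lung-adenocarcinoma
#' growth, tracking proliferating (`nb_pc`), quiescent (`nb_qc`) and
#' necrotic (`nb_nc`) cell counts plus a dimensionless vascular-support
#' variable `A`. Cells proliferate at `k_div`, become quiescent when they
#' fall outside a proliferative rim of width `L_p`, become necrotic
#' outside a viable rim `L_v`, and necrotic debris is cleared at `k_lys`.
#' Vascularization (xenograft mode only) widens both rims by the factor
#' `1 + a_ang * A`; the immune system removes viable cells at a small
#' constant rate `e_imm`; gefitinib reduces the division rate through a
#' saturable inhibition term whose parameters depend on the tumor
#' genotype. In vitro mode switches angiogenesis and immune clearance off
#' entirely.
#'
#' Geometry assumes perfectly spherical tumors with constant cell density
#' `cancer_cd = 2.8e8` cells/cm^3:
#' `tumor_volume = (nb_pc + nb_qc + nb_nc) / cancer_cd` and
#' `tumor_radius = (3 * tumor_volume / (4 pi))^(1/3)`.
#'
#' @name growth_model
NULL

#' Literature constants for the mutation profiles
#'
#' Values taken verbatim from the cited kinase-kinetics literature:
#' KRAS mutation reduces GTP hydrolysis by 98%; EGFR exon 19 deletion
#' shifts the ATP Michaelis constant from 5.0 to 129 uM and the gefitinib
#' inhibition constant from 16.4 to 0.833 nM (estimated from an IC50 of
#' 6 nM); PIK3CA mutation increases PI3K complex activity 2.7-fold.
#'
#' @return Named list of the seven constants.
#' @export
mutation_literature <- function() {
  list(
    kras_hydrolysis_reduction = 0.98,
    egfr_atp_km_wt_uM = 5.0,
    egfr_atp_km_mut_uM = 129,
    gefitinib_ki_wt_nM = 16.4,
    gefitinib_ki_mut_nM = 0.833,
    gefitinib_ic50_mut_nM = 6,
    pik3ca_pi3k_fold = 2.7
  )
}

#' Tumor mutation profile
#'
#' @param kras KRAS mutation present?
#' @param egfr_ex19del EGFR exon 19 deletion present (confers gefitinib
#'   sensitivity)?
#' @param pik3ca PIK3CA mutation present (confers gefitinib resistance)?
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(kras = FALSE, egfr_ex19del = FALSE,
                             pik3ca = FALSE) {
  structure(list(kras = isTRUE(kras), egfr_ex19del = isTRUE(egfr_ex19del),
                 pik3ca = isTRUE(pik3ca), literature = mutation_literature()),
            class = "mutation_profile")
}

#' Growth-model parameters
#'
#' All rates are first-order (1/day) and expressed at the reference body
#' mass `ref_mass_g`; rates are rescaled allometrically (exponent -1/4)
#' to the scenario's body mass before integration. Rim widths are in
#' micrometers.
#'
#' @param k_div Division rate of proliferating cells (1/day).
#' @param k_q Quiescence transition rate (1/day).
#' @param k_n Necrosis rate of quiescent cells (1/day).
#' @param k_lys Necrotic clearance rate (1/day).
#' @param N_lys Clearance capacity (cells): necrotic debris is removed
#'   at `k_lys * nc / (1 + nc / N_lys)`, first-order for small pools and
#'   saturating to the fixed capacity `k_lys * N_lys` cells/day for
#'   heavily loaded ones (limited phagocytic capacity). The default is
#'   effectively unsaturable.
#' @param L_p Proliferative rim width (um).
#' @param L_v Viable rim width (um); `L_p <= L_v`.
#' @param A_max Maximal vascular support (dimensionless; the support
#'   variable `A` relaxes toward `A_max * nb_pc / (N_half + nb_pc)`).
#' @param d_ang Vascular turnover rate (1/day): how fast `A` tracks its
#'   target, hence how fast support regresses when the tumor shrinks.
#' @param a_ang Rim-extension strength per unit vascular support
#'   (dimensionless).
#' @param N_half Half-saturation cell count of the angiogenic stimulus.
#' @param e_imm Immune kill rate on viable cells (1/day); forced to 0 in
#'   vitro.
#' @param I_max Maximal fractional inhibition of division by gefitinib,
#'   in `[0, 1]` (cytostatic action).
#' @param k_apo Gefitinib-induced death rate of proliferating cells at
#'   full receptor occupancy (1/day; cytotoxic action). Killed cells
#'   join the necrotic-debris pool; quiescent cells are insensitive.
#' @param prolif_mult Baseline proliferation multiplier (dimensionless).
#' @param egfr_prolif_mult Proliferation-drive factor of the
#'   constitutively active EGFR exon-19-deletion receptor (calibratable;
#'   applied when the profile carries the deletion).
#' @param pik3ca_prolif_mult Cell-line growth factor applied when the
#'   profile carries PIK3CA (the PIK3CA xenograft line grows at its own
#'   intrinsic rate).
#' @param cancer_cd Cancer cell density (cells/cm^3).
#' @param ref_mass_g Body mass (g) at which the rate values are expressed.
#' @return An object of class `growth_params` (named list).
#' @export
growth_params <- function(k_div = 0.3, k_q = 1.5, k_n = 0.15, k_lys = 0.05,
                          L_p = 120, L_v = 260, N_lys = 1e12,
                          A_max = 1, d_ang = 0.3,
                          a_ang = 5, N_half = 1e7, e_imm = 0.005,
                          I_max = 0.95, k_apo = 0, prolif_mult = 1,
                          egfr_prolif_mult = 1, pik3ca_prolif_mult = 1,
                          cancer_cd = 2.8e8, ref_mass_g = 2.63) {
  p <- list(k_div = k_div, k_q = k_q, k_n = k_n, k_lys = k_lys,
            N_lys = N_lys, L_p = L_p,
            L_v = L_v, A_max = A_max, d_ang = d_ang, a_ang = a_ang,
            N_half = N_half, e_imm = e_imm, I_max = I_max, k_apo = k_apo,
            prolif_mult = prolif_mult,
            egfr_prolif_mult = egfr_prolif_mult,
            pik3ca_prolif_mult = pik3ca_prolif_mult,
            cancer_cd = cancer_cd, ref_mass_g = ref_mass_g)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || v < 0, logical(1L))]
  if (length(bad)) stop("negative or non-numeric parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (p$L_p > p$L_v) stop("L_p must not exceed L_v", call. = FALSE)
  if (p$I_max > 1) stop("I_max must lie in [0, 1]", call. = FALSE)
  structure(p, class = "growth_params")
}

# parameters treated as first-order rates for allometric rescaling
.rate_parameters <- c("k_div", "k_q", "k_n", "k_lys", "d_ang",
                      "e_imm", "k_apo")

#' Override growth parameters from a named vector
#'
#' Convenience used by calibration: unknown names raise an error.
#'
#' @param params A [growth_params()] object.
#' @param theta Named numeric vector of overrides.
#' @return Updated `growth_params`.
#' @export
set_growth_params <- function(params, theta) {
  stopifnot(inherits(params, "growth_params"))
  if (length(theta) == 0L) return(params)
  unknown <- setdiff(names(theta), names(params))
  if (length(unknown)) stop("unknown growth parameters: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(theta)) params[[nm]] <- unname(theta[[nm]])
  if (any(unlist(params) < 0) || params$L_p > params$L_v ||
      params$I_max > 1) {
    stop("invalid parameter combination (negative value, L_p > L_v, ",
         "or I_max > 1)", call. = FALSE)
  }
  params
}

#' Simulation scenario
#'
#' @param mode `"in_vitro"` (avascular spheroid; angiogenesis and immune
#'   clearance off) or `"xenograft"` (vascularized, immunosuppressed
#'   mouse).
#' @param mutations A [mutation_profile()].
#' @param dosing `NULL` for placebo, or a list with `conc_nM` (constant
#'   effective gefitinib exposure while treatment is on) and optional
#'   `start`/`end` days (default: whole horizon). The nominal study dose
#'   is 25 mg/kg oral; exposure in nM is the calibratable surrogate of
#'   that dose.
#' @param body_mass_g Body mass; defaults 2.63 g (in vitro reference) or
#'   23 g (mouse).
#' @param horizon Simulation length in days.
#' @param grid Output times (days); default daily.
#' @param n0 Initial cell count; see [cells_from_radius()] /
#'   [cells_from_volume()].
#' @param init `"proliferating"` starts all `n0` cells in the
#'   proliferating compartment (a freshly seeded spheroid);
#'   `"equilibrated"` (the xenograft default) first grows the tumor
#'   untreated from `n0 / 2` until it reaches `n0`, and starts the
#'   reported simulation from that composition — an established,
#'   vascularized tumor at the moment dosing begins.
#' @return An object of class `growth_scenario`.
#' @export
growth_scenario <- function(mode = c("in_vitro", "xenograft"),
                            mutations = mutation_profile(),
                            dosing = NULL, body_mass_g = NULL,
                            horizon = 30, grid = NULL, n0 = 1000,
                            init = NULL) {
  mode <- match.arg(mode)
  if (is.null(init)) {
    init <- if (mode == "in_vitro") "proliferating" else "equilibrated"
  }
  init <- match.arg(init, c("proliferating", "equilibrated"))
  if (is.null(body_mass_g)) {
    body_mass_g <- if (mode == "in_vitro") 2.63 else 23
  }
  if (is.null(grid)) grid <- seq(0, horizon, by = 1)
  if (!is.null(dosing)) {
    stopifnot(is.list(dosing), is.numeric(dosing$conc_nM),
              dosing$conc_nM >= 0)
    if (is.null(dosing$start)) dosing$start <- 0
    if (is.null(dosing$end)) dosing$end <- horizon
  }
  stopifnot(body_mass_g > 0, horizon > 0, n0 >= 0,
            all(grid >= 0), all(grid <= horizon + 1e-9))
  structure(list(mode = mode, mutations = mutations, dosing = dosing,
                 body_mass_g = body_mass_g, horizon = horizon,
                 grid = sort(unique(grid)), n0 = n0, init = init),
            class = "growth_scenario")
}

#' Tumor volume from cell counts
#'
#' `volume = (nb_pc + nb_qc + nb_nc) / cancer_cd`, in cm^3.
#'
#' @param nb_pc,nb_qc,nb_nc Cell counts (`>= 0`).
#' @param cancer_cd Cell density in cells/cm^3 (`> 0`).
#' @return Volume in cm^3.
#' @export
tumor_volume <- function(nb_pc, nb_qc, nb_nc, cancer_cd = 2.8e8) {
  if (any(cancer_cd <= 0)) stop("cancer_cd must be positive", call. = FALSE)
  (nb_pc + nb_qc + nb_nc) / cancer_cd
}

#' Sphere-equivalent tumor radius
#'
#' `radius = (3 * volume / (4 pi))^(1/3)`; input in cm^3, output in cm.
#'
#' @param volume Tumor volume in cm^3 (`>= 0`).
#' @return Radius in cm.
#' @export
tumor_radius <- function(volume) {
  if (any(volume < 0)) stop("volume must be nonnegative", call. = FALSE)
  (volume * 3 / (4 * pi))^(1 / 3)
}

#' Initial cell count from a spheroid radius
#'
#' @param radius_um Radius in micrometers.
#' @param cancer_cd Cell density (cells/cm^3).
#' @return Cell count.
#' @export
cells_from_radius <- function(radius_um, cancer_cd = 2.8e8) {
  (4 / 3) * pi * (radius_um * 1e-4)^3 * cancer_cd
}

#' Initial cell count from a tumor volume
#'
#' @param volume_mm3 Volume in mm^3.
#' @param cancer_cd Cell density (cells/cm^3).
#' @return Cell count.
#' @export
cells_from_volume <- function(volume_mm3, cancer_cd = 2.8e8) {
  volume_mm3 * 1e-3 * cancer_cd
}

#' Gefitinib inhibition term
#'
#' Saturable fractional inhibition of the division rate:
#' `I = I_max * (1 - b_res) * C / (C + Ki_eff)`, zero at zero exposure
#' and fully suppressed (`I = 0`) under complete resistance
#' (`b_res = 1`).
#'
#' @param conc_nM Effective gefitinib exposure (nM).
#' @param ki_nM Effective inhibition constant (nM).
#' @param b_res Resistance factor in `[0, 1]`.
#' @param I_max Maximal inhibition in `[0, 1]`.
#' @return Inhibition in `[0, 1]`.
#' @export
gefitinib_inhibition <- function(conc_nM, ki_nM, b_res = 0, I_max = 1) {
  stopifnot(all(conc_nM >= 0), all(ki_nM >= 0))
  out <- ifelse(conc_nM == 0, 0,
                I_max * (1 - b_res) * conc_nM / (conc_nM + ki_nM))
  pmin(pmax(out, 0), 1)
}

#' Apply a mutation profile to growth parameters
#'
#' Returns the genotype-effective parameters plus the pharmacodynamic
#' constants used by the gefitinib term. The mapping is a declared
#' surrogate of the underlying pathway biology: EGFR exon 19 deletion
#' makes the tumor gefitinib sensitive (Ki drops from 16.4 to 0.833 nM)
#' and constitutively active (proliferation-drive factor
#' `egfr_prolif_mult`); the PIK3CA hotspot mutation renders the PI3K
#' node constitutively active (2.7-fold activity) independently of
#' upstream EGFR, so receptor-level inhibition no longer propagates —
#' full downstream resistance, `b_res = 1` — and selects the PIK3CA
#' line's intrinsic proliferation factor; KRAS mutation sustains pathway
#' activation, modeled as a proliferation-drive multiplier `1 + 0.98`
#' from the 98% reduction in GTP hydrolysis. The literature constants
#' are also returned verbatim for inspection.
#'
#' @param params A [growth_params()] object.
#' @param profile A [mutation_profile()].
#' @return List with `params` (effective [growth_params()]), `pd`
#'   (elements `ki_nM`, `b_res`, `sensitive`), and `literature`.
#' @export
apply_mutations <- function(params, profile) {
  stopifnot(inherits(params, "growth_params"),
            inherits(profile, "mutation_profile"))
  lit <- profile$literature
  eff <- params
  pd <- list(ki_nM = lit$gefitinib_ki_wt_nM, b_res = 0, sensitive = FALSE)
  if (profile$egfr_ex19del) {
    pd$ki_nM <- lit$gefitinib_ki_mut_nM
    pd$sensitive <- TRUE
    eff$prolif_mult <- eff$prolif_mult * eff$egfr_prolif_mult
  }
  if (profile$pik3ca) {
    pd$b_res <- 1 # constitutive PI3K activity bypasses EGFR inhibition
    eff$prolif_mult <- eff$prolif_mult * eff$pik3ca_prolif_mult
  }
  if (profile$kras) {
    eff$prolif_mult <- eff$prolif_mult * (1 + lit$kras_hydrolysis_reduction)
  }
  list(params = eff, pd = pd, literature = lit)
}

#' Simulate the growth model
#'
#' Integrates the rim-structured ODE system on the scenario's output grid
#' with `deSolve::lsoda` (rtol 1e-8, atol 1e-3 cells). Rate parameters
#' are first rescaled allometrically from `ref_mass_g` to the scenario
#' body mass (exponent -1/4), then the mutation profile is applied.
#'
#' The system, with `R` the current sphere-equivalent radius (um),
#' `L_p_eff = L_p (1 + a_ang A)`, `L_v_eff = L_v (1 + a_ang A)`,
#' `g_q = ((R - L_p_eff)_+ / R)^3`, `g_n = ((R - L_v_eff)_+ / R)^3`, and
#' `I` the gefitinib inhibition:
#' \preformatted{
#'  d nb_pc / dt = k_div (1 - I) nb_pc - k_q g_q nb_pc - e_imm nb_pc
#'                 - k_apo occ nb_pc
#'  d nb_qc / dt = k_q g_q nb_pc - k_n g_n nb_qc - e_imm nb_qc
#'  d nb_nc / dt = k_n g_n nb_qc + k_apo occ nb_pc
#'                 - k_lys nb_nc / (1 + nb_nc / N_lys)
#'  d A / dt     = d_ang (A_max nb_pc / (N_half + nb_pc) - A) (xenograft)
#' }
#' In vitro, `A = 0` and `e_imm = 0` throughout.
#'
#' @param params A [growth_params()] object (values at `ref_mass_g`).
#' @param scenario A [growth_scenario()].
#' @param y0 Optional explicit initial state `c(nb_pc, nb_qc, nb_nc, A)`
#'   (e.g. from [equilibrated_state()]), bypassing the scenario's `init`
#'   policy.
#' @param return_init Return the initial state instead of integrating
#'   the trajectory (used by [equilibrated_state()]).
#' @return Trajectory data frame with columns `t`, `nb_pc`, `nb_qc`,
#'   `nb_nc`, `A`, `volume_mm3`, `radius_um`, `prolif_fraction`.
#' @export
simulate_growth <- function(params, scenario, y0 = NULL,
                            return_init = FALSE) {
  stopifnot(inherits(params, "growth_params"),
            inherits(scenario, "growth_scenario"))
  # allometric transfer of rates to the scenario body mass
  scale <- (scenario$body_mass_g / params$ref_mass_g)^(-1 / 4)
  for (nm in .rate_parameters) params[[nm]] <- params[[nm]] * scale
  eff <- apply_mutations(params, scenario$mutations)
  p <- eff$params
  pd <- eff$pd
  in_vitro <- scenario$mode == "in_vitro"
  if (in_vitro) {
    p$e_imm <- 0
    p$A_max <- 0
  }
  dosing <- scenario$dosing
  k_div_eff <- p$k_div * p$prolif_mult

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    pc <- y[1L]; qc <- y[2L]; nc <- y[3L]; A <- if (in_vitro) 0 else y[4L]
    vol_cm3 <- (pc + qc + nc) / p$cancer_cd
    R <- tumor_radius(vol_cm3) * 1e4 # um
    ext <- 1 + p$a_ang * A
    g_q <- if (R > 0) (max(R - p$L_p * ext, 0) / R)^3 else 0
    g_n <- if (R > 0) (max(R - p$L_v * ext, 0) / R)^3 else 0
    occ <- 0 # drug-bound receptor fraction reaching the pathway
    if (!is.null(dosing) && t >= dosing$start && t <= dosing$end) {
      occ <- gefitinib_inhibition(dosing$conc_nM, pd$ki_nM, pd$b_res, 1)
    }
    I <- p$I_max * occ
    kill <- p$k_apo * occ * pc
    clear <- p$k_lys * nc / (1 + nc / p$N_lys) # saturable clearance
    d_pc <- k_div_eff * (1 - I) * pc - p$k_q * g_q * pc - p$e_imm * pc -
      kill
    d_qc <- p$k_q * g_q * pc - p$k_n * g_n * qc - p$e_imm * qc
    d_nc <- p$k_n * g_n * qc + kill - clear
    d_A <- if (in_vitro) 0 else {
      p$d_ang * (p$A_max * pc / (p$N_half + pc) - A)
    }
    list(c(d_pc, d_qc, d_nc, d_A))
  }

  y0_given <- !is.null(y0)
  if (y0_given) {
    stopifnot(length(y0) == 4L, all(y0 >= 0))
    y0 <- c(nb_pc = unname(y0[1L]), nb_qc = unname(y0[2L]),
            nb_nc = unname(y0[3L]), A = unname(y0[4L]))
  } else {
    y0 <- c(nb_pc = scenario$n0, nb_qc = 0, nb_nc = 0, A = 0)
  }
  if (!y0_given && scenario$init == "equilibrated" && scenario$n0 > 0) {
    # untreated pre-growth from n0/2 up to n0 fixes the initial
    # composition (and vascular support) of an established tumor
    dosing_main <- dosing
    dosing <- NULL
    n_pre <- scenario$n0 / 2
    A_ss <- if (in_vitro) 0 else p$A_max * n_pre / (p$N_half + n_pre)
    y_pre <- c(nb_pc = n_pre, nb_qc = 0, nb_nc = 0, A = A_ss)
    pre <- deSolve::lsodar(y_pre, seq(0, 365, by = 0.5), deriv,
                           parms = NULL, rtol = 1e-8, atol = 1e-3,
                           rootfunc = function(t, y, parms) {
                             sum(pmax(y[1:3], 0)) - scenario$n0
                           })
    y_end <- pmax(pre[nrow(pre), c("nb_pc", "nb_qc", "nb_nc", "A")], 0)
    total_pre <- sum(y_end[1:3])
    if (total_pre > 0) {
      y0 <- c(y_end[1:3] * scenario$n0 / total_pre, A = unname(y_end[4L]))
      names(y0) <- c("nb_pc", "nb_qc", "nb_nc", "A")
    }
    dosing <- dosing_main
  }
  if (return_init) return(y0)
  out <- deSolve::lsoda(y0, scenario$grid, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-3)
  if (attr(out, "istate")[1L] < 0 || any(!is.finite(out))) {
    stop("integration failed (non-finite state); parameters: ",
         paste(sprintf("%s=%g", names(params), unlist(params)),
               collapse = ", "),
         call. = FALSE)
  }
  out <- as.data.frame(out)
  names(out)[1L] <- "t"
  out$nb_pc <- pmax(out$nb_pc, 0)
  out$nb_qc <- pmax(out$nb_qc, 0)
  out$nb_nc <- pmax(out$nb_nc, 0)
  out$A <- pmax(out$A, 0)
  total <- out$nb_pc + out$nb_qc + out$nb_nc
  vol_cm3 <- tumor_volume(out$nb_pc, out$nb_qc, out$nb_nc, p$cancer_cd)
  out$volume_mm3 <- vol_cm3 * 1e3
  out$radius_um <- tumor_radius(vol_cm3) * 1e4
  out$prolif_fraction <- ifelse(total > 0, out$nb_pc / total, 0)
  out
}

#' Write a trajectory CSV
#'
#' Header `t,nb_pc,nb_qc,nb_nc,A,volume_mm3,radius_um,prolif_fraction`.
#'
#' @param trajectory Output of [simulate_growth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}


#' Initial state of an established (equilibrated) tumor
#'
#' Runs the scenario's untreated pre-growth phase and returns the
#' resulting initial state vector `c(nb_pc, nb_qc, nb_nc, A)` at the
#' scenario's `n0`. Arms that share a genotype and initial size share
#' this state, so it can be computed once and passed to
#' [simulate_growth()] as `y0`.
#'
#' @param params A [growth_params()] object.
#' @param scenario A [growth_scenario()] with `init = "equilibrated"`.
#' @return Numeric initial state of length 4.
#' @export
equilibrated_state <- function(params, scenario) {
  simulate_growth(params, scenario, return_init = TRUE)
}
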