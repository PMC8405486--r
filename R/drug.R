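## Drug physicochemistry: ionization, lipophilicity partitioning, and the
## building blocks of passive permeability.

#' Construct a drug record
#'
#' @param name Drug name.
#' @param mw Molecular weight, g/mol.
#' @param charge_class One of `"neutral"`, `"acid"`, `"base"`,
#'   `"amphoteric"`.  Metadata only: ionization is computed from whichever
#'   of `pka`/`pkb` are present.
#' @param pka Ionization constant of the strongest acidic group (`NA` if the
#'   molecule has no acidic group).
#' @param pkb Ionization constant of the strongest basic group (`NA` if
#'   absent).
#' @param logp Octanol-water log10 partition coefficient.
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param fu_csf Unbound fraction in CSF, in (0, 1]; default 1 (CSF has
#'   negligible protein).
#' @param kpuu Named numeric vector `c(ecf = , lv = , cm = )` of target
#'   unbound tissue-to-plasma partition coefficients used to calibrate the
#'   asymmetry factors.
#' @param af Optional pre-specified asymmetry factors: a list with elements
#'   `bbb`, `bcsfb_lv`, `bcsfb_tfv`, each `c(af_in = , af_ef = )`.
#' @return An object of class `cns_drug`.
#' @export
cns_drug <- function(name, mw, charge_class = "neutral", pka = NA, pkb = NA,
                     logp, fu_plasma = 1, fu_csf = 1,
                     kpuu = c(ecf = 1, lv = 1, cm = 1), af = NULL) {
  if (!is.finite(mw) || mw <= 0 || mw > 5000)
    stop("`mw` must be a positive molecular weight (g/mol)", call. = FALSE)
  if (!is.finite(logp)) stop("`logp` must be finite", call. = FALSE)
  charge_class <- match.arg(charge_class,
                            c("neutral", "acid", "base", "amphoteric"))
  for (f in c(fu_plasma, fu_csf))
    if (!is.finite(f) || f <= 0 || f > 1)
      stop("unbound fractions must lie in (0, 1]", call. = FALSE)
  kpuu <- kpuu[c("ecf", "lv", "cm")]
  if (any(is.na(kpuu)) || any(kpuu <= 0))
    stop("`kpuu` must supply positive ecf, lv, cm targets", call. = FALSE)
  structure(list(name = name, mw = mw, charge_class = charge_class,
                 pka = pka, pkb = pkb, logp = logp,
                 fu_plasma = fu_plasma, fu_csf = fu_csf,
                 kpuu = kpuu, af = af),
            class = "cns_drug")
}

#' @export
print.cns_drug <- function(x, ...) {
  cat(sprintf("<cns_drug> %s: MW %.2f, %s, pKa %s, pKb %s, logP %.2f\n",
              x$name, x$mw, x$charge_class,
              format(x$pka), format(x$pkb), x$logp))
  cat(sprintf("  Kp_uu  ECF %.4g | LV %.4g | CM %.4g;  fu,p %.3g  fu,CSF %.3g\n",
              x$kpuu["ecf"], x$kpuu["lv"], x$kpuu["cm"],
              x$fu_plasma, x$fu_csf))
  invisible(x)
}

#' Neutral drug fraction in a compartment (pH factor)
#'
#' Adapted Henderson-Hasselbalch neutral fractions.  For the acidic group
#' `PHF_acidic = 1 / (1 + 10^(pH - pKa))`; for the basic group
#' `PHF_basic = 1 / (1 + 10^(pKb - pH))`; the overall neutral fraction is
#' their product.  A missing group contributes a factor of 1.
#'
#' @param drug A [cns_drug] object (only `pka`/`pkb` are used).
#' @param ph_comp Compartment pH, in [1, 14].
#' @return List with `phf_acidic`, `phf_basic`, `phf`.
#' @export
compute_phf <- function(drug, ph_comp) {
  if (any(ph_comp < 1 | ph_comp > 14))
    stop("`ph_comp` must lie in [1, 14]", call. = FALSE)
  phf_a <- if (is.null(drug$pka) || is.na(drug$pka)) rep(1, length(ph_comp))
           else 1 / (1 + 10^(ph_comp - drug$pka))
  phf_b <- if (is.null(drug$pkb) || is.na(drug$pkb)) rep(1, length(ph_comp))
           else 1 / (1 + 10^(drug$pkb - ph_comp))
  list(phf_acidic = phf_a, phf_basic = phf_b, phf = phf_a * phf_b)
}

#' Octanol-water partition coefficient from logP
#'
#' @param logp log10 partition coefficient.
#' @return `10^logp` (dimensionless).
#' @export
octanol_water_partition <- function(logp) {
  if (!is.numeric(logp) || any(!is.finite(logp)))
    stop("`logp` must be finite", call. = FALSE)
  10^logp
}

#' Transport coefficient configuration
#'
#' The aqueous-diffusion and transmembrane-permeability relations are
#' config-parameterized: the supplementary constants of the source lineage
#' are not printed in the main literature, so the functional forms below
#' carry documented stand-in coefficients that an owner of the original
#' supplement can override.
#'
#' * Aqueous diffusivity: `D(MW) = d_ref * (mw_ref / MW)^(1/3)` (cm2/min),
#'   a Stokes-Einstein-type inverse-cube-root size scaling anchored at
#'   `d_ref` = 6e-4 cm2/min (1e-5 cm2/s, a typical small-molecule value)
#'   for `mw_ref` = 100 g/mol.
#' * Transmembrane permeability:
#'   `log10 P_trans = a * logP + b - c * log10(MW)` (P_trans in cm/min),
#'   a log-linear lipophilicity/size relation with defaults a = 0.6,
#'   b = -3.0, c = 0.5 chosen to put a logP 0, MW 300 drug at ~1e-6 cm/s.
#'
#' @param d_ref Reference aqueous diffusion coefficient, cm2/min.
#' @param mw_ref Reference molecular weight, g/mol.
#' @param perm_a,perm_b,perm_c Coefficients of the permeability relation.
#' @return A named list of coefficients.
#' @export
transport_config <- function(d_ref = 6e-4, mw_ref = 100,
                             perm_a = 0.6, perm_b = -3.0, perm_c = 0.5) {
  list(d_ref = d_ref, mw_ref = mw_ref,
       perm_a = perm_a, perm_b = perm_b, perm_c = perm_c)
}

#' Aqueous diffusion coefficient of a drug
#'
#' @param mw Molecular weight, g/mol.
#' @param config A [transport_config()] list.
#' @return Diffusion coefficient in cm2/min; strictly decreasing in MW.
#' @export
aqueous_diffusivity <- function(mw, config = transport_config()) {
  if (!is.numeric(mw) || any(!is.finite(mw)) || any(mw <= 0))
    stop("`mw` must be positive", call. = FALSE)
  config$d_ref * (config$mw_ref / mw)^(1 / 3)
}

## Equivalent spherical molecular radius (nm) assuming unit density:
## r = (3 MW / (4 pi N_A rho))^(1/3), rho = 1 g/cm3.
molecular_radius_nm <- function(mw) {
  1e7 * (3 * mw / (4 * pi * 6.02214076e23))^(1 / 3)
}

#' Transmembrane (phospholipid bilayer) permeability
#'
#' @param drug A [cns_drug] object (uses `logp` and `mw`).
#' @param config A [transport_config()] list.
#' @return Permeability of the neutral species in cm/min.
#' @export
transmembrane_permeability <- function(drug, config = transport_config()) {
  10^(config$perm_a * drug$logp + config$perm_b -
        config$perm_c * log10(drug$mw))
}

#' Phospholipid non-specific binding clearances
#'
#' Drug exchange between the aqueous brain compartments (ECF, ICF) and the
#' brain-cell-membrane phospholipid pool is a pair of diffusion clearances
#' `CL_wo` (water to membrane) and `CL_ow` (membrane to water) constructed
#' so that the steady-state membrane-to-water concentration ratio equals
#' the octanol-water partition coefficient: `CL_wo / CL_ow = 10^logP`.
#'
#' @param drug A [cns_drug] object.
#' @param physiology A [cns_physiology] object (used for the default
#'   kinetic scale).
#' @param kinetic_scale Water-to-membrane clearance `CL_wo` in mL/min.
#'   Defaults to the cerebral blood flow, which is large relative to the
#'   barrier clearances so binding is near-equilibrium yet time-resolved.
#' @return List with `p_octw`, `cl_wo`, `cl_ow` (mL/min).
#' @export
build_membrane_binding <- function(drug, physiology,
                                   kinetic_scale = physiology$q_cbf) {
  if (!is.finite(kinetic_scale) || kinetic_scale <= 0)
    stop("`kinetic_scale` must be positive", call. = FALSE)
  p <- octanol_water_partition(drug$logp)
  list(p_octw = p, cl_wo = kinetic_scale, cl_ow = kinetic_scale / p)
}

#' Packaged drug fixtures
#'
#' The twelve model-evaluation drugs with molecular weight, charge class,
#' ionization constants, logP and regional Kp_uu targets.  Kp_uu sets are
#' keyed by population (`rat`, `human`) and, for morphine, by dose group.
#' Printed asymmetry-factor columns from the source table are
#' typographically ambiguous and are deliberately not shipped; the
#' steady-state solver ([solve_asymmetry_factors()]) is the authoritative
#' path.
#'
#' @param name Optional single drug name; if omitted all drugs are
#'   returned as a named list.
#' @param population Which Kp_uu set to select: `"rat"` (default) or
#'   `"human"`.  Drugs without a population-specific set fall back to the
#'   other set with a message.
#' @param dose_group For morphine: `"4mg/kg"` (default), `"10-40mg/kg"`.
#' @return A [cns_drug] or named list of them.
#' @export
drug_fixture <- function(name = NULL, population = c("rat", "human"),
                         dose_group = NULL) {
  population <- match.arg(population)
  path <- system.file("extdata", "drugs.json", package = "cnspbpk")
  raw <- jsonlite::read_json(path)
  build1 <- function(d) {
    sets <- d$kpuu
    key <- population
    if (identical(d$name, "morphine") && population == "rat") {
      key <- paste0("rat_", dose_group %||% "4mg/kg")
    }
    if (is.null(sets[[key]])) {
      key <- setdiff(names(sets), key)[1]
      message(d$name, ": no `", population,
              "` Kp_uu set in fixtures; using `", key, "` values")
    }
    kp <- unlist(sets[[key]])
    cns_drug(name = d$name, mw = d$mw, charge_class = d$charge_class,
             pka = d$pka %||% NA, pkb = d$pkb %||% NA, logp = d$logp,
             fu_plasma = d$fu_plasma, fu_csf = d$fu_csf %||% 1,
             kpuu = kp[c("ecf", "lv", "cm")])
  }
  if (!is.null(name)) {
    hit <- which(vapply(raw$drugs, function(d) identical(d$name, name), TRUE))
    if (!length(hit))
      stop("unknown drug `", name, "`; available: ",
           paste(vapply(raw$drugs, `[[`, "", "name"), collapse = ", "),
           call. = FALSE)
    return(build1(raw$drugs[[hit]]))
  }
  out <- lapply(raw$drugs, build1)
  names(out) <- vapply(raw$drugs, `[[`, "", "name")
  out
}
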