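## The nine-compartment CNS system.
##
## State layout (amounts, ng):  MV (brain microvessels), ECF, ICF, LYS
## (lysosomes), BCM (brain cell membrane phospholipids), LV (lateral
## ventricles), TFV (third+fourth ventricles), CM (cisterna magna), SAS
## (subarachnoid space).  Plasma drives MV through the cerebral blood flow;
## drug leaving the SAS with the CSF flow is eliminated to an absorption
## sink (plasma is an external forcing function, so recirculation would be
## a no-op).
##
## Flux conventions:
##  * transcellular flux A->B is P_trans * SA * PHF_A * Cu_A, so only the
##    neutral species crosses membranes and pH gradients drive ion trapping;
##  * paracellular flux crosses tight junctions irrespective of charge;
##  * asymmetry factors AF_in / AF_ef multiply the total passive influx /
##    efflux clearance of their barrier (switchable to transcellular-only);
##  * bulk flows (Q_ECF, Q_CSF) transport drug irrespective of gradients.

.cns_comps <- c("mv", "ecf", "icf", "lys", "bcm", "lv", "tfv", "cm", "sas")
.cns_barriers <- c("bbb", "bcsfb_lv", "bcsfb_tfv")

## Renkin-type steric hindrance polynomial for diffusion through a
## cylindrical pore, lambda = molecular radius / pore radius.
.renkin <- function(lambda) {
  ifelse(lambda >= 1, 0,
         (1 - lambda)^2 *
           (1 - 2.104 * lambda + 2.09 * lambda^3 - 0.95 * lambda^5))
}

#' Paracellular clearance of a barrier
#'
#' Aqueous diffusion through the tight-junction pores:
#' `CL_para = D_aq * (SA * f_para) * F(lambda) / L`, with `F` the Renkin
#' hindrance polynomial and `lambda` the ratio of molecular to pore radius.
#' All charge species (anions, cations, zwitterions, neutrals) use the
#' same paracellular rate.  `lambda >= 1` gives zero clearance (steric
#' exclusion), not an error.
#'
#' @param physiology A [cns_physiology].
#' @param drug A [cns_drug].
#' @param barrier `"bbb"`, `"bcsfb_lv"`, or `"bcsfb_tfv"`.
#' @param transport A [transport_config()].
#' @return Clearance in mL/min.
#' @export
paracellular_clearance <- function(physiology, drug,
                                   barrier = c("bbb", "bcsfb_lv", "bcsfb_tfv"),
                                   transport = transport_config()) {
  barrier <- match.arg(barrier)
  sa <- physiology[[paste0("sa_", barrier)]]
  d_aq <- aqueous_diffusivity(drug$mw, transport)
  lambda <- molecular_radius_nm(drug$mw) / physiology$pore_radius_nm
  len_cm <- physiology$paracellular_length_um * 1e-4
  d_aq * sa * physiology$paracellular_fraction * .renkin(lambda) / len_cm
}

#' Assemble the CNS system for a drug and physiology
#'
#' Computes per-compartment neutral fractions, barrier transcellular and
#' paracellular clearances, membrane-binding clearances, and the flux
#' topology.  Asymmetry factors are then either solved from the drug's
#' Kp_uu targets ([solve_asymmetry_factors()], the default) or taken from
#' pre-specified values on the drug record.
#'
#' @param physiology A [cns_physiology].
#' @param drug A [cns_drug].
#' @param af_mode `"solve"` (calibrate AFs from Kp_uu at steady state) or
#'   `"provided"` (use `drug$af`; error if absent).
#' @param transport A [transport_config()].
#' @param kinetic_scale Membrane-binding water-side clearance, mL/min;
#'   default cerebral blood flow (see [build_membrane_binding()]).
#' @param icf_exchange If `FALSE`, all exchange with brain ICF (and through
#'   it the lysosomes) is switched off; used to isolate the
#'   ECF-membrane binding equilibrium.
#' @param af_applies_to Whether an AF multiplies the `"total"` passive
#'   clearance of its barrier (default) or the `"transcellular"` route only.
#' @return A `cns_system` object.
#' @export
build_system <- function(physiology, drug, af_mode = c("solve", "provided"),
                         transport = transport_config(),
                         kinetic_scale = NULL, icf_exchange = TRUE,
                         af_applies_to = c("total", "transcellular")) {
  af_mode <- match.arg(af_mode)
  af_applies_to <- match.arg(af_applies_to)
  stopifnot(inherits(physiology, "cns_physiology"), inherits(drug, "cns_drug"))

  ph <- c(mv = physiology$ph_plasma, ecf = physiology$ph_ecf,
          icf = physiology$ph_icf, lys = physiology$ph_lys,
          bcm = physiology$ph_icf,  # unused: no transmembrane flux from BCM
          lv = physiology$ph_csf, tfv = physiology$ph_csf,
          cm = physiology$ph_csf, sas = physiology$ph_csf)
  phf <- vapply(ph, function(p) compute_phf(drug, p)$phf, numeric(1))

  p_trans <- transmembrane_permeability(drug, transport)
  barriers <- list()
  sa_of <- c(bbb = physiology$sa_bbb, bcsfb_lv = physiology$sa_bcsfb_lv,
             bcsfb_tfv = physiology$sa_bcsfb_tfv)
  target_of <- c(bbb = drug$kpuu[["ecf"]], bcsfb_lv = drug$kpuu[["lv"]],
                 bcsfb_tfv = drug$kpuu[["cm"]])
  for (b in .cns_barriers) {
    barriers[[b]] <- list(
      cl_trans = p_trans * sa_of[[b]],
      cl_para = paracellular_clearance(physiology, drug, b, transport),
      kpuu_target = target_of[[b]],
      af_in = NA_real_, af_ef = NA_real_)
  }

  binding <- build_membrane_binding(
    drug, physiology,
    kinetic_scale = kinetic_scale %||% physiology$q_cbf)

  system <- structure(
    list(physiology = physiology, drug = drug, transport = transport,
         phf = phf, barriers = barriers, binding = binding,
         icf_exchange = icf_exchange, af_applies_to = af_applies_to),
    class = "cns_system")

  if (af_mode == "provided") {
    if (is.null(drug$af))
      stop("af_mode = \"provided\" but the drug record has no `af` values",
           call. = FALSE)
    map <- c(bbb = "bbb", bcsfb_lv = "bcsfb_lv", bcsfb_tfv = "bcsfb_tfv")
    for (b in .cns_barriers) {
      afb <- drug$af[[map[[b]]]]
      if (is.null(afb) || any(is.na(afb[c("af_in", "af_ef")])))
        stop("missing pre-specified AF for barrier ", b, call. = FALSE)
      system$barriers[[b]]$af_in <- afb[["af_in"]]
      system$barriers[[b]]$af_ef <- afb[["af_ef"]]
    }
    system
  } else {
    solve_asymmetry_factors(system)
  }
}

## Influx / efflux clearances of a barrier given its AFs.
## `phf_src` is the neutral fraction on the donor side.
.barrier_cl <- function(bar, phf_src, direction, af_applies_to) {
  af <- if (direction == "in") bar$af_in else bar$af_ef
  if (is.na(af)) af <- 1
  if (af_applies_to == "total") {
    af * (bar$cl_para + bar$cl_trans * phf_src)
  } else {
    bar$cl_para + af * bar$cl_trans * phf_src
  }
}

#' Rate matrix of the CNS system
#'
#' Returns the 9x9 rate matrix `A` (states are amounts in ng, order
#' MV, ECF, ICF, LYS, BCM, LV, TFV, CM, SAS) and the input vector `b_unit`
#' such that `dx/dt = A x + b_unit * Cu_plasma(t)`.
#'
#' @param system A `cns_system`.
#' @return List with `A`, `b_unit`, `volumes`, `fu_out` (the factor mapping
#'   compartment amount/volume to reported unbound concentration).
#' @export
cns_rate_matrix <- function(system) {
  p <- system$physiology
  drug <- system$drug
  comps <- .cns_comps
  vols <- c(mv = p$v_mv, ecf = p$v_ecf, icf = p$v_icf, lys = p$v_lys,
            bcm = p$v_bcm, lv = p$v_lv, tfv = p$v_tfv, cm = p$v_cm,
            sas = p$v_sas)
  ## factor mapping total concentration to the transportable (unbound)
  ## concentration; CSF compartments carry f_u,CSF, all others are tracked
  ## as unbound already (BCM is a membrane phase, handled separately).
  fu <- setNames(rep(1, 9), comps)
  fu[c("lv", "tfv", "cm", "sas")] <- drug$fu_csf

  A <- matrix(0, 9, 9, dimnames = list(comps, comps))
  add_flux <- function(from, to, cl, fu_from = 1) {
    # flux = cl * fu_from * (amount_from / V_from); `to = NA` is a sink
    k <- cl * fu_from / vols[[from]]
    A[from, from] <<- A[from, from] - k
    if (!is.na(to)) A[to, from] <<- A[to, from] + k
  }

  phf <- system$phf
  aat <- system$af_applies_to
  tissue_of <- c(bbb = "ecf", bcsfb_lv = "lv", bcsfb_tfv = "tfv")
  for (b in .cns_barriers) {
    bar <- system$barriers[[b]]
    tis <- tissue_of[[b]]
    cl_in <- .barrier_cl(bar, phf[["mv"]], "in", aat)
    cl_out <- .barrier_cl(bar, phf[[tis]], "out", aat)
    add_flux("mv", tis, cl_in)
    add_flux(tis, "mv", cl_out, fu_from = fu[[tis]])
  }

  if (system$icf_exchange) {
    cl_bcm_mem <- transmembrane_permeability(drug, system$transport) * p$sa_bcm
    cl_lys_mem <- transmembrane_permeability(drug, system$transport) * p$sa_lys
    add_flux("ecf", "icf", cl_bcm_mem * phf[["ecf"]])
    add_flux("icf", "ecf", cl_bcm_mem * phf[["icf"]])
    add_flux("icf", "lys", cl_lys_mem * phf[["icf"]])
    add_flux("lys", "icf", cl_lys_mem * phf[["lys"]])
    add_flux("icf", "bcm", system$binding$cl_wo)
    add_flux("bcm", "icf", system$binding$cl_ow)
  }
  add_flux("ecf", "bcm", system$binding$cl_wo)
  add_flux("bcm", "ecf", system$binding$cl_ow)

  q_csf_tot <- p$q_csf + p$q_ecf
  add_flux("ecf", "lv", p$q_ecf)
  add_flux("lv", "tfv", q_csf_tot)
  add_flux("tfv", "cm", q_csf_tot)
  add_flux("cm", "sas", q_csf_tot)
  add_flux("sas", NA, q_csf_tot)          # CSF absorption sink
  add_flux("mv", NA, p$q_cbf)             # venous return to plasma

  b_unit <- setNames(numeric(9), comps)
  b_unit[["mv"]] <- p$q_cbf               # Q_CBF * Cu_plasma into MV

  list(A = A, b_unit = b_unit, volumes = vols, fu_out = fu)
}

#' Steady-state unbound concentrations under constant plasma
#'
#' Direct linear solve of the rate matrix (no integration) for a constant
#' unbound plasma concentration.  Compartments decoupled from the system
#' (e.g. ICF/lysosomes with `icf_exchange = FALSE`) stay at zero.
#'
#' @param system A `cns_system`.
#' @param cu_plasma Constant unbound plasma concentration, ng/mL.
#' @return Named vector of unbound concentrations (ng/mL; `bcm` is the
#'   membrane-phase concentration).
#' @export
cns_steady_state <- function(system, cu_plasma = 1) {
  m <- cns_rate_matrix(system)
  act <- diag(m$A) != 0 | m$b_unit != 0
  x <- numeric(9)
  x[act] <- lti_steady_state(m$A[act, act, drop = FALSE],
                             m$b_unit[act] * cu_plasma)
  setNames(x / m$volumes * m$fu_out, .cns_comps)
}

## Regional Kp_uu at steady state under unit unbound plasma concentration.
.cns_steady_kpuu <- function(system) {
  cu <- cns_steady_state(system, 1)
  c(ecf = cu[["ecf"]], lv = cu[["lv"]], cm = cu[["cm"]])
}

#' Calibrate asymmetry factors against Kp_uu targets
#'
#' Under a constant unit unbound plasma concentration, the steady state of
#' the full linear CNS system must satisfy `Cu_ECF = Kp_uu_ECF`,
#' `Cu_LV = Kp_uu_LV`, `Cu_CM = Kp_uu_CM` simultaneously.  Per barrier the
#' three-scenario rule selects which AF is free: `Kp_uu < 1` implies active
#' efflux (`AF_in = 1`, solve `AF_ef`); `Kp_uu > 1` implies active influx
#' (`AF_ef = 1`, solve `AF_in`); `Kp_uu = 1` fixes both at 1.  The coupled
#' system is solved by Gauss-Seidel sweeps of monotone 1-D root finds on
#' log10(AF) in [1, 1e12].
#'
#' @param system A `cns_system` (AFs may be unset).
#' @param tol Relative tolerance on the recovered Kp_uu.
#' @param max_sweeps Maximum Gauss-Seidel sweeps.
#' @return The system with `af_in`/`af_ef` filled on every barrier and an
#'   attribute `kpuu_recovered`.
#' @export
solve_asymmetry_factors <- function(system, tol = 1e-9, max_sweeps = 100) {
  region_of <- c(bbb = "ecf", bcsfb_lv = "lv", bcsfb_tfv = "cm")
  free <- character(0)
  for (b in .cns_barriers) {
    k <- system$barriers[[b]]$kpuu_target
    if (abs(k - 1) < 1e-12) {
      system$barriers[[b]]$af_in <- 1
      system$barriers[[b]]$af_ef <- 1
      free[b] <- "none"
    } else if (k < 1) {
      system$barriers[[b]]$af_in <- 1
      system$barriers[[b]]$af_ef <- 1
      free[b] <- "af_ef"
    } else {
      system$barriers[[b]]$af_in <- 1
      system$barriers[[b]]$af_ef <- 1
      free[b] <- "af_in"
    }
  }

  resid <- function(sys, b) {
    reg <- region_of[[b]]
    log(.cns_steady_kpuu(sys)[[reg]] / sys$barriers[[b]]$kpuu_target)
  }

  for (sweep in seq_len(max_sweeps)) {
    moved <- 0
    for (b in .cns_barriers) {
      if (free[[b]] == "none") next
      slot <- free[[b]]
      f <- function(la) {
        sys <- system
        sys$barriers[[b]][[slot]] <- 10^la
        resid(sys, b)
      }
      ## residual is monotone in log AF: increasing for af_in, decreasing
      ## for af_ef.  Expand the upper bracket in log10 steps instead of
      ## probing AF = 1e12 outright (which is numerically singular).
      up <- if (slot == "af_in") 1 else -1
      f0 <- f(0)
      if (abs(f0) < tol) {
        la <- 0
      } else if (up * f0 > 0) {
        stop("Kp_uu = ", system$barriers[[b]]$kpuu_target,
             " at barrier ", b, " is unreachable with ", slot, " >= 1 ",
             "(steady-state ratio at AF = 1 is already ",
             signif(exp(f0) * system$barriers[[b]]$kpuu_target, 4), ")",
             call. = FALSE)
      } else {
        hi <- 0
        fhi <- f0
        repeat {
          hi <- hi + 1
          fhi <- tryCatch(f(hi), error = function(e) e)
          if (inherits(fhi, "error") || hi >= 12) break
          if (up * fhi > 0) break
        }
        if (inherits(fhi, "error") || up * fhi <= 0)
          stop("no asymmetry factor in [1, 1e12] reaches Kp_uu = ",
               system$barriers[[b]]$kpuu_target, " at barrier ", b,
               call. = FALSE)
        la <- uniroot(f, c(hi - 1, hi), tol = 1e-13)$root
      }
      old <- system$barriers[[b]][[slot]]
      system$barriers[[b]][[slot]] <- 10^la
      moved <- max(moved, abs(log(10^la / old)))
    }
    rec <- .cns_steady_kpuu(system)
    targ <- vapply(.cns_barriers,
                   function(b) system$barriers[[b]]$kpuu_target, numeric(1))
    ok <- free == "none" | abs(log(rec[region_of[.cns_barriers]] / targ)) < tol
    if (all(ok)) break
    if (sweep == max_sweeps)
      stop("asymmetry-factor calibration did not converge in ",
           max_sweeps, " sweeps", call. = FALSE)
  }
  attr(system, "kpuu_recovered") <- .cns_steady_kpuu(system)
  system
}

#' Interspecies scaling of an asymmetry factor
#'
#' Divides an AF calibrated in one species by a transporter-expression
#' scaling factor, clamping at the passive limit of 1 (with a warning)
#' when the quotient falls below it.
#'
#' @param af Asymmetry factor (>= 1).
#' @param scaling_factor Positive scaling factor (e.g. 8 for an at least
#'   eight-fold lower transporter expression in the target species).
#' @return The scaled AF, >= 1.
#' @export
scale_af_interspecies <- function(af, scaling_factor) {
  if (scaling_factor <= 0) stop("`scaling_factor` must be positive",
                                call. = FALSE)
  out <- af / scaling_factor
  if (any(out < 1)) {
    warning("scaled asymmetry factor fell below 1; clamped to the passive ",
            "limit", call. = FALSE)
    out <- pmax(out, 1)
  }
  out
}

#' @export
print.cns_system <- function(x, ...) {
  cat(sprintf("<cns_system> %s in %s physiology\n", x$drug$name,
              attr(x$physiology, "species")))
  for (b in .cns_barriers) {
    bar <- x$barriers[[b]]
    cat(sprintf("  %-9s CL_trans %.4g  CL_para %.4g mL/min | Kp_uu %.4g -> AF_in %.4g AF_ef %.4g\n",
                b, bar$cl_trans, bar$cl_para, bar$kpuu_target,
                bar$af_in, bar$af_ef))
  }
  cat(sprintf("  binding CL_wo %.4g CL_ow %.4g (P_octw %.4g)\n",
              x$binding$cl_wo, x$binding$cl_ow, x$binding$p_octw))
  invisible(x)
}
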