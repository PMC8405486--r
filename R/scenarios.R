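## In-silico experiments: parameter sensitivity analysis and the
## altered-CSF-dynamics surrogacy study.

## Extract solved AFs from a system so they can be frozen across
## perturbed physiologies.
.af_of <- function(system) {
  lapply(system$barriers,
         function(b) c(af_in = b$af_in, af_ef = b$af_ef))
}

## Rebuild a system on a (possibly perturbed) physiology with AFs frozen.
.rebuild_frozen <- function(system, physiology) {
  drug <- system$drug
  drug$af <- .af_of(system)
  build_system(physiology, drug, af_mode = "provided",
               transport = system$transport,
               icf_exchange = system$icf_exchange,
               af_applies_to = system$af_applies_to)
}

#' Parameter sensitivity analysis
#'
#' Each physiology parameter is varied individually by the given fold
#' changes and the PK descriptors (`C_max`, `T_max`, `AUC`) of the selected
#' compartments are compared to the physiological run through the
#' sensitivity index `log2(Y_d / Y_o)`.  By default the asymmetry factors
#' are *not* re-solved after perturbation: the perturbation probes the
#' physiology's effect at fixed drug disposition (set `resolve_af = TRUE`
#' for the alternative reading).
#'
#' @param physiology A [cns_physiology].
#' @param drugs A list of [cns_drug] objects (or a single one).
#' @param plasma_spec A [plasma_model_spec] shared across runs.
#' @param doses List of [dose_event] objects.
#' @param parameters Character vector of physiology parameter paths.
#' @param folds Fold changes, default `c(1.1, 1.5, 2)`.
#' @param compartments Compartments to report, default
#'   `c("ecf", "icf", "sas")`.
#' @param times Simulation grid, min.
#' @param resolve_af Re-solve AFs on the perturbed physiology?
#' @return Data frame: `drug`, `parameter`, `fold`, `compartment`,
#'   `descriptor`, `y_o`, `y_d`, `index`, `status`.  A failed perturbed
#'   simulation is flagged (`status = "failed"`), not fatal.
#' @export
run_sensitivity <- function(physiology, drugs, plasma_spec, doses,
                            parameters, folds = c(1.1, 1.5, 2),
                            compartments = c("ecf", "icf", "sas"),
                            times = seq(0, 720, by = 1),
                            resolve_af = FALSE) {
  if (inherits(drugs, "cns_drug")) drugs <- list(drugs)
  descr <- c("cmax", "tmax", "auc")
  rows <- list()
  for (drug in drugs) {
    sys0 <- build_system(physiology, drug)
    sim0 <- simulate_pbpk(sys0, plasma_spec, doses, times)
    d0 <- sim0$descriptors
    for (par in parameters) for (fold in folds) {
      res <- tryCatch({
        phys_d <- apply_perturbations(physiology, setNames(fold, par))
        sys_d <- if (resolve_af) build_system(phys_d, drug)
                 else .rebuild_frozen(sys0, phys_d)
        simulate_pbpk(sys_d, plasma_spec, doses, times)$descriptors
      }, error = function(e) e)
      failed <- inherits(res, "error")
      for (cp in compartments) for (ds in descr) {
        y_o <- d0[[ds]][d0$compartment == cp]
        y_d <- if (failed) NA_real_ else res[[ds]][res$compartment == cp]
        rows[[length(rows) + 1]] <- data.frame(
          drug = drug$name, parameter = par, fold = fold,
          compartment = cp, descriptor = ds, y_o = y_o, y_d = y_d,
          index = if (failed) NA_real_ else log2(y_d / y_o),
          status = if (failed) "failed" else "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Altered-CSF-dynamics scenario
#'
#' Scales the CSF volumes (`v_lv`, `v_tfv`, `v_cm`, `v_sas`) by
#' `folds["volume"]` and the CSF flow (`q_csf`) by `folds["flow"]`, keeps
#' the asymmetry factors at their physiological calibration, and simulates
#' the system under a shared plasma forcing (default: the packaged human
#' 1-compartment acetaminophen model, standing in for a fixed simple
#' plasma model that isolates the CSF parameters from plasma kinetics).
#'
#' @param physiology A [cns_physiology] (human by default usage).
#' @param drug A [cns_drug].
#' @param plasma_spec A [plasma_model_spec]; default packaged human
#'   1-compartment model.
#' @param doses List of [dose_event] objects.
#' @param folds Named vector `c(volume = , flow = )`, both positive.
#' @param times Simulation grid, min.
#' @return List of class `csf_scenario`: `label`, `sim` (scenario
#'   simulation), `sim_physiological`, `ecf_sas_ratio` (time series, `NA`
#'   where the SAS concentration is 0), and `deltas` (descriptor changes
#'   for ECF and SAS, scenario vs physiological).
#' @export
run_csf_scenarios <- function(physiology, drug,
                              plasma_spec = plasma_fixture("acetaminophen",
                                                           "human"),
                              doses, folds = c(volume = 1, flow = 1),
                              times = seq(0, 1440, by = 2)) {
  if (any(folds <= 0)) stop("folds must be positive", call. = FALSE)
  vol <- unname(folds[["volume"]])
  flo <- unname(folds[["flow"]])
  sys0 <- build_system(physiology, drug)
  sim0 <- simulate_pbpk(sys0, plasma_spec, doses, times)
  if (vol != 1 || flo != 1) {
    phys_d <- apply_perturbations(
      physiology, c(v_lv = vol, v_tfv = vol, v_cm = vol, v_sas = vol,
                    q_csf = flo))
    sim_d <- simulate_pbpk(.rebuild_frozen(sys0, phys_d), plasma_spec,
                           doses, times)
  } else {
    sim_d <- sim0
  }
  sas <- sim_d$conc["sas", ]
  ratio <- ifelse(sas > 0, sim_d$conc["ecf", ] / sas, NA_real_)
  deltas <- do.call(rbind, lapply(c("ecf", "sas"), function(cp) {
    a <- sim_d$descriptors[sim_d$descriptors$compartment == cp, ]
    b <- sim0$descriptors[sim0$descriptors$compartment == cp, ]
    data.frame(compartment = cp,
               cmax = a$cmax, cmax_rel = a$cmax / b$cmax,
               tmax = a$tmax, tmax_shift = a$tmax - b$tmax,
               auc = a$auc, auc_rel = a$auc / b$auc)
  }))
  structure(list(label = sprintf("volume x%g, flow x%g", vol, flo),
                 folds = c(volume = vol, flow = flo),
                 sim = sim_d, sim_physiological = sim0,
                 ecf_sas_ratio = ratio, deltas = deltas),
            class = "csf_scenario")
}

#' @export
print.csf_scenario <- function(x, ...) {
  cat("<csf_scenario>", x$label, "\n")
  print(x$deltas, row.names = FALSE)
  invisible(x)
}

#' Replicate simulation with nominal CNS physiology variability
#'
#' Applies a multiplicative log-normal perturbation with the stated
#' coefficient of variation to a whitelist of physiology parameters,
#' independently per replicate, and returns percentile bands of the
#' resulting concentration profiles.  The log-normal SD is
#' `sqrt(log(1 + (cv/100)^2))` so the realized CV matches the nominal one.
#'
#' @param physiology A [cns_physiology].
#' @param drug A [cns_drug].
#' @param plasma_spec A [plasma_model_spec].
#' @param doses List of [dose_event] objects.
#' @param cv Nominal percent CV (e.g. 30 or 50); 0 gives identical
#'   replicates.
#' @param n_reps Number of replicates.
#' @param seed Integer seed (deterministic output).
#' @param parameters Physiology parameters receiving variability; default
#'   barrier geometry and flows.
#' @param times Simulation grid, min.
#' @return List with `bands` (compartment, time_min, median, lo, hi),
#'   `cv`, `seed`.
#' @export
add_physiology_iiv <- function(physiology, drug, plasma_spec, doses,
                               cv, n_reps = 100, seed = 1,
                               parameters = c("q_cbf", "q_ecf", "q_csf",
                                              "sa_bbb", "sa_bcsfb_lv",
                                              "sa_bcsfb_tfv",
                                              "pore_radius_nm",
                                              "paracellular_fraction"),
                               times = seq(0, 720, by = 5)) {
  stopifnot(cv >= 0, n_reps >= 1)
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  sys0 <- build_system(physiology, drug)
  sims <- array(NA_real_, c(9, length(times), n_reps))
  withr_seed(seed, {
    for (r in seq_len(n_reps)) {
      folds <- setNames(exp(rnorm(length(parameters), 0, sdlog)), parameters)
      ## paracellular_fraction must stay in (0,1); the log-normal already
      ## keeps it positive, clamp the upper side defensively
      if ("paracellular_fraction" %in% parameters)
        folds["paracellular_fraction"] <-
          min(folds[["paracellular_fraction"]],
              0.99 / physiology$paracellular_fraction)
      phys_r <- apply_perturbations(physiology, folds)
      sims[, , r] <- simulate_pbpk(.rebuild_frozen(sys0, phys_r),
                                   plasma_spec, doses, times)$conc
    }
  })
  qs <- apply(sims, c(1, 2), quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE, type = 7)
  bands <- data.frame(
    compartment = rep(.cns_comps, each = length(times)),
    time_min = rep(times, 9),
    median = as.vector(t(qs[1, , ])),
    lo = as.vector(t(qs[2, , ])),
    hi = as.vector(t(qs[3, , ])))
  list(bands = bands, cv = cv, seed = seed, n_reps = n_reps)
}
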