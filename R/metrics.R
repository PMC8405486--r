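## Model-evaluation statistics and replicate-simulation (VPC) machinery.
##
## All fold-error statistics work on log10 prediction errors of
## time-matched medians: RA_drug = mean(log10(MedP/Obs)) within a drug and
## compartment, then %AFE = 100 * 10^mean(RA) across drugs (bias),
## %AAFE = 100 * 10^mean(|RA|) (typical-profile accuracy),
## %MARA = 100 * 10^mean(ARA) with ARA the within-drug mean absolute log
## error (spread of individuals around the median), and SMAPE the
## symmetric mean absolute percentage error bounded at 200%.

#' Validate an observed concentration dataset
#'
#' @param df Data frame with columns `drug`, `species`, `individual`,
#'   `compartment`, `time_min`, `conc` (unbound, ng/mL; must be positive
#'   since the metrics operate on logs).
#' @return The validated data frame with class `observed_dataset`.
#' @export
observed_dataset <- function(df) {
  need <- c("drug", "species", "individual", "compartment", "time_min", "conc")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("observed data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$conc) | df$conc <= 0))
    stop("observed concentrations must be positive (record ",
         which(!is.finite(df$conc) | df$conc <= 0)[1], ")", call. = FALSE)
  class(df) <- c("observed_dataset", "data.frame")
  df
}

#' Visual-predictive-check replicate simulation
#'
#' Runs `n_reps` replicate simulations of the joint plasma+CNS system with
#' sampled inter-individual (eta) and residual (epsilon) variability and
#' summarizes them as the median and empirical 2.5/97.5 percentile bands
#' per compartment and time point (percentiles by linear interpolation,
#' `stats::quantile` type 7).  When an observed dataset is supplied, each
#' observation is matched *exactly* (no interpolation) to its time point
#' and the time-matched replicate median `MedP` is returned per record.
#'
#' @param system A `cns_system`.
#' @param plasma_spec A [plasma_model_spec].
#' @param doses List of [dose_event] objects.
#' @param times Simulation grid, min; must contain all observed times.
#' @param n_reps Number of replicate simulations (>= 2), default 200.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param observed Optional [observed_dataset] to match.
#' @param residual Apply residual error to the replicate curves (default
#'   TRUE, matching an observation-level predictive check).
#' @return List of class `cns_vpc` with `bands` (data frame: compartment,
#'   time_min, median, lo, hi), and, when `observed` is given, `medp`
#'   (vector aligned with the observed rows).
#' @export
vpc <- function(system, plasma_spec, doses, times, n_reps = 200, seed = 1,
                observed = NULL, residual = TRUE) {
  stopifnot(n_reps >= 2)
  comps <- .cns_comps
  sims <- array(NA_real_, c(length(comps), length(times), n_reps),
                dimnames = list(comps, NULL, NULL))
  withr_seed(seed, {
    vars <- sample_variability(plasma_spec, n_reps, seed = seed + 1L)
    for (r in seq_len(n_reps)) {
      sim <- simulate_pbpk(system, plasma_spec, doses, times,
                           eta = vars[[r]]$eta)
      conc <- sim$conc
      if (residual) {
        for (cp in comps) conc[cp, ] <- vars[[r]]$residual(conc[cp, ])
      }
      sims[, , r] <- conc
    }
  })
  qs <- apply(sims, c(1, 2), quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE, type = 7)
  bands <- data.frame(
    compartment = rep(comps, each = length(times)),
    time_min = rep(times, length(comps)),
    median = as.vector(t(qs[1, , ])),
    lo = as.vector(t(qs[2, , ])),
    hi = as.vector(t(qs[3, , ])))
  out <- list(bands = bands, n_reps = n_reps, seed = seed)
  if (!is.null(observed)) {
    medp <- vapply(seq_len(nrow(observed)), function(i) {
      ci <- match(observed$compartment[i], comps)
      ti <- which(abs(times - observed$time_min[i]) < 1e-9)
      if (is.na(ci) || !length(ti))
        stop("observation ", i, " (", observed$compartment[i], " @ ",
             observed$time_min[i], " min) has no exactly matching ",
             "simulation time", call. = FALSE)
      median(sims[ci, ti[1], ])
    }, numeric(1))
    out$medp <- medp
  }
  class(out) <- "cns_vpc"
  out
}

#' Relative accuracy per drug and compartment
#'
#' `RA = mean(log10(MedP/Obs))` and `ARA = mean(|log10(MedP/Obs)|)` over
#' all observations (all individuals pooled) of a drug within a
#' compartment.
#'
#' @param observed An [observed_dataset].
#' @param medp Matched median predictions, aligned with the observed rows.
#' @return Data frame: `drug`, `compartment`, `ra`, `ara`, `m` (number of
#'   observations).
#' @export
relative_accuracy <- function(observed, medp) {
  if (length(medp) != nrow(observed))
    stop("`medp` must align with the observed rows", call. = FALSE)
  bad <- which(!is.finite(medp) | medp <= 0)
  if (length(bad))
    stop("non-positive matched prediction for record ", bad[1],
         " (", observed$drug[bad[1]], ", ", observed$compartment[bad[1]],
         " @ ", observed$time_min[bad[1]], " min)", call. = FALSE)
  le <- log10(medp / observed$conc)
  grp <- interaction(observed$drug, observed$compartment, drop = TRUE)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(drug = observed$drug[i][1],
               compartment = observed$compartment[i][1],
               ra = mean(le[i]), ara = mean(abs(le[i])), m = sum(i))
  }))
  rownames(out) <- NULL
  out
}

#' Fold-error summary across drugs
#'
#' Averages the per-drug relative accuracies within each compartment
#' (drugs weighted equally) and reports them on the percent fold scale:
#' `%AFE = 100 * 10^mean(RA)`, `%AAFE = 100 * 10^mean(|RA|)`,
#' `%MARA = 100 * 10^mean(ARA)`.
#'
#' @param ra A data frame from [relative_accuracy()].
#' @return Data frame: `compartment`, `n_drugs`, `pct_afe`, `pct_aafe`,
#'   `pct_mara`.
#' @export
fold_errors <- function(ra) {
  if (!nrow(ra)) stop("no relative-accuracy rows", call. = FALSE)
  out <- do.call(rbind, lapply(unique(ra$compartment), function(cp) {
    i <- ra$compartment == cp
    data.frame(compartment = cp, n_drugs = sum(i),
               pct_afe = 100 * 10^mean(ra$ra[i]),
               pct_aafe = 100 * 10^mean(abs(ra$ra[i])),
               pct_mara = 100 * 10^mean(ra$ara[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Symmetric mean absolute percentage error
#'
#' `SMAPE = (100/M) * sum(|2 (Obs - MedP) / (Obs + MedP)|)` per
#' compartment (all drugs and individuals pooled); bounded at 200%.
#'
#' @param observed An [observed_dataset].
#' @param medp Matched median predictions aligned with the observed rows.
#' @return Data frame: `compartment`, `smape_pct`.
#' @export
smape <- function(observed, medp) {
  if (length(medp) != nrow(observed))
    stop("`medp` must align with the observed rows", call. = FALSE)
  if (any(medp + observed$conc <= 0))
    stop("Obs + MedP must be positive", call. = FALSE)
  term <- abs(2 * (observed$conc - medp) / (observed$conc + medp))
  out <- do.call(rbind, lapply(unique(observed$compartment), function(cp) {
    i <- observed$compartment == cp
    data.frame(compartment = cp, smape_pct = 100 * mean(term[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' @param observed An [observed_dataset].
#' @param medp Matched median predictions.
#' @return List of class `evaluation_report` with `per_drug`
#'   (relative accuracies) and `per_compartment` (%AFE, %AAFE, %MARA,
#'   SMAPE).
#' @export
evaluate_predictions <- function(observed, medp) {
  ra <- relative_accuracy(observed, medp)
  fe <- fold_errors(ra)
  sm <- smape(observed, medp)
  per_comp <- merge(fe, sm, by = "compartment")
  structure(list(per_drug = ra, per_compartment = per_comp),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\nPer compartment:\n")
  print(x$per_compartment, row.names = FALSE)
  cat("Per drug:\n")
  print(x$per_drug, row.names = FALSE)
  invisible(x)
}
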