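## Simulation drivers and PK descriptors.

.new_cns_simulation <- function(times, conc, plasma, system) {
  desc <- do.call(rbind, lapply(rownames(conc), function(cp) {
    d <- pk_descriptors(conc[cp, ], times)
    data.frame(compartment = cp, cmax = d$cmax, tmax = d$tmax, auc = d$auc)
  }))
  structure(list(times = times, conc = conc, plasma = plasma,
                 descriptors = desc, drug = system$drug$name,
                 species = attr(system$physiology, "species")),
            class = "cns_simulation")
}

#' Simulate the CNS system driven by a plasma profile
#'
#' Integrates the linear CNS system exactly with piecewise matrix
#' exponentials (machine-precision propagation; no step-size tuning).
#' Returns unbound concentrations per compartment (the brain cell membrane
#' is reported as membrane-phase concentration).
#'
#' @param system A `cns_system` from [build_system()].
#' @param plasma Either a single number (constant unbound plasma
#'   concentration, ng/mL) or a data frame with `time_min` and
#'   `conc_unbound` covering the time grid (e.g. from [simulate_plasma()]);
#'   the profile is taken piecewise linear between its samples.
#' @param times Sorted time grid, min.
#' @param x0 Initial amounts (ng, length 9); default all zero.
#' @return A `cns_simulation`: times, a 9 x T unbound concentration matrix
#'   (ng/mL), the driving plasma profile, and per-compartment descriptors
#'   (`cmax`, `tmax`, `auc`).
#' @export
simulate_cns <- function(system, plasma, times, x0 = NULL) {
  stopifnot(inherits(system, "cns_system"))
  if (is.unsorted(times)) stop("`times` must be sorted", call. = FALSE)
  m <- cns_rate_matrix(system)
  x0 <- x0 %||% numeric(9)

  if (is.numeric(plasma) && length(plasma) == 1) {
    cp <- rep(plasma, length(times))
    x <- lti_simulate(m$A, x0, times,
                      rates = list(list(t0 = times[1] - 1,
                                        t1 = times[length(times)] + 1,
                                        b = m$b_unit * plasma)))
  } else {
    if (!all(c("time_min", "conc_unbound") %in% names(plasma)))
      stop("`plasma` must have columns time_min and conc_unbound",
           call. = FALSE)
    if (min(plasma$time_min) > times[1] ||
        max(plasma$time_min) < times[length(times)])
      stop("plasma profile does not cover the requested time grid",
           call. = FALSE)
    cp <- approx(plasma$time_min, plasma$conc_unbound, xout = times)$y
    x <- lti_simulate_pwlin(m$A, x0, times, m$b_unit %o% cp)
  }
  conc <- sweep(x, 1, m$volumes, "/") * m$fu_out
  conc[] <- pmax(conc, 0)
  .new_cns_simulation(times, conc, cp, system)
}

#' Simulate plasma and CNS jointly
#'
#' Builds the joint (plasma + CNS) linear system so the CNS sees the exact
#' continuous plasma forcing rather than a sampled profile.  The plasma
#' block is autonomous (the CNS does not feed back; cerebral uptake is a
#' negligible fraction of the systemic mass balance and the empirical
#' plasma model already describes the observed plasma data).
#'
#' @param system A `cns_system`.
#' @param plasma_spec A [plasma_model_spec].
#' @param doses List of [dose_event] objects.
#' @param times Sorted time grid, min.
#' @param eta Optional named eta vector for the plasma parameters.
#' @return A `cns_simulation` whose `plasma` element is the unbound plasma
#'   concentration profile.
#' @export
simulate_pbpk <- function(system, plasma_spec, doses, times, eta = NULL) {
  stopifnot(inherits(system, "cns_system"),
            inherits(plasma_spec, "plasma_model_spec"))
  spec <- .plasma_apply_eta(plasma_spec, eta)
  P <- .plasma_matrix(spec)
  np <- nrow(P)
  m <- cns_rate_matrix(system)

  A <- matrix(0, np + 9, np + 9)
  A[seq_len(np), seq_len(np)] <- P
  A[np + seq_len(9), np + seq_len(9)] <- m$A
  cen <- match("cen", rownames(P))
  # Q_CBF * fu_p * C_cen drives the microvessels
  A[np + seq_len(9), cen] <- m$b_unit * spec$fu_plasma / spec$v_cen

  inp <- .plasma_inputs(spec, doses, rownames(P))
  if (length(inp$rates))
    inp$rates <- lapply(inp$rates,
                        function(r) { r$b <- c(r$b, numeric(9)); r })
  x <- lti_simulate(A, numeric(np + 9), times,
                    boluses = inp$boluses, rates = inp$rates)

  cp_unbound <- pmax(x[cen, ] / spec$v_cen, 0) * spec$fu_plasma
  conc <- sweep(x[np + seq_len(9), , drop = FALSE], 1, m$volumes, "/") *
    m$fu_out
  conc[] <- pmax(conc, 0)
  rownames(conc) <- .cns_comps
  .new_cns_simulation(times, conc, cp_unbound, system)
}

#' Pharmacokinetic descriptors of a concentration-time series
#'
#' `C_max` is the maximum concentration, `T_max` the time of the *first*
#' maximum (tie-break rule), and `AUC` the trapezoidal area over the grid.
#'
#' @param conc Concentration vector (or a `cns_simulation`, in which case
#'   a per-compartment data frame is returned).
#' @param times Time grid matching `conc`.
#' @return List with `cmax`, `tmax`, `auc`, or a data frame for a
#'   simulation object.
#' @export
pk_descriptors <- function(conc, times = NULL) {
  if (inherits(conc, "cns_simulation")) return(conc$descriptors)
  if (length(conc) < 2 || length(conc) != length(times))
    stop("need >= 2 time points with matching concentrations", call. = FALSE)
  i <- which.max(conc)
  auc <- sum(diff(times) * (head(conc, -1) + tail(conc, -1)) / 2)
  list(cmax = conc[[i]], tmax = times[[i]], auc = auc)
}

#' Tidy data frame of a CNS simulation
#'
#' @param x A `cns_simulation`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `drug`, `compartment`, `time_min`,
#'   `conc_ng_per_ml`.
#' @export
as.data.frame.cns_simulation <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  comps <- rownames(x$conc)
  data.frame(
    drug = x$drug,
    compartment = rep(comps, each = length(x$times)),
    time_min = rep(x$times, length(comps)),
    conc_ng_per_ml = as.vector(t(x$conc)))
}

#' @export
print.cns_simulation <- function(x, ...) {
  cat(sprintf("<cns_simulation> %s (%s): %d compartments x %d times [%g, %g] min\n",
              x$drug, x$species, nrow(x$conc), length(x$times),
              min(x$times), max(x$times)))
  print(x$descriptors, row.names = FALSE)
  invisible(x)
}
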