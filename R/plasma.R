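## Empirical compartmental plasma models: the forcing function of the CNS
## system.  Parameters are fixed inputs (no estimation machinery);
## inter-individual variability (IIV) enters as p * exp(eta) per parameter
## and residual variability on the observation scale.

#' Construct an empirical plasma model specification
#'
#' A 1-3 compartment linear mammillary model with optional first-order
#' absorption.  Unused peripheral compartments carry zero `q`/`v`.
#'
#' @param cl_cen Central clearance, mL/min.
#' @param v_cen Central volume, mL.
#' @param q_cen_per1,q_cen_per2 Inter-compartmental clearances, mL/min.
#' @param v_per1,v_per2 Peripheral volumes, mL.
#' @param ka First-order absorption rate constant, 1/min (`NA` for iv-only
#'   models).
#' @param f_bio Bioavailability of absorbed doses.
#' @param iiv_cv Named vector of percent coefficients of variation for the
#'   exponential IIV model, names among `cl_cen`, `q_cen_per1`,
#'   `q_cen_per2`, `v_cen`, `v_per1`, `v_per2`, `ka`.
#' @param resid_prop_cv Proportional residual error, percent CV.
#' @param resid_add_sd Additive residual error SD, ng/mL.
#' @param fu_plasma Unbound plasma fraction used for the unbound output.
#' @param cv_transform How a percent CV maps to the normal SD omega of the
#'   exponential model: `"cv"` (omega = CV/100, default) or `"lognormal"`
#'   (omega = sqrt(log(1 + (CV/100)^2))).
#' @param label Optional drug/species label.
#' @return An object of class `plasma_model_spec`.
#' @export
plasma_model_spec <- function(cl_cen, v_cen, q_cen_per1 = 0, v_per1 = 0,
                              q_cen_per2 = 0, v_per2 = 0, ka = NA,
                              f_bio = 1, iiv_cv = numeric(0),
                              resid_prop_cv = 0, resid_add_sd = 0,
                              fu_plasma = 1,
                              cv_transform = c("cv", "lognormal"),
                              label = "") {
  cv_transform <- match.arg(cv_transform)
  if (cl_cen <= 0 || v_cen <= 0)
    stop("central clearance and volume must be positive", call. = FALSE)
  if ((q_cen_per1 > 0) != (v_per1 > 0) || (q_cen_per2 > 0) != (v_per2 > 0))
    stop("peripheral q and v must be both zero or both positive",
         call. = FALSE)
  if (length(iiv_cv) && any(iiv_cv < 0))
    stop("IIV %CV must be >= 0", call. = FALSE)
  n_cpt <- 1L + (v_per1 > 0) + (v_per2 > 0)
  structure(list(n_cpt = n_cpt, cl_cen = cl_cen, v_cen = v_cen,
                 q_cen_per1 = q_cen_per1, v_per1 = v_per1,
                 q_cen_per2 = q_cen_per2, v_per2 = v_per2,
                 ka = ka, f_bio = f_bio, iiv_cv = iiv_cv,
                 resid_prop_cv = resid_prop_cv, resid_add_sd = resid_add_sd,
                 fu_plasma = fu_plasma, cv_transform = cv_transform,
                 label = label),
            class = "plasma_model_spec")
}

#' Construct a dose event
#'
#' @param amount Dose amount, ng.
#' @param route `"iv-bolus"`, `"iv-infusion"`, or
#'   `"first-order-absorption"`.
#' @param time Start time, min.
#' @param duration Infusion duration, min (infusions only).
#' @return A `dose_event` list.
#' @export
dose_event <- function(amount, route = c("iv-bolus", "iv-infusion",
                                         "first-order-absorption"),
                       time = 0, duration = NULL) {
  route <- match.arg(route)
  if (amount <= 0) stop("dose amount must be positive", call. = FALSE)
  if (route == "iv-infusion" && (is.null(duration) || duration <= 0))
    stop("infusions need a positive duration", call. = FALSE)
  structure(list(amount = amount, route = route, time = time,
                 duration = duration), class = "dose_event")
}

## Apply an eta vector to the structural parameters: p -> p * exp(eta_p).
.plasma_apply_eta <- function(spec, eta) {
  if (is.null(eta) || !length(eta)) return(spec)
  for (nm in names(eta)) {
    if (!nm %in% c("cl_cen", "q_cen_per1", "q_cen_per2",
                   "v_cen", "v_per1", "v_per2", "ka"))
      stop("unknown eta parameter `", nm, "`", call. = FALSE)
    spec[[nm]] <- spec[[nm]] * exp(eta[[nm]])
  }
  spec
}

## Rate matrix of the plasma system in amounts.  State order:
## depot (if ka), central, per1 (if used), per2 (if used).
.plasma_matrix <- function(spec) {
  states <- c(if (is.finite(spec$ka)) "depot", "cen",
              if (spec$v_per1 > 0) "per1", if (spec$v_per2 > 0) "per2")
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  i <- function(s) match(s, states)
  cen <- i("cen")
  A[cen, cen] <- -spec$cl_cen / spec$v_cen
  if (is.finite(spec$ka)) {
    A[i("depot"), i("depot")] <- -spec$ka
    A[cen, i("depot")] <- spec$ka * spec$f_bio
  }
  if (spec$v_per1 > 0) {
    p <- i("per1")
    A[cen, cen] <- A[cen, cen] - spec$q_cen_per1 / spec$v_cen
    A[p, cen] <- spec$q_cen_per1 / spec$v_cen
    A[cen, p] <- spec$q_cen_per1 / spec$v_per1
    A[p, p] <- -spec$q_cen_per1 / spec$v_per1
  }
  if (spec$v_per2 > 0) {
    p <- i("per2")
    A[cen, cen] <- A[cen, cen] - spec$q_cen_per2 / spec$v_cen
    A[p, cen] <- spec$q_cen_per2 / spec$v_cen
    A[cen, p] <- spec$q_cen_per2 / spec$v_per2
    A[p, p] <- -spec$q_cen_per2 / spec$v_per2
  }
  A
}

## Translate dose events into boluses/rates on a plasma state layout.
.plasma_inputs <- function(spec, doses, states) {
  boluses <- data.frame(time = numeric(0), state = integer(0),
                        amount = numeric(0))
  rates <- list()
  for (d in doses) {
    if (d$route == "iv-bolus") {
      boluses <- rbind(boluses, data.frame(time = d$time,
                                           state = match("cen", states),
                                           amount = d$amount))
    } else if (d$route == "iv-infusion") {
      b <- numeric(length(states))
      b[match("cen", states)] <- d$amount / d$duration
      rates[[length(rates) + 1]] <- list(t0 = d$time, t1 = d$time + d$duration,
                                         b = b)
    } else {  # first-order absorption
      if (!is.finite(spec$ka))
        stop("absorption dose given but the plasma spec has no `ka`",
             call. = FALSE)
      boluses <- rbind(boluses, data.frame(time = d$time,
                                           state = match("depot", states),
                                           amount = d$amount))
    }
  }
  list(boluses = boluses, rates = rates)
}

#' Simulate the empirical plasma model
#'
#' Solves the linear mammillary system exactly (piecewise matrix
#' exponential).  With an `eta` vector each structural parameter `p`
#' becomes `p * exp(eta_p)`; `eta = NULL` (or all zeros) gives the typical
#' profile.
#'
#' @param spec A [plasma_model_spec].
#' @param doses List of [dose_event] objects.
#' @param times Sorted non-negative time grid, min.
#' @param eta Optional named eta vector.
#' @return Data frame with `time_min`, `conc` (total, ng/mL) and
#'   `conc_unbound` (ng/mL).
#' @export
simulate_plasma <- function(spec, doses, times, eta = NULL) {
  stopifnot(inherits(spec, "plasma_model_spec"))
  if (is.unsorted(times) || any(times < 0))
    stop("`times` must be sorted and non-negative", call. = FALSE)
  spec <- .plasma_apply_eta(spec, eta)
  A <- .plasma_matrix(spec)
  states <- rownames(A)
  inp <- .plasma_inputs(spec, doses, states)
  x <- lti_simulate(A, numeric(nrow(A)), times,
                    boluses = inp$boluses, rates = inp$rates)
  conc <- x[match("cen", states), ] / spec$v_cen
  conc <- pmax(conc, 0)
  data.frame(time_min = times, conc = conc,
             conc_unbound = conc * spec$fu_plasma)
}

#' Sample inter-individual and residual variability
#'
#' Draws one eta vector per individual (`eta_p ~ Normal(0, omega_p^2)` for
#' every parameter with a nonzero percent CV) plus a residual-draw function
#' applying `obs = pred * (1 + eps_prop) + eps_add`.  Deterministic given
#' `seed`; the residual functions use the ambient RNG stream, so callers
#' that need reproducible residuals should invoke them in a fixed order
#' under their own seed.
#'
#' @param spec A [plasma_model_spec].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return List of `n` elements, each `list(eta, residual)`.
#' @export
sample_variability <- function(spec, n, seed) {
  stopifnot(n >= 1)
  omega <- .iiv_omega(spec)
  sd_prop <- spec$resid_prop_cv / 100
  sd_add <- spec$resid_add_sd
  out <- withr_seed(seed, {
    lapply(seq_len(n), function(i) {
      eta <- setNames(rnorm(length(omega), 0, omega), names(omega))
      list(eta = eta,
           residual = function(pred) {
             pred * (1 + rnorm(length(pred), 0, sd_prop)) +
               rnorm(length(pred), 0, sd_add)
           })
    })
  })
  out
}

.iiv_omega <- function(spec) {
  cv <- spec$iiv_cv[spec$iiv_cv > 0]
  if (!length(cv)) return(setNames(numeric(0), character(0)))
  if (spec$cv_transform == "cv") cv / 100 else sqrt(log(1 + (cv / 100)^2))
}

## Run `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Packaged empirical plasma model fixtures
#'
#' @param drug Drug name.
#' @param species `"rat"` or `"human"`.
#' @return A [plasma_model_spec].
#' @export
plasma_fixture <- function(drug, species = c("rat", "human")) {
  species <- match.arg(species)
  path <- system.file("extdata", "plasma_models.json", package = "cnspbpk")
  raw <- jsonlite::read_json(path)
  hit <- NULL
  for (m in raw$models)
    if (identical(m$drug, drug) && identical(m$species, species)) hit <- m
  if (is.null(hit)) {
    avail <- vapply(raw$models,
                    function(m) paste0(m$species, "/", m$drug), "")
    stop("no packaged plasma model for ", species, "/", drug,
         "; available: ", paste(avail, collapse = ", "), call. = FALSE)
  }
  plasma_model_spec(cl_cen = hit$cl_cen, v_cen = hit$v_cen,
                    q_cen_per1 = hit$q_cen_per1 %||% 0,
                    v_per1 = hit$v_per1 %||% 0,
                    q_cen_per2 = hit$q_cen_per2 %||% 0,
                    v_per2 = hit$v_per2 %||% 0,
                    ka = hit$ka %||% NA, f_bio = hit$f_bio %||% 1,
                    iiv_cv = unlist(hit$iiv_cv),
                    resid_prop_cv = hit$resid_prop_cv %||% 0,
                    resid_add_sd = hit$resid_add_sd %||% 0,
                    fu_plasma = hit$fu_plasma %||% 1,
                    label = paste(species, drug))
}
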