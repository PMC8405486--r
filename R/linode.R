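## Linear time-invariant ODE machinery.
##
## Every model in this package (empirical plasma model, CNS model, and the
## joint plasma+CNS system) is a linear ODE  dx/dt = A x + b(t)  with b(t)
## piecewise constant (infusions) or piecewise linear (a sampled forcing
## profile).  Such systems are propagated *exactly* between breakpoints with
## a matrix exponential of an augmented system, which is unconditionally
## stable no matter how stiff the rate matrix is.

.expm <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M, sparse = FALSE)))
}

## Steady state of dx/dt = A x + b  (A must be a Hurwitz / non-singular
## rate matrix, which holds whenever every compartment has an outflow path).
lti_steady_state <- function(A, b) {
  ## row equilibration: rate constants span many orders of magnitude when
  ## asymmetry factors are probed at extreme bracket values
  r <- apply(abs(A), 1, max)
  r[r == 0] <- 1
  as.vector(solve(A / r, -b / r))
}

## Propagate dx/dt = A x + b(t) over a sorted time grid.
##
## boluses: data.frame(time, state, amount) -- instantaneous additions,
##   applied at their time point before the state is recorded there.
## rates: list of list(t0, t1, b) -- constant input vectors active on
##   [t0, t1).  Overlapping rates add.
## Returns a (nrow(A) x length(times)) matrix of states.
lti_simulate <- function(A, x0, times, boluses = NULL, rates = NULL) {
  n <- nrow(A)
  stopifnot(length(x0) == n, !is.unsorted(times))
  ev <- numeric(0)
  if (!is.null(boluses) && nrow(boluses)) ev <- c(ev, boluses$time)
  if (length(rates)) ev <- c(ev, unlist(lapply(rates, function(r) c(r$t0, r$t1))))
  ev <- ev[ev > times[1] & ev < times[length(times)]]
  path <- sort(unique(c(times, ev)))

  active_b <- function(tmid) {
    b <- numeric(n)
    for (r in rates) if (tmid >= r$t0 && tmid < r$t1) b <- b + r$b
    b
  }
  apply_bolus <- function(x, tt) {
    if (is.null(boluses) || !nrow(boluses)) return(x)
    hit <- abs(boluses$time - tt) < 1e-9
    if (any(hit)) {
      for (i in which(hit)) x[boluses$state[i]] <- x[boluses$state[i]] + boluses$amount[i]
    }
    x
  }

  cache <- new.env(parent = emptyenv())
  step <- function(x, dt, b) {
    key <- paste(format(dt, digits = 17), paste(format(b, digits = 17), collapse = ","))
    E <- cache[[key]]
    if (is.null(E)) {
      if (any(b != 0)) {
        E <- .expm(rbind(cbind(A, b), 0) * dt)
      } else {
        E <- .expm(A * dt)
      }
      cache[[key]] <- E
    }
    if (ncol(E) > n) (E %*% c(x, 1))[seq_len(n)] else as.vector(E %*% x)
  }

  out <- matrix(NA_real_, n, length(times),
                dimnames = list(rownames(A), NULL))
  x <- apply_bolus(x0, path[1])
  oi <- 1L
  if (path[1] == times[oi]) { out[, oi] <- x; oi <- oi + 1L }
  for (k in seq_along(path)[-1]) {
    dt <- path[k] - path[k - 1]
    if (dt > 0) {
      x <- step(x, dt, active_b((path[k - 1] + path[k]) / 2))
    }
    x <- apply_bolus(x, path[k])
    if (oi <= length(times) && path[k] == times[oi]) { out[, oi] <- x; oi <- oi + 1L }
  }
  out
}

## Propagate dx/dt = A x + u(t) where u(t) is linear between grid points
## (u given column-wise at `times`).  Used when the CNS model is driven by
## an externally sampled plasma profile rather than the joint system.
lti_simulate_pwlin <- function(A, x0, times, input_mat) {
  n <- nrow(A)
  m <- length(times)
  stopifnot(nrow(input_mat) == n, ncol(input_mat) == m)
  out <- matrix(NA_real_, n, m, dimnames = list(rownames(A), NULL))
  x <- x0
  out[, 1] <- x
  for (k in seq_len(m)[-1]) {
    dt <- times[k] - times[k - 1]
    if (dt == 0) { out[, k] <- x; next }
    u0 <- input_mat[, k - 1]
    c1 <- (input_mat[, k] - u0) / dt
    Maug <- rbind(cbind(A, u0, c1), matrix(0, 2, n + 2))
    Maug[n + 2, n + 1] <- 1  # local clock: d(t)/dt = 1
    z <- .expm(Maug * dt) %*% c(x, 1, 0)
    x <- z[seq_len(n)]
    out[, k] <- x
  }
  out
}
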