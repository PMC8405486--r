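neutral_unit <- function(kp = 1) {
  cns_drug("probe", mw = 250, logp = 0.5,
           kpuu = c(ecf = kp, lv = kp, cm = kp))
}

test_that("build_system computes neutral fractions per compartment", {
  sys <- build_system(rat_phys, neutral_unit())
  expect_equal(unname(sys$phf), rep(1, 9))  # no ionizable groups
  base <- cns_drug("b", mw = 250, charge_class = "base", pkb = 9,
                   logp = 0.5, kpuu = c(ecf = 1, lv = 1, cm = 1))
  sysb <- build_system(rat_phys, base)
  expect_lt(sysb$phf[["lys"]], sysb$phf[["icf"]])     # acidic lysosome
  expect_lt(sysb$phf[["icf"]], sysb$phf[["ecf"]])
  expect_error(build_system(rat_phys, neutral_unit(), af_mode = "provided"),
               "af")
})

test_that("paracellular clearance shows pore-size limits and monotonicity", {
  d <- drug_fixture("morphine", "rat")
  # enormous pore: hindrance ~ 1, clearance ~ free-diffusion value
  wide <- apply_perturbations(rat_phys, c(pore_radius_nm = 1e6))
  free <- aqueous_diffusivity(d$mw) * rat_phys$sa_bbb *
    rat_phys$paracellular_fraction / (rat_phys$paracellular_length_um * 1e-4)
  expect_equal(paracellular_clearance(wide, d, "bbb"), free,
               tolerance = 1e-3)
  # steric exclusion: molecule larger than the pore
  tiny <- apply_perturbations(rat_phys, c(pore_radius_nm = 0.05))
  expect_equal(paracellular_clearance(tiny, d, "bbb"), 0)
  # strictly decreasing on a pore-radius grid (brute force)
  cls <- vapply(seq(2, 0.55, by = -0.05), function(r) {
    p <- apply_perturbations(rat_phys, c(pore_radius_nm = r / 0.9))
    paracellular_clearance(p, d, "bbb")
  }, numeric(1))
  expect_true(all(diff(cls) < 0))
})

test_that("asymmetry-factor scenario logic follows the Kp_uu branch rules", {
  # all targets 1: every AF is exactly 1
  sys <- build_system(rat_phys, neutral_unit(1))
  for (b in c("bbb", "bcsfb_lv", "bcsfb_tfv")) {
    expect_identical(sys$barriers[[b]]$af_in, 1)
    expect_identical(sys$barriers[[b]]$af_ef, 1)
  }
  # Kp_uu < 1 leaves AF_in at 1, Kp_uu > 1 leaves AF_ef at 1
  lo <- build_system(rat_phys, neutral_unit(0.4))
  expect_identical(lo$barriers$bbb$af_in, 1)
  expect_gt(lo$barriers$bbb$af_ef, 1)
  hi <- build_system(rat_phys, neutral_unit(1.8))
  expect_identical(hi$barriers$bbb$af_ef, 1)
  expect_gt(hi$barriers$bbb$af_in, 1)
})

test_that("reduced symmetric single-barrier system gives AF_ef = 2 at Kp_uu 0.5", {
  # kill bulk flows and make ECF pH equal plasma pH so passive transport is
  # symmetric; the steady-state balance then forces Cl_in/Cl_out = 1/AF_ef
  p <- apply_perturbations(rat_phys, c(q_ecf = 1e-10, q_csf = 1e-10))
  p$ph_ecf <- p$ph_plasma
  p$ph_csf <- p$ph_plasma
  sys <- build_system(p, neutral_unit(0.5))
  expect_equal(sys$barriers$bbb$af_ef, 2, tolerance = 1e-6)
})

test_that("solved systems reproduce their Kp_uu targets at steady state", {
  qnd <- drug_fixture("quinidine", "rat")
  sys <- build_system(rat_phys, qnd)
  cu <- cns_steady_state(sys, cu_plasma = 1)
  expect_equal(unname(cu[["ecf"]]), 1.5, tolerance = 1e-6)
  expect_equal(unname(cu[["lv"]]), 1.5, tolerance = 1e-6)
  expect_equal(unname(cu[["cm"]]), 1.5, tolerance = 1e-6)
  # and linearly in the plasma level
  cu2 <- cns_steady_state(sys, cu_plasma = 7)
  expect_equal(unname(cu2[["ecf"]]), 7 * 1.5, tolerance = 1e-6)
})

test_that("unreachable Kp_uu raises a diagnostic error", {
  # a target this close to 1 cannot be met with AF >= 1 when bulk washout
  # already pushes the passive steady state below it at this tiny barrier
  p <- apply_perturbations(rat_phys, c(sa_bcsfb_lv = 1e-6))
  expect_error(build_system(p, neutral_unit(0.999)), "unreachable")
})

test_that("interspecies AF scaling divides and clamps", {
  expect_equal(scale_af_interspecies(8, 8), 1)
  expect_equal(scale_af_interspecies(16, 8), 2)
  expect_warning(out <- scale_af_interspecies(4, 8), "clamp")
  expect_equal(out, 1)
  expect_error(scale_af_interspecies(4, -1), "positive")
})

test_that("simulation respects nullity, linearity and convergence", {
  sys <- build_system(rat_phys, drug_fixture("phenytoin", "rat"))
  times <- seq(0, 600, by = 10)
  z <- simulate_cns(sys, 0, times)
  expect_true(all(z$conc == 0))

  s1 <- simulate_cns(sys, 1, times)
  s2 <- simulate_cns(sys, 2, times)
  expect_equal(s2$conc, 2 * s1$conc, tolerance = 1e-10)
  expect_true(all(s1$conc >= 0))

  # constant plasma: ECF converges to the steady-state linear solve
  long <- simulate_cns(sys, 1, c(0, 5000))
  want <- cns_steady_state(sys, 1)
  expect_equal(unname(long$conc["ecf", 2]), want[["ecf"]], tolerance = 1e-4)
  expect_equal(unname(long$conc["ecf", 2]), 0.26, tolerance = 1e-3)
})

test_that("mass is conserved up to the boundary fluxes", {
  # augment the system with exact cumulative boundary-flux integrators:
  # d(cum_in)/dt = Q_CBF * Cu_p, d(cum_out)/dt = venous return + CSF
  # absorption; then total(t) - total(0) must equal cum_in - cum_out to
  # propagation precision over any interval
  d <- drug_fixture("acetaminophen", "rat")
  sys <- build_system(rat_phys, d)
  m <- cns_rate_matrix(sys)
  q_out <- rat_phys$q_csf + rat_phys$q_ecf
  Aaug <- rbind(cbind(m$A, 0, 0), 0, 0)
  Aaug[10, 1] <- rat_phys$q_cbf / rat_phys$v_mv     # venous return from MV
  Aaug[10, 9] <- q_out / rat_phys$v_sas             # CSF absorption from SAS
  baug <- c(m$b_unit, 0, rat_phys$q_cbf)            # cum_in under Cu_p = 1
  times <- seq(0, 200, by = 10)
  x <- cnspbpk:::lti_simulate(
    Aaug, numeric(11), times,
    rates = list(list(t0 = -1, t1 = 1e9, b = baug)))
  total <- colSums(x[1:9, , drop = FALSE])
  balance <- x[11, ] - x[10, ]
  expect_equal(unname(total - total[1]), unname(balance - balance[1]),
               tolerance = 1e-9)
})

test_that("joint plasma+CNS simulation agrees with profile-driven CNS", {
  # a slowly varying forcing keeps the piecewise-linear resampling error
  # of the profile-driven route far below the comparison tolerance
  d <- drug_fixture("raclopride", "rat")
  spec <- plasma_model_spec(cl_cen = 1, v_cen = 100, label = "slow 1-cpt")
  sys <- build_system(rat_phys, d)
  doses <- list(dose_event(1e6, "iv-bolus"))
  times <- seq(0, 360, by = 1)
  joint <- simulate_pbpk(sys, spec, doses, times)
  prof <- simulate_plasma(spec, doses, times)
  driven <- simulate_cns(sys, prof, times)
  expect_equal(driven$conc["ecf", ], joint$conc["ecf", ], tolerance = 1e-4)
  expect_equal(joint$plasma, prof$conc_unbound, tolerance = 1e-10)
})

test_that("PK descriptors handle constant, triangular and monotone profiles", {
  tt <- seq(0, 10, by = 1)
  d <- pk_descriptors(rep(3, 11), tt)
  expect_equal(d$cmax, 3); expect_equal(d$tmax, 0); expect_equal(d$auc, 30)

  tri <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  d <- pk_descriptors(tri, tt)
  expect_equal(d$cmax, 5); expect_equal(d$tmax, 5)
  expect_equal(d$auc, 0.5 * 10 * 5)

  dec <- exp(-tt)
  d <- pk_descriptors(dec, tt)
  expect_equal(d$tmax, 0)   # first-maximum tie-break
  expect_error(pk_descriptors(3, 0), ">= 2")
})
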