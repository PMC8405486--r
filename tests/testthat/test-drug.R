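test_that("neutral fractions follow the adapted Henderson-Hasselbalch forms", {
  inert <- cns_drug("inert", mw = 200, logp = 1)
  for (ph in c(1, 5, 7.4, 14))
    expect_equal(compute_phf(inert, ph)$phf, 1)

  acid <- cns_drug("acid", mw = 200, charge_class = "acid", pka = 6.5,
                   logp = 1)
  expect_equal(compute_phf(acid, 6.5)$phf_acidic, 0.5)  # symmetry point

  # acetaminophen acidic group at pH 7.4
  apap <- drug_fixture("acetaminophen", "rat")
  expect_equal(compute_phf(apap, 7.4)$phf_acidic,
               1 / (1 + 10^(7.4 - 9.46)), tolerance = 1e-12)
  expect_equal(compute_phf(apap, 7.4)$phf_acidic, 0.99136, tolerance = 1e-4)

  # morphine basic group at pH 7.4
  mor <- drug_fixture("morphine", "rat")
  expect_equal(compute_phf(mor, 7.4)$phf_basic,
               1 / (1 + 10^(9.12 - 7.4)), tolerance = 1e-12)
  expect_equal(compute_phf(mor, 7.4)$phf_basic, 0.01869, tolerance = 1e-3)

  expect_error(compute_phf(apap, 15), "1, 14")
})

test_that("PHF monotonicity and composition properties hold", {
  ph_grid <- seq(2, 12, by = 0.25)
  acid <- cns_drug("a", mw = 200, charge_class = "acid", pka = 5, logp = 0)
  base <- cns_drug("b", mw = 200, charge_class = "base", pkb = 9, logp = 0)
  both <- cns_drug("z", mw = 347.24, charge_class = "amphoteric",
                   pka = 5.31, pkb = 9.32, logp = 3.38)
  expect_true(all(diff(compute_phf(acid, ph_grid)$phf) < 0))
  expect_true(all(diff(compute_phf(base, ph_grid)$phf) > 0))
  amp <- compute_phf(both, ph_grid)
  expect_true(all(amp$phf <= pmin(amp$phf_acidic, amp$phf_basic) + 1e-15))
  expect_equal(amp$phf, amp$phf_acidic * amp$phf_basic)
  # species fractions conserve: neutral + charged = 1 per group
  expect_equal(amp$phf_acidic + (1 - amp$phf_acidic), rep(1, length(ph_grid)))
})

test_that("partitioning and diffusivity relations evaluate correctly", {
  expect_equal(octanol_water_partition(0), 1)
  expect_equal(octanol_water_partition(2.47), 295.1, tolerance = 1e-3)
  expect_equal(octanol_water_partition(-1.85), 0.01413, tolerance = 1e-3)
  expect_error(octanol_water_partition(NaN), "finite")

  cfg <- transport_config()
  expect_equal(aqueous_diffusivity(cfg$mw_ref, cfg), cfg$d_ref)
  expect_equal(aqueous_diffusivity(8 * 123, cfg),
               aqueous_diffusivity(123, cfg) / 2)   # cube-root scaling
  expect_error(aqueous_diffusivity(0), "positive")
  mws <- seq(100, 600, by = 50)
  expect_true(all(diff(aqueous_diffusivity(mws)) < 0))
})

test_that("transmembrane permeability is log-linear in lipophilicity", {
  cfg <- transport_config()
  d1 <- cns_drug("x", mw = 300, logp = 1, kpuu = c(ecf=1, lv=1, cm=1))
  d2 <- cns_drug("y", mw = 300, logp = 1 + 1 / cfg$perm_a,
                 kpuu = c(ecf=1, lv=1, cm=1))
  expect_equal(transmembrane_permeability(d2, cfg) /
                 transmembrane_permeability(d1, cfg), 10)
  mtx <- drug_fixture("methotrexate", "rat")
  qnd <- drug_fixture("quinidine", "rat")
  expect_lt(transmembrane_permeability(mtx), transmembrane_permeability(qnd))
  flat <- transport_config(perm_a = 0, perm_b = -4, perm_c = 0)
  expect_equal(transmembrane_permeability(mtx, flat), 1e-4)
  expect_equal(transmembrane_permeability(qnd, flat), 1e-4)
})

test_that("membrane binding clearances encode the partition coefficient", {
  p <- rat_phys
  d0 <- cns_drug("n", mw = 300, logp = 0, kpuu = c(ecf=1, lv=1, cm=1))
  b0 <- build_membrane_binding(d0, p)
  expect_equal(b0$cl_wo, b0$cl_ow)
  d2 <- cns_drug("l", mw = 300, logp = 2, kpuu = c(ecf=1, lv=1, cm=1))
  b2 <- build_membrane_binding(d2, p)
  expect_equal(b2$cl_ow, b2$cl_wo / 100)
  expect_error(build_membrane_binding(d2, p, kinetic_scale = 0), "positive")
  for (lp in c(-2, -0.3, 1.7, 4)) {
    d <- cns_drug("r", mw = 250, logp = lp, kpuu = c(ecf=1, lv=1, cm=1))
    b <- build_membrane_binding(d, p)
    expect_equal(b$cl_wo / b$cl_ow, 10^lp)
  }
  # two-pool equilibrium: aqueous/membrane system settles at P_oct-water
  b <- build_membrane_binding(d2, p, kinetic_scale = 1)
  vw <- 1; vm <- 0.2
  A <- matrix(c(-b$cl_wo / vw, b$cl_ow / vm,
                b$cl_wo / vw, -b$cl_ow / vm), 2, 2, byrow = TRUE)
  x <- cnspbpk:::lti_simulate(A, c(10, 0), c(0, 5000))
  ratio <- (x[2, 2] / vm) / (x[1, 2] / vw)
  expect_equal(ratio, 100, tolerance = 1e-6)
})

test_that("drug fixtures expose all twelve drugs and dose variants", {
  drugs <- suppressMessages(drug_fixture(population = "rat"))
  expect_length(drugs, 12)
  expect_setequal(
    names(drugs),
    c("acetaminophen", "atenolol", "indomethacin", "methotrexate",
      "morphine", "oxycodone", "paliperidone", "phenytoin", "quinidine",
      "raclopride", "remoxipride", "risperidone"))
  m1 <- drug_fixture("morphine", "rat", dose_group = "4mg/kg")
  m2 <- drug_fixture("morphine", "rat", dose_group = "10-40mg/kg")
  expect_equal(unname(m1$kpuu["ecf"]), 0.38)
  expect_equal(unname(m2$kpuu["ecf"]), 0.23)
  ind <- drug_fixture("indomethacin", "human")
  expect_equal(ind$fu_csf, 0.47)
  expect_error(drug_fixture("aspirin"), "available")
})
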