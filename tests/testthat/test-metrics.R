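flat_obs <- function(conc, n = 4, drug = "d1", compartment = "ecf") {
  observed_dataset(data.frame(
    drug = drug, species = "rat", individual = seq_len(n),
    compartment = compartment, time_min = 10 * seq_len(n), conc = conc))
}

test_that("relative accuracy matches hand calculations", {
  obs <- flat_obs(rep(5, 4))
  ra <- relative_accuracy(obs, rep(5, 4))
  expect_equal(ra$ra, 0)
  expect_equal(ra$ara, 0)
  expect_equal(ra$m, 4)

  ra2 <- relative_accuracy(obs, rep(10, 4))      # uniform 2x over
  expect_equal(ra2$ra, log10(2), tolerance = 1e-12)
  expect_equal(ra2$ara, log10(2), tolerance = 1e-12)

  obs2 <- flat_obs(c(5, 5), n = 2)
  ra3 <- relative_accuracy(obs2, c(10, 2.5))     # 2x over and 2x under
  expect_equal(ra3$ra, 0, tolerance = 1e-12)
  expect_equal(ra3$ara, log10(2), tolerance = 1e-12)

  expect_error(relative_accuracy(obs, c(1, 2, -1, 4)), "non-positive")
  expect_error(relative_accuracy(obs, 1:3), "align")
})

test_that("fold errors aggregate per-drug accuracies as printed", {
  ra0 <- data.frame(drug = c("a", "b"), compartment = "ecf",
                    ra = c(0, 0), ara = c(0, 0), m = c(3, 3))
  fe <- fold_errors(ra0)
  expect_equal(fe$pct_afe, 100)
  expect_equal(fe$pct_aafe, 100)
  expect_equal(fe$pct_mara, 100)

  ra1 <- data.frame(drug = "a", compartment = "ecf",
                    ra = log10(2), ara = log10(2), m = 5)
  fe1 <- fold_errors(ra1)
  expect_equal(fe1$pct_afe, 200, tolerance = 1e-12)
  expect_equal(fe1$pct_aafe, 200, tolerance = 1e-12)
  expect_equal(fe1$pct_mara, 200, tolerance = 1e-12)

  ra2 <- data.frame(drug = c("a", "b"), compartment = "ecf",
                    ra = c(log10(2), -log10(2)),
                    ara = c(log10(2), log10(2)), m = c(5, 5))
  fe2 <- fold_errors(ra2)
  expect_equal(fe2$pct_afe, 100, tolerance = 1e-12)   # bias cancels
  expect_equal(fe2$pct_aafe, 200, tolerance = 1e-12)  # spread does not
  expect_error(fold_errors(ra0[0, ]), "rows")
})

test_that("SMAPE matches its definition and bounds", {
  obs <- flat_obs(rep(3, 4))
  expect_equal(smape(obs, rep(3, 4))$smape_pct, 0)
  obs1 <- flat_obs(3, n = 1)
  expect_equal(smape(obs1, 1)$smape_pct, 100)    # |2*2/4| * 100
  expect_equal(smape(obs1, 1e-12)$smape_pct, 200, tolerance = 1e-9)
})

test_that("metric invariances: scaling, antisymmetry, nested means", {
  set.seed(31)
  for (i in 1:10) {
    d <- random_obs_dataset()
    ra <- relative_accuracy(d$obs, d$medp)
    fe <- fold_errors(ra)
    sm <- smape(d$obs, d$medp)

    # scale invariance
    obs_s <- d$obs; obs_s$conc <- obs_s$conc * 37.5
    ra_s <- relative_accuracy(obs_s, d$medp * 37.5)
    expect_equal(ra_s$ra, ra$ra, tolerance = 1e-12)
    expect_equal(smape(obs_s, d$medp * 37.5)$smape_pct, sm$smape_pct,
                 tolerance = 1e-12)

    # antisymmetry: swap obs and pred
    obs_sw <- d$obs; obs_sw$conc <- d$medp
    ra_sw <- relative_accuracy(obs_sw, d$obs$conc)
    expect_equal(ra_sw$ra, -ra$ra, tolerance = 1e-12)
    expect_equal(ra_sw$ara, ra$ara, tolerance = 1e-12)
    expect_equal(smape(obs_sw, d$obs$conc)$smape_pct, sm$smape_pct,
                 tolerance = 1e-12)

    # %MARA >= %AAFE >= %AFE (Jensen on nested absolute means)
    expect_true(all(fe$pct_mara >= fe$pct_aafe - 1e-9))
    expect_true(all(fe$pct_aafe >= fe$pct_afe - 1e-9))
  }
})

test_that("statistics agree with the naive-loop reference", {
  set.seed(77)
  for (i in 1:20) {
    d <- random_obs_dataset(n_drugs = sample(1:4, 1),
                            n_comp = sample(1:3, 1),
                            n_obs = sample(3:10, 1))
    ra <- relative_accuracy(d$obs, d$medp)
    fe <- merge(fold_errors(ra), smape(d$obs, d$medp), by = "compartment")
    want <- oracle_metrics(d$obs, d$medp)
    for (cp in names(want)) {
      got <- fe[fe$compartment == cp, ]
      for (stat in c("pct_afe", "pct_aafe", "pct_mara", "smape_pct"))
        expect_equal(got[[stat]], unname(want[[cp]][stat]),
                     tolerance = 1e-12, info = paste(cp, stat))
    }
  }
})

test_that("vpc matches observations exactly in time and is seeded", {
  sys <- build_system(rat_phys, drug_fixture("atenolol", "rat"))
  spec <- plasma_fixture("atenolol", "rat")
  doses <- list(dose_event(1e6, "iv-bolus"))
  times <- seq(0, 120, by = 10)
  obs <- flat_obs(c(1, 1, 1), n = 3)
  obs$time_min <- c(10, 20, 35)   # 35 is not on the grid
  expect_error(vpc(sys, spec, doses, times, n_reps = 5, seed = 1,
                   observed = obs), "matching")
  obs$time_min <- c(10, 20, 30)
  v1 <- vpc(sys, spec, doses, times, n_reps = 10, seed = 4, observed = obs)
  v2 <- vpc(sys, spec, doses, times, n_reps = 10, seed = 4, observed = obs)
  expect_identical(v1$bands, v2$bands)
  expect_identical(v1$medp, v2$medp)
  expect_length(v1$medp, 3)
  expect_true(all(v1$bands$lo <= v1$bands$hi))
})
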