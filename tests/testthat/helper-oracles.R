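# Independent oracles, deliberately implemented by different routes than
# the package internals (eigen decomposition instead of expm; explicit
# loops instead of vectorized grouping).

# Homogeneous linear ODE solution x(t) = V exp(L t) V^-1 x0 via eigen
# decomposition (valid for the diagonalizable random systems used in tests).
oracle_lti_eigen <- function(A, x0, times) {
  ev <- eigen(A)
  Vi <- solve(ev$vectors)
  sapply(times, function(t)
    Re(ev$vectors %*% (exp(ev$values * t) * (Vi %*% x0))))
}

# Naive one-loop reference for all five evaluation statistics.
oracle_metrics <- function(obs, medp) {
  key <- paste(obs$drug, obs$compartment)
  ra <- list()
  for (k in unique(key)) {
    le <- c()
    for (i in seq_len(nrow(obs)))
      if (key[i] == k) le <- c(le, log10(medp[i] / obs$conc[i]))
    ra[[k]] <- list(drug = obs$drug[key == k][1],
                    compartment = obs$compartment[key == k][1],
                    ra = mean(le), ara = mean(abs(le)))
  }
  comps <- unique(obs$compartment)
  out <- list()
  for (cp in comps) {
    ras <- aras <- c()
    for (k in names(ra))
      if (ra[[k]]$compartment == cp) {
        ras <- c(ras, ra[[k]]$ra)
        aras <- c(aras, ra[[k]]$ara)
      }
    s <- 0; m <- 0
    for (i in seq_len(nrow(obs)))
      if (obs$compartment[i] == cp) {
        s <- s + abs(2 * (obs$conc[i] - medp[i]) / (obs$conc[i] + medp[i]))
        m <- m + 1
      }
    out[[cp]] <- c(pct_afe = 100 * 10^mean(ras),
                   pct_aafe = 100 * 10^mean(abs(ras)),
                   pct_mara = 100 * 10^mean(aras),
                   smape_pct = 100 * s / m)
  }
  out
}

# Random small observed dataset + matched predictions.
random_obs_dataset <- function(n_drugs = 3, n_comp = 2, n_obs = 8) {
  drugs <- paste0("drug", seq_len(n_drugs))
  comps <- c("ecf", "lv", "cm", "sas")[seq_len(n_comp)]
  df <- expand.grid(drug = drugs, compartment = comps,
                    j = seq_len(n_obs), stringsAsFactors = FALSE)
  df$species <- "rat"
  df$individual <- ((df$j - 1) %% 3) + 1
  df$time_min <- df$j * 10
  df$conc <- exp(rnorm(nrow(df), 2, 1))
  medp <- df$conc * exp(rnorm(nrow(df), 0, 0.5))
  list(obs = observed_dataset(df[, c("drug", "species", "individual",
                                     "compartment", "time_min", "conc")]),
       medp = medp)
}

# Shared small fixtures (kept cheap; built once per test file load).
rat_phys <- default_physiology("rat")
human_phys <- default_physiology("human")
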