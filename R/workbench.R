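## Workbench: synthetic observed-data generator, CSV I/O, and the command
## line interface.  The generator stands in for in vivo microdialysis
## datasets (which are not redistributable), so the whole evaluation
## pipeline is testable from code alone.

#' Generate a synthetic observed dataset
#'
#' Simulates individual profiles from the model (typical profile plus
#' optional plasma IIV), samples them at the stated times/compartments and
#' applies multiplicative log-normal noise.  Deterministic given `seed`;
#' the output is the same dialect the evaluation reader consumes.
#'
#' @param system A `cns_system`.
#' @param plasma_spec A [plasma_model_spec].
#' @param doses List of [dose_event] objects.
#' @param sample_times Observation times, min.
#' @param compartments Sampled compartments, default `c("ecf", "lv", "cm")`
#'   (microdialysis-accessible sites).
#' @param n_individuals Number of individuals.
#' @param noise_cv Multiplicative residual noise, percent CV (log-normal);
#'   0 gives exact model values.
#' @param iiv Sample plasma etas per individual?
#' @param seed Integer seed.
#' @return An [observed_dataset].
#' @export
generate_synthetic_observed <- function(system, plasma_spec, doses,
                                        sample_times,
                                        compartments = c("ecf", "lv", "cm"),
                                        n_individuals = 6, noise_cv = 20,
                                        iiv = TRUE, seed = 1) {
  stopifnot(noise_cv >= 0, n_individuals >= 1)
  grid <- sort(unique(c(0, sample_times)))
  sdlog <- sqrt(log(1 + (noise_cv / 100)^2))
  rows <- withr_seed(seed, {
    vars <- sample_variability(plasma_spec, n_individuals, seed = seed + 1L)
    out <- list()
    for (i in seq_len(n_individuals)) {
      eta <- if (iiv) vars[[i]]$eta else NULL
      sim <- simulate_pbpk(system, plasma_spec, doses, grid, eta = eta)
      idx <- match(sample_times, grid)
      for (cp in compartments) {
        pred <- sim$conc[cp, idx]
        obs <- pred * exp(rnorm(length(pred), 0, sdlog))
        out[[length(out) + 1]] <- data.frame(
          drug = system$drug$name,
          species = attr(system$physiology, "species"),
          individual = i, compartment = cp,
          time_min = sample_times, conc = obs)
      }
    }
    out
  })
  df <- do.call(rbind, rows)
  df <- df[df$conc > 0, , drop = FALSE]
  observed_dataset(df)
}

#' Write / read the tidy concentration CSV dialect
#'
#' UTF-8, header row, '.' decimal; columns as produced by
#' [as.data.frame.cns_simulation()] or [generate_synthetic_observed()].
#'
#' @param df Data frame to write.
#' @param path File path.
#' @return `read_cns_csv` returns the data frame.
#' @export
write_cns_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cns_csv
#' @export
read_cns_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

.write_manifest <- function(dir, config) {
  config$package_version <- as.character(utils::packageVersion("cnspbpk"))
  config$r_version <- R.version.string
  config$config_hash <- sum(utf8ToInt(paste(deparse(config), collapse = "")))
  jsonlite::write_json(config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.cli_opts <- function(argv) {
  opts <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument `", a, "`",
                                   call. = FALSE)
    key <- gsub("^--", "", a)
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  opts
}

.cli_system <- function(opts) {
  species <- opts$species %||% "rat"
  drug <- drug_fixture(opts$drug %||% "acetaminophen", population = species)
  phys <- default_physiology(species)
  build_system(phys, drug)
}

.cli_doses <- function(opts) {
  list(dose_event(amount = as.numeric(opts$dose %||% "1e6"),
                  route = opts$route %||% "iv-bolus",
                  duration = if (!is.null(opts$duration))
                    as.numeric(opts$duration)))
}

.cli_times <- function(opts) {
  seq(0, as.numeric(opts$tmax %||% "360"), by = as.numeric(opts$dt %||% "2"))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (CNS trajectories for a packaged drug),
#' `evaluate` (VPC + fold errors against an observed CSV), `sensitivity`,
#' `scenario` (altered CSF dynamics), `fixtures` (write a synthetic
#' observed dataset).  Every run writes its outputs plus a `manifest.json`
#' (config, seed, versions) into `--out`.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("simulate", "--drug", "acetaminophen", "--species", "rat",
#'      "--dose", "1e6", "--out", "out_dir")`.
#' @return Exit status, invisibly: 0 on success, 1 on error (with a
#'   message on stderr).
#' @export
cns_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv))
      stop("usage: <simulate|evaluate|sensitivity|scenario|fixtures> ",
           "[--options]", call. = FALSE)
    cmd <- argv[1]
    opts <- .cli_opts(argv[-1])
    out_dir <- opts$out %||% "."
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    seed <- as.integer(opts$seed %||% "1")
    species <- opts$species %||% "rat"
    drug_name <- opts$drug %||% "acetaminophen"

    if (cmd == "simulate") {
      system <- .cli_system(opts)
      spec <- plasma_fixture(drug_name, species)
      sim <- simulate_pbpk(system, spec, .cli_doses(opts), .cli_times(opts))
      write_cns_csv(as.data.frame(sim), file.path(out_dir, "trajectories.csv"))
      write_cns_csv(sim$descriptors, file.path(out_dir, "descriptors.csv"))
      message("AF solution for ", drug_name, ":")
      for (b in .cns_barriers) {
        bar <- system$barriers[[b]]
        message(sprintf("  %-9s Kp_uu %.4g -> AF_in %.4g, AF_ef %.4g", b,
                        bar$kpuu_target, bar$af_in, bar$af_ef))
      }
    } else if (cmd == "evaluate") {
      system <- .cli_system(opts)
      spec <- plasma_fixture(drug_name, species)
      obs <- observed_dataset(read_cns_csv(opts$observed))
      times <- sort(unique(c(.cli_times(opts), obs$time_min)))
      v <- vpc(system, spec, .cli_doses(opts), times,
               n_reps = as.integer(opts[["n-reps"]] %||% "200"),
               seed = seed, observed = obs)
      rep <- evaluate_predictions(obs, v$medp)
      write_cns_csv(rep$per_compartment,
                    file.path(out_dir, "evaluation_compartment.csv"))
      write_cns_csv(rep$per_drug, file.path(out_dir, "evaluation_drug.csv"))
      write_cns_csv(v$bands, file.path(out_dir, "vpc_bands.csv"))
    } else if (cmd == "sensitivity") {
      phys <- default_physiology(species)
      drug <- drug_fixture(drug_name, population = species)
      spec <- plasma_fixture(drug_name, species)
      params <- strsplit(opts$params %||% "q_csf,sa_bbb,pore_radius_nm",
                         ",")[[1]]
      folds <- as.numeric(strsplit(opts$folds %||% "1.1,1.5,2", ",")[[1]])
      res <- run_sensitivity(phys, drug, spec, .cli_doses(opts), params,
                             folds = folds, times = .cli_times(opts))
      write_cns_csv(res, file.path(out_dir, "sensitivity.csv"))
    } else if (cmd == "scenario") {
      phys <- default_physiology("human")
      drug <- drug_fixture(drug_name, population = "human")
      sc <- run_csf_scenarios(
        phys, drug, doses = .cli_doses(opts),
        folds = c(volume = as.numeric(opts[["volume-fold"]] %||% "1"),
                  flow = as.numeric(opts[["flow-fold"]] %||% "1")),
        times = .cli_times(opts))
      write_cns_csv(as.data.frame(sc$sim), file.path(out_dir, "scenario.csv"))
      write_cns_csv(sc$deltas, file.path(out_dir, "scenario_deltas.csv"))
    } else if (cmd == "fixtures") {
      system <- .cli_system(opts)
      spec <- plasma_fixture(drug_name, species)
      obs <- generate_synthetic_observed(
        system, spec, .cli_doses(opts),
        sample_times = seq(10, as.numeric(opts$tmax %||% "360"), by = 30),
        n_individuals = as.integer(opts$individuals %||% "6"),
        noise_cv = as.numeric(opts[["noise-cv"]] %||% "20"), seed = seed)
      write_cns_csv(obs, file.path(out_dir, "synthetic_observed.csv"))
    } else {
      stop("unknown subcommand `", cmd, "`; expected simulate, evaluate, ",
           "sensitivity, scenario, or fixtures", call. = FALSE)
    }
    .write_manifest(out_dir, list(command = cmd, options = opts, seed = seed))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
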