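## CNS physiology: the anatomical/physiological constants that
## parameterize the nine-compartment model for one species/population.

# Registry of required fields with their canonical units.  Volumes are mL,
# flows mL/min, surface areas cm2.  `derived` fields are recomputed from
# their parents when loaded from defaults (and after perturbation) unless
# the config or the user pins them explicitly.
.phys_fields <- data.frame(
  name = c("v_mv", "v_ecf", "v_icf", "v_lys", "v_lv", "v_tfv", "v_cm",
           "v_sas", "v_brain", "bcm_fraction", "v_bcm",
           "q_cbf", "q_ecf", "q_csf",
           "sa_bbb", "sa_bcsfb_lv", "sa_bcsfb_tfv", "sa_lys", "sa_bcm",
           "pore_radius_nm", "paracellular_length_um", "paracellular_fraction",
           "n_cells", "cell_radius_um",
           "ph_plasma", "ph_ecf", "ph_icf", "ph_lys", "ph_csf"),
  units = c(rep("mL", 9), "1", "mL",
            rep("mL/min", 3),
            rep("cm2", 5),
            "nm", "um", "1",
            "count", "um",
            rep("pH", 5)),
  derived = FALSE,
  stringsAsFactors = FALSE
)
.phys_fields$derived[.phys_fields$name %in% c("v_bcm", "sa_bcm")] <- TRUE

#' Surface area of the brain-cell membrane from cell geometry
#'
#' Total membrane surface area assuming all brain cells are spheres of
#' equal radius: `cell_count * 4 * pi * r^2`, returned in cm2.
#'
#' @param cell_count Number of brain cells (neurons plus glia).
#' @param cell_radius_um Cell radius in micrometres.
#' @return Surface area in cm2.
#' @examples
#' derive_sa_bcm(1e8, 10)  # ~1257 cm2
#' @export
derive_sa_bcm <- function(cell_count, cell_radius_um) {
  if (!is.numeric(cell_count) || cell_count < 1)
    stop("`cell_count` must be a count >= 1", call. = FALSE)
  if (!is.numeric(cell_radius_um) || cell_radius_um <= 0)
    stop("`cell_radius_um` must be positive", call. = FALSE)
  cell_count * 4 * pi * (cell_radius_um * 1e-4)^2
}

.phys_recompute_derived <- function(x) {
  auto <- attr(x, "auto")
  if ("v_bcm" %in% auto) x$v_bcm <- x$bcm_fraction * x$v_brain
  if ("sa_bcm" %in% auto) x$sa_bcm <- derive_sa_bcm(x$n_cells, x$cell_radius_um)
  x
}

.phys_validate <- function(x) {
  req <- .phys_fields$name
  missing <- setdiff(req, names(x))
  if (length(missing))
    stop("physiology is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ph <- grep("^ph_", req, value = TRUE)
  pos <- setdiff(req, c(ph, "paracellular_fraction", "bcm_fraction"))
  for (f in pos)
    if (!is.finite(x[[f]]) || x[[f]] <= 0)
      stop("physiology field `", f, "` must be strictly positive (got ",
           x[[f]], ")", call. = FALSE)
  for (f in ph)
    if (x[[f]] < 1 || x[[f]] > 14)
      stop("physiology field `", f, "` must be a pH in [1, 14] (got ",
           x[[f]], ")", call. = FALSE)
  for (f in c("paracellular_fraction", "bcm_fraction"))
    if (x[[f]] <= 0 || x[[f]] >= 1)
      stop("physiology field `", f, "` must lie in (0, 1)", call. = FALSE)
  invisible(x)
}

#' Construct a CNS physiology set
#'
#' @param values Named list of numeric fields (see `cns_physiology_fields()`).
#'   `v_bcm` and `sa_bcm` may be omitted, in which case they are derived from
#'   `bcm_fraction * v_brain` and from the brain-cell geometry respectively,
#'   and stay coupled to their parents under [apply_perturbations()].
#' @param species Species/population label, e.g. `"rat"` or `"human"`.
#' @return An object of class `cns_physiology` (a named list of numeric
#'   fields with attributes `species` and `auto`).
#' @export
cns_physiology <- function(values, species = "custom") {
  x <- values
  auto <- character(0)
  if (is.null(x$v_bcm)) auto <- c(auto, "v_bcm")
  if (is.null(x$sa_bcm)) auto <- c(auto, "sa_bcm")
  attr(x, "auto") <- auto
  x <- .phys_recompute_derived(x)
  attr(x, "species") <- species
  class(x) <- "cns_physiology"
  .phys_validate(x)
  x
}

#' Field registry for physiology configs
#'
#' @return A data frame of field names, canonical units, and whether the
#'   field is derived by default.
#' @export
cns_physiology_fields <- function() .phys_fields

#' Load a physiology set from a structured JSON config
#'
#' The config dialect is a JSON object with a `species` string and a
#' `fields` object mapping each field name to
#' `{"value": <number>, "units": "<units>", "source": "<citation>"}`.
#' Units strings are checked against the canonical unit table.
#'
#' @param source Path to a JSON file, or an already-parsed list.
#' @param species Optional species label that must match the config.
#' @return A [cns_physiology] object.
#' @export
load_physiology <- function(source, species = NULL) {
  cfg <- if (is.character(source)) jsonlite::read_json(source) else source
  if (is.null(cfg$fields)) stop("config has no `fields` object", call. = FALSE)
  if (!is.null(species) && !identical(cfg$species, species))
    stop("config is for species `", cfg$species, "`, not `", species, "`",
         call. = FALSE)
  vals <- list()
  for (nm in names(cfg$fields)) {
    f <- cfg$fields[[nm]]
    idx <- match(nm, .phys_fields$name)
    if (is.na(idx))
      stop("unknown physiology field `", nm, "` in config", call. = FALSE)
    if (is.null(f$units) || !identical(f$units, .phys_fields$units[idx]))
      stop("field `", nm, "` must carry units \"", .phys_fields$units[idx],
           "\" (got \"", f$units %||% "<none>", "\")", call. = FALSE)
    vals[[nm]] <- as.numeric(f$value)
  }
  cns_physiology(vals, species = cfg$species %||% "custom")
}

#' Packaged default physiology
#'
#' Best-effort literature values for rat and human; each field carries its
#' provenance in the packaged JSON config.  Where several literature values
#' exist the mean was used.
#'
#' @param species `"rat"` or `"human"`.
#' @return A [cns_physiology] object.
#' @export
default_physiology <- function(species = c("human", "rat")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("physiology_", species, ".json"),
                      package = "cnspbpk")
  load_physiology(path, species = species)
}

#' Serialize a physiology set back to the config dialect
#'
#' @param physiology A [cns_physiology] object.
#' @param path Optional file path; if given the JSON is written there.
#' @return The config list, invisibly when `path` is given.
#' @export
serialize_physiology <- function(physiology, path = NULL) {
  stopifnot(inherits(physiology, "cns_physiology"))
  fields <- list()
  for (nm in .phys_fields$name) {
    fields[[nm]] <- list(value = physiology[[nm]],
                         units = .phys_fields$units[match(nm, .phys_fields$name)])
  }
  cfg <- list(species = attr(physiology, "species"), fields = fields)
  if (!is.null(path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(cfg))
  }
  cfg
}

#' Multiply named physiology parameters by fold changes
#'
#' Returns a new set with each named parameter scaled; the input is not
#' modified.  Derived fields (`v_bcm`, `sa_bcm`) are recomputed from their
#' perturbed parents unless they were pinned explicitly or are themselves
#' the perturbation target (in which case they decouple from their parents).
#'
#' @param base A [cns_physiology] object.
#' @param perturbations Named numeric vector of fold changes, e.g.
#'   `c(q_csf = 5, v_lv = 5)`; all folds must be positive.
#' @return A new [cns_physiology] object.
#' @export
apply_perturbations <- function(base, perturbations) {
  stopifnot(inherits(base, "cns_physiology"))
  folds <- unlist(perturbations)
  bad <- setdiff(names(folds), .phys_fields$name)
  if (length(bad))
    stop("unknown parameter path(s): ", paste(bad, collapse = ", "),
         "\nvalid paths: ", paste(.phys_fields$name, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(folds)) || any(folds <= 0))
    stop("fold changes must be positive and finite", call. = FALSE)
  out <- base
  for (nm in names(folds)) {
    out[[nm]] <- out[[nm]] * folds[[nm]]
    if (nm %in% c("v_bcm", "sa_bcm"))  # direct hit decouples the field
      attr(out, "auto") <- setdiff(attr(out, "auto"), nm)
  }
  out <- .phys_recompute_derived(out)
  .phys_validate(out)
  out
}

#' @export
print.cns_physiology <- function(x, ...) {
  cat("<cns_physiology> species:", attr(x, "species"), "\n")
  df <- data.frame(field = .phys_fields$name,
                   value = unlist(x[.phys_fields$name]),
                   units = .phys_fields$units)
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
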