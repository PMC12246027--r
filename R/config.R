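# Configuration loading with unit handling, result writers and run
# manifests. Configs are YAML with nested blocks (material, profile, mesh,
# load, thresholds, kinetics, schedule, fixture); any dimensional value may
# be written as a number (SI assumed) or as a "value unit" string.

.unit_table <- c(
  "-" = 1, "1" = 1,
  "s" = 1, "ms" = 1e-3, "min" = 60, "h" = 3600, "d" = 86400,
  "1/s" = 1, "1/min" = 1 / 60, "1/h" = 1 / 3600, "1/d" = 1 / 86400,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6, "GPa" = 1e9,
  "Pa.s" = 1, "Pa*s" = 1, "MPa.s" = 1e6,
  "m" = 1, "mm" = 1e-3, "um" = 1e-6,
  "N" = 1, "kN" = 1e3,
  "m2/s" = 1, "mm2/s" = 1e-6, "um2/s" = 1e-12,
  "m^2/s" = 1, "mm^2/s" = 1e-6,
  "mol/m3" = 1, "mol/m^3" = 1, "mM" = 1, "M" = 1e3, "mmol/l" = 1,
  "m3/mol/s" = 1, "m^3/mol/s" = 1, "m3/(mol.s)" = 1, "m^3*mol^-1*s^-1" = 1,
  "m4/Ns" = 1, "m^4/(N.s)" = 1, "m4/(N.s)" = 1,
  "Pa.m3/mol" = 1, "m3/mol" = 1, "m^3/mol" = 1,
  "J/mol/K" = 1, "K" = 1, "cells/m3" = 1, "cells/m^3" = 1
)

#' Parse a quantity with an optional unit tag
#'
#' Accepts a plain number (taken as SI) or a string \code{"value unit"}, e.g.
#' \code{"0.2484 1/h"}, \code{"2 mM"}, \code{"1 MPa"}. Unknown units are an
#' error.
#'
#' @param x Number or string.
#' @return Numeric value in SI units (mol m^-3 for concentrations).
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1)
    stop("cannot parse quantity: ", deparse(x))
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  val <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(val)) stop("cannot parse numeric value in: ", x)
  if (length(parts) == 1) return(val)
  unit <- paste(parts[-1], collapse = "")
  fac <- .unit_table[unit]
  if (is.na(fac)) stop("unknown unit '", unit, "' in: ", x)
  val * unname(fac)
}

.known_blocks <- function() {
  list(material = names(formals(material_params)),
       kinetics = setdiff(names(formals(kinetics_params)),
                          "literal_reported_dnac"),
       thresholds = names(formals(damage_thresholds)),
       schedule = names(formals(treatment_schedule)),
       load = names(formals(load_spec)),
       mesh = names(formals(mesh_spec)),
       fixture = names(formals(fixture_spec)),
       grid = names(formals(kinetics_grid)))
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, rejects unknown blocks or keys, normalizes every
#' dimensional entry to SI via \code{\link{parse_quantity}}, and fills all
#' unspecified values from the mature-bovine reference preset (the
#' constructor defaults of \code{\link{material_params}},
#' \code{\link{kinetics_params}}, \code{\link{damage_thresholds}}, ...).
#'
#' @param path YAML file path.
#' @return An object of class \code{run_config}: list with any of the blocks
#'   \code{material}, \code{kinetics}, \code{thresholds}, \code{schedule},
#'   \code{load}, \code{mesh}, \code{fixture}, \code{grid}, each a
#'   constructed parameter object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- .known_blocks()
  bad <- setdiff(names(raw), names(known))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         " (expected among: ", paste(names(known), collapse = ", "), ")")
  ctor <- list(material = material_params, kinetics = kinetics_params,
               thresholds = damage_thresholds, schedule = treatment_schedule,
               load = load_spec, mesh = mesh_spec, fixture = fixture_spec,
               grid = kinetics_grid)
  out <- list()
  for (blk in names(known)) {
    given <- raw[[blk]]
    if (is.null(given)) given <- list()
    bad_keys <- setdiff(names(given), known[[blk]])
    if (length(bad_keys))
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad_keys, collapse = ", "),
           " (expected among: ", paste(known[[blk]], collapse = ", "), ")")
    numeric_like <- vapply(given, function(v)
      is.numeric(v) || is.character(v), logical(1))
    given[numeric_like] <- lapply(given[numeric_like], function(v) {
      # leave non-numeric strings (e.g. fixture pattern names) untouched
      if (is.character(v) && !grepl("^[-0-9.eE+]", v)) return(v)
      parse_quantity(v)
    })
    out[[blk]] <- do.call(ctor[[blk]], given)
  }
  structure(out, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration with blocks:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Hash of an arbitrary configuration object
#'
#' Deterministic MD5 of the deparsed object; used in run manifests so any
#' published number can be traced to the exact configuration that produced
#' it.
#'
#' @param obj Any R object.
#' @return 32-character hex string.
#' @export
config_hash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(obj, file = tf, control = c("all", "hexNumeric"))
  unname(tools::md5sum(tf))
}

#' Write scenario results and a run manifest
#'
#' Writes each table to \code{<dir>/<name>.csv} (idempotent overwrite) plus a
#' \code{manifest.yaml} with the config hash, package version and file list.
#' An empty result writes a header-only CSV.
#'
#' @param result A data.frame / \code{scenario_result}, or a named list of
#'   them.
#' @param dir Output directory (created if needed).
#' @param name Base filename for a single table.
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(result, dir, name = "result") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- if (is.data.frame(result)) stats::setNames(list(result), name)
            else result
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "chondrosim",
    version = as.character(utils::packageVersion("chondrosim")),
    config_hash = config_hash(lapply(tables, function(t)
      list(names = names(t), hash = config_hash(as.data.frame(t))))),
    files = basename(files),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(c(files, file.path(dir, "manifest.yaml")))
}
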