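# Strain-field container and exchange format. A strain_field is the interface
# between the impact stage and the biology stage: per sample point it carries
# cylindrical coordinates, the maximum shear strain from the Green-Lagrange
# tensor, and the pore pressure at peak impact force.

#' Maximum shear strain from a Green-Lagrange strain tensor
#'
#' \eqn{\gamma_{max} = (E_I - E_{III})/2} where \eqn{E_I \ge E_{II} \ge
#' E_{III}} are the principal Green-Lagrange strains. Set
#' \code{halved = FALSE} for the alternative convention \eqn{E_I - E_{III}}.
#'
#' @param E_GL Symmetric 3x3 Green-Lagrange strain tensor.
#' @param halved Divide the principal-strain difference by two (default TRUE).
#' @param tol Symmetry tolerance (relative to the largest entry).
#' @return Nonnegative scalar maximum shear strain (-).
#' @export
max_shear_strain <- function(E_GL, halved = TRUE, tol = 1e-8) {
  stopifnot(is.matrix(E_GL), all(dim(E_GL) == c(3, 3)))
  scale <- max(abs(E_GL), 1e-300)
  if (max(abs(E_GL - t(E_GL))) > tol * scale)
    stop("E_GL must be symmetric")
  ev <- eigen((E_GL + t(E_GL)) / 2, symmetric = TRUE, only.values = TRUE)$values
  g <- max(ev) - min(ev)
  if (halved) g / 2 else g
}

#' Construct a strain field
#'
#' @param r,z Cylindrical coordinates of the sample points (m); \code{z} is
#'   measured downward from the articular surface (0 = surface).
#' @param gamma_max Maximum shear strain at each point (-), >= 0.
#' @param pore_pressure Pore pressure at each point (Pa).
#' @param time Extraction time (s), typically the time of peak impact force.
#' @return An object of class \code{strain_field} (a data.frame with columns
#'   \code{r_m}, \code{z_m}, \code{gamma_max}, \code{pore_pressure_Pa} and a
#'   \code{time} attribute).
#' @export
strain_field <- function(r, z, gamma_max, pore_pressure = 0, time = NA_real_) {
  n <- length(r)
  stopifnot(length(z) == n, length(gamma_max) == n)
  if (length(pore_pressure) == 1) pore_pressure <- rep(pore_pressure, n)
  stopifnot(length(pore_pressure) == n)
  if (any(!is.finite(gamma_max)) || any(gamma_max < 0))
    stop("gamma_max must be finite and nonnegative everywhere")
  out <- data.frame(r_m = r, z_m = z, gamma_max = gamma_max,
                    pore_pressure_Pa = pore_pressure)
  attr(out, "time") <- time
  class(out) <- c("strain_field", "data.frame")
  out
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("Strain field: %d points, r in [%.3g, %.3g] mm, depth in [%.3g, %.3g] mm\n",
              nrow(x), 1e3 * min(x$r_m), 1e3 * max(x$r_m),
              1e3 * min(x$z_m), 1e3 * max(x$z_m)))
  cat(sprintf("  gamma_max: max %.3g, mean %.3g; pore pressure max %.3g MPa\n",
              max(x$gamma_max), mean(x$gamma_max),
              1e-6 * max(x$pore_pressure_Pa)))
  if (is.finite(attr(x, "time")))
    cat(sprintf("  extracted at t = %.3g ms\n", 1e3 * attr(x, "time")))
  invisible(x)
}

#' @export
plot.strain_field <- function(x, what = c("gamma_max", "pore_pressure_Pa"), ...) {
  what <- match.arg(what)
  rs <- sort(unique(x$r_m)); zs <- sort(unique(x$z_m))
  if (length(rs) * length(zs) == nrow(x)) {
    m <- matrix(NA_real_, length(rs), length(zs))
    m[cbind(match(x$r_m, rs), match(x$z_m, zs))] <- x[[what]]
    graphics::filled.contour(rs * 1e3, zs * 1e3, m,
                             xlab = "r (mm)", ylab = "depth (mm)",
                             main = what, ...)
  } else {
    graphics::plot(x$r_m * 1e3, x[[what]], xlab = "r (mm)", ylab = what, ...)
  }
  invisible(x)
}

.strain_cols <- c("r_m", "z_m", "gamma_max", "pore_pressure_Pa")

#' Write a strain field to its CSV exchange format
#'
#' Plain CSV with header \code{r_m, z_m, gamma_max, pore_pressure_Pa} and an
#' optional \code{# time_s:} comment line. The round trip through
#' \code{\link{load_strain_field}} is lossless.
#'
#' @param field A \code{\link{strain_field}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_strain_field <- function(field, path) {
  stopifnot(inherits(field, "strain_field"))
  con <- file(path, "w")
  on.exit(close(con))
  t0 <- attr(field, "time")
  if (!is.null(t0) && is.finite(t0))
    writeLines(sprintf("# time_s: %.17g", t0), con)
  utils::write.csv(as.data.frame(field)[, .strain_cols], con, row.names = FALSE)
  invisible(path)
}

#' Load a strain field from CSV
#'
#' The bypass interface that lets the biology stage run without the
#' finite-element stage: any file with the schema written by
#' \code{\link{export_strain_field}} (or the fixture generator) is accepted.
#'
#' @param path CSV file path.
#' @return A \code{\link{strain_field}}.
#' @export
load_strain_field <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  t0 <- NA_real_
  if (startsWith(first, "# time_s:"))
    t0 <- as.numeric(sub("# time_s:", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(.strain_cols, names(df))
  if (length(missing))
    stop("strain-field schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(df$gamma_max)) || any(df$gamma_max < 0))
    stop("strain-field schema error: gamma_max must be nonnegative")
  strain_field(df$r_m, df$z_m, df$gamma_max, df$pore_pressure_Pa, time = t0)
}

#' Sample a strain field onto grid points by nearest sample point
#'
#' Strains live at element centroids of the impact mesh; the kinetics grid has
#' its own cell centers. Transfer is nearest-neighbour in (r, z).
#'
#' @param field A \code{\link{strain_field}}.
#' @param r,z Target coordinates (m), equal length.
#' @return Vector of \code{gamma_max} at the targets.
#' @export
sample_strain <- function(field, r, z) {
  stopifnot(inherits(field, "strain_field"), length(r) == length(z))
  # scale depth so r and z distances are comparable on slender domains
  rs <- field$r_m; zs <- field$z_m
  sc <- max(diff(range(rs)), 1e-12) / max(diff(range(zs)), 1e-12)
  idx <- vapply(seq_along(r), function(i) {
    which.min((rs - r[i])^2 + (sc * (zs - z[i]))^2)
  }, integer(1))
  field$gamma_max[idx]
}
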