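# Strain-thresholded cell damage: maps the peak maximum-shear-strain field to
# the initial damaged-cell fraction and builds the initial cell populations.

#' Nonlinear cellular damage function
#'
#' Fraction of initially healthy cells damaged by a local maximum shear strain
#' \eqn{\epsilon}:
#' \deqn{f_{dmg}(\epsilon) = 0 \ (\epsilon < \epsilon_{init}); \quad
#'  \frac{\epsilon_{max}}{\epsilon}
#'  \frac{\epsilon - \epsilon_{init}}{\epsilon_{max} - \epsilon_{init}}
#'  \ (\epsilon_{init} \le \epsilon \le \epsilon_{max}); \quad 1 \
#'  (\epsilon > \epsilon_{max})}
#' Continuous and nondecreasing in \eqn{\epsilon}; at the reference thresholds
#' (0.40, 1.50) a strain of 0.679 damages 56\% of cells.
#'
#' @param gamma_max Maximum shear strain (-), >= 0, vectorized.
#' @param thresholds A \code{\link{damage_thresholds}} object.
#' @return Damaged fraction in [0, 1].
#' @export
damage_fraction <- function(gamma_max, thresholds = damage_thresholds()) {
  stopifnot(all(is.finite(gamma_max)), all(gamma_max >= 0))
  e0 <- thresholds$eps_init; e1 <- thresholds$eps_max
  f <- numeric(length(gamma_max))
  mid <- gamma_max >= e0 & gamma_max <= e1
  f[mid] <- (e1 / gamma_max[mid]) * (gamma_max[mid] - e0) / (e1 - e0)
  f[gamma_max > e1] <- 1
  f
}

#' Invert the damage function on its rising branch
#'
#' Smallest strain whose damage fraction equals \code{f} (used by the fixture
#' generator to encode a target superficial damage level).
#'
#' @param f Target damaged fraction in [0, 1).
#' @param thresholds A \code{\link{damage_thresholds}} object.
#' @return Maximum shear strain (-).
#' @export
damage_inverse <- function(f, thresholds = damage_thresholds()) {
  stopifnot(f >= 0, f < 1)
  if (f == 0) return(thresholds$eps_init)
  e0 <- thresholds$eps_init; e1 <- thresholds$eps_max
  # f = (e1/eps)(eps - e0)/(e1 - e0)  =>  eps (e1 - f (e1 - e0)) = e1 e0
  e1 * e0 / (e1 - f * (e1 - e0))
}

#' Seed the initial cell populations from a strain field
#'
#' Nodewise: \code{C_dmg = f_dmg(gamma) * C_init}, \code{C_h = (1 - f_dmg) *
#' C_init}, \code{C_dead = 0}. The total is conserved by construction.
#'
#' @param gamma_max Maximum shear strain per grid point (-), >= 0.
#' @param thresholds A \code{\link{damage_thresholds}} object.
#' @param C_init Initial total cell density (cells m^-3), homogeneous.
#' @return An object of class \code{cell_field}: list of vectors \code{C_h},
#'   \code{C_dmg}, \code{C_dead} plus \code{C_init}.
#' @export
seed_cell_field <- function(gamma_max, thresholds = damage_thresholds(),
                            C_init = 0.5e14) {
  if (any(gamma_max < 0)) stop("negative strain in seed_cell_field")
  f <- damage_fraction(gamma_max, thresholds)
  structure(list(C_h = (1 - f) * C_init, C_dmg = f * C_init,
                 C_dead = numeric(length(f)), C_init = C_init),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  n <- length(x$C_h)
  cat(sprintf("Cell field on %d points; mean fractions: healthy %.3f, damaged %.3f, dead %.3f\n",
              n, mean(x$C_h) / x$C_init, mean(x$C_dmg) / x$C_init,
              mean(x$C_dead) / x$C_init))
  invisible(x)
}
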