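# Shared objects for the test suite. Everything is generated in code; no
# stored fixtures.

ref_material <- function(...) material_params(...)

ref_profile <- function() make_depth_profile_fixture()

ref_field <- function() make_strain_fixture()

# random symmetric 3x3 strain tensor with entries in [-scale, scale]
random_sym3 <- function(scale = 0.3) {
  A <- matrix(stats::runif(9, -scale, scale), 3, 3)
  (A + t(A)) / 2
}

# random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

HOUR <- 3600
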