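# Axisymmetric finite-element mesh: 4-node displacement-pressure
# quadrilaterals on a tensor-product grid, radially graded toward the
# indenter edge where the strain gradients concentrate. The axial coordinate
# zn runs upward from the fixed bottom (z = 0) to the articular surface
# (z = thickness); reporting depths are thickness - z.

#' Impact-mesh specification
#'
#' @param nr,nz Element counts radially / axially (>= 4 each).
#' @param radius Cartilage radius (m), default 12.5 mm.
#' @param thickness Cartilage thickness (m), default 1 mm.
#' @param indenter_radius Contact radius (m); a node is placed exactly here.
#' @param refine_radius Outer edge of the radially refined band (m).
#' @return An object of class \code{mesh_spec}.
#' @export
mesh_spec <- function(nr = 60, nz = 20, radius = 12.5e-3, thickness = 1e-3,
                      indenter_radius = 2.5e-3, refine_radius = 4e-3) {
  stopifnot(nr >= 4, nz >= 4, radius > indenter_radius,
            refine_radius > indenter_radius, radius > refine_radius)
  structure(list(nr = nr, nz = nz, radius = radius, thickness = thickness,
                 indenter_radius = indenter_radius,
                 refine_radius = refine_radius),
            class = "mesh_spec")
}

#' Build the finite-element mesh
#'
#' @param spec A \code{\link{mesh_spec}}.
#' @return List with node coordinates, element connectivity (counterclockwise
#'   Q1 quads), centroids and boundary node index sets.
#' @export
build_mesh <- function(spec) {
  nr <- spec$nr; nz <- spec$nz
  n1 <- max(4L, round(nr * 0.3))            # contact patch
  n2 <- max(2L, round(nr * 0.2))            # fillet / edge band
  n3 <- nr - n1 - n2                        # far field
  stopifnot(n3 >= 2)
  rn <- c(seq(0, spec$indenter_radius, length.out = n1 + 1),
          seq(spec$indenter_radius, spec$refine_radius,
              length.out = n2 + 1)[-1],
          seq(spec$refine_radius, spec$radius, length.out = n3 + 1)[-1])
  zn <- seq(0, spec$thickness, length.out = nz + 1)
  # aspect-ratio guard (spec invariant)
  ar <- max(outer(diff(rn), diff(zn), "/"), outer(diff(zn), diff(rn), "/"))
  if (ar > 20)
    warning("element aspect ratio ", round(ar, 1), " exceeds 20")
  nnr <- length(rn); nnz <- length(zn)
  nid <- function(i, j) i + (j - 1L) * nnr
  nodes <- cbind(r = rep(rn, nnz), z = rep(zn, each = nnr))
  elems <- matrix(0L, nr * nz, 4)
  k <- 0L
  for (j in seq_len(nz)) for (i in seq_len(nr)) {
    k <- k + 1L
    elems[k, ] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L),
                    nid(i, j + 1L))
  }
  top_nodes <- nid(seq_len(nnr), nnz)
  bottom_nodes <- nid(seq_len(nnr), 1L)
  axis_nodes <- nid(1L, seq_len(nnz))
  outer_nodes <- nid(nnr, seq_len(nnz))
  list(spec = spec, rn = rn, zn = zn, nodes = nodes, elems = elems,
       n_nodes = nrow(nodes), n_elems = nrow(elems),
       r_cent = (nodes[elems[, 1], 1] + nodes[elems[, 2], 1]) / 2,
       z_cent = (nodes[elems[, 1], 2] + nodes[elems[, 4], 2]) / 2,
       top_nodes = top_nodes, bottom_nodes = bottom_nodes,
       axis_nodes = axis_nodes, outer_nodes = outer_nodes)
}

#' Half-sine impact load specification
#'
#' @param F_peak Peak impact force (N), > 0 allowed 0 for null tests.
#' @param t_impact Total impact duration (s), > 0.
#' @param indenter_radius Contact radius (m); 5-mm-diameter indenter.
#' @param fillet Width of the rounded (filleted) indenter edge (m) over which
#'   the contact traction tapers to zero.
#' @return An object of class \code{load_spec}.
#' @export
load_spec <- function(F_peak = 4000, t_impact = 1e-3,
                      indenter_radius = 2.5e-3, fillet = 1e-3) {
  stopifnot(F_peak >= 0, t_impact > 0, indenter_radius > 0,
            fillet >= 0, fillet < indenter_radius)
  structure(list(F_peak = F_peak, t_impact = t_impact,
                 indenter_radius = indenter_radius, fillet = fillet),
            class = "load_spec")
}

#' Half-sine force waveform
#'
#' \eqn{F(t) = F_{peak} \sin(\pi t / t_{impact})} inside the impact window;
#' zero (with a warning) outside. Peak at \eqn{t_{impact}/2}; the window
#' average is \eqn{2 F_{peak}/\pi}.
#'
#' @param t Time (s), vectorized.
#' @param load A \code{\link{load_spec}}.
#' @return Force (N).
#' @export
force_waveform <- function(t, load) {
  out <- ifelse(t >= 0 & t <= load$t_impact,
                load$F_peak * sin(pi * t / load$t_impact), 0)
  if (any(t < 0 | t > load$t_impact))
    warning("time outside the impact window; returning zero force")
  out
}
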