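# Element strain kinematics: displacement gradient of the trilinear
# interpolant at the element centroid, small-strain / Green-Lagrange tensors,
# and projection onto the cylindrical (radial, circumferential, axial) basis.

# Corner groups of the fixed element ordering whose local coordinate is 1
# along each axis (see .hex_corner_offsets).
.face_plus <- list(x = c(2L, 3L, 6L, 7L), y = c(3L, 4L, 7L, 8L),
                   z = c(5L, 6L, 7L, 8L))
.face_minus <- list(x = c(1L, 4L, 5L, 8L), y = c(1L, 2L, 5L, 6L),
                    z = c(1L, 2L, 3L, 4L))

#' Displacement gradient at element centroids
#'
#' For the trilinear interpolant on a rectangular hexahedron the gradient at
#' the centroid reduces to face-averaged corner differences per axis:
#' `du/dx = (mean(u on the +x face) - mean(u on the -x face)) / sx`. The
#' centroid value is exact for affine fields and superconvergent
#' (central-difference) for smooth ones.
#'
#' @param mesh a `hex_mesh`.
#' @param nodal n_nodes x 3 matrix of nodal displacements (mm), as from
#'   [sample_nodal_displacements()].
#' @return array (m x 3 x 3): per element the matrix `G[a, b] = du_a / dx_b`
#'   (dimensionless).
#' @export
element_displacement_gradient <- function(mesh, nodal) {
  stopifnot(inherits(mesh, "hex_mesh"), nrow(nodal) == nrow(mesh$nodes))
  m <- nrow(mesh$elements)
  G <- array(0, c(m, 3L, 3L))
  for (b in 1:3) {
    ax <- c("x", "y", "z")[b]
    plus <- mesh$elements[, .face_plus[[ax]], drop = FALSE]
    minus <- mesh$elements[, .face_minus[[ax]], drop = FALSE]
    for (a in 1:3) {
      ua <- nodal[, a]
      G[, a, b] <- (ua[plus[, 1]] + ua[plus[, 2]] + ua[plus[, 3]] +
                    ua[plus[, 4]] -
                    ua[minus[, 1]] - ua[minus[, 2]] - ua[minus[, 3]] -
                    ua[minus[, 4]]) / (4 * mesh$spacing[b])
    }
  }
  G
}

#' Strain tensor from a displacement gradient
#'
#' `infinitesimal`: `eps = (G + G^T) / 2`. `green_lagrange`:
#' `E = (F^T F - I) / 2` with `F = I + G`; the two coincide to first order in
#' `G`.
#'
#' @param G array (m x 3 x 3) of displacement gradients, or a single 3 x 3
#'   matrix.
#' @param measure `"infinitesimal"` (default) or `"green_lagrange"`.
#' @return array (m x 3 x 3) of symmetric strain tensors (or 3 x 3 for a
#'   single input).
#' @export
strain_tensor <- function(G, measure = c("infinitesimal", "green_lagrange")) {
  measure <- match.arg(measure)
  single <- is.matrix(G)
  if (single) G <- array(G, c(1L, 3L, 3L))
  E <- array(0, dim(G))
  if (measure == "infinitesimal") {
    for (a in 1:3) for (b in 1:3)
      E[, a, b] <- (G[, a, b] + G[, b, a]) / 2
  } else {
    # E = (G + G^T + G^T G) / 2
    for (a in 1:3) for (b in 1:3) {
      q <- G[, 1, a] * G[, 1, b] + G[, 2, a] * G[, 2, b] +
        G[, 3, a] * G[, 3, b]
      E[, a, b] <- (G[, a, b] + G[, b, a] + q) / 2
    }
  }
  if (single) E[1, , ] else E
}

#' Cylindrical normal components of strain tensors
#'
#' Projects each tensor onto the local orthonormal basis of the frame at the
#' element centroid: `eps_rr = e_r' eps e_r`, `eps_tt = e_t' eps e_t`,
#' `eps_zz = e_z' eps e_z`.
#'
#' @param E array (m x 3 x 3) of symmetric tensors.
#' @param centroids m x 3 world positions of the evaluation points, mm.
#' @param frame a [build_frame()].
#' @return data.frame with columns `err`, `ett`, `ezz` and logical `on_axis`
#'   (components are `NA` in-plane for on-axis points).
#' @export
cylindrical_components <- function(E, centroids, frame) {
  cyl <- to_cylindrical(frame, centroids)
  ct <- cyl$e_r[, 1]; st <- cyl$e_r[, 2]
  exx <- E[, 1, 1]; eyy <- E[, 2, 2]; ezz <- E[, 3, 3]; exy <- E[, 1, 2]
  err <- ct^2 * exx + 2 * ct * st * exy + st^2 * eyy
  ett <- st^2 * exx - 2 * ct * st * exy + ct^2 * eyy
  data.frame(err = err, ett = ett, ezz = ezz, on_axis = cyl$on_axis)
}

#' Compute the full per-element strain field of a meshed meniscus
#'
#' Runs [element_displacement_gradient()], [strain_tensor()] and
#' [cylindrical_components()] over the whole mesh. Elements whose centroid
#' falls on the cylinder axis are flagged and carry `NA` in-plane components
#' but keep their Cartesian tensors.
#'
#' @param mesh a `hex_mesh`.
#' @param nodal n_nodes x 3 nodal displacements (mm).
#' @param frame a [build_frame()].
#' @param measure strain measure, see [strain_tensor()].
#' @return object of class `strain_field`: list with `tensors` (m x 3 x 3),
#'   `err`, `ett`, `ezz` (per element, dimensionless), `on_axis`, `measure`,
#'   plus the `mesh` and `frame` used.
#' @export
compute_strain_field <- function(mesh, nodal, frame,
                                 measure = c("infinitesimal",
                                             "green_lagrange")) {
  measure <- match.arg(measure)
  G <- element_displacement_gradient(mesh, nodal)
  E <- strain_tensor(G, measure)
  cc <- cylindrical_components(E, element_centroids(mesh), frame)
  structure(list(tensors = E, err = cc$err, ett = cc$ett, ezz = cc$ezz,
                 on_axis = cc$on_axis, measure = measure,
                 mesh = mesh, frame = frame),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat("<strain_field> ", length(x$ezz), " elements, measure ", x$measure,
      "; median axial strain ",
      format(100 * stats::median(x$ezz, na.rm = TRUE), digits = 4), " %\n",
      sep = "")
  invisible(x)
}
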