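# Voxel-resolution hexahedral meshing of a segmentation and sampling of the
# displacement field at mesh nodes.  One 8-node brick per foreground voxel;
# nodes sit on the corner lattice (voxel centers - spacing/2), so each element
# is exactly the voxel box and its centroid is exactly the voxel center.

# Corner offsets in the fixed element ordering: counterclockwise bottom face
# (z = 0) starting at the local origin, then the top face in the same order
# (the usual VTK_HEXAHEDRON ordering).
.hex_corner_offsets <- matrix(c(
  0L, 0L, 0L,
  1L, 0L, 0L,
  1L, 1L, 0L,
  0L, 1L, 0L,
  0L, 0L, 1L,
  1L, 0L, 1L,
  1L, 1L, 1L,
  0L, 1L, 1L), ncol = 3L, byrow = TRUE)

#' Convert a label mask into a voxel-resolution hexahedral mesh
#'
#' Every voxel carrying one of `target_labels` becomes one 8-node hexahedral
#' element whose geometry is exactly the voxel box; nodes are deduplicated
#' across neighboring voxels, giving a conforming mesh. Element size equals
#' the voxel spacing (0.096 mm^3 per element at 0.4 x 0.4 x 0.6 mm).
#'
#' @param mask a [label_mask()].
#' @param target_labels integer labels to mesh (default: all positive labels).
#' @return object of class `hex_mesh` with fields `nodes` (n x 3 world mm),
#'   `elements` (m x 8 node indices in the documented corner order),
#'   `element_to_voxel` (m x 3 voxel indices), `labels` (length m),
#'   `spacing`, `origin`, `grid_dim`.
#' @export
mask_to_hexmesh <- function(mask, target_labels = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask$labels)
  if (is.null(target_labels))
    target_labels <- setdiff(unique(as.vector(mask$labels)), 0L)
  sel <- which(mask$labels %in% target_labels)
  if (!length(sel)) stop("no voxels carry the requested labels",
                         call. = FALSE)
  ijk <- arrayInd(sel, d)
  nd <- d + 1L # corner lattice dims
  # node lattice linear ids for the 8 corners of each element
  conn <- matrix(0L, nrow = length(sel), ncol = 8L)
  for (c8 in 1:8) {
    o <- .hex_corner_offsets[c8, ]
    conn[, c8] <- (ijk[, 1] + o[1]) +
      (ijk[, 2] + o[2] - 1L) * nd[1] +
      (ijk[, 3] + o[3] - 1L) * nd[1] * nd[2]
  }
  used <- sort(unique(as.vector(conn)))
  remap <- integer(nd[1] * nd[2] * nd[3])
  remap[used] <- seq_along(used)
  elements <- matrix(remap[conn], ncol = 8L)
  cijk <- arrayInd(used, nd)
  nodes <- sweep(sweep(cijk - 1.5, 2L, mask$spacing, "*"), 2L,
                 mask$origin, "+")
  structure(list(nodes = nodes, elements = elements,
                 element_to_voxel = ijk,
                 labels = mask$labels[sel],
                 spacing = mask$spacing, origin = mask$origin,
                 grid_dim = d),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("<hex_mesh> ", nrow(x$elements), " hexahedral elements, ",
      nrow(x$nodes), " nodes, element volume ",
      format(prod(x$spacing), digits = 4), " mm^3\n", sep = "")
  invisible(x)
}

#' Element centroids in world coordinates
#' @param mesh a `hex_mesh`.
#' @return numeric matrix (m x 3), mm. Centroids coincide with the centers of
#'   the source voxels.
#' @export
element_centroids <- function(mesh) {
  sweep(sweep(mesh$element_to_voxel - 1, 2L, mesh$spacing, "*"), 2L,
        mesh$origin, "+")
}

#' Sample a displacement field at the mesh nodes
#'
#' The field is sampled at voxel centers; node positions (voxel corners) are
#' interpolated trilinearly from the surrounding centers, with clamped-edge
#' extrapolation outside the center lattice so no zero displacement is
#' fabricated at the mesh surface.
#'
#' @param field a [displacement_field()] on the grid the mesh was built from.
#' @param mesh a `hex_mesh`.
#' @return numeric matrix (n_nodes x 3) of nodal displacements in mm.
#' @export
sample_nodal_displacements <- function(field, mesh) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(mesh, "hex_mesh"))
  if (!all(dim(field$vectors)[1:3] == mesh$grid_dim) ||
      any(abs(field$spacing - mesh$spacing) > 1e-9) ||
      any(abs(field$origin - mesh$origin) > 1e-9))
    stop("field grid does not match the mesh's source grid", call. = FALSE)
  # continuous voxel-center coordinates of the nodes
  cc <- sweep(sweep(mesh$nodes, 2L, mesh$origin, "-"), 2L, mesh$spacing,
              "/") + 1
  out <- matrix(0, nrow(mesh$nodes), 3L)
  for (a in 1:3)
    out[, a] <- .interp3(field$vectors[, , , a], cc[, 1], cc[, 2], cc[, 3],
                         clamp = TRUE)
  out
}

#' Export a mesh as a plain node/element CSV pair
#'
#' Writes `<prefix>_nodes.csv` (node id, x, y, z in mm) and
#' `<prefix>_elements.csv` (element id, the 8 node ids in corner order, and
#' the element label).
#'
#' @param mesh a `hex_mesh`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_mesh_csv <- function(mesh, prefix) {
  np <- paste0(prefix, "_nodes.csv")
  ep <- paste0(prefix, "_elements.csv")
  nodes <- data.frame(node = seq_len(nrow(mesh$nodes)),
                      x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                      z = mesh$nodes[, 3])
  utils::write.csv(nodes, np, row.names = FALSE)
  el <- as.data.frame(mesh$elements)
  names(el) <- paste0("n", 1:8)
  el <- cbind(element = seq_len(nrow(el)), el, label = mesh$labels)
  utils::write.csv(el, ep, row.names = FALSE)
  invisible(c(np, ep))
}

#' Export a mesh (with optional per-element and per-node data) as legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid with hexahedron cells, any
#' per-element scalar arrays as CELL_DATA and nodal vectors as POINT_DATA.
#'
#' @param mesh a `hex_mesh`.
#' @param path output `.vtk` path.
#' @param cell_data named list of per-element numeric vectors.
#' @param point_vectors optional n_nodes x 3 matrix (e.g. displacements).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list(),
                           point_vectors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "hexahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], trim = TRUE), con)
    }
  }
  if (!is.null(point_vectors)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    utils::write.table(format(point_vectors, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
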