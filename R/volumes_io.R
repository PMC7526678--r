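# ---- raster containers -----------------------------------------------------
#
# All stages of the pipeline share one grid convention: voxel index (i, j, k)
# (1-based) has its CENTER at world position origin + (i-1, j-1, k-1) * spacing
# (mm).  Array axes are (x, y, z) = (sagittal, coronal, axial); the load axis
# is z.  Mesh nodes live on the corner lattice offset -spacing/2 from centers.

#' 3D scalar image volume
#'
#' The common raster substrate of the pipeline: a 3D array of intensities with
#' anisotropic voxel spacing and a world-space origin. The world coordinate of
#' voxel `(i, j, k)` (1-based) is `origin + (i-1, j-1, k-1) * spacing`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all `> 0`.
#' @param origin numeric length-3, world position (mm) of voxel `(1, 1, 1)`.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(0.4, 0.4, 0.6))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  .check_grid(data, spacing, origin, n_dim = 3L)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Integer label mask on an image grid
#'
#' Same grid contract as [image_volume()]; voxel values are non-negative
#' integer labels (0 = background).
#'
#' @param labels 3D integer array; 0 is background, positive values are
#'   anatomical labels.
#' @param spacing,origin grid description as in [image_volume()].
#' @param dictionary optional named integer vector declaring the label values
#'   in use, e.g. `c(BODY = 1, ARA = 2, PRA = 3)`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       dictionary = NULL) {
  .check_grid(labels, spacing, origin, n_dim = 3L)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("label values must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!is.null(dictionary)) {
    extra <- setdiff(unique(as.vector(labels)), c(0L, as.integer(dictionary)))
    if (length(extra))
      stop("labels outside the declared dictionary: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), dictionary = dictionary),
            class = "label_mask")
}

#' Dense 3D displacement field
#'
#' Per-voxel displacement vectors (mm) sampled at the voxel centers of the
#' unloaded (reference) grid. The convention throughout the package is that
#' `x + u(x)` maps a reference (unloaded) material point to its loaded
#' position, so strains derived from the field are material strains relative
#' to the unloaded state.
#'
#' @param vectors 4D numeric array `(nx, ny, nz, 3)` of displacements in mm.
#' @param spacing,origin grid description as in [image_volume()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("vectors must be a (nx, ny, nz, 3) array", call. = FALSE)
  .check_grid(vectors[, , , 1, drop = FALSE], spacing, origin, n_dim = 4L)
  if (!all(is.finite(vectors)))
    stop("displacement field contains non-finite values", call. = FALSE)
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

#' Region-of-interest crop box in voxel indices
#'
#' Half-open on the upper side: the crop keeps voxels with 1-based index
#' `i` satisfying `lower[a] < i <= upper[a]` when `lower`/`upper` are given as
#' 0-based bounds, i.e. voxels `lower + 1 .. upper` along each axis.
#'
#' @param lower,upper integer length-3, 0-based lower (inclusive) and upper
#'   (exclusive) voxel bounds with `lower < upper` componentwise.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("lower and upper must each have 3 components", call. = FALSE)
  if (any(lower < 0L) || any(lower >= upper))
    stop("need 0 <= lower < upper componentwise", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "roi_box")
}

.check_grid <- function(data, spacing, origin, n_dim) {
  if (length(dim(data)) != n_dim)
    stop("expected a ", n_dim - (n_dim == 4L), "D array payload", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(sort(unique(as.vector(x$labels))),
                                 collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(rowSums(matrix(x$vectors, ncol = 3L)^2))
  cat("<displacement_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " voxels, |u| max ", format(max(m), digits = 4), " mm\n", sep = "")
  invisible(x)
}

#' Grid dimensions of a volume-like object
#' @param x an `image_volume`, `label_mask` or `displacement_field`.
#' @return integer length-3 grid dimensions.
#' @export
grid_dim <- function(x) {
  if (inherits(x, "image_volume")) dim(x$data)
  else if (inherits(x, "label_mask")) dim(x$labels)
  else if (inherits(x, "displacement_field")) dim(x$vectors)[1:3]
  else stop("not a volume-like object", call. = FALSE)
}

#' World coordinates of voxel centers
#'
#' @param x a volume-like object.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of world positions in mm.
#' @export
voxel_to_world <- function(x, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  sweep(sweep(ijk - 1, 2L, x$spacing, "*"), 2L, x$origin, "+")
}

.same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

.payload <- function(x) {
  if (inherits(x, "image_volume")) x$data
  else if (inherits(x, "label_mask")) x$labels
  else x$vectors
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a 3D volume or displacement field from NIfTI
#'
#' Scalar payloads are returned as [image_volume()] (or [label_mask()] with
#' `as = "mask"`); 5D vector payloads with three components are returned as
#' [displacement_field()]. Grids must be axis-aligned: an xform with
#' off-diagonal rotation/shear terms is rejected rather than silently
#' reinterpreted, because the downstream geometry assumes axis-aligned voxels.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as one of `"auto"`, `"image"`, `"mask"`, `"field"`.
#' @return an `image_volume`, `label_mask` or `displacement_field`.
#' @export
read_volume <- function(path, as = c("auto", "image", "mask", "field")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  x <- RNifti::xform(img)
  off <- x[1:3, 1:3]; diag(off) <- 0
  if (any(abs(off) > 1e-4 * max(abs(diag(x[1:3, 1:3])))))
    stop("NIfTI grid is not axis-aligned; rotated/sheared headers are not ",
         "supported", call. = FALSE)
  spacing <- abs(diag(x[1:3, 1:3]))
  if (any(spacing <= 0)) stop("non-positive voxel spacing", call. = FALSE)
  origin <- x[1:3, 4]
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop RNifti attributes
  is_field <- length(d) == 5L && d[4] == 1L && d[5] == 3L
  if (length(d) == 4L && d[4] == 1L) { # degenerate 4th axis
    arr <- array(arr, dim = d[1:3]); d <- d[1:3]
  }
  if (as == "field" || (as == "auto" && is_field)) {
    if (!is_field) stop("not a 3-component vector NIfTI: ", path, call. = FALSE)
    return(displacement_field(array(arr, dim = c(d[1:3], 3L)), spacing, origin))
  }
  if (length(dim(arr)) != 3L)
    stop("expected a 3D scalar NIfTI, got ", length(d), "D: ", path,
         call. = FALSE)
  if (as == "mask")
    label_mask(array(as.integer(round(arr)), dim = dim(arr)), spacing, origin)
  else
    image_volume(arr, spacing, origin)
}

#' Write a volume, mask or displacement field to NIfTI
#'
#' Scalar volumes are written as 3D images; displacement fields as 5D NIfTI
#' vector images with three components. Spacing goes into `pixdim` and origin
#' into the (diagonal) qform/sform, so [read_volume()] round-trips `data`,
#' `spacing` and `origin`.
#'
#' @param vol an `image_volume`, `label_mask` or `displacement_field`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dirp <- dirname(path)
  if (!dir.exists(dirp)) stop("output directory does not exist: ", dirp,
                              call. = FALSE)
  if (inherits(vol, "displacement_field")) {
    v <- vol$vectors
    arr <- array(v, dim = c(dim(v)[1:3], 1L, 3L))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vol$spacing, 1, 1)
  } else {
    arr <- .payload(vol)
    if (inherits(vol, "label_mask")) storage.mode(arr) <- "integer"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
  }
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop a volume-like object to a region of interest
#'
#' The origin is shifted by `lower * spacing`, so world coordinates of
#' surviving voxels are unchanged; applying the same [roi_box()] to every load
#' case of one specimen keeps their grids congruent.
#'
#' @param vol an `image_volume`, `label_mask` or `displacement_field`.
#' @param roi an [roi_box()] lying inside the grid.
#' @return object of the same class on the cropped grid.
#' @export
crop_to_roi <- function(vol, roi) {
  stopifnot(inherits(roi, "roi_box"))
  d <- grid_dim(vol)
  if (any(roi$upper > d))
    stop("ROI exceeds grid dimensions (", paste(d, collapse = "x"), ")",
         call. = FALSE)
  ix <- (roi$lower[1] + 1L):roi$upper[1]
  iy <- (roi$lower[2] + 1L):roi$upper[2]
  iz <- (roi$lower[3] + 1L):roi$upper[3]
  origin <- vol$origin + roi$lower * vol$spacing
  if (inherits(vol, "displacement_field"))
    displacement_field(vol$vectors[ix, iy, iz, , drop = FALSE],
                       vol$spacing, origin)
  else if (inherits(vol, "label_mask"))
    label_mask(vol$labels[ix, iy, iz, drop = FALSE], vol$spacing, origin,
               dictionary = vol$dictionary)
  else
    image_volume(vol$data[ix, iy, iz, drop = FALSE], vol$spacing, origin)
}
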