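# Synthetic meniscus phantom: C-shaped wedge geometry, analytic deformation
# fields with known ground truth, MRI-like magnitude images, and a two-group
# cohort of characteristic strains for the statistics stage.

#' Label dictionary used by the phantom mask
#'
#' `BODY` is the meniscal body; `ARA`/`PRA` are the anterior/posterior root
#' attachments.
#' @return named integer vector.
#' @export
meniscus_labels <- function() c(BODY = 1L, ARA = 2L, PRA = 3L)

#' Geometry of the C-shaped wedge phantom
#'
#' A meniscus stand-in: an annular sector in the axial plane (the C shape)
#' whose height tapers linearly from `peripheral_height` at the outer rim to
#' `inner_height` at the inner rim (the wedge profile), plus two short angular
#' extensions at the open ends of the C standing in for the root attachments.
#'
#' Defaults approximate an adult medial meniscus sampled at the MR resolution
#' used throughout the package (0.4 x 0.4 x 0.6 mm voxels).
#'
#' @param center in-plane (x, y) position of the cylindrical origin, mm.
#' @param inner_radius,outer_radius annulus radii, mm (`0 < inner < outer`).
#' @param angular_span angular extent of the body in degrees (`< 360`).
#' @param attachment_span degrees allotted to each root attachment beyond the
#'   body ends.
#' @param peripheral_height,inner_height wedge heights at outer/inner rim, mm.
#' @param theta0 start angle of the body arc, degrees (counterclockwise from
#'   the +x axis viewed from proximal).
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param spacing,origin grid description as in [image_volume()].
#' @return object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(center = NULL,
                             inner_radius = 8, outer_radius = 17,
                             angular_span = 250, attachment_span = 15,
                             peripheral_height = 8, inner_height = 2,
                             theta0 = 55,
                             grid_shape = c(96L, 96L, 32L),
                             spacing = c(0.4, 0.4, 0.6),
                             origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(center))
    center <- origin[1:2] + (grid_shape[1:2] - 1) * spacing[1:2] / 2
  stopifnot(inner_radius > 0, inner_radius < outer_radius,
            angular_span > 0, angular_span < 360,
            attachment_span >= 0,
            inner_height > 0, inner_height <= peripheral_height)
  structure(list(center = as.numeric(center),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 angular_span = angular_span,
                 attachment_span = attachment_span,
                 peripheral_height = peripheral_height,
                 inner_height = inner_height,
                 theta0 = theta0, grid_shape = grid_shape,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "phantom_geometry")
}

# angular offset of theta from theta0, counterclockwise, in [0, 2*pi)
.ang_from <- function(theta, theta0) (theta - theta0) %% (2 * pi)

#' Rasterize the phantom geometry into a label mask
#'
#' A voxel is included when its center lies inside the annular sector and
#' within the local wedge height `h(r)` (centered on the grid's axial
#' mid-plane). Body voxels get label `BODY`; the angular extensions at the two
#' open ends get `ARA` (at the start angle) and `PRA` (at the end angle).
#'
#' @param geom a [phantom_geometry()].
#' @return a [label_mask()] with the [meniscus_labels()] dictionary.
#' @export
make_meniscus_mask <- function(geom) {
  stopifnot(inherits(geom, "phantom_geometry"))
  d <- geom$grid_shape
  if (geom$outer_radius >
      min((d[1:2] - 1) * geom$spacing[1:2]) / 2 + 1e-9) {
    ext <- (d[1:2] - 1) * geom$spacing[1:2]
    ctr_ok <- all(geom$center - geom$origin[1:2] >= geom$outer_radius - 1e-9) &&
      all(ext - (geom$center - geom$origin[1:2]) >= geom$outer_radius - 1e-9)
    if (!ctr_ok)
      stop("phantom outer radius exceeds the grid extent", call. = FALSE)
  }
  xs <- geom$origin[1] + (seq_len(d[1]) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  z_mid <- (zs[1] + zs[length(zs)]) / 2
  X <- array(xs, d); Y <- aperm(array(ys, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(zs, d[c(3, 1, 2)]), c(2, 3, 1))
  dx <- X - geom$center[1]; dy <- Y - geom$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  span <- geom$angular_span * pi / 180
  att <- geom$attachment_span * pi / 180
  th0 <- geom$theta0 * pi / 180
  dlt <- .ang_from(theta, th0)
  in_annulus <- r >= geom$inner_radius & r <= geom$outer_radius
  # wedge height at radius r
  w <- (r - geom$inner_radius) / (geom$outer_radius - geom$inner_radius)
  h <- geom$inner_height + (geom$peripheral_height - geom$inner_height) *
    pmin(pmax(w, 0), 1)
  in_height <- abs(Z - z_mid) <= h / 2
  lab <- meniscus_labels()
  out <- array(0L, d)
  body <- in_annulus & in_height & dlt <= span
  ara  <- in_annulus & in_height & dlt > 2 * pi - att
  pra  <- in_annulus & in_height & dlt > span & dlt <= span + att
  out[body] <- lab[["BODY"]]
  out[ara]  <- lab[["ARA"]]
  out[pra]  <- lab[["PRA"]]
  if (!any(out > 0L)) stop("phantom geometry produced an empty mask",
                           call. = FALSE)
  label_mask(out, geom$spacing, geom$origin, dictionary = lab)
}

#' Analytic deformation specification
#'
#' Ground-truth displacement fields used to deform the phantom and to
#' validate registration and strain recovery. Supported modes:
#' \describe{
#'   \item{affine}{`u(x) = A x + b`; parameters `A` (3x3), `b` (3).}
#'   \item{uniform_axial}{`u = (0, 0, eps * (z - z_ref))`; parameters
#'     `epsilon`, `z_ref` (mm).}
#'   \item{radial}{in-plane `u = alpha * (p - center)`; parameters `alpha`,
#'     `center` (2-vector, mm).}
#'   \item{rigid}{rotation by `angle` (radians, about the z axis through
#'     `center`) plus `translation` (3-vector, mm).}
#'   \item{gaussian_bump}{`u = amplitude * exp(-|x - center|^2 / (2 width^2))`;
#'     `amplitude` is a 3-vector in mm, `width` in mm.}
#'   \item{wedge_axial}{`u_z = profile(theta) * (z - z_ref)` with `profile` a
#'     function of the in-plane angle about `center` returning axial strain.}
#'   \item{composite}{`specs`: ordered list of deformation specs; fields add.}
#' }
#'
#' @param mode one of the modes above.
#' @param ... mode-specific parameters.
#' @return object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("affine", "uniform_axial", "radial",
                                      "rigid", "gaussian_bump", "wedge_axial",
                                      "composite"), ...) {
  mode <- match.arg(mode)
  p <- list(...)
  need <- switch(mode,
    affine = c("A", "b"),
    uniform_axial = c("epsilon", "z_ref"),
    radial = c("alpha", "center"),
    rigid = c("angle", "center", "translation"),
    gaussian_bump = c("center", "amplitude", "width"),
    wedge_axial = c("profile", "center", "z_ref"),
    composite = "specs")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("deformation_spec('", mode, "') needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(c(list(mode = mode), p), class = "deformation_spec")
}

#' Evaluate a deformation spec on a voxel grid
#'
#' The analytic field is evaluated at every voxel center of `grid`.
#'
#' @param spec a [deformation_spec()].
#' @param grid a volume-like object (or a `label_mask`) describing the grid.
#' @return a [displacement_field()] in mm.
#' @export
make_displacement <- function(spec, grid) {
  stopifnot(inherits(spec, "deformation_spec"))
  d <- grid_dim(grid)
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  X <- array(xs, d); Y <- aperm(array(ys, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(zs, d[c(3, 1, 2)]), c(2, 3, 1))
  u <- .eval_deformation(spec, X, Y, Z)
  vec <- array(0, c(d, 3L))
  vec[, , , 1] <- u$ux; vec[, , , 2] <- u$uy; vec[, , , 3] <- u$uz
  displacement_field(vec, grid$spacing, grid$origin)
}

# Evaluate at arbitrary world coordinates (arrays X, Y, Z of equal shape).
.eval_deformation <- function(spec, X, Y, Z) {
  zero <- X * 0
  switch(spec$mode,
    affine = {
      A <- spec$A; b <- spec$b
      list(ux = A[1, 1] * X + A[1, 2] * Y + A[1, 3] * Z + b[1],
           uy = A[2, 1] * X + A[2, 2] * Y + A[2, 3] * Z + b[2],
           uz = A[3, 1] * X + A[3, 2] * Y + A[3, 3] * Z + b[3])
    },
    uniform_axial = list(ux = zero, uy = zero,
                         uz = spec$epsilon * (Z - spec$z_ref)),
    radial = list(ux = spec$alpha * (X - spec$center[1]),
                  uy = spec$alpha * (Y - spec$center[2]), uz = zero),
    rigid = {
      ca <- cos(spec$angle); sa <- sin(spec$angle)
      dx <- X - spec$center[1]; dy <- Y - spec$center[2]
      list(ux = ca * dx - sa * dy + spec$center[1] + spec$translation[1] - X,
           uy = sa * dx + ca * dy + spec$center[2] + spec$translation[2] - Y,
           uz = zero + spec$translation[3])
    },
    gaussian_bump = {
      g <- exp(-((X - spec$center[1])^2 + (Y - spec$center[2])^2 +
                 (Z - spec$center[3])^2) / (2 * spec$width^2))
      list(ux = spec$amplitude[1] * g, uy = spec$amplitude[2] * g,
           uz = spec$amplitude[3] * g)
    },
    wedge_axial = {
      theta <- atan2(Y - spec$center[2], X - spec$center[1])
      eps <- array(spec$profile(as.vector(theta)), dim = dim(X))
      list(ux = zero, uy = zero, uz = eps * (Z - spec$z_ref))
    },
    composite = {
      acc <- list(ux = zero, uy = zero, uz = zero)
      for (s in spec$specs) {
        u <- .eval_deformation(s, X, Y, Z)
        acc$ux <- acc$ux + u$ux; acc$uy <- acc$uy + u$uy
        acc$uz <- acc$uz + u$uz
      }
      acc
    },
    stop("unknown deformation mode: ", spec$mode, call. = FALSE))
}

#' Warp an image with a displacement field (backward warping)
#'
#' The field follows the package convention `x + u(x)`: reference position to
#' deformed position. The warped ("loaded") image at voxel `x` therefore takes
#' the intensity of the input at the preimage `x'` with `x' + u(x') = x`,
#' found by fixed-point iteration, sampled trilinearly. Samples outside the
#' grid take `background`.
#'
#' @param vol an [image_volume()].
#' @param field a congruent [displacement_field()] (mm).
#' @param background fill value for out-of-grid samples.
#' @param iterations fixed-point iterations for the preimage.
#' @return a warped [image_volume()] on the same grid.
#' @export
warp_image <- function(vol, field, background = 0, iterations = 10L) {
  stopifnot(inherits(vol, "image_volume"),
            inherits(field, "displacement_field"))
  if (!.same_grid(vol, field))
    stop("image and field grids are not congruent", call. = FALSE)
  d <- dim(vol$data)
  sp <- vol$spacing
  # field in voxel units, per component
  uv <- field$vectors
  u1 <- uv[, , , 1] / sp[1]; u2 <- uv[, , , 2] / sp[2]
  u3 <- uv[, , , 3] / sp[3]
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  px <- g$x; py <- g$y; pz <- g$z
  for (i in seq_len(iterations)) {
    px <- g$x - .interp3(u1, px, py, pz, clamp = TRUE)
    py <- g$y - .interp3(u2, px, py, pz, clamp = TRUE)
    pz <- g$z - .interp3(u3, px, py, pz, clamp = TRUE)
  }
  out <- .interp3(vol$data, px, py, pz, fill = background)
  image_volume(array(out, d), vol$spacing, vol$origin)
}

#' Synthesize one phantom specimen: mask, unloaded image, loaded images
#'
#' The unloaded volume is a smooth intensity profile on the mask (a bright
#' tissue plateau with seeded smooth texture so registration has structure)
#' plus Rician noise, the standard noise model for magnitude MR images. Each
#' loaded volume is the unloaded volume warped by its ground-truth deformation
#' field plus fresh Rician noise. The same seed reproduces identical outputs.
#'
#' @param geom a [phantom_geometry()].
#' @param deformations named list of [deformation_spec()], one per load level
#'   (names are the load labels, e.g. `"BW25"`).
#' @param noise_sd Rician noise sigma, in intensity units (tissue plateau is
#'   1); 0 disables noise.
#' @param seed integer RNG seed.
#' @return list with `mask` ([label_mask()]), `unloaded` ([image_volume()])
#'   and `loaded`: a named list of `list(image, field)` per load level.
#' @export
synthesize_specimen <- function(geom, deformations, noise_sd = 0.02,
                                seed = 1L) {
  stopifnot(inherits(geom, "phantom_geometry"), is.list(deformations))
  mask <- make_meniscus_mask(geom)
  d <- dim(mask$labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tex <- .gauss3(array(stats::rnorm(prod(d)), d), 1.5)
  tex <- tex / max(abs(tex), 1e-12)
  base <- ifelse(mask$labels > 0L, 1.0, 0.15) + 0.25 * tex
  unloaded <- image_volume(base, mask$spacing, mask$origin)
  if (noise_sd > 0)
    unloaded$data <- .rician(unloaded$data, noise_sd)
  loaded <- lapply(deformations, function(spec) {
    fld <- make_displacement(spec, mask)
    img <- warp_image(image_volume(base, mask$spacing, mask$origin), fld,
                      background = 0.15)
    if (noise_sd > 0) img$data <- .rician(img$data, noise_sd)
    list(image = img, field = fld)
  })
  list(mask = mask, unloaded = unloaded, loaded = loaded)
}

.rician <- function(a, sd) {
  n <- length(a)
  sqrt((a + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- cohort generator ------------------------------------------------------

#' Specification of a synthetic two-group cohort
#'
#' Emulates a cadaver study with `n_per_group` mild and severe degenerated
#' knees, each contributing a medial and a lateral meniscus measured at three
#' load levels. Group means are the per-region, specimen-level mean
#' characteristic strains (in percent, at 100 % body weight); means at lower
#' loads scale linearly with the load fraction. Axial means are negative
#' (compression); circumferential and radial means positive (tension).
#'
#' @param n_per_group specimens per degeneration group (`>= 2`).
#' @param load_levels body-weight fractions, default `c(0.25, 0.5, 1)`.
#' @param group_means named list with elements `axial`, `circumferential`,
#'   `radial`, each `c(mild =, severe =)` in percent at full load.
#' @param group_sds matching standard deviations in percent (not scaled with
#'   load); zero gives the degenerate point-mass limit.
#' @param medial_lateral_split medial/lateral load fraction pair; enters as a
#'   scale factor `split / 0.5` on the per-side strain magnitudes.
#' @param zone_jitter_sd sd (percent) of the perturbation distinguishing the
#'   inner/outer zone rows of one region from the region-level draw.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12L,
                        load_levels = c(0.25, 0.5, 1),
                        group_means = list(
                          axial = c(mild = -3.1, severe = -7.3),
                          circumferential = c(mild = 0.35, severe = 0.45),
                          radial = c(mild = 0.37, severe = 0.41)),
                        group_sds = list(axial = 3.0,
                                         circumferential = 0.5,
                                         radial = 0.5),
                        medial_lateral_split = c(medial = 0.6, lateral = 0.4),
                        zone_jitter_sd = 0.2,
                        seed = 1L) {
  stopifnot(n_per_group >= 2L, all(load_levels > 0), all(load_levels <= 1),
            all(unlist(group_sds) >= 0), zone_jitter_sd >= 0)
  stopifnot(all(c("axial", "circumferential", "radial") %in%
                  names(group_means)))
  structure(list(n_per_group = as.integer(n_per_group),
                 load_levels = load_levels, group_means = group_means,
                 group_sds = group_sds,
                 medial_lateral_split = medial_lateral_split,
                 zone_jitter_sd = zone_jitter_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Anatomical region codes
#' @return character vector `ARA, AH, PI, PH, PRA`.
#' @export
meniscus_regions <- function() c("ARA", "AH", "PI", "PH", "PRA")

#' Draw a synthetic cohort table of characteristic strains
#'
#' One region-level characteristic strain is drawn per specimen, side, load,
#' region and direction from a normal distribution with the configured group
#' mean (scaled by load fraction and by the medial/lateral split factor) and
#' group sd. Body regions (AH, PI, PH) are emitted as an inner and an outer
#' zone row, each the region draw plus a small zone perturbation; root
#' attachments carry zone `"attachment"`.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` (the cohort table) with columns `specimen`, `group`,
#'   `kl_grade`, `side`, `load`, `region`, `zone`, `direction`, `strain_pct`.
#' @export
synthesize_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_per_group
  groups <- c("mild", "severe")
  specimens <- data.frame(
    specimen = sprintf("S%02d", seq_len(2L * n)),
    group = rep(groups, each = n),
    kl_grade = c(sample(1:2, n, replace = TRUE),
                 sample(3:4, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  sides <- names(spec$medial_lateral_split)
  regions <- meniscus_regions()
  dirs <- names(spec$group_means)
  key <- expand.grid(specimen = specimens$specimen, side = sides,
                     load = spec$load_levels, region = regions,
                     direction = dirs, stringsAsFactors = FALSE)
  key <- merge(key, specimens, by = "specimen", sort = FALSE)
  mu <- mapply(function(dir, grp, load, side) {
    spec$group_means[[dir]][[grp]] * load *
      (spec$medial_lateral_split[[side]] / 0.5)
  }, key$direction, key$group, key$load, key$side)
  sd <- vapply(key$direction, function(d) spec$group_sds[[d]], numeric(1))
  key$region_value <- stats::rnorm(nrow(key), mu, sd)
  body <- key$region %in% c("AH", "PI", "PH")
  att <- key[!body, ]
  att$zone <- "attachment"
  att$strain_pct <- att$region_value
  inner <- key[body, ]; outer <- key[body, ]
  inner$zone <- "inner"; outer$zone <- "outer"
  jit <- spec$zone_jitter_sd
  inner$strain_pct <- inner$region_value + stats::rnorm(nrow(inner), 0, jit)
  outer$strain_pct <- outer$region_value + stats::rnorm(nrow(outer), 0, jit)
  out <- rbind(att, inner, outer)
  out$region_value <- NULL
  out <- out[order(out$specimen, out$side, out$load,
                   match(out$region, regions), out$zone, out$direction), ]
  rownames(out) <- NULL
  out[, c("specimen", "group", "kl_grade", "side", "load", "region", "zone",
          "direction", "strain_pct")]
}
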