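# Per-meniscus cylindrical frame (circle fit to the outer rim) and the
# partition of mesh elements into the five anatomical regions
# (ARA, AH, PI, PH, PRA) and inner/outer zones.

#' Algebraic least-squares circle fit (Kasa)
#'
#' Fits `x^2 + y^2 = 2 a x + 2 b y + c` by linear least squares. Exact for
#' points lying exactly on a circle; for noisy data it is the standard
#' algebraic approximation to the geometric (distance-minimizing) fit.
#'
#' @param points numeric matrix (n x 2) of in-plane points, mm.
#' @return list with `center` (length 2) and `radius` (mm).
#' @export
fit_circle <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  M <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  fit <- tryCatch(qr.solve(M, rhs), error = function(e)
    stop("degenerate (collinear) points: circle fit is singular",
         call. = FALSE))
  qrM <- qr(M)
  if (qrM$rank < 3L)
    stop("degenerate (collinear) points: circle fit is singular",
         call. = FALSE)
  center <- fit[1:2]
  radius <- sqrt(fit[3] + sum(center^2))
  list(center = as.numeric(center), radius = radius)
}

#' Cylindrical coordinate frame of one meniscus
#'
#' The axis is the grid z axis (the load direction); `center` is the in-plane
#' origin, typically from [fit_circle()] on outer-rim points. Angles are
#' measured counterclockwise viewed from proximal (+z), in `(-pi, pi]`.
#'
#' @param center in-plane (x, y) origin, mm.
#' @param axis axial direction; must be the (possibly flipped) z axis.
#' @param radius_fit optional fitted circle radius, informational.
#' @return object of class `cyl_frame`.
#' @export
build_frame <- function(center, axis = c(0, 0, 1), radius_fit = NA_real_) {
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  if (abs(abs(axis[3]) - 1) > 1e-9)
    stop("the cylindrical axis must be the grid z axis", call. = FALSE)
  structure(list(center = as.numeric(center)[1:2], axis = axis,
                 radius_fit = radius_fit),
            class = "cyl_frame")
}

#' Cylindrical coordinates and local basis of world points
#'
#' @param frame a [build_frame()].
#' @param points numeric matrix (n x 3), world mm.
#' @return list with vectors `r`, `theta`, `z`, matrices `e_r`, `e_theta`
#'   (n x 3) and logical `on_axis` flagging points with `r` below `tol`
#'   where the in-plane basis is undefined.
#' @param tol radius below which a point counts as on-axis, mm.
#' @export
to_cylindrical <- function(frame, points, tol = 1e-9) {
  stopifnot(inherits(frame, "cyl_frame"))
  points <- matrix(points, ncol = 3L)
  dx <- points[, 1] - frame$center[1]
  dy <- points[, 2] - frame$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  on_axis <- r < tol
  ct <- ifelse(on_axis, NA_real_, dx / r)
  st <- ifelse(on_axis, NA_real_, dy / r)
  list(r = r, theta = theta, z = points[, 3],
       e_r = cbind(ct, st, 0), e_theta = cbind(-st, ct, 0),
       e_z = c(0, 0, 1), on_axis = on_axis)
}

#' Angular separation line between body and a root attachment
#'
#' Encodes the line from the cylindrical origin to a user-chosen point on the
#' outer circumference; only the angle matters.
#'
#' @param angle angle in radians, `(-pi, pi]`.
#' @param side `"anterior"` or `"posterior"`: which attachment the line cuts.
#' @return object of class `separation_line`.
#' @export
separation_line <- function(angle, side = c("anterior", "posterior")) {
  side <- match.arg(side)
  angle <- ((angle + pi) %% (2 * pi)) - pi
  structure(list(angle = angle, side = side), class = "separation_line")
}

# Angular offsets of element centroid angles from the anterior line, measured
# along the body orientation (the arc direction containing most elements).
# Returns offsets delta in [0, 2*pi), the body span delta_p, and the
# orientation sign.
.body_arc <- function(theta, line_a, line_p) {
  if (abs(((line_a$angle - line_p$angle) %% (2 * pi))) < 1e-12)
    stop("the two separation lines coincide", call. = FALSE)
  d_ccw <- (theta - line_a$angle) %% (2 * pi)
  span_ccw <- (line_p$angle - line_a$angle) %% (2 * pi)
  n_ccw <- sum(d_ccw <= span_ccw)
  d_cw <- (line_a$angle - theta) %% (2 * pi)
  span_cw <- (line_a$angle - line_p$angle) %% (2 * pi)
  n_cw <- sum(d_cw <= span_cw)
  if (n_ccw >= n_cw)
    list(delta = d_ccw, span = span_ccw, orientation = 1L)
  else
    list(delta = d_cw, span = span_cw, orientation = -1L)
}

#' Separate root attachments from the meniscal body
#'
#' Element membership is decided by the element CENTROID angle in the frame.
#' The body is the arc between the two separation lines (taken in the
#' orientation that contains the majority of elements); elements beyond the
#' anterior line are `ARA`, beyond the posterior line `PRA`.
#'
#' @param mesh a `hex_mesh`.
#' @param frame a [build_frame()].
#' @param line_a,line_p the anterior and posterior [separation_line()]s.
#' @return list with `region` (character per element: `ARA`, `PRA`, `BODY`),
#'   `delta` (centroid angle offsets along the body arc), `span` (body arc
#'   length, radians) and `orientation` (`+1` counterclockwise).
#' @export
separate_attachments <- function(mesh, frame, line_a, line_p) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(frame, "cyl_frame"),
            inherits(line_a, "separation_line"),
            inherits(line_p, "separation_line"))
  if (line_a$side == line_p$side)
    stop("need one anterior and one posterior separation line", call. = FALSE)
  if (line_a$side == "posterior") { tmp <- line_a; line_a <- line_p; line_p <- tmp }
  cyl <- to_cylindrical(frame, element_centroids(mesh))
  arc <- .body_arc(cyl$theta, line_a, line_p)
  if (arc$span < 1e-9) stop("empty body arc between the separation lines",
                            call. = FALSE)
  region <- rep("BODY", nrow(mesh$elements))
  beyond <- arc$delta > arc$span
  # distance past the posterior line vs past the anterior line (backwards)
  past_p <- arc$delta - arc$span
  past_a <- 2 * pi - arc$delta
  region[beyond & (past_a <= past_p)] <- "ARA"
  region[beyond & (past_a > past_p)] <- "PRA"
  list(region = region, delta = arc$delta, span = arc$span,
       orientation = arc$orientation)
}

#' Trisect the meniscal body into AH, PI and PH
#'
#' The internal angle between the two root attachments is divided by three;
#' the sub-region adjacent to the anterior attachment is `AH`, the middle
#' `PI` (pars intermedia), the one adjacent to the posterior attachment `PH`.
#'
#' @param separation result of [separate_attachments()].
#' @return character vector per element with `ARA`/`PRA` retained and `BODY`
#'   replaced by `AH`, `PI` or `PH`.
#' @export
trisect_body <- function(separation) {
  region <- separation$region
  body <- region == "BODY"
  if (!any(body)) stop("no body elements to trisect", call. = FALSE)
  t3 <- separation$span / 3
  d <- separation$delta[body]
  sub <- ifelse(d < t3, "AH", ifelse(d < 2 * t3, "PI", "PH"))
  region[body] <- sub
  region
}

#' Split body regions into inner and outer zones
#'
#' Per angular bin along the body arc, the local meniscal width is the radial
#' extent `[r_min, r_max]` of the body element centroids in the bin; elements
#' with normalized radial position `(r - r_min) / (r_max - r_min)` at or
#' below `inner_fraction` are the inner zone, the rest the outer zone.
#' Attachment elements always carry zone `"attachment"`.
#'
#' @param mesh a `hex_mesh`.
#' @param frame a [build_frame()].
#' @param separation result of [separate_attachments()].
#' @param inner_fraction fraction of the local width forming the inner zone;
#'   default 2/3.
#' @param angular_bin bin width in degrees for the local width estimate
#'   (360 reproduces a single global width).
#' @return character vector per element: `"inner"`, `"outer"` or
#'   `"attachment"`.
#' @export
split_zones <- function(mesh, frame, separation, inner_fraction = 2 / 3,
                        angular_bin = 5) {
  stopifnot(inner_fraction > 0, inner_fraction <= 1, angular_bin > 0)
  cyl <- to_cylindrical(frame, element_centroids(mesh))
  zone <- rep("attachment", nrow(mesh$elements))
  body <- separation$region == "BODY"
  if (!any(body)) return(zone)
  d <- separation$delta[body]
  r <- cyl$r[body]
  bw <- angular_bin * pi / 180
  bin <- pmin(floor(d / bw), ceiling(separation$span / bw) - 1)
  rmin <- stats::ave(r, bin, FUN = min)
  rmax <- stats::ave(r, bin, FUN = max)
  width <- rmax - rmin
  rho <- ifelse(width > 1e-12, (r - rmin) / width, 0)
  if (any(width <= 1e-12))
    warning("angular bin(s) with zero radial width: all their elements ",
            "assigned to the inner zone")
  zone[body] <- ifelse(rho <= inner_fraction + 1e-12, "inner", "outer")
  zone
}

#' Full regional labeling of a meniscus mesh
#'
#' Convenience wrapper running [separate_attachments()], [trisect_body()] and
#' [split_zones()] and returning a per-element region/zone labeling.
#'
#' @inheritParams split_zones
#' @inheritParams separate_attachments
#' @return object of class `region_labeling`: list with character vectors
#'   `region` (`ARA, AH, PI, PH, PRA`) and `zone`
#'   (`inner, outer, attachment`), one entry per element.
#' @export
label_regions <- function(mesh, frame, line_a, line_p,
                          inner_fraction = 2 / 3, angular_bin = 5) {
  sep <- separate_attachments(mesh, frame, line_a, line_p)
  region <- trisect_body(sep)
  zone <- split_zones(mesh, frame, sep, inner_fraction, angular_bin)
  structure(list(region = region, zone = zone), class = "region_labeling")
}

#' Auto-extract outer-rim points for the circle fit
#'
#' Replaces the manual point picking of an interactive workflow: per angular
#' bin (about the centroid of the body voxels), the outermost body element
#' centroid is returned as a rim point.
#'
#' @param mesh a `hex_mesh`.
#' @param body_labels element labels belonging to the body (default 1).
#' @param angular_bin bin width, degrees.
#' @return numeric matrix (n_bins x 2) of in-plane rim points, mm.
#' @export
outer_rim_points <- function(mesh, body_labels = 1L, angular_bin = 10) {
  cen <- element_centroids(mesh)
  sel <- mesh$labels %in% body_labels
  if (!any(sel)) stop("no body elements", call. = FALSE)
  p <- cen[sel, 1:2, drop = FALSE]
  mid <- colMeans(p)
  th <- atan2(p[, 2] - mid[2], p[, 1] - mid[1])
  r <- sqrt((p[, 1] - mid[1])^2 + (p[, 2] - mid[2])^2)
  bin <- floor((th + pi) / (angular_bin * pi / 180))
  keep <- unlist(lapply(split(seq_along(r), bin), function(i)
    i[which.max(r[i])]), use.names = FALSE)
  p[keep, , drop = FALSE]
}
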