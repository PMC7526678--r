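test_that("meniscus mask matches a brute-force per-voxel inclusion test", {
  geom <- phantom_geometry(grid_shape = c(32L, 32L, 12L),
                           inner_radius = 2.5, outer_radius = 5.5,
                           angular_span = 359.99, attachment_span = 0,
                           peripheral_height = 3.6, inner_height = 1.2)
  mask <- make_meniscus_mask(geom)
  d <- geom$grid_shape
  z_mid <- geom$origin[3] + (d[3] - 1) * geom$spacing[3] / 2
  n_brute <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- geom$origin + (c(i, j, k) - 1) * geom$spacing
    r <- sqrt(sum((p[1:2] - geom$center)^2))
    if (r < geom$inner_radius || r > geom$outer_radius) next
    w <- (r - geom$inner_radius) / (geom$outer_radius - geom$inner_radius)
    h <- geom$inner_height +
      (geom$peripheral_height - geom$inner_height) * w
    if (abs(p[3] - z_mid) <= h / 2) n_brute <- n_brute + 1L
  }
  # full annulus: angular test passes everywhere (span ~ 360, no attachments)
  expect_equal(sum(mask$labels > 0L), n_brute)
})

test_that("mask shrinks monotonically with a thinner annulus", {
  full <- make_meniscus_mask(small_geom(angular_span = 359.99,
                                        attachment_span = 0))
  thin <- make_meniscus_mask(small_geom(angular_span = 359.99,
                                        attachment_span = 0,
                                        inner_radius = 7.2))
  expect_gt(sum(thin$labels > 0L), 0L)
  expect_lt(sum(thin$labels > 0L), sum(full$labels > 0L))
})

test_that("mask is mirror-symmetric about the mid-span plane", {
  # symmetric grid, symmetric geometry: reflecting the voxel grid about the
  # bisector of the C must reproduce the mask
  geom <- phantom_geometry(grid_shape = c(41L, 41L, 11L),
                           spacing = c(0.5, 0.5, 0.5),
                           inner_radius = 3, outer_radius = 8,
                           angular_span = 180, attachment_span = 20,
                           peripheral_height = 4, inner_height = 1,
                           theta0 = 0)  # C spans [0, 180], bisector = y axis
  mask <- make_meniscus_mask(geom)
  # reflection about the vertical bisector x -> -x maps theta -> pi - theta:
  # the geometry maps onto itself with the two attachments exchanged
  flipped <- mask$labels[rev(seq_len(41)), , ]
  lab <- meniscus_labels()
  expect_equal(flipped > 0L, mask$labels > 0L)
  expect_equal(flipped == lab[["BODY"]], mask$labels == lab[["BODY"]])
  expect_equal(flipped == lab[["ARA"]], mask$labels == lab[["PRA"]])
})

test_that("analytic deformation fields match their closed forms", {
  grid <- image_volume(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  # uniform axial: u_z = eps * (z - z_ref)
  f <- make_displacement(deformation_spec("uniform_axial", epsilon = -0.05,
                                          z_ref = 0), grid)
  expect_equal(f$vectors[3, 4, 8, 3], -0.05 * (7 * 0.5))
  expect_true(all(f$vectors[, , , 1:2] == 0))
  # rigid identity
  f0 <- make_displacement(deformation_spec("rigid", angle = 0,
                                           center = c(0, 0),
                                           translation = c(0, 0, 0)), grid)
  expect_true(all(f0$vectors == 0))
  # composite additivity at random voxels
  s1 <- deformation_spec("radial", alpha = 0.01, center = c(1.2, 0.7))
  s2 <- deformation_spec("uniform_axial", epsilon = -0.03, z_ref = 0.4)
  fc <- make_displacement(deformation_spec("composite", specs = list(s1, s2)),
                          grid)
  f1 <- make_displacement(s1, grid)
  f2 <- make_displacement(s2, grid)
  set.seed(42)
  idx <- cbind(sample(8, 100, TRUE), sample(8, 100, TRUE),
               sample(8, 100, TRUE), sample(3, 100, TRUE))
  expect_equal(fc$vectors[idx], f1$vectors[idx] + f2$vectors[idx],
               tolerance = 1e-12)
  expect_error(make_displacement(structure(list(mode = "nope"),
                                           class = "deformation_spec"), grid))
})

test_that("affine fields interpolate exactly (trilinear affine exactness)", {
  grid <- image_volume(array(0, c(10, 9, 8)), spacing = c(0.4, 0.4, 0.6),
                       origin = c(-1, 2, 0.5))
  A <- matrix(c(0.01, 0.002, 0, -0.003, 0.02, 0.001, 0, 0.004, -0.05), 3,
              byrow = TRUE)
  b <- c(0.1, -0.2, 0.3)
  f <- make_displacement(deformation_spec("affine", A = A, b = b), grid)
  set.seed(7)
  for (rep in 1:20) {
    p_vox <- c(runif(1, 1, 10), runif(1, 1, 9), runif(1, 1, 8))
    world <- grid$origin + (p_vox - 1) * grid$spacing
    truth <- as.vector(A %*% world + b)
    got <- vapply(1:3, function(a)
      point_trilinear(f$vectors[, , , a], p_vox), numeric(1))
    expect_equal(got, truth, tolerance = 1e-12)
  }
})

test_that("warping reproduces identity, integer shifts and analytic warps", {
  sp <- c(0.5, 0.5, 0.5)
  img <- image_volume(array(rnorm(20^3), c(20, 20, 20)), spacing = sp)
  zero <- displacement_field(array(0, c(20, 20, 20, 3)), spacing = sp)
  expect_equal(warp_image(img, zero)$data, img$data, tolerance = 1e-12)

  # constant field of exactly +2 voxels along x shifts the content
  piece <- image_volume(array(rep(c(0, 1), each = 10 * 20 * 20),
                              c(20, 20, 20)), spacing = sp)
  vec <- array(0, c(20, 20, 20, 3)); vec[, , , 1] <- 2 * sp[1]
  shift <- displacement_field(vec, spacing = sp)
  wr <- warp_image(piece, shift, background = 0)
  # x + u maps reference to deformed: content moves +2 voxels
  expect_equal(wr$data[5:20, , ], piece$data[3:18, , ], tolerance = 1e-9)

  # smooth bump on a smooth image agrees with the analytic warped image
  d <- c(24, 24, 24)
  xs <- (seq_len(d[1]) - 1) * sp[1]
  img_fun <- function(x, y, z) sin(x) + cos(1.3 * y) + 0.5 * sin(0.7 * z)
  X <- array(xs, d)
  Y <- aperm(array(xs, d), c(2, 1, 3))
  Z <- aperm(array(xs, d), c(3, 2, 1))
  smooth <- image_volume(img_fun(X, Y, Z), spacing = sp)
  bump <- deformation_spec("gaussian_bump", center = c(5.75, 5.75, 5.75),
                           amplitude = c(0.3, -0.2, 0.25), width = 2.5)
  fld <- make_displacement(bump, smooth)
  warped <- warp_image(smooth, fld, background = NA)
  # analytic oracle: for each deformed voxel x find the preimage by dense
  # root search along the (small) displacement and evaluate the image there
  set.seed(3)
  err <- c()
  for (rep in 1:30) {
    i <- sample(6:18, 3, TRUE)
    x_def <- (i - 1) * sp
    p <- x_def
    for (k in 1:50) p <- x_def - (unlist(meniscusstrain:::.eval_deformation(
      bump, p[1], p[2], p[3])) |> unname())
    err <- c(err, abs(warped$data[i[1], i[2], i[3]] -
                        img_fun(p[1], p[2], p[3])))
  }
  # trilinear interpolation error on this grid is O(h^2 * |f''|) ~ 3e-2
  expect_lt(stats::median(err), 4e-2)
  expect_lt(max(err), 1e-1)
})

test_that("specimen synthesis is deterministic and respects prescribed strain ratios", {
  geom <- small_geom()
  specs <- list(
    BW25 = deformation_spec("uniform_axial", epsilon = -0.01, z_ref = 0),
    BW50 = deformation_spec("uniform_axial", epsilon = -0.015, z_ref = 0),
    BW100 = deformation_spec("uniform_axial", epsilon = -0.03, z_ref = 0))
  a <- synthesize_specimen(geom, specs, noise_sd = 0.02, seed = 9)
  b <- synthesize_specimen(geom, specs, noise_sd = 0.02, seed = 9)
  expect_identical(a$unloaded$data, b$unloaded$data)
  expect_identical(a$loaded$BW100$image$data, b$loaded$BW100$image$data)

  # noise-free identity deformation: loaded equals unloaded
  idn <- synthesize_specimen(geom, list(BW25 = deformation_spec(
    "rigid", angle = 0, center = c(0, 0), translation = c(0, 0, 0))),
    noise_sd = 0, seed = 1)
  expect_equal(idn$loaded$BW25$image$data, idn$unloaded$data,
               tolerance = 1e-9)

  # ground-truth mean axial strain over the mask scales 1 : 1.5 : 3
  msk <- a$mask$labels > 0L
  mean_ezz <- vapply(a$loaded, function(l) {
    u <- l$field$vectors[, , , 3]
    # prescribed uniform strain: recover from the linear profile
    zs <- (seq_len(dim(u)[3]) - 1) * geom$spacing[3]
    du <- apply(u, 3, mean)
    stats::coef(stats::lm(du ~ zs))[[2]]
  }, numeric(1))
  expect_equal(unname(mean_ezz / mean_ezz[1]), c(1, 1.5, 3),
               tolerance = 1e-6)
})

test_that("cohort generator: determinism, degenerate sds, sign convention", {
  a <- synthesize_cohort(cohort_spec(seed = 5))
  b <- synthesize_cohort(cohort_spec(seed = 5))
  expect_identical(a, b)
  expect_equal(nrow(a), 2 * 12 * 2 * 3 * 3 * (2 + 3 * 2))
  expect_setequal(unique(a$region), meniscus_regions())

  # sd -> 0 limit: every specimen's value equals its (scaled) group mean
  tiny <- cohort_spec(group_sds = list(axial = 1e-9, circumferential = 1e-9,
                                       radial = 1e-9),
                      zone_jitter_sd = 1e-12, seed = 2)
  t0 <- synthesize_cohort(tiny)
  ax <- t0[t0$direction == "axial" & t0$load == 1 & t0$side == "medial", ]
  expect_equal(unique(round(ax$strain_pct[ax$group == "mild"], 6)),
               -3.1 * 1.2)
  expect_equal(unique(round(ax$strain_pct[ax$group == "severe"], 6)),
               -7.3 * 1.2)
  # axial compression is negative, circumferential/radial tension positive
  expect_true(all(t0$strain_pct[t0$direction == "axial"] < 0))
  expect_true(all(t0$strain_pct[t0$direction != "axial"] > 0))
})

test_that("group statistics are invariant to permuting specimen ids within groups", {
  tab <- synthesize_cohort(cohort_spec(seed = 31))
  mild_ids <- unique(tab$specimen[tab$group == "mild"])
  set.seed(1)
  perm <- setNames(sample(mild_ids), mild_ids)
  tab2 <- tab
  sel <- tab2$specimen %in% mild_ids
  tab2$specimen[sel] <- perm[tab2$specimen[sel]]
  sub <- function(t) {
    s <- t[t$direction == "axial" & t$load == 1 & t$region == "PI" &
             t$side == "medial" & t$zone == "inner", ]
    list(mild = s$strain_pct[s$group == "mild"],
         severe = s$strain_pct[s$group == "severe"])
  }
  x <- sub(tab); y <- sub(tab2)
  expect_equal(mann_whitney(x$mild, x$severe)$p,
               mann_whitney(y$mild, y$severe)$p)
})
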