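test_that("make_mesh produces watertight genus-0 meshes with the right geometry", {
  sph <- make_mesh("ellipsoid", c(1, 1, 1), subdivisions = 2)
  expect_equal(sqrt(rowSums(sph$vertices^2)), rep(1, nrow(sph$vertices)),
               tolerance = 1e-6)
  ell <- make_mesh("ellipsoid", c(3, 2, 1), subdivisions = 3)
  expect_equal(apply(ell$vertices, 2, range), cbind(c(-3, 3), c(-2, 2), c(-1, 1)),
               tolerance = 1e-6)
  for (m in list(sph, ell, make_mesh("superellipsoid", c(2, 1, 1), 2))) {
    V <- nrow(m$vertices); F_ <- nrow(m$faces); E <- nrow(morphoqtl:::mesh_edges(m))
    expect_equal(V - E + F_, 2)  # Euler characteristic of a closed genus-0 mesh
  }
  ## vertex count grows with subdivisions
  expect_gt(nrow(make_mesh("ellipsoid", c(1, 1, 1), 3)$vertices),
            nrow(sph$vertices))
  expect_error(make_mesh("ellipsoid", c(1, 0, 1)), "positive")
})

test_that("project_to_mesh handles face/edge/vertex cases and matches the
           independent brute-force oracle", {
  mesh <- make_mesh("ellipsoid", c(1.5, 1, 0.7), subdivisions = 1)
  ## a point on a face projects to itself
  f1 <- mesh$faces[1, ]
  centroid <- colMeans(mesh$vertices[f1, ])
  pr <- project_to_mesh(centroid, mesh)
  expect_equal(pr$distance, 0, tolerance = 1e-12)
  expect_equal(pr$points[1, ], centroid, tolerance = 1e-12)
  ## a point along the outward normal of a face centroid
  e1 <- mesh$vertices[f1[2], ] - mesh$vertices[f1[1], ]
  e2 <- mesh$vertices[f1[3], ] - mesh$vertices[f1[1], ]
  nrm <- morphoqtl:::crossprod3(e1, e2)
  nrm <- nrm / sqrt(sum(nrm^2)) * sign(sum(nrm * centroid))
  pr2 <- project_to_mesh(centroid + 0.05 * nrm, mesh)
  expect_equal(pr2$distance, 0.05, tolerance = 1e-9)
  expect_equal(pr2$points[1, ], centroid, tolerance = 1e-9)
  ## random points vs brute force
  set.seed(99)
  pts <- matrix(rnorm(60, sd = 1.5), 20, 3)
  got <- project_to_mesh(pts, mesh)
  want <- oracle_project_to_mesh(pts, mesh)
  expect_equal(got$distance, want$distance, tolerance = 1e-9)
  expect_equal(got$points, want$points, tolerance = 1e-7)
})

test_that("poisson-disk template respects the minimum distance and packing bounds", {
  sph <- make_mesh("ellipsoid", c(1, 1, 1), subdivisions = 3)
  fixed <- diag(3)  # three orthogonal surface points
  tpl <- poisson_disk_template(sph, fixed, radius = 0.5, seed = 7)
  cfg <- tpl$reference_config
  semis <- cfg[!attr(cfg, "fixed"), , 1]
  dd <- as.matrix(dist(semis))
  expect_gte(min(dd[upper.tri(dd)]), 0.5)
  ## spherical-cap packing bound: disjoint caps of half-angle asin(0.25)
  ## around each point cannot exceed the sphere area
  cap <- 2 * pi * (1 - cos(asin(0.25)))
  expect_gte(nrow(semis), 10)
  expect_lte(nrow(semis), floor(4 * pi / cap))
  ## all semilandmarks on the surface
  expect_lt(max(abs(sqrt(rowSums(semis^2)) - 1)), 0.02)
  ## target_count mode gets within ~15%
  tpl2 <- poisson_disk_template(sph, fixed, target_count = 60, seed = 3)
  ns <- sum(!attr(tpl2$reference_config, "fixed"))
  expect_gt(ns, 60 * 0.85)
  expect_lt(ns, 60 * 1.15)
})

test_that("template transfer reproduces the reference and follows affine maps", {
  sph <- make_mesh("ellipsoid", c(1, 1, 1), subdivisions = 3)
  set.seed(5)
  fixed <- sph$vertices[sample(nrow(sph$vertices), 8), ]
  tpl <- poisson_disk_template(sph, fixed, radius = 0.45, seed = 2)
  ## identity transfer
  back <- transfer_template(tpl, fixed, sph)
  expect_lt(max(abs(back[, , 1] - tpl$reference_config[, , 1])), 1e-6)
  ## affine (anisotropic scaling) target
  S <- diag(c(1.4, 0.9, 1.1))
  tgt_mesh <- tri_mesh(sph$vertices %*% S, sph$faces)
  out <- transfer_template(tpl, fixed %*% S, tgt_mesh)
  want <- tpl$reference_config[, , 1] %*% S
  edge <- mean(sqrt(rowSums((sph$vertices[sph$faces[, 1], ] -
                               sph$vertices[sph$faces[, 2], ])^2)))
  expect_lt(mean(sqrt(rowSums((out[, , 1] - want)^2))), 0.02 * edge)
  ## all output semilandmarks lie on the target mesh
  prd <- project_to_mesh(out[, , 1], tgt_mesh)$distance
  expect_lt(max(prd), 1e-6 * max(apply(tgt_mesh$vertices, 2, function(v) diff(range(v)))))
})

test_that("bending-energy sliding lowers the objective and fixes landmarks", {
  sph <- make_mesh("ellipsoid", c(1, 1, 1), subdivisions = 3)
  set.seed(8)
  fixed <- sph$vertices[sample(nrow(sph$vertices), 10), ]
  tpl <- poisson_disk_template(sph, fixed, radius = 0.4, seed = 4)
  ref_cfg <- tpl$reference_config
  ## target = reference: no sliding displacement
  sl0 <- slide_semilandmarks(ref_cfg, ref_cfg, sph, iters = 2)
  expect_lt(max(abs(sl0$config[, , 1] - ref_cfg[, , 1])), 1e-6)
  ## rotated semilandmark starts on the same sphere: sliding must reduce the
  ## bending energy against the unslid baseline
  th <- 0.25
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  start <- ref_cfg[, , 1]
  fmask <- attr(ref_cfg, "fixed")
  start[!fmask, ] <- start[!fmask, ] %*% Rz
  start_ls <- landmark_sample(start, fixed = fmask)
  sl <- slide_semilandmarks(ref_cfg, start_ls, sph, iters = 3)
  expect_gt(sl$energy0, 0)
  expect_lt(sl$energy[1], sl$energy0)
  ## within-iteration non-increase (pre-projection vs entering energy)
  expect_true(all(sl$energy <= sl$energy_in + 1e-8))
  ## final energy strictly below the unslid baseline
  expect_lt(min(sl$energy), 0.9 * sl$energy0)
  ## fixed landmarks immobile
  expect_equal(sl$config[fmask, , 1], start[fmask, ], tolerance = 1e-12)
})

test_that("signed surface distance: zero on identity, radius gap on spheres,
           sign flips with orientation", {
  s1 <- make_mesh("ellipsoid", c(1, 1, 1), subdivisions = 2)
  expect_equal(signed_surface_distance(s1, s1), rep(0, nrow(s1$vertices)))
  s2 <- make_mesh("ellipsoid", c(1.1, 1.1, 1.1), subdivisions = 2)
  d12 <- signed_surface_distance(s1, s2)
  expect_lt(max(abs(d12 - 0.1)), 0.015)
  expect_true(all(d12 > 0))
  s1f <- tri_mesh(s1$vertices, s1$faces, normals = -vertex_normals(s1))
  expect_equal(signed_surface_distance(s1f, s2), -d12, tolerance = 1e-12)
})
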