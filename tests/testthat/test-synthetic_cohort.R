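test_that("config validates its parameters", {
  expect_error(synth_config(spacing = 0), "spacing")
  expect_error(synth_config(wavelength = -1), "wavelength")
  expect_error(synth_config(sigma = 0), "sigma")
  expect_error(synth_config(n = -1), "n must be")
  expect_error(synth_config(phase_sd = -0.1), "jitter")
})

test_that("a zero-amplitude fold is a flat sheet with straight-down normals", {
  cfg <- synth_config(x_extent = 5, y_extent = 4, amplitude = 0)
  surf <- make_folded_surfaces(cfg)
  expect_true(all(surf$mid$vertices[, 3] == 0))
  expect_true(all(surf$pial$vertices[, 3] == cfg$thickness / 2))
  expect_equal(surf$analytic_normals,
               matrix(rep(c(0, 0, -1), each = nrow(surf$mid$vertices)), ncol = 3))
})

test_that("averaging pial and white reproduces the analytic mid surface", {
  surf <- make_folded_surfaces(synth_config(x_extent = 10, y_extent = 5))
  mid <- build_midsurface(surf$pial, surf$white)
  expect_lt(max(abs(mid$vertices - surf$mid$vertices)), 1e-9)
})

test_that("mesh normals track the analytic fold normals", {
  surf <- make_folded_surfaces(synth_config())
  mid <- compute_inner_normals(build_midsurface(surf$pial, surf$white))
  dev <- acos(pmin(1, pmax(-1, rowSums(mid$normals * surf$analytic_normals))))
  expect_lt(max(dev) * 180 / pi, 2)
})

test_that("uniform field volumes hold the stated vector everywhere", {
  f <- make_uniform_field(c(0, 0, -0.4), c(4, 3, 2), diag(4))
  expect_true(all(f$vectors[, , , 3] == -0.4))
  expect_true(all(f$vectors[, , , 1:2] == 0))
  mesh <- surface_mesh(rbind(c(1, 1, 1), c(2.2, 0.4, 0.9)),
                       matrix(integer(0), 0, 3))
  s <- sample_nearest(f, mesh)
  expect_equal(s$vectors, matrix(rep(c(0, 0, -0.4), each = 2), ncol = 3))
  expect_error(make_uniform_field(c(0, 0, 0), c(2, 2, 2), diag(4)), "nonzero")
})

test_that("point-pair field matches the independent closed form at the midpoint", {
  # sources 2d apart on x: |E| at midpoint = I/(2 pi sigma d^2), SI units
  d_m <- 0.05
  I_A <- 2e-3
  sigma <- 0.276
  oracle <- I_A / (2 * pi * sigma * d_m^2)
  E <- point_pair_field(rbind(c(0, 0, 0)), c(-50, 0, 0), c(50, 0, 0),
                        current = 2, sigma = 0.276)
  expect_equal(E[1, 1], oracle, tolerance = 1e-12)
  expect_equal(E[1, 2:3], c(0, 0))
  expect_equal(signif(E[1, 1], 4), 0.4613)
})

test_that("field is purely axial on the perpendicular bisector plane", {
  set.seed(66)
  pts <- cbind(0, runif(20, -30, 30), runif(20, -30, 30))
  E <- point_pair_field(pts, c(-25, 0, 0), c(25, 0, 0))
  expect_true(all(abs(E[, 2:3]) < 1e-15))
  expect_true(all(E[, 1] > 0))   # current runs from the anode toward the cathode
})

test_that("E agrees with minus the numerical gradient of the potential", {
  # independent oracle: potential of the pair, differentiated centrally
  phi <- function(p, ra, rc, I_A, sigma) {
    I_A / (4 * pi * sigma) * (1 / sqrt(sum((p - ra)^2)) - 1 / sqrt(sum((p - rc)^2)))
  }
  ra <- c(-30, 5, 10) / 1000; rc <- c(40, -10, 15) / 1000
  I_A <- 2e-3; sigma <- 0.276
  set.seed(77)
  pts <- matrix(runif(30, -20, 20), ncol = 3)
  E <- point_pair_field(pts, ra * 1000, rc * 1000, current = 2, sigma = sigma)
  h <- 1e-6
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ] / 1000
    grad <- vapply(1:3, function(ax) {
      dp <- rep(0, 3); dp[ax] <- h
      (phi(p + dp, ra, rc, I_A, sigma) - phi(p - dp, ra, rc, I_A, sigma)) / (2 * h)
    }, 1)
    expect_lt(sqrt(sum((E[i, ] + grad)^2)) / sqrt(sum(grad^2)), 1e-3)
  }
})

test_that("voxels inside the exclusion radius carry a zero vector", {
  cfg <- synth_config(exclusion_radius = 2)
  f <- make_point_pair_field(cfg, c(5, 5, 5), c(100, 100, 100),
                             c(11, 11, 11), diag(4))
  expect_true(all(f$vectors[6, 6, 6, ] == 0))   # voxel at the source
  expect_true(all(f$vectors[6, 6, 4, ] == 0))   # 2 mm away: still excluded
  expect_false(all(f$vectors[6, 6, 2, ] == 0))  # 4 mm away: live
  expect_error(point_pair_field(rbind(c(0, 0, 0)), c(1, 1, 1), c(2, 2, 2),
                                sigma = -1), "sigma")
})

test_that("cohorts are reproducible, sized, and jitter as configured", {
  cfg <- synth_config(n = 2, x_extent = 8, y_extent = 4, spacing = 2, seed = 99)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1, c2)
  expect_length(make_cohort(synth_config(n = 0)), 0L)
  frozen <- synth_config(n = 3, x_extent = 8, y_extent = 4, spacing = 2,
                         phase_sd = 0, amplitude_sd = 0)
  c3 <- make_cohort(frozen)
  expect_identical(c3[[1]]$pial$vertices, c3[[2]]$pial$vertices)
  expect_identical(c3[[2]]$pial$vertices, c3[[3]]$pial$vertices)
  # jittered cohorts differ across subjects
  expect_false(identical(c1[[1]]$pial$vertices, c1[[2]]$pial$vertices))
  # seeds track each subject's own fold: bank seed sits at z ~ 0 on the wall
  expect_lt(abs(c1[[1]]$seeds$z[1]), 1e-9)
  expect_equal(c1[[1]]$seeds$z[2], c1[[1]]$amplitude)
})

test_that("icospheres are unit-radius and wound outward", {
  sph <- make_icosphere(2, radius = 3, center = c(1, 0, 0))
  r <- sqrt(rowSums(sweep(sph$vertices, 2, c(1, 0, 0), "-")^2))
  expect_lt(max(abs(r - 3)), 1e-12)
  V <- sph$vertices; F <- sph$faces
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  centroid <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  outward <- rowSums(fn * sweep(centroid, 2, c(1, 0, 0), "-"))
  expect_true(all(outward > 0))
})

test_that("written cohorts exercise the pipeline's own readers", {
  cfg <- synth_config(n = 1, x_extent = 8, y_extent = 4, spacing = 2,
                      amplitude = 4, wavelength = 16, seed = 5)
  cohort <- make_cohort(cfg)
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_cohort(cohort, dir, surface_format = "off")
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  expect_identical(nrow(man), 3L)   # one row per montage
  pial <- read_surface(man$pial[1], format = "off")
  expect_lt(max(abs(pial$vertices - cohort[[1]]$pial$vertices)), 1e-6)
  field <- read_field_nifti(man$field[1])
  expect_equal(field$vectors, cohort[[1]]$fields[[man$montage[1]]]$vectors)
  m <- read_montage(man$montage_file[1])
  expect_equal(m$anode_center, cohort[[1]]$montages[[man$montage[1]]]$anode_center)
})
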