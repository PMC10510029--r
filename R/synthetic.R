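#' Configuration for the synthetic folded-cortex cohort
#'
#' The synthetic stand-in for a surface-reconstruction + field-modelling
#' study: a sinusoidally folded cortical sheet with closed-form normals,
#' and analytic current fields from point source/sink pairs in an infinite
#' homogeneous conductor.  The mid surface is
#' `z = A * sin(2*pi*x/lambda + phi)` over a rectangular grid; pial and
#' white surfaces are offset by half the cortical thickness along the
#' outer analytic normal.  With the default phase the central "sulcus"
#' trough lies at `x = 0`, the sulcal banks (maximal slope) at
#' `x = -lambda/4` (M1-like, "precentral") and `x = +lambda/4` (S1-like),
#' and the gyral crowns at `x = -lambda/2` and `x = +lambda/2`.  The grid
#' boundary columns sit on inflection lines of the fold, where one-sided
#' normal stencils are exact to second order.
#'
#' @param x_extent,y_extent half-extents of the grid (mm).
#' @param spacing grid spacing (mm, > 0).
#' @param amplitude fold amplitude A (mm).
#' @param wavelength fold wavelength lambda (mm, > 0).
#' @param thickness cortical thickness t (mm, >= 0).
#' @param phase fold phase phi (rad).
#' @param sigma tissue conductivity (S/m, > 0; grey-matter default 0.276).
#' @param current injected current (mA, default 2).
#' @param voxel_size field-volume voxel edge (mm).
#' @param exclusion_radius source exclusion radius, in voxels.
#' @param n cohort size (>= 0, default 20).
#' @param phase_sd,amplitude_sd inter-subject jitter: standard deviations
#'   of normal jitter on `phase` (rad) and `amplitude` (mm).
#' @param seed RNG seed for [make_cohort()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(x_extent = 45, y_extent = 15, spacing = 1,
                         amplitude = 15, wavelength = 60, thickness = 2.5,
                         phase = -pi / 2, sigma = 0.276, current = 2,
                         voxel_size = 1, exclusion_radius = 2,
                         n = 20, phase_sd = 0.2, amplitude_sd = 1.5,
                         seed = 1L) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (wavelength <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (thickness < 0) stop("thickness must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (voxel_size <= 0) stop("voxel_size must be > 0", call. = FALSE)
  if (n < 0) stop("cohort size n must be >= 0", call. = FALSE)
  if (phase_sd < 0 || amplitude_sd < 0)
    stop("jitter standard deviations must be >= 0", call. = FALSE)
  structure(list(x_extent = x_extent, y_extent = y_extent, spacing = spacing,
                 amplitude = amplitude, wavelength = wavelength,
                 thickness = thickness, phase = phase, sigma = sigma,
                 current = current, voxel_size = voxel_size,
                 exclusion_radius = exclusion_radius, n = n,
                 phase_sd = phase_sd, amplitude_sd = amplitude_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

fold_inner_normal <- function(x, config) {
  # analytic inner unit normal of z = A sin(2 pi x / lambda + phi)
  k <- 2 * pi / config$wavelength
  nx <- config$amplitude * k * cos(k * x + config$phase)
  n <- unname(cbind(nx, 0, -1))
  n / rownorms(n)
}

#' Generate pial/white/mid surfaces for the synthetic fold
#'
#' Triangulates the rectangular grid with consistent outward (upward)
#' winding; the pial surface is the mid surface offset by `+thickness/2`
#' along the outer analytic normal and the white surface by
#' `-thickness/2`, so [build_midsurface()] reproduces the analytic mid
#' surface exactly.
#'
#' @param config a `synth_config`.
#' @return List with `pial`, `white`, `mid` (`surface_mesh`es) and
#'   `analytic_normals` (`n x 3` inner unit normals of the mid surface).
#' @export
make_folded_surfaces <- function(config) {
  if (!inherits(config, "synth_config")) stop("expected a synth_config", call. = FALSE)
  xs <- seq(-config$x_extent, config$x_extent, by = config$spacing)
  ys <- seq(-config$y_extent, config$y_extent, by = config$spacing)
  nx <- length(xs); ny <- length(ys)
  if (nx < 2L || ny < 2L) stop("grid must have at least 2 x 2 vertices", call. = FALSE)
  g <- expand.grid(x = xs, y = ys)               # x varies fastest
  k <- 2 * pi / config$wavelength
  z <- config$amplitude * sin(k * g$x + config$phase)
  mid_v <- cbind(g$x, g$y, z)
  inner <- fold_inner_normal(g$x, config)
  faces <- grid_faces(nx, ny)
  outer <- -inner
  h <- config$thickness / 2
  list(
    pial = surface_mesh(mid_v + h * outer, faces),
    white = surface_mesh(mid_v - h * outer, faces),
    mid = surface_mesh(mid_v, faces),
    analytic_normals = inner
  )
}

grid_faces <- function(nx, ny) {
  # two CCW-from-above triangles per cell, consistent diagonal
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Tessellated unit-ish sphere (subdivided icosahedron)
#'
#' Outward-wound icosphere used as a geometry oracle: vertex normals of a
#' sphere are known analytically.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @param radius sphere radius (mm, default 1).
#' @param center length-3 centre (default origin).
#' @return A `surface_mesh`.
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / rownorms(V)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env(parent = emptyenv())
    Vl <- lapply(seq_len(nrow(V)), function(i) V[i, ])
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      id <- mids[[key]]
      if (!is.null(id)) return(id)
      m <- (Vl[[a]] + Vl[[b]]) / 2
      Vl[[length(Vl) + 1L]] <<- m / vnorm(m)
      assign(key, length(Vl), envir = mids)
      length(Vl)
    }
    Fl <- vector("list", nrow(F) * 4L)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      Fl[[4L * f - 3L]] <- c(a, ab, ca)
      Fl[[4L * f - 2L]] <- c(b, bc, ab)
      Fl[[4L * f - 1L]] <- c(c, ca, bc)
      Fl[[4L * f]] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, Vl)
    F <- do.call(rbind, Fl)
  }
  surface_mesh(sweep(V * radius, 2L, as_point3(center), "+"), F)
}

#' Uniform vector field volume
#'
#' Every voxel holds the same (nonzero) vector; the exact-oracle field for
#' pipeline validation.
#'
#' @param vector nonzero length-3 field vector (V/m).
#' @param shape length-3 voxel counts.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `vector_field`.
#' @export
make_uniform_field <- function(vector, shape, affine) {
  vector <- as_point3(vector, "field vector")
  if (all(vector == 0)) stop("uniform field vector must be nonzero", call. = FALSE)
  shape <- as.integer(shape)
  arr <- array(0, dim = c(shape, 3L))
  for (c in 1:3) arr[, , , c] <- vector[c]
  vector_field(arr, affine)
}

#' Field of a point current source/sink pair at arbitrary points
#'
#' Electric field of a point source (+I at `anode_pos`) and sink (-I at
#' `cathode_pos`) in an infinite homogeneous conductor of conductivity
#' `sigma`:
#' `E(r) = I/(4 pi sigma) * ((r-ra)/|r-ra|^3 - (r-rc)/|r-rc|^3)` in SI
#' units.  Coordinates are mm and current mA; the result is V/m.
#'
#' @param points `n x 3` matrix of evaluation points (mm).
#' @param anode_pos,cathode_pos source/sink positions (mm), distinct.
#' @param current injected current (mA, > 0).
#' @param sigma conductivity (S/m, > 0).
#' @return `n x 3` matrix of field vectors (V/m).
#' @export
point_pair_field <- function(points, anode_pos, cathode_pos,
                             current = 2, sigma = 0.276) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  points <- as_matrix3(points, "points") / 1000     # mm -> m
  ra <- as_point3(anode_pos, "anode_pos") / 1000
  rc <- as_point3(cathode_pos, "cathode_pos") / 1000
  if (all(ra == rc)) stop("source and sink must be distinct", call. = FALSE)
  coef <- (current / 1000) / (4 * pi * sigma)       # mA -> A
  da <- sweep(points, 2L, ra, "-")
  dc <- sweep(points, 2L, rc, "-")
  na3 <- rownorms(da)^3
  nc3 <- rownorms(dc)^3
  coef * (da / na3 - dc / nc3)
}

#' Analytic point-source-pair field volume
#'
#' Evaluates [point_pair_field()] at every voxel centre.  Voxels whose
#' centre lies within `exclusion_radius` voxels (in world mm, using the
#' largest voxel edge) of either source get the zero vector, which
#' downstream produces missing angles rather than singular values.
#'
#' @param config a `synth_config` (supplies `current`, `sigma`,
#'   `exclusion_radius`).
#' @param anode_pos,cathode_pos source/sink positions (mm).
#' @param shape length-3 voxel counts.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `vector_field`.
#' @export
make_point_pair_field <- function(config, anode_pos, cathode_pos, shape, affine) {
  if (!inherits(config, "synth_config")) stop("expected a synth_config", call. = FALSE)
  shape <- as.integer(shape)
  affine <- check_affine(affine)
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  centers <- voxel_to_world(affine, idx)
  E <- point_pair_field(centers, anode_pos, cathode_pos,
                        current = config$current, sigma = config$sigma)
  voxel_edge <- max(sqrt(colSums(affine[1:3, 1:3]^2)))
  excl <- config$exclusion_radius * voxel_edge
  da <- rownorms(sweep(centers, 2L, as_point3(anode_pos), "-"))
  dc <- rownorms(sweep(centers, 2L, as_point3(cathode_pos), "-"))
  E[da <= excl | dc <= excl, ] <- 0
  arr <- array(0, dim = c(shape, 3L))
  for (c in 1:3) arr[, , , c] <- E[, c]             # expand.grid order = column-major
  vector_field(arr, affine)
}

fold_volume_geometry <- function(config, amplitude = config$amplitude) {
  margin <- 2
  zmax <- amplitude + config$thickness / 2 + margin
  lo <- c(-config$x_extent - margin, -config$y_extent - margin, -zmax)
  hi <- c(config$x_extent + margin, config$y_extent + margin, zmax)
  shape <- as.integer(floor((hi - lo) / config$voxel_size)) + 1L
  affine <- diag(c(rep(config$voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  list(shape = shape, affine = affine)
}

#' Generate a reproducible synthetic cohort
#'
#' Each subject gets a fold with normally jittered phase (sd `phase_sd`)
#' and amplitude (sd `amplitude_sd`, clamped to at least 1 mm), surfaces,
#' analytic bank/crown seeds and motor-strip endpoints tracking the
#' subject's own fold, three montages, and one point-source-pair field per
#' montage:
#' \describe{
#'   \item{PA-like}{sources straddling the fold along x (the fold's
#'     "posterior-anterior" axis): anode `(75, 0, 10)`, cathode
#'     `(-75, 0, 10)`; current crosses the sulcus.}
#'   \item{ML-like}{sources along y, parallel to the sulcus: anode
#'     `(0, 75, 10)`, cathode `(0, -75, 10)`.}
#'   \item{conventional-like}{anode 20 mm above the subject's M1-like
#'     crown, distant frontal cathode `(60, 45, 40)`.}
#' }
#' In this synthetic frame the fold axis is x, so the across-sulcus
#' ("posterior to anterior") direction is `-x`; subject records carry
#' `anterior_axis = c(-1, 0, 0)` for [motor_strip_target()].
#' The same seed always yields an identical cohort.
#'
#' @param config a `synth_config`.
#' @return List of `n` subject records, each a list with `id`, `amplitude`,
#'   `phase`, `pial`, `white`, `analytic_normals`, `seeds` (data.frame),
#'   `strip` (medial/lateral endpoints), `anterior_axis`, `montages`
#'   (named list of `montage_spec`) and `fields` (named list of
#'   `vector_field`).
#' @export
make_cohort <- function(config) {
  if (!inherits(config, "synth_config")) stop("expected a synth_config", call. = FALSE)
  set.seed(config$seed)
  lapply(seq_len(config$n), function(i) {
    phase_i <- config$phase + rnorm(1, sd = config$phase_sd)
    amp_i <- max(1, config$amplitude + rnorm(1, sd = config$amplitude_sd))
    make_subject(config, sprintf("sub-%02d", i), amp_i, phase_i)
  })
}

make_subject <- function(config, id, amplitude, phase) {
  cfg_i <- config
  cfg_i$amplitude <- amplitude
  cfg_i$phase <- phase
  surf <- make_folded_surfaces(cfg_i)
  k <- 2 * pi / config$wavelength
  # seed x for a given fold phase angle u: k x + phase = u
  seed_x <- function(u) (u - phase) / k
  seeds <- data.frame(
    subject = id,
    label = c("M1_BANK", "M1_CROWN", "S1_BANK", "S1_CROWN"),
    x = c(seed_x(-pi), seed_x(-3 * pi / 2), seed_x(0), seed_x(pi / 2)),
    y = 0,
    z = c(0, amplitude, 0, amplitude),
    stringsAsFactors = FALSE)
  crown_x <- seed_x(-3 * pi / 2)
  strip <- list(medial = c(crown_x, config$y_extent - 2, amplitude),
                lateral = c(crown_x, -(config$y_extent - 2), amplitude))
  montages <- list(
    PA = montage_spec("PA", anode_center = c(75, 0, 10),
                      cathode_center = c(-75, 0, 10),
                      anode_label = "CP3", cathode_label = "FCz",
                      current = config$current),
    ML = montage_spec("ML", anode_center = c(0, 75, 10),
                      cathode_center = c(0, -75, 10),
                      anode_label = "CPz", cathode_label = "FC3",
                      current = config$current),
    conventional = montage_spec("conventional",
                                anode_center = c(crown_x, 0, amplitude + 20),
                                cathode_center = c(60, 45, 40),
                                anode_label = "C1", cathode_label = "FP2",
                                current = config$current))
  geom <- fold_volume_geometry(config, amplitude)
  fields <- lapply(montages, function(m)
    make_point_pair_field(cfg_i, m$anode_center, m$cathode_center,
                          geom$shape, geom$affine))
  list(id = id, amplitude = amplitude, phase = phase,
       pial = surf$pial, white = surf$white,
       analytic_normals = surf$analytic_normals,
       seeds = seeds, strip = strip, anterior_axis = c(-1, 0, 0),
       montages = montages, fields = fields)
}

#' Write a synthetic cohort to disk in the formats the pipeline reads
#'
#' Per subject: pial/white surfaces, one NIfTI field volume per montage,
#' a seed CSV and one montage config file per montage, plus a cohort-level
#' `manifest.csv` (one row per subject x montage with the file paths)
#' consumable by [run_manifest()].
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @param surface_format any format accepted by [write_surface()]
#'   (default `"gifti"`).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, surface_format = "gifti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(surface_format, off = ".off", ply = ".ply",
                gifti = ".surf.gii", freesurfer = "", ".dat")
  rows <- list()
  for (s in cohort) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    pial_p <- file.path(sd, paste0("pial", ext))
    white_p <- file.path(sd, paste0("white", ext))
    write_surface(s$pial, pial_p, format = surface_format)
    write_surface(s$white, white_p, format = surface_format)
    seeds_p <- file.path(sd, "seeds.csv")
    write_roi_seeds(s$seeds, seeds_p)
    for (mn in names(s$fields)) {
      field_p <- file.path(sd, paste0("field_", mn, ".nii.gz"))
      write_field_nifti(s$fields[[mn]], field_p)
      mont_p <- file.path(sd, paste0("montage_", mn, ".txt"))
      write_montage(s$montages[[mn]], mont_p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, montage = mn, pial = pial_p, white = white_p,
        field = field_p, seeds = seeds_p, montage_file = mont_p,
        surface_format = surface_format, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_p <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_p, row.names = FALSE)
  invisible(manifest_p)
}
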