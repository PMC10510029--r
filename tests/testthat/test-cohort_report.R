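# a fast cohort configuration used throughout this file
fast_cfg <- function(n = 3, seed = 42)
  synth_config(n = n, seed = seed, x_extent = 25, y_extent = 8, spacing = 1,
               amplitude = 8, wavelength = 33, voxel_size = 2)

test_that("flat sheet with uniform inward field gives zero-degree ROIs", {
  cfg <- synth_config(x_extent = 12, y_extent = 6, amplitude = 0)
  surf <- make_folded_surfaces(cfg)
  vol <- fold_volume_geometry_test(cfg)
  field <- make_uniform_field(c(0, 0, -1), vol$shape, vol$affine)
  # within-gyrus seeds more than 2k hops apart so ring ROIs keep distinct centres
  seeds <- data.frame(label = c("M1_BANK", "M1_CROWN", "S1_BANK", "S1_CROWN"),
                      x = c(-11, -2, 2, 11), y = 0, z = 0)
  res <- run_subject(surf$pial, surf$white, field, seeds)
  expect_equal(res$summaries$mean_theta_deg, rep(0, 4), tolerance = 1e-12)
  expect_equal(res$summaries$mean_magnitude_Vpm, rep(1, 4))
  expect_true(is.na(res$theta_elm_deg))
})

test_that("run_subject validates its inputs with labelled errors", {
  cfg <- synth_config(x_extent = 8, y_extent = 4, spacing = 2)
  surf <- make_folded_surfaces(cfg)
  vol <- fold_volume_geometry_test(cfg)
  field <- make_uniform_field(c(1, 0, 0), vol$shape, vol$affine)
  seeds <- data.frame(label = "M1_BANK", x = 0, y = 0, z = 0)
  expect_error(run_subject(surf$pial, NULL, field, seeds), "surface_mesh")
  expect_error(run_subject(surf$pial, surf$white, field,
                           data.frame(label = "A", x = 0)), "columns")
})

test_that("per-subject logging reports stage counts when asked", {
  cfg <- synth_config(x_extent = 8, y_extent = 4, spacing = 2)
  surf <- make_folded_surfaces(cfg)
  vol <- fold_volume_geometry_test(cfg)
  field <- make_uniform_field(c(1, 0, 0), vol$shape, vol$affine)
  seeds <- data.frame(label = c("M1_BANK", "M1_CROWN"), x = c(-8, 0), y = 0, z = 0)
  msgs <- capture_messages(
    run_subject(surf$pial, surf$white, field, seeds, k = 1, verbose = TRUE))
  expect_true(any(grepl("midsurface: ", msgs)))
  expect_true(any(grepl("overlap resolution", msgs)))
  expect_true(any(grepl("sampled", msgs)))
})

test_that("run_cohort assembles one row per subject, montage, gyrus and ROI", {
  cohort <- make_cohort(fast_cfg(n = 2))
  tab <- run_cohort(cohort)
  expect_identical(nrow(tab), 2L * 3L * 4L)
  expect_setequal(unique(tab$montage), c("PA", "ML", "conventional"))
  key <- paste(tab$subject, tab$montage, tab$gyrus, tab$roi)
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(tab$mean_theta_deg >= 0 & tab$mean_theta_deg <= 180))
  expect_true(all(tab$mean_magnitude_Vpm >= 0))
  # proxy angle present exactly on M1 bank rows of PA and ML
  has_elm <- !is.na(tab$theta_elm_deg)
  expect_true(all(tab$label[has_elm] == "M1_BANK"))
  expect_identical(sort(unique(tab$montage[has_elm])), c("ML", "PA"))
  expect_length(attr(tab, "failures"), 0L)
})

test_that("failing subjects are reported and skipped, not fatal", {
  cohort <- make_cohort(fast_cfg(n = 2))
  cohort[[1]]$seeds$label <- c("M1_BANK", "M1_BANK", "S1_BANK", "S1_CROWN")
  # duplicated centre labels make ROI resolution impossible for subject 1
  cohort[[1]]$seeds$x[2] <- cohort[[1]]$seeds$x[1]
  tab <- suppressWarnings(run_cohort(cohort))
  expect_length(attr(tab, "failures"), 3L)   # all three montages of subject 1
  expect_identical(unique(tab$subject), cohort[[2]]$id)
})

test_that("cohort summaries reproduce closed-form mean and standard error", {
  base <- data.frame(montage = "PA", gyrus = "M1", roi = "bank", label = "M1_BANK",
                     n_vertices = 10L, min_theta_deg = 0, max_theta_deg = 0,
                     theta_elm_deg = NA_real_)
  tab <- do.call(rbind, lapply(1:3, function(i)
    cbind(subject = paste0("s", i), base,
          mean_theta_deg = c(10, 20, 30)[i],
          mean_magnitude_Vpm = 0.4)))
  s <- summarize_cohort(tab)
  expect_equal(s$mean_theta_deg, 20)
  expect_equal(s$se_theta_deg, 10 / sqrt(3))   # sd({10,20,30}) = 10
  expect_equal(s$se_theta_deg, 5.7735, tolerance = 1e-4)
  expect_equal(s$min_theta_deg, 10)
  expect_equal(s$max_theta_deg, 30)
  single <- tab[1, ]
  expect_true(is.na(summarize_cohort(single)$se_theta_deg))
  expect_error(summarize_cohort(tab[0, ]), "empty")
})

test_that("replicated identical subjects summarize with zero spread", {
  cohort <- make_cohort(synth_config(n = 3, phase_sd = 0, amplitude_sd = 0,
                                     x_extent = 20, y_extent = 6,
                                     amplitude = 8, wavelength = 30,
                                     voxel_size = 2))
  tab <- run_cohort(cohort, montages = "PA")
  s <- summarize_cohort(tab)
  expect_true(all(s$se_theta_deg < 1e-12))
  expect_equal(s$mean_theta_deg, tab$mean_theta_deg[match(
    paste(s$gyrus, s$roi), paste(tab$gyrus, tab$roi))])
})

test_that("correlate_proxy implements the Pearson product-moment formula", {
  mk <- function(x, y) data.frame(
    subject = paste0("s", seq_along(x)), montage = "PA", gyrus = "M1",
    roi = "bank", label = "M1_BANK", n_vertices = 1L,
    mean_theta_deg = x, mean_magnitude_Vpm = 1,
    min_theta_deg = 0, max_theta_deg = 180, theta_elm_deg = y)
  expect_equal(correlate_proxy(mk(c(1, 2, 3), c(10, 20, 30)), "PA")$r, 1)
  expect_equal(correlate_proxy(mk(c(1, 2, 3), c(30, 20, 10)), "PA")$r, -1)
  # hand-evaluated Pearson: sxy=8, sxx=syy=10 -> r = 0.8
  res <- correlate_proxy(mk(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), "PA")
  expect_equal(res$r, 0.8)
  expect_identical(res$n, 5L)
  expect_error(correlate_proxy(mk(c(1, 2), c(1, 2)), "PA"), "at least 3")
  expect_error(correlate_proxy(mk(c(1, 1, 1), c(1, 2, 3)), "PA"), "zero variance")
  # invariance under affine rescaling of either variable
  expect_equal(correlate_proxy(mk(c(1, 2, 3, 4, 5) * 3 + 7, c(2, 1, 4, 3, 5)), "PA")$r,
               0.8, tolerance = 1e-12)
})

test_that("same seed and config give byte-identical cohort CSVs", {
  cfg <- fast_cfg(n = 2, seed = 7)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p1, p2)))
  write_cohort_table(run_cohort(make_cohort(cfg)), p1)
  write_cohort_table(run_cohort(make_cohort(cfg)), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("run_manifest reproduces the in-memory pipeline from files", {
  cfg <- fast_cfg(n = 1, seed = 13)
  cohort <- make_cohort(cfg)
  dir <- tempfile("man")
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- write_cohort(cohort, dir, surface_format = "off")
  tab_files <- run_manifest(manifest)
  tab_mem <- run_cohort(cohort)
  ord <- function(t) t[order(t$montage, t$label), ]
  a <- ord(tab_files); b <- ord(tab_mem)
  expect_equal(a$mean_theta_deg, b$mean_theta_deg, tolerance = 1e-8)
  expect_equal(a$theta_elm_deg, b$theta_elm_deg, tolerance = 1e-8)
  expect_identical(a$n_vertices, b$n_vertices)
})
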