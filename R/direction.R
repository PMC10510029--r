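#' Angle between two 3-D vectors, in degrees
#'
#' `acos` of the normalized dot product, clamped to `[-1, 1]`; result in
#' `[0, 180]`.  In this pipeline's convention (inner normal vs field
#' vector) 0 degrees is absolute radial-inward current, 90 tangential,
#' 180 radial-outward.
#'
#' @param s,ef nonzero length-3 vectors.
#' @return Angle in degrees.
#' @export
angle_between <- function(s, ef) {
  s <- as_point3(s, "s"); ef <- as_point3(ef, "ef")
  ns <- vnorm(s); nef <- vnorm(ef)
  if (ns == 0 || nef == 0) stop("zero-length vector has no direction", call. = FALSE)
  acos(max(-1, min(1, sum(s * ef) / (ns * nef)))) * 180 / pi
}

#' Per-vertex current direction and intensity
#'
#' Computes `theta`, the angle (degrees) between each inner surface normal
#' and the field vector sampled at that vertex, and the field magnitude
#' (V/m).  Vertices whose sampled vector is exactly zero (e.g. inside a
#' source exclusion zone) get `theta = NA` (excluded from aggregates) and
#' magnitude 0.
#'
#' @param mesh a `surface_mesh` with normals set.
#' @param sampled a `sampled_field` with one vector per mesh vertex.
#' @return An object of class `direction_result`: list with numeric
#'   vectors `theta` (degrees, `[0, 180]` or NA) and `magnitude` (V/m).
#' @export
compute_direction <- function(mesh, sampled) {
  stopifnot_mesh(mesh)
  if (is.null(mesh$normals)) stop("mesh normals are not set; call compute_inner_normals()",
                                  call. = FALSE)
  if (!inherits(sampled, "sampled_field")) stop("expected a sampled_field", call. = FALSE)
  if (nrow(sampled$vectors) != n_vertices(mesh))
    stop("sampled field has ", nrow(sampled$vectors), " vectors for ",
         n_vertices(mesh), " vertices", call. = FALSE)
  mag <- rownorms(sampled$vectors)
  dotp <- rowSums(mesh$normals * sampled$vectors)
  ctheta <- pmin(1, pmax(-1, dotp / ifelse(mag > 0, mag, 1)))
  theta <- acos(ctheta) * 180 / pi
  theta[mag == 0] <- NA_real_
  structure(list(theta = theta, magnitude = mag), class = "direction_result")
}

#' @export
print.direction_result <- function(x, ...) {
  ok <- !is.na(x$theta)
  cat(sprintf("<direction_result> %d vertices (%d with field), mean theta %.1f deg\n",
              length(x$theta), sum(ok), mean(x$theta[ok])))
  invisible(x)
}

#' Classify an angle as radial-inward, tangential or radial-outward
#'
#' Three-way map used for display: `< 45` radial_inward, `45..135`
#' tangential, `> 135` radial_outward.  Bin edges are presentational and
#' configurable.
#'
#' @param theta angle(s) in degrees, in `[0, 180]` (NA passed through).
#' @param edges length-2 increasing bin edges (default `c(45, 135)`).
#' @return Factor with levels `radial_inward`, `tangential`,
#'   `radial_outward`.
#' @export
classify_direction <- function(theta, edges = c(45, 135)) {
  bad <- !is.na(theta) & (theta < 0 | theta > 180)
  if (any(bad)) stop("theta out of range [0, 180]: ", theta[bad][1], call. = FALSE)
  lv <- c("radial_inward", "tangential", "radial_outward")
  out <- ifelse(theta < edges[1], lv[1], ifelse(theta <= edges[2], lv[2], lv[3]))
  factor(out, levels = lv)
}

#' Summarize current direction and intensity within an ROI
#'
#' Arithmetic mean (plain degrees, no circular statistics: theta is an
#' unsigned separation angle in `[0, 180]`), plus min/max, over the ROI's
#' vertices with a non-missing angle.
#'
#' @param result a `direction_result`.
#' @param roi an `roi` whose vertex indices are valid for `result`.
#' @return An object of class `roi_summary`: list with `label`,
#'   `n_vertices`, `mean_theta`, `mean_magnitude`, `theta_range`
#'   (c(min, max)).
#' @export
summarize_roi <- function(result, roi) {
  if (!inherits(result, "direction_result")) stop("expected a direction_result", call. = FALSE)
  if (!inherits(roi, "roi")) stop("expected an roi", call. = FALSE)
  if (max(roi$vertices) > length(result$theta))
    stop("ROI vertex index exceeds result length", call. = FALSE)
  th <- result$theta[roi$vertices]
  mg <- result$magnitude[roi$vertices]
  ok <- !is.na(th)
  if (!any(ok)) stop("ROI '", roi$label, "' has no vertex with a field value", call. = FALSE)
  out <- list(label = roi$label, n_vertices = sum(ok),
              mean_theta = mean(th[ok]), mean_magnitude = mean(mg[ok]),
              theta_range = c(min(th[ok]), max(th[ok])))
  stopifnot(out$theta_range[1] <= out$mean_theta, out$mean_theta <= out$theta_range[2])
  structure(out, class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> %s: n=%d, theta %.1f deg [%.1f, %.1f], |E| %.3f V/m\n",
              x$label, x$n_vertices, x$mean_theta,
              x$theta_range[1], x$theta_range[2], x$mean_magnitude))
  invisible(x)
}

#' Export per-vertex direction results as a table
#'
#' @param result a `direction_result`.
#' @param rois optional list of `roi` objects used to label vertices
#'   (first matching ROI wins); unlabelled vertices get `"none"`.
#' @param subject,montage identifiers recycled across rows.
#' @return data.frame with columns `subject`, `montage`, `vertex`,
#'   `theta_deg`, `magnitude_Vpm`, `roi_label`.
#' @export
direction_table <- function(result, rois = NULL, subject = "subject",
                            montage = "montage") {
  n <- length(result$theta)
  lab <- rep("none", n)
  for (r in rev(rois %||% list())) lab[r$vertices] <- r$label
  data.frame(subject = subject, montage = montage, vertex = seq_len(n),
             theta_deg = result$theta, magnitude_Vpm = result$magnitude,
             roi_label = lab, stringsAsFactors = FALSE)
}
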