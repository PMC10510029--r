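#' Electrode montage specification
#'
#' Geometry of a bipolar tDCS montage: anode and cathode centre
#' coordinates (world mm) plus nominal stimulation parameters.  Defaults
#' mirror a typical protocol: 2 mA through disc electrodes of 17 mm
#' radius and 2 mm height.  The 10-10 labels are informational only; no
#' scalp positioning is computed here.
#'
#' @param name montage name (e.g. `"PA"`, `"ML"`, `"conventional"`).
#' @param anode_center,cathode_center length-3 world coordinates (mm);
#'   must differ.
#' @param anode_label,cathode_label optional 10-10 labels (e.g. `"CP3"`).
#' @param current stimulation current in mA (> 0, default 2).
#' @param electrode_radius disc radius in mm (> 0, default 17).
#' @param electrode_height disc height in mm (default 2).
#' @return An object of class `montage_spec`.
#' @export
montage_spec <- function(name, anode_center, cathode_center,
                         anode_label = "", cathode_label = "",
                         current = 2, electrode_radius = 17,
                         electrode_height = 2) {
  anode_center <- as_point3(anode_center, "anode_center")
  cathode_center <- as_point3(cathode_center, "cathode_center")
  if (all(anode_center == cathode_center))
    stop("anode and cathode centres must differ", call. = FALSE)
  if (current <= 0) stop("current must be positive (mA)", call. = FALSE)
  if (electrode_radius <= 0) stop("electrode_radius must be positive (mm)", call. = FALSE)
  structure(list(name = as.character(name),
                 anode_center = anode_center, cathode_center = cathode_center,
                 anode_label = anode_label, cathode_label = cathode_label,
                 current = current, electrode_radius = electrode_radius,
                 electrode_height = electrode_height),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> %s: anode %s(%s) -> cathode %s(%s), %.3g mA\n",
              x$name, x$anode_label, paste(x$anode_center, collapse = ","),
              x$cathode_label, paste(x$cathode_center, collapse = ","),
              x$current))
  invisible(x)
}

#' Unit vector from anode to cathode
#'
#' The electrode-location estimate of current direction: conventional
#' current flows from anode to cathode through the head.
#'
#' @param montage a `montage_spec`.
#' @return Unit length-3 vector.
#' @export
electrode_vector <- function(montage) {
  if (!inherits(montage, "montage_spec")) stop("expected a montage_spec", call. = FALSE)
  normalize(montage$cathode_center - montage$anode_center)
}

#' Target direction: mean inner normal of an ROI
#'
#' The orientation of a cortical target patch, as the normalized
#' arithmetic mean of its inner vertex normals.
#'
#' @param mesh a `surface_mesh` with normals.
#' @param roi a non-empty `roi`.
#' @return A `target_vector` (unit `direction`, `kind = "roi_mean_normal"`).
#' @export
mean_roi_normal <- function(mesh, roi) {
  stopifnot_mesh(mesh)
  if (is.null(mesh$normals)) stop("mesh normals are not set", call. = FALSE)
  if (!inherits(roi, "roi")) stop("expected an roi", call. = FALSE)
  m <- colMeans(mesh$normals[roi$vertices, , drop = FALSE])
  if (vnorm(m) < 1e-6)
    stop("ill-defined target: ROI normals cancel (mean norm < 1e-6)", call. = FALSE)
  target_vector(m / vnorm(m), "roi_mean_normal")
}

target_vector <- function(direction, kind) {
  direction <- as_point3(direction, "direction")
  if (abs(vnorm(direction) - 1) > 1e-9)
    stop("target direction must be unit length", call. = FALSE)
  structure(list(direction = direction, kind = kind), class = "target_vector")
}

#' Target direction orthogonal to the motor strip
#'
#' From the medial and lateral endpoints of the precentral gyrus the strip
#' vector is `normalize(lateral - medial)`; the target is the component of
#' a world anterior axis orthogonal to the strip (Gram-Schmidt), i.e. the
#' posterior-to-anterior direction across the strip, so that 0 degrees
#' keeps meaning radial-inward in comparisons.
#'
#' @param medial_point,lateral_point strip endpoints, world mm.
#' @param anterior_axis unit world axis resolving the orthogonal plane
#'   (default `c(0, 1, 0)`, +y in RAS).
#' @return A `target_vector` (`kind = "motor_strip_orthogonal"`).
#' @export
motor_strip_target <- function(medial_point, lateral_point,
                               anterior_axis = c(0, 1, 0)) {
  medial_point <- as_point3(medial_point, "medial_point")
  lateral_point <- as_point3(lateral_point, "lateral_point")
  if (all(medial_point == lateral_point))
    stop("strip endpoints must differ", call. = FALSE)
  a <- normalize(as_point3(anterior_axis, "anterior_axis"))
  strip <- normalize(lateral_point - medial_point)
  if (abs(sum(a * strip)) > 1 - 1e-6)
    stop("degenerate orientation: motor strip is parallel to the anterior axis",
         call. = FALSE)
  ortho <- a - sum(a * strip) * strip
  target_vector(ortho / vnorm(ortho), "motor_strip_orthogonal")
}

#' Electrode-location proxy angle for current direction
#'
#' The angle (degrees) between the anode-to-cathode vector and a target
#' direction (mean ROI inner normal or motor-strip orthogonal): 0 degrees
#' = absolute radial-inward current at the target, 90 tangential, 180
#' radial-outward.
#'
#' @param montage a `montage_spec`.
#' @param target a `target_vector`.
#' @return An object of class `proxy_result`: list with `theta_elm`
#'   (degrees), `montage` (name) and `target_kind`.
#' @export
proxy_angle <- function(montage, target) {
  if (!inherits(target, "target_vector")) stop("expected a target_vector", call. = FALSE)
  th <- angle_between(electrode_vector(montage), target$direction)
  structure(list(theta_elm = th, montage = montage$name,
                 target_kind = target$kind),
            class = "proxy_result")
}

#' @export
print.proxy_result <- function(x, ...) {
  cat(sprintf("<proxy_result> %s vs %s: theta_ELM = %.1f deg\n",
              x$montage, x$target_kind, x$theta_elm))
  invisible(x)
}

#' Read and write montage configuration files
#'
#' Plain-text key-value format, one `key = value` pair per line; vector
#' values are comma-separated.  Keys: `name`, `anode_label`,
#' `cathode_label`, `anode_center`, `cathode_center` (mm),
#' `current` (mA), `electrode_radius` (mm), `electrode_height` (mm).
#'
#' @param path file path.
#' @return `read_montage()` returns a `montage_spec`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("parse error in ", path, " line ", i, ": expected 'key = value'",
           call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num3 <- function(key) as.numeric(strsplit(kv[[key]], ",")[[1]])
  montage_spec(
    name = kv$name %||% "montage",
    anode_center = num3("anode_center"), cathode_center = num3("cathode_center"),
    anode_label = kv$anode_label %||% "", cathode_label = kv$cathode_label %||% "",
    current = as.numeric(kv$current %||% "2"),
    electrode_radius = as.numeric(kv$electrode_radius %||% "17"),
    electrode_height = as.numeric(kv$electrode_height %||% "2"))
}

#' @rdname read_montage
#' @param montage a `montage_spec` to write.
#' @export
write_montage <- function(montage, path) {
  fmt3 <- function(v) paste(formatC(v, format = "g", digits = 17), collapse = ", ")
  writeLines(c(
    paste("name =", montage$name),
    paste("anode_label =", montage$anode_label),
    paste("cathode_label =", montage$cathode_label),
    paste("anode_center =", fmt3(montage$anode_center)),
    paste("cathode_center =", fmt3(montage$cathode_center)),
    paste("current =", formatC(montage$current, format = "g", digits = 17)),
    paste("electrode_radius =", formatC(montage$electrode_radius, format = "g", digits = 17)),
    paste("electrode_height =", formatC(montage$electrode_height, format = "g", digits = 17))
  ), path)
  invisible(path)
}
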