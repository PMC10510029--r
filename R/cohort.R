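#' Run the per-subject current-direction pipeline
#'
#' Executes the full chain for one subject and one montage:
#' mid-surface averaging, inner normals, four ring ROIs from the seed
#' table, within-gyrus bank/crown overlap resolution, nearest-neighbour
#' field sampling, per-vertex angles, and per-ROI summaries.  If a
#' `montage` is given, the electrode-location proxy angle against the mean
#' inner normal of the target ROI (default `M1_BANK`) is added.
#'
#' Seed labels are expected as `<GYRUS>_<ROI>` (e.g. `M1_BANK`); overlaps
#' are resolved only between the bank/crown pair of the same gyrus.
#'
#' @param pial,white `surface_mesh`es with matching topology.
#' @param field a `vector_field`.
#' @param seeds data.frame with columns `label`, `x`, `y`, `z`.
#' @param montage optional `montage_spec` for the proxy angle.
#' @param k ring depth for ROI growth (default 5).
#' @param mask optional voxel mask passed to [sample_nearest()].
#' @param proxy_target label of the ROI whose mean normal is the proxy
#'   target (default `"M1_BANK"`).
#' @param verbose log stage-by-stage counts via [message()].
#' @return List with `summaries` (data.frame: one row per ROI with
#'   `label`, `gyrus`, `roi`, `n_vertices`, `mean_theta_deg`,
#'   `mean_magnitude_Vpm`, `min_theta_deg`, `max_theta_deg`),
#'   `theta_elm_deg` (or `NA`), `mid` (the mid surface with normals),
#'   `rois` (resolved ROI list) and `direction` (the per-vertex result).
#' @export
run_subject <- function(pial, white, field, seeds, montage = NULL, k = 5L,
                        mask = NULL, proxy_target = "M1_BANK",
                        verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  mid <- build_midsurface(pial, white)
  say("midsurface: %d vertices, %d faces", n_vertices(mid), n_faces(mid))
  mid <- compute_inner_normals(mid)
  say("inner normals computed for %d vertices", n_vertices(mid))
  if (!all(c("label", "x", "y", "z") %in% names(seeds)))
    stop("seeds must have columns label, x, y, z", call. = FALSE)
  rois <- lapply(seq_len(nrow(seeds)), function(i)
    build_roi(mid, seeds$label[i], c(seeds$x[i], seeds$y[i], seeds$z[i]), k = k))
  names(rois) <- seeds$label
  for (r in rois) say("roi %s: %d vertices, %d faces before overlap resolution",
                      r$label, length(r$vertices), length(r$faces))
  gyrus_of <- function(label) sub("_.*$", "", label)
  for (g in unique(gyrus_of(seeds$label))) {
    pair <- which(gyrus_of(seeds$label) == g)
    if (length(pair) == 2L) {
      res <- resolve_overlaps(mid, rois[[pair[1]]], rois[[pair[2]]])
      rois[[pair[1]]] <- res[[1]]; rois[[pair[2]]] <- res[[2]]
    }
  }
  for (r in rois) say("roi %s: %d vertices after overlap resolution",
                      r$label, length(r$vertices))
  sampled <- sample_nearest(field, mid, mask = mask)
  say("sampled %d vertices from %s voxel volume",
      nrow(sampled$vectors), paste(field$shape, collapse = "x"))
  dirres <- compute_direction(mid, sampled)
  summaries <- do.call(rbind, lapply(rois, function(r) {
    s <- summarize_roi(dirres, r)
    data.frame(label = s$label, gyrus = gyrus_of(s$label),
               roi = tolower(sub("^.*_", "", s$label)),
               n_vertices = s$n_vertices, mean_theta_deg = s$mean_theta,
               mean_magnitude_Vpm = s$mean_magnitude,
               min_theta_deg = s$theta_range[1], max_theta_deg = s$theta_range[2],
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  theta_elm <- NA_real_
  if (!is.null(montage) && proxy_target %in% names(rois)) {
    target <- mean_roi_normal(mid, rois[[proxy_target]])
    theta_elm <- proxy_angle(montage, target)$theta_elm
    say("theta_ELM (%s vs %s mean normal): %.2f deg",
        montage$name, proxy_target, theta_elm)
  }
  list(summaries = summaries, theta_elm_deg = theta_elm, mid = mid,
       rois = rois, direction = dirres)
}

#' Run the pipeline across a synthetic cohort
#'
#' Applies [run_subject()] to every subject and montage of a
#' [make_cohort()] result and assembles the cohort table: one row per
#' subject x montage x gyrus x ROI.  The proxy angle is computed for the
#' montages in `proxy_montages` (default PA and ML, the flanking-pair
#' montages; a conventional montage has no meaningful anode-to-cathode
#' axis through the target) and is recorded on the target gyrus's bank
#' row.  Subjects failing any stage are dropped from the table with a
#' warning naming the stage.
#'
#' @param cohort list of subjects from [make_cohort()].
#' @param montages character vector of montage names (default: all of the
#'   first subject's).
#' @param k ring depth (default 5).
#' @param mask optional voxel mask.
#' @param proxy_montages montages for which the proxy angle is computed.
#' @param verbose log per-stage counts.
#' @return data.frame with columns `subject`, `montage`, `gyrus`, `roi`,
#'   `label`, `n_vertices`, `mean_theta_deg`, `mean_magnitude_Vpm`,
#'   `min_theta_deg`, `max_theta_deg`, `theta_elm_deg`.  Failed subjects
#'   are listed in `attr(, "failures")`.
#' @export
run_cohort <- function(cohort, montages = NULL, k = 5L, mask = NULL,
                       proxy_montages = c("PA", "ML"), verbose = FALSE) {
  if (length(cohort) == 0L)
    return(structure(empty_cohort_table(), failures = character()))
  montages <- montages %||% names(cohort[[1]]$fields)
  rows <- list(); failures <- character()
  for (s in cohort) {
    for (mn in montages) {
      res <- tryCatch(
        run_subject(s$pial, s$white, s$fields[[mn]], s$seeds,
                    montage = if (mn %in% proxy_montages) s$montages[[mn]],
                    k = k, mask = mask, verbose = verbose),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", s$id, mn, conditionMessage(res)))
        warning("subject ", s$id, ", montage ", mn, " failed: ",
                conditionMessage(res), call. = FALSE)
        next
      }
      tab <- res$summaries
      tab$theta_elm_deg <- ifelse(
        tab$label == "M1_BANK" & !is.na(res$theta_elm_deg),
        res$theta_elm_deg, NA_real_)
      tab <- cbind(subject = s$id, montage = mn, tab)
      rows[[length(rows) + 1L]] <- tab
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_cohort_table()
  rownames(out) <- NULL
  structure(out, failures = failures)
}

empty_cohort_table <- function() {
  data.frame(subject = character(), montage = character(), label = character(),
             gyrus = character(), roi = character(), n_vertices = integer(),
             mean_theta_deg = numeric(), mean_magnitude_Vpm = numeric(),
             min_theta_deg = numeric(), max_theta_deg = numeric(),
             theta_elm_deg = numeric(), stringsAsFactors = FALSE)
}

#' Cohort-level summary table (mean, SE, range per condition)
#'
#' Arithmetic mean, standard error (sample sd over sqrt(n); `NA` when
#' n = 1), minimum and maximum of the per-subject ROI means, per
#' montage x gyrus x ROI, for both the angle and the intensity, plus the
#' same statistics for the proxy angle where present.
#'
#' @param table cohort table from [run_cohort()].
#' @return data.frame with one row per montage x gyrus x roi.
#' @export
summarize_cohort <- function(table) {
  if (nrow(table) == 0L) stop("empty cohort table", call. = FALSE)
  se <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  groups <- unique(table[, c("montage", "gyrus", "roi")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- table[table$montage == g$montage & table$gyrus == g$gyrus &
                 table$roi == g$roi, ]
    if (nrow(sub) == 0L) stop("empty condition ", paste(g, collapse = "/"), call. = FALSE)
    elm <- sub$theta_elm_deg[!is.na(sub$theta_elm_deg)]
    data.frame(
      montage = g$montage, gyrus = g$gyrus, roi = g$roi, n = nrow(sub),
      mean_theta_deg = mean(sub$mean_theta_deg), se_theta_deg = se(sub$mean_theta_deg),
      min_theta_deg = min(sub$mean_theta_deg), max_theta_deg = max(sub$mean_theta_deg),
      mean_magnitude_Vpm = mean(sub$mean_magnitude_Vpm),
      se_magnitude_Vpm = se(sub$mean_magnitude_Vpm),
      min_magnitude_Vpm = min(sub$mean_magnitude_Vpm),
      max_magnitude_Vpm = max(sub$mean_magnitude_Vpm),
      mean_theta_elm_deg = if (length(elm)) mean(elm) else NA_real_,
      se_theta_elm_deg = se(elm),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between proxy and model angles
#'
#' Correlates, across subjects, the electrode-location proxy angle
#' `theta_ELM` with the model-based ROI mean angle `theta_SEF` for the
#' given montage(s) and ROI.
#'
#' @param table cohort table from [run_cohort()].
#' @param montage montage name(s) to include.
#' @param gyrus,roi condition selecting the ROI rows (defaults `M1`,
#'   `bank`).
#' @return List with `r` (Pearson product-moment correlation) and `n`
#'   (number of pairs).
#' @export
correlate_proxy <- function(table, montage, gyrus = "M1", roi = "bank") {
  sub <- table[table$montage %in% montage & table$gyrus == gyrus &
               table$roi == roi & !is.na(table$theta_elm_deg), ]
  if (nrow(sub) < 3L)
    stop("need at least 3 paired observations, got ", nrow(sub), call. = FALSE)
  x <- sub$mean_theta_deg; y <- sub$theta_elm_deg
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance in ",
         if (sd(x) == 0) "theta_SEF" else "theta_ELM", call. = FALSE)
  list(r = cor(x, y), n = nrow(sub))
}

#' Read and write cohort tables as CSV
#'
#' UTF-8 CSV with fixed column order; identical inputs give byte-identical
#' files.
#'
#' @param table cohort table ([run_cohort()]) or summary
#'   ([summarize_cohort()]).
#' @param path file path.
#' @return `read_cohort_table()` returns the data.frame.
#' @export
write_cohort_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Process subjects listed in a manifest file
#'
#' Reads the `manifest.csv` written by [write_cohort()] (or assembled by
#' hand for real data): one row per subject x montage with columns
#' `subject`, `montage`, `pial`, `white`, `field`, `seeds`,
#' `montage_file`, and optionally `surface_format`.  Runs the pipeline on
#' every row and returns the cohort table.
#'
#' @param manifest_path path to the manifest CSV.
#' @param k ring depth (default 5).
#' @param mask optional mask NIfTI path applied to all rows.
#' @param proxy_montages montages for which the proxy angle is computed.
#' @param verbose log per-stage counts.
#' @return Cohort table as from [run_cohort()].
#' @export
run_manifest <- function(manifest_path, k = 5L, mask = NULL,
                         proxy_montages = c("PA", "ML"), verbose = FALSE) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject", "montage", "pial", "white", "field", "seeds")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  mask_arr <- if (!is.null(mask)) read_mask_nifti(mask)
  rows <- list(); failures <- character()
  for (i in seq_len(nrow(man))) {
    m <- man[i, ]
    res <- tryCatch({
      fmt <- if ("surface_format" %in% names(man)) m$surface_format else NULL
      pial <- read_surface(m$pial, format = fmt)
      white <- read_surface(m$white, format = fmt)
      field <- read_field_nifti(m$field)
      seeds <- read_roi_seeds(m$seeds)
      montage <- if (m$montage %in% proxy_montages &&
                     "montage_file" %in% names(man) && nzchar(m$montage_file))
        read_montage(m$montage_file)
      run_subject(pial, white, field, seeds, montage = montage, k = k,
                  mask = mask_arr, verbose = verbose)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s/%s: %s", m$subject, m$montage,
                                      conditionMessage(res)))
      warning("manifest row ", i, " (", m$subject, "/", m$montage, ") failed: ",
              conditionMessage(res), call. = FALSE)
      next
    }
    tab <- res$summaries
    tab$theta_elm_deg <- ifelse(tab$label == "M1_BANK" & !is.na(res$theta_elm_deg),
                                res$theta_elm_deg, NA_real_)
    rows[[length(rows) + 1L]] <- cbind(subject = m$subject, montage = m$montage, tab)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_cohort_table()
  rownames(out) <- NULL
  structure(out, failures = failures)
}
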