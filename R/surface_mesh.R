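#' Triangle surface mesh in world (RAS) millimetres
#'
#' Container for a cortical surface: an `n x 3` vertex matrix, an `m x 3`
#' integer face matrix (1-based vertex indices, consistent winding), and
#' optionally an `n x 3` matrix of unit inner normals (pointing toward the
#' white matter, i.e. away from the outward winding direction).
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm, RAS).
#' @param faces integer `m x 3` matrix of 1-based vertex indices; each face
#'   must reference three distinct valid vertices.
#' @param normals optional numeric `n x 3` matrix of unit inner normals.
#' @return An object of class `surface_mesh`.
#' @seealso [build_midsurface()], [compute_inner_normals()], [read_surface()]
#' @export
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1L, 2L, 3L)))
#' m
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as_matrix3(vertices, "vertices")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  storage.mode(faces) <- "integer"
  nv <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nv)
      stop("face indices must be between 1 and the number of vertices", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] | faces[, 2] == faces[, 3]))
      stop("a face may not repeat a vertex", call. = FALSE)
  }
  if (!is.null(normals)) {
    normals <- as_matrix3(normals, "normals")
    if (nrow(normals) != nv)
      stop("normals must have one row per vertex", call. = FALSE)
    len <- rownorms(normals)
    if (any(abs(len - 1) > 1e-9))
      stop("normals must be unit length (|len - 1| <= 1e-9)", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, normals: %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$normals)) "absent" else "present"))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a surface_mesh", call. = FALSE)
  mesh
}

#' Average pial and white-matter surfaces into a mid-grey surface
#'
#' The grey-matter analysis surface is built by vertex-wise averaging of a
#' pial and a white-matter mesh that share topology (same vertex count,
#' identical face list, 1:1 vertex correspondence as produced by a single
#' surface reconstruction).  Sampling the field on this mid surface keeps
#' the lookup inside grey matter rather than adjacent CSF or white matter.
#'
#' @param pial,white `surface_mesh` objects with identical vertex counts
#'   and identical face matrices.
#' @return A `surface_mesh` whose vertex `i` is the midpoint of pial vertex
#'   `i` and white vertex `i`; faces are copied; normals are unset.
#' @export
build_midsurface <- function(pial, white) {
  stopifnot_mesh(pial); stopifnot_mesh(white)
  if (n_vertices(pial) != n_vertices(white))
    stop("pial/white vertex correspondence broken: vertex counts differ (",
         n_vertices(pial), " vs ", n_vertices(white), ")", call. = FALSE)
  if (n_faces(pial) != n_faces(white) || !identical(unname(pial$faces), unname(white$faces)))
    stop("pial/white vertex correspondence broken: face lists differ", call. = FALSE)
  surface_mesh((pial$vertices + white$vertices) / 2, pial$faces)
}

#' Translate a surface by a world-space offset
#'
#' Used e.g. to undo the central-voxel-to-RAS offset some reconstruction
#' tools bake into their surface files, so surfaces and field volumes share
#' one world frame.
#'
#' @param mesh a `surface_mesh`.
#' @param offset length-3 numeric offset in mm.
#' @return The translated `surface_mesh` (faces and normals unchanged).
#' @export
translate_surface <- function(mesh, offset) {
  stopifnot_mesh(mesh)
  offset <- as.numeric(offset)
  if (length(offset) != 3L || !all(is.finite(offset)))
    stop("offset must be 3 finite numbers", call. = FALSE)
  mesh$vertices <- sweep(mesh$vertices, 2L, offset, "+")
  mesh
}

#' Compute inner (white-matter-pointing) unit vertex normals
#'
#' Per-vertex normals are the normalized area-weighted average of incident
#' face normals (right-hand rule on the winding), negated so they point to
#' the interior.  Meshes are expected to be wound outward (face normals
#' away from the white matter), the convention the synthetic generator and
#' all supported readers follow.  Degenerate (zero-area) faces are skipped;
#' a vertex all of whose incident faces are degenerate (or that touches no
#' face) is an error.
#'
#' @param mesh a `surface_mesh`.
#' @return The mesh with `normals` set to unit inner normals.
#' @export
compute_inner_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0L) stop("mesh has no faces; normals are undefined", call. = FALSE)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cross3(e1, e2)            # |cr| = 2 * face area: summing is area weighting
  area2 <- rownorms(cr)
  ok <- area2 > 1e-12
  N <- matrix(0, nrow(V), 3L)
  touched <- logical(nrow(V))
  if (any(ok)) {
    Fok <- F[ok, , drop = FALSE]
    crok <- cr[ok, , drop = FALSE]
    for (c in 1:3) {
      agg <- rowsum(crok, Fok[, c])
      ids <- as.integer(rownames(agg))
      N[ids, ] <- N[ids, ] + agg
      touched[ids] <- TRUE
    }
  }
  if (!all(touched)) {
    bad <- which(!touched)[1]
    stop("degenerate geometry: vertex ", bad,
         " has no non-degenerate incident face", call. = FALSE)
  }
  len <- rownorms(N)
  if (any(len < 1e-12))
    stop("degenerate geometry: incident face normals cancel at vertex ",
         which(len < 1e-12)[1], call. = FALSE)
  mesh$normals <- -N / len        # negate: winding is outward, we want inner
  mesh
}
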