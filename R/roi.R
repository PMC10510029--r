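#' Labelled region of interest on a surface mesh
#'
#' An ROI is a labelled set of vertices (with the faces entirely contained
#' in it) grown around a centre vertex, e.g. the sulcal-bank or
#' gyral-crown patches `M1_BANK`, `M1_CROWN`, `S1_BANK`, `S1_CROWN`.
#'
#' @param label character label.
#' @param center_vertex centre vertex index (must be a member).
#' @param vertices integer vector of member vertex indices (non-empty).
#' @param faces integer vector of member face indices; every member face
#'   must have all three corners in `vertices`.
#' @param mesh the `surface_mesh` the indices refer to (used for checks).
#' @return An object of class `roi`.
#' @seealso [build_roi()], [resolve_overlaps()]
#' @export
roi <- function(label, center_vertex, vertices, faces, mesh) {
  stopifnot_mesh(mesh)
  vertices <- sort(unique(as.integer(vertices)))
  faces <- sort(unique(as.integer(faces)))
  center_vertex <- as.integer(center_vertex)
  if (length(vertices) == 0L) stop("an ROI may not be empty", call. = FALSE)
  if (!center_vertex %in% vertices)
    stop("center_vertex must belong to the ROI", call. = FALSE)
  if (length(faces) && (min(faces) < 1L || max(faces) > n_faces(mesh)))
    stop("ROI face index out of range", call. = FALSE)
  if (length(faces)) {
    corner_ok <- matrix(mesh$faces[faces, , drop = FALSE] %in% vertices, ncol = 3L)
    if (!all(corner_ok))
      stop("every ROI face must have all three corners in the ROI", call. = FALSE)
  }
  structure(list(label = as.character(label), center_vertex = center_vertex,
                 vertices = vertices, faces = faces),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s: %d vertices, %d faces, centre vertex %d\n",
              x$label, length(x$vertices), length(x$faces), x$center_vertex))
  invisible(x)
}

#' Nearest mesh vertex to a world-space point
#'
#' Snaps an anatomical seed coordinate (e.g. a visually identified
#' hand-knob bank/crown centre) to the mesh, minimizing Euclidean
#' distance; ties go to the smallest index.
#'
#' @param mesh a `surface_mesh` with at least one vertex.
#' @param point length-3 point in mm.
#' @return A vertex index.
#' @export
nearest_vertex <- function(mesh, point) {
  stopifnot_mesh(mesh)
  if (n_vertices(mesh) == 0L) stop("mesh has no vertices", call. = FALSE)
  point <- as_point3(point)
  d2 <- rowSums(sweep(mesh$vertices, 2L, point, "-")^2)
  which.min(d2)   # which.min returns the first (= smallest-index) minimum
}

# undirected edge list of the face graph, one row per unique edge
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mesh_graph <- function(mesh, weighted = FALSE) {
  e <- mesh_edges(mesh)
  g <- igraph::make_empty_graph(n = n_vertices(mesh), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  if (weighted) {
    w <- rownorms(mesh$vertices[e[, 1], , drop = FALSE] -
                  mesh$vertices[e[, 2], , drop = FALSE])
    igraph::E(g)$weight <- w
  }
  g
}

#' Vertices within k edge hops of a centre vertex
#'
#' The k-ring neighbourhood on the face-edge graph (centre = ring 0), the
#' "extend radially outward by k vertices" construction used to grow ROIs.
#'
#' @param mesh a `surface_mesh`.
#' @param center centre vertex index.
#' @param k non-negative integer ring depth.
#' @return Sorted integer vector of vertex indices.
#' @export
ring_neighborhood <- function(mesh, center, k) {
  stopifnot_mesh(mesh)
  center <- as.integer(center)
  if (is.na(center) || center < 1L || center > n_vertices(mesh))
    stop("invalid center vertex index: ", center, call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a non-negative integer", call. = FALSE)
  if (k == 0L) return(center)
  g <- mesh_graph(mesh)
  sort(as.integer(igraph::ego(g, order = k, nodes = center)[[1]]))
}

#' Faces entirely contained in a vertex set
#'
#' @param mesh a `surface_mesh`.
#' @param vertex_set integer vector of vertex indices.
#' @return Sorted integer vector of face indices whose three corners are
#'   all in `vertex_set`.
#' @export
faces_within <- function(mesh, vertex_set) {
  stopifnot_mesh(mesh)
  vertex_set <- as.integer(vertex_set)
  if (length(vertex_set) && (min(vertex_set) < 1L || max(vertex_set) > n_vertices(mesh)))
    stop("vertex_set index out of range", call. = FALSE)
  inside <- logical(n_vertices(mesh))
  inside[vertex_set] <- TRUE
  F <- mesh$faces
  which(inside[F[, 1]] & inside[F[, 2]] & inside[F[, 3]])
}

#' Graph geodesic distance between two vertices
#'
#' Length of the shortest path along mesh edges, each edge weighted by its
#' Euclidean length (a graph approximation of the polyhedral geodesic,
#' adequate at ROI scale).
#'
#' @param mesh a `surface_mesh`.
#' @param a,b vertex indices.
#' @return Distance in mm; 0 iff `a == b`.
#' @export
geodesic_distance <- function(mesh, a, b) {
  stopifnot_mesh(mesh)
  a <- as.integer(a); b <- as.integer(b)
  nv <- n_vertices(mesh)
  if (anyNA(c(a, b)) || a < 1L || a > nv || b < 1L || b > nv)
    stop("invalid vertex index", call. = FALSE)
  if (a == b) return(0)
  g <- mesh_graph(mesh, weighted = TRUE)
  d <- igraph::distances(g, v = a, to = b)[1, 1]
  if (!is.finite(d))
    stop("vertices ", a, " and ", b, " are in different connected components",
         call. = FALSE)
  d
}

#' Build an ROI by ring expansion around a seed point
#'
#' Snaps the seed to the nearest vertex, grows the k-ring neighbourhood
#' (default `k = 5`), and includes the faces entirely within it.  A seed
#' far from the mesh still snaps to the nearest vertex.
#'
#' @param mesh a `surface_mesh`.
#' @param label ROI label.
#' @param seed_point length-3 seed coordinate in mm.
#' @param k ring depth (default 5).
#' @return An `roi`.
#' @export
build_roi <- function(mesh, label, seed_point, k = 5L) {
  center <- nearest_vertex(mesh, seed_point)
  verts <- ring_neighborhood(mesh, center, k)
  roi(label, center, verts, faces_within(mesh, verts), mesh)
}

#' Resolve overlapping vertices between two ROIs by geodesic distance
#'
#' Each vertex present in both ROIs is kept only in the ROI whose centre
#' is geodesically closer (graph geodesic along mesh edges).  Exactly
#' equal distances go to the bank-labelled ROI when exactly one of the two
#' labels contains "BANK" (case-insensitive), otherwise to the
#' lexicographically smaller label.  Faces are recomputed from the updated
#' vertex sets; non-shared vertices are untouched.
#'
#' @param mesh the common `surface_mesh`.
#' @param roi_a,roi_b `roi` objects built on `mesh`.
#' @return A list of the two updated ROIs, in input order.
#' @export
resolve_overlaps <- function(mesh, roi_a, roi_b) {
  stopifnot_mesh(mesh)
  shared <- intersect(roi_a$vertices, roi_b$vertices)
  if (roi_a$center_vertex %in% roi_b$vertices ||
      roi_b$center_vertex %in% roi_a$vertices)
    stop("internal consistency error: an ROI centre lies inside the other ROI",
         call. = FALSE)
  if (length(shared) == 0L) return(list(roi_a, roi_b))
  g <- mesh_graph(mesh, weighted = TRUE)
  d <- igraph::distances(g, v = c(roi_a$center_vertex, roi_b$center_vertex),
                         to = shared)
  a_wins_tie <- tie_goes_to_first(roi_a$label, roi_b$label)
  keep_a <- d[1, ] < d[2, ] | (d[1, ] == d[2, ] & a_wins_tie)
  va <- setdiff(roi_a$vertices, shared[!keep_a])
  vb <- setdiff(roi_b$vertices, shared[keep_a])
  list(
    roi(roi_a$label, roi_a$center_vertex, va, faces_within(mesh, va), mesh),
    roi(roi_b$label, roi_b$center_vertex, vb, faces_within(mesh, vb), mesh)
  )
}

tie_goes_to_first <- function(label_a, label_b) {
  bank_a <- grepl("BANK", label_a, ignore.case = TRUE)
  bank_b <- grepl("BANK", label_b, ignore.case = TRUE)
  if (bank_a != bank_b) bank_a else label_a <= label_b
}

#' Read and write ROI seed tables
#'
#' Plain-text (CSV) table with columns `subject`, `label`, `x`, `y`, `z`
#' (mm, world space), one row per ROI seed.
#'
#' @param path file path.
#' @return `read_roi_seeds()` returns a data.frame with those columns.
#' @export
read_roi_seeds <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "label", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("seed table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  df[, need]
}

#' @rdname read_roi_seeds
#' @param seeds a data.frame with columns `subject`, `label`, `x`, `y`, `z`.
#' @export
write_roi_seeds <- function(seeds, path) {
  write.csv(seeds[, c("subject", "label", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Export ROI membership as a table
#'
#' @param rois list of `roi` objects.
#' @param subject subject identifier recycled across rows.
#' @return data.frame with columns `subject`, `label`, `vertex`.
#' @export
roi_membership <- function(rois, subject = "subject") {
  do.call(rbind, lapply(rois, function(r)
    data.frame(subject = subject, label = r$label, vertex = r$vertices,
               stringsAsFactors = FALSE)))
}
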