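# geometry fixtures and independent oracles, built in code

# flat triangulated sheet in the z = 0 plane, wound outward toward +z,
# interior below (inner normals should be (0, 0, -1))
flat_sheet <- function(nx = 5, ny = 4, spacing = 1) {
  xs <- seq(0, by = spacing, length.out = nx)
  ys <- seq(0, by = spacing, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  surface_mesh(V, do.call(rbind, faces))
}

tetrahedron <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  F <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(V, F)
}

single_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
}

# independent breadth-first search oracle over the face-edge graph
bfs_oracle <- function(mesh, center, k) {
  adj <- vector("list", nrow(mesh$vertices))
  F <- mesh$faces
  for (f in seq_len(nrow(F))) {
    tri <- F[f, ]
    for (p in 1:3) for (q in 1:3) if (p != q)
      adj[[tri[p]]] <- c(adj[[tri[p]]], tri[q])
  }
  dist <- rep(Inf, nrow(mesh$vertices))
  dist[center] <- 0
  frontier <- center
  depth <- 0
  while (length(frontier) && depth < k) {
    depth <- depth + 1
    nxt <- integer()
    for (v in frontier) for (w in adj[[v]]) if (dist[w] > depth) {
      dist[w] <- depth
      nxt <- c(nxt, w)
    }
    frontier <- unique(nxt)
  }
  sort(which(dist <= k))
}

# exhaustive simple-path enumeration oracle for graph geodesics (tiny meshes)
enumeration_oracle <- function(mesh, a, b) {
  V <- mesh$vertices
  edges <- unique(rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                        mesh$faces[, c(3, 1)],
                        mesh$faces[, c(2, 1)], mesh$faces[, c(3, 2)],
                        mesh$faces[, c(1, 3)]))
  nbr <- split(edges[, 2], edges[, 1])
  best <- Inf
  recurse <- function(v, visited, len) {
    if (len >= best) return()
    if (v == b) { best <<- len; return() }
    for (w in nbr[[as.character(v)]]) if (!w %in% visited)
      recurse(w, c(visited, w), len + sqrt(sum((V[v, ] - V[w, ])^2)))
  }
  recurse(a, a, 0)
  best
}

# brute-force nearest voxel centre in world mm with row-major tie-break
exhaustive_nearest <- function(field, points) {
  shape <- field$shape
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  centers <- voxel_to_world(field$affine, idx)
  rank_rm <- (idx[, 1] * shape[2] + idx[, 2]) * shape[3] + idx[, 3]
  t(apply(points, 1L, function(p) {
    d2 <- colSums((t(centers) - p)^2)
    cand <- which(d2 == min(d2))
    idx[cand[which.min(rank_rm[cand])], ]
  }))
}

# a coarse randomly-parameterised folded mesh for property tests
random_fold_mesh <- function() {
  cfg <- synth_config(x_extent = 8, y_extent = 6, spacing = 2,
                      amplitude = runif(1, 0, 6), wavelength = runif(1, 15, 40),
                      phase = runif(1, -pi, pi))
  make_folded_surfaces(cfg)$mid
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

default_seeds <- function(cfg = synth_config()) {
  k <- 2 * pi / cfg$wavelength
  seed_x <- function(u) (u - cfg$phase) / k
  data.frame(
    label = c("M1_BANK", "M1_CROWN", "S1_BANK", "S1_CROWN"),
    x = c(seed_x(-pi), seed_x(-3 * pi / 2), seed_x(0), seed_x(pi / 2)),
    y = 0,
    z = cfg$amplitude * c(0, 1, 0, 1),
    stringsAsFactors = FALSE)
}

normalize_test <- function(v) v / sqrt(sum(v^2))

# axis-aligned 1 mm volume covering a synthetic sheet with 2 mm margin
fold_volume_geometry_test <- function(cfg) {
  zmax <- cfg$amplitude + cfg$thickness / 2 + 2
  lo <- c(-cfg$x_extent - 2, -cfg$y_extent - 2, -zmax)
  hi <- c(cfg$x_extent + 2, cfg$y_extent + 2, zmax)
  shape <- as.integer(floor((hi - lo) / cfg$voxel_size)) + 1L
  affine <- diag(c(rep(cfg$voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  list(shape = shape, affine = affine)
}
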