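#' Volumetric vector field with a voxel-to-world affine
#'
#' Holds one 3-component field vector per voxel (V/m, components along the
#' world axes) plus the 4x4 affine mapping 0-based voxel indices (voxel
#' centres at integer coordinates, the NIfTI convention) to world mm.
#'
#' @param vectors numeric 4-D array `ni x nj x nk x 3` of field vectors.
#' @param affine invertible 4x4 voxel-index-to-world-mm matrix.
#' @return An object of class `vector_field`.
#' @seealso [sample_nearest()], [read_field_nifti()]
#' @export
vector_field <- function(vectors, affine) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("vectors must be an ni x nj x nk x 3 array", call. = FALSE)
  if (!all(is.finite(vectors))) stop("all vector components must be finite", call. = FALSE)
  affine <- check_affine(affine)
  structure(list(vectors = vectors, affine = affine,
                 shape = dim(vectors)[1:3]),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d x %d voxels, 3 components\n",
              x$shape[1], x$shape[2], x$shape[3]))
  invisible(x)
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  storage.mode(affine) <- "double"
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular", call. = FALSE)
  affine
}

#' Convert between world mm and continuous voxel coordinates
#'
#' Voxel indices are 0-based with voxel centres at integer coordinates.
#'
#' @param affine invertible 4x4 voxel-to-world matrix.
#' @param points `n x 3` matrix (or length-3 vector) of world-mm points
#'   (`world_to_voxel`) or continuous voxel coordinates (`voxel_to_world`).
#' @return `n x 3` matrix of continuous voxel coordinates / world points.
#' @export
world_to_voxel <- function(affine, points) {
  affine <- check_affine(affine)
  points <- as_matrix3(points, "points")
  inv <- solve(affine)
  sweep(points %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(affine, points) {
  affine <- check_affine(affine)
  points <- as_matrix3(points, "voxel coordinates")
  sweep(points %*% t(affine[1:3, 1:3]), 2L, affine[1:3, 4], "+")
}

#' Sample a vector field at surface vertices by nearest-neighbour lookup
#'
#' For every mesh vertex the field vector of the voxel whose centre is
#' nearest in world millimetres is returned (no interpolation).  Ties are
#' broken by row-major voxel order (smallest `i`, then `j`, then `k`).
#' With `mask` given, the search is restricted to voxels where the mask is
#' nonzero (e.g. grey-matter-labelled voxels).  Vertices outside the
#' volume's voxel lattice expanded by half a voxel are an error (they
#' indicate a coordinate-convention bug upstream), never clamped.
#'
#' @param field a `vector_field`.
#' @param mesh a `surface_mesh` whose vertices lie inside the volume.
#' @param mask optional logical/numeric `ni x nj x nk` array; nonzero
#'   voxels are eligible.
#' @return An object of class `sampled_field`: list with `vectors`
#'   (`n x 3`, V/m) and `voxel_index` (`n x 3`, 0-based source voxel).
#' @export
sample_nearest <- function(field, mesh, mask = NULL) {
  if (!inherits(field, "vector_field")) stop("expected a vector_field", call. = FALSE)
  stopifnot_mesh(mesh)
  shape <- field$shape
  vox <- world_to_voxel(field$affine, mesh$vertices)
  for (d in 1:3) {
    out <- which(vox[, d] < -0.5 | vox[, d] > shape[d] - 0.5)
    if (length(out))
      stop("vertex ", out[1], " is outside the field volume (voxel coordinate ",
           formatC(vox[out[1], d]), " on axis ", d, ")", call. = FALSE)
  }
  L <- field$affine[1:3, 1:3]
  if (!is.null(mask)) {
    if (!identical(dim(mask)[1:3], as.integer(shape)) &&
        !identical(dim(mask)[1:3], shape))
      stop("mask shape must match the field volume", call. = FALSE)
    keep <- which(as.logical(mask != 0))
    if (length(keep) == 0L) stop("mask excludes every voxel", call. = FALSE)
    idx0 <- arrayInd(keep, .dim = shape) - 1L
    centers <- voxel_to_world(field$affine, idx0)
    rank_rm <- (idx0[, 1] * shape[2] + idx0[, 2]) * shape[3] + idx0[, 3]
    best <- t(vapply(seq_len(n_vertices(mesh)), function(i) {
      d2 <- colSums((t(centers) - mesh$vertices[i, ])^2)
      cand <- which(d2 == min(d2))
      cand[which.min(rank_rm[cand])]
    }, 1L))
    src <- idx0[as.integer(best), , drop = FALSE]
  } else {
    src <- nearest_voxel_unmasked(vox, shape, L)
  }
  flat <- ((src[, 3] * shape[2] + src[, 2]) * shape[1]) + src[, 1] + 1L  # column-major
  nvox <- prod(shape)
  vecs <- cbind(field$vectors[flat],
                field$vectors[flat + nvox],
                field$vectors[flat + 2L * nvox])
  structure(list(vectors = vecs, voxel_index = src), class = "sampled_field")
}

# provably-nearest local search: any voxel centre closer (in world mm) than
# the rounded candidate lies within an index ball of radius
# ||L^-1||_2 * d0 around the continuous voxel coordinate
nearest_voxel_unmasked <- function(vox, shape, L) {
  n <- nrow(vox)
  c0 <- round(vox)
  for (d in 1:3) c0[, d] <- pmin(pmax(c0[, d], 0), shape[d] - 1)
  diffw <- (vox - c0) %*% t(L)
  d0 <- sqrt(rowSums(diffw^2))
  opnorm_inv <- max(svd(solve(L), nu = 0, nv = 0)$d)
  r <- ceiling(opnorm_inv * d0 + 1e-9)
  rmax <- max(r, 1)
  offs <- as.matrix(expand.grid(i = -rmax:rmax, j = -rmax:rmax, k = -rmax:rmax))
  best_d2 <- rep(Inf, n)
  best_rank <- rep(Inf, n)
  best_idx <- matrix(0L, n, 3L)
  Lt <- t(L)
  for (o in seq_len(nrow(offs))) {
    cand <- sweep(c0, 2L, as.numeric(offs[o, ]), "+")
    ok <- cand[, 1] >= 0 & cand[, 1] < shape[1] &
          cand[, 2] >= 0 & cand[, 2] < shape[2] &
          cand[, 3] >= 0 & cand[, 3] < shape[3]
    if (!any(ok)) next
    dw <- (vox - cand) %*% Lt
    d2 <- rowSums(dw^2)
    rank_rm <- (cand[, 1] * shape[2] + cand[, 2]) * shape[3] + cand[, 3]
    better <- ok & (d2 < best_d2 | (d2 == best_d2 & rank_rm < best_rank))
    if (any(better)) {
      best_d2[better] <- d2[better]
      best_rank[better] <- rank_rm[better]
      best_idx[better, ] <- cand[better, , drop = FALSE]
    }
  }
  storage.mode(best_idx) <- "integer"
  best_idx
}

#' @export
print.sampled_field <- function(x, ...) {
  cat(sprintf("<sampled_field> %d vertices\n", nrow(x$vectors)))
  invisible(x)
}

#' Read and write field volumes as NIfTI
#'
#' The volume is NIfTI-1, 4-D with the last dimension of size 3 (field
#' components along the world x, y, z axes); the affine is taken from the
#' file's sform/qform.  Masks are 3-D NIfTI volumes, nonzero = included.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_field_nifti()` returns a `vector_field`;
#'   `read_mask_nifti()` a logical 3-D array.
#' @export
read_field_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a 4-D NIfTI with 3 components in the last dimension, got dims ",
         paste(dim(arr), collapse = "x"), call. = FALSE)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  vector_field(arr, aff)
}

#' @rdname read_field_nifti
#' @param field a `vector_field` to write.
#' @export
write_field_nifti <- function(field, path) {
  if (!inherits(field, "vector_field")) stop("expected a vector_field", call. = FALSE)
  img <- RNifti::asNifti(field$vectors)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_field_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D NIfTI mask, got dims ",
         paste(dim(arr), collapse = "x"), call. = FALSE)
  arr != 0
}
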