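# small internal vector helpers; all take plain numeric vectors/matrices

vnorm <- function(v) sqrt(sum(v^2))

rownorms <- function(m) sqrt(rowSums(m^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  # row-wise cross product of two n x 3 matrices
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

as_point3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L) stop(what, " must have exactly 3 coordinates", call. = FALSE)
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  x
}

as_matrix3 <- function(x, what = "coordinates") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop(what, " must be an n x 3 matrix", call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
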