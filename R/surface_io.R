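#' Read and write triangle surface meshes
#'
#' Supported dialects:
#' \describe{
#'   \item{`"off"`}{ASCII OFF. Full double precision.}
#'   \item{`"ply"`}{PLY, ASCII or binary little-endian (autodetected on
#'     read; chosen by `binary=` on write). Vertices are written as
#'     float64, so round trips are exact to 1e-6 mm and better.}
#'   \item{`"gifti"`}{GIfTI surface (`.surf.gii`): a POINTSET and a
#'     TRIANGLE data array, Base64 or GZip-Base64 encoded. The format
#'     stores float32 coordinates, so round trips are exact only to
#'     float32 resolution (about 1e-5 relative).}
#'   \item{`"freesurfer"`}{FreeSurfer binary triangle surface (big-endian
#'     float32 coordinates). A per-file world offset (the `cras` line of
#'     the embedded volume-geometry block) is honoured: on read it is
#'     added to the vertices via [translate_surface()] (set
#'     `apply_offset = FALSE` to keep raw coordinates, with the offset
#'     attached as attribute `"world_offset"`); on write an `offset`
#'     argument is stored in the file and subtracted from the vertices.}
#' }
#' `format` defaults to a guess from the file extension
#' (`.off`, `.ply`, `.gii`, anything else = freesurfer).
#'
#' @param path file path.
#' @param format one of `"off"`, `"ply"`, `"gifti"`, `"freesurfer"`, or
#'   `NULL` to guess from the extension.
#' @param apply_offset freesurfer only: apply the stored world offset
#'   (default `TRUE`).
#' @return `read_surface()` returns a `surface_mesh`; `write_surface()`
#'   returns `path` invisibly.
#' @export
read_surface <- function(path, format = NULL, apply_offset = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||% guess_surface_format(path)
  mesh <- switch(format,
    off = read_off(path),
    ply = read_ply(path),
    gifti = read_gifti_surface(path),
    freesurfer = read_freesurfer_surface(path, apply_offset = apply_offset),
    stop("unknown surface format: ", format, call. = FALSE)
  )
  mesh
}

#' @rdname read_surface
#' @param mesh a `surface_mesh` to write.
#' @param binary ply only: write binary little-endian instead of ASCII.
#' @param offset freesurfer only: world offset (mm) to record in the file;
#'   the stored coordinates are `vertices - offset`.
#' @export
write_surface <- function(mesh, path, format = NULL, binary = FALSE,
                          offset = c(0, 0, 0)) {
  stopifnot_mesh(mesh)
  format <- format %||% guess_surface_format(path)
  switch(format,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    gifti = write_gifti_surface(mesh, path),
    freesurfer = write_freesurfer_surface(mesh, path, offset = offset),
    stop("unknown surface format: ", format, call. = FALSE)
  )
  invisible(path)
}

guess_surface_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.off$", low)) return("off")
  if (grepl("\\.ply$", low)) return("ply")
  if (grepl("\\.gii$", low)) return("gifti")
  "freesurfer"
}

# ---- OFF ------------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("parse error in ", path, ": empty file", call. = FALSE)
  i <- 1L
  if (toupper(lines[1]) == "OFF") i <- 2L
  if (length(lines) < i) stop("parse error in ", path, ": missing count line", call. = FALSE)
  counts <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
  if (length(counts) < 2L || anyNA(counts))
    stop("parse error in ", path, " line ", i, ": expected 'nv nf ne'", call. = FALSE)
  nv <- as.integer(counts[1]); nf <- as.integer(counts[2])
  body <- lines[-seq_len(i)]
  if (length(body) < nv + nf)
    stop("parse error in ", path, ": expected ", nv + nf,
         " data lines, found ", length(body), call. = FALSE)
  V <- parse_num_block(body[seq_len(nv)], 3L, path, offset = i)
  Fl <- lapply(seq_len(nf), function(j) {
    f <- suppressWarnings(as.numeric(strsplit(body[nv + j], "\\s+")[[1]]))
    if (length(f) < 4L || anyNA(f[1:4]) || f[1] != 3)
      stop("parse error in ", path, " line ", i + nv + j,
           ": expected a triangle '3 i j k'", call. = FALSE)
    f[2:4]
  })
  F <- do.call(rbind, Fl) + 1L
  validate_read_faces(F, nv, path)
  surface_mesh(V, F)
}

write_off <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  writeLines(apply(mesh$vertices, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  if (n_faces(mesh) > 0L)
    writeLines(apply(mesh$faces - 1L, 1L, function(f)
      paste(c(3L, f), collapse = " ")), con)
}

parse_num_block <- function(lines, ncol, path, offset = 0L) {
  vals <- suppressWarnings(lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  bad <- which(vapply(vals, function(v) length(v) < ncol || anyNA(v[seq_len(ncol)]), TRUE))
  if (length(bad))
    stop("parse error in ", path, " line ", offset + bad[1],
         ": expected ", ncol, " numbers", call. = FALSE)
  do.call(rbind, lapply(vals, function(v) v[seq_len(ncol)]))
}

validate_read_faces <- function(F, nv, path) {
  if (nrow(F) && (min(F) < 1L || max(F) > nv))
    stop("validation error in ", path, ": face index out of range (valid 0..",
         nv - 1L, " in file indexing)", call. = FALSE)
}

# ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply"))
    stop("parse error in ", path, ": not a PLY file (missing 'ply' magic)", call. = FALSE)
  fmt <- NULL; elements <- list(); cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("parse error in ", path, ": header not terminated", call. = FALSE)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[5], list = TRUE,
                                                    count_type = tok[3], type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <- list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("parse error in ", path, ": unsupported PLY format '", fmt %||% "?", "'", call. = FALSE)
  ve <- elements[["vertex"]]; fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe))
    stop("parse error in ", path, ": need 'vertex' and 'face' elements", call. = FALSE)
  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < ve$count + fe$count)
      stop("parse error in ", path, ": truncated PLY body", call. = FALSE)
    pnames <- vapply(ve$props, `[[`, "", "name")
    block <- parse_num_block(lines[seq_len(ve$count)], length(pnames), path)
    V <- block[, match(c("x", "y", "z"), pnames), drop = FALSE]
    Fl <- lapply(seq_len(fe$count), function(j) {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[ve$count + j]), "\\s+")[[1]]))
      if (length(f) < 1L || anyNA(f[1]) || f[1] != 3 || length(f) < 4L)
        stop("parse error in ", path, ": face ", j, " is not a triangle", call. = FALSE)
      f[2:4]
    })
    F <- do.call(rbind, Fl) + 1L
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_scalar <- function(type, n = 1L) {
      sz <- sizes[[type]]
      if (is.null(sz)) stop("parse error in ", path, ": PLY type '", type, "'", call. = FALSE)
      what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
      readBin(con, what, n = n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    pr <- ve$props
    V <- matrix(NA_real_, ve$count, 3L)
    simple <- all(!vapply(pr, `[[`, TRUE, "list"))
    if (!simple) stop("parse error in ", path, ": list property on vertex element", call. = FALSE)
    pnames <- vapply(pr, `[[`, "", "name")
    types <- vapply(pr, `[[`, "", "type")
    if (length(unique(types)) == 1L) {
      block <- read_scalar(types[1], n = ve$count * length(pr))
      block <- matrix(block, ncol = length(pr), byrow = TRUE)
      V <- block[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else {
      for (i in seq_len(ve$count))
        for (p in seq_along(pr)) {
          val <- read_scalar(types[p])
          k <- match(pnames[p], c("x", "y", "z"))
          if (!is.na(k)) V[i, k] <- val
        }
    }
    fp <- fe$props[[1]]
    if (!fp$list) stop("parse error in ", path, ": face element lacks a list property", call. = FALSE)
    F <- matrix(NA_integer_, fe$count, 3L)
    for (i in seq_len(fe$count)) {
      cnt <- read_scalar(fp$count_type)
      if (cnt != 3L) stop("parse error in ", path, ": face ", i, " has ", cnt, " corners", call. = FALSE)
      F[i, ] <- read_scalar(fp$type, 3L)
    }
    F <- F + 1L
  }
  validate_read_faces(F, nrow(V), path)
  surface_mesh(V, F)
}

write_ply <- function(mesh, path, binary = FALSE) {
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n_vertices(mesh)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", n_faces(mesh)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    if (n_faces(mesh) > 0L)
      for (i in seq_len(n_faces(mesh))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
      }
  } else {
    writeLines(apply(mesh$vertices, 1L, function(v)
      paste(sprintf("%.17g", v), collapse = " ")), con)
    if (n_faces(mesh) > 0L)
      writeLines(apply(mesh$faces - 1L, 1L, function(f)
        paste(c(3L, f), collapse = " ")), con)
  }
}

# ---- GIfTI ----------------------------------------------------------------

read_gifti_surface <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L)
    stop("parse error in ", path, ": no DataArray elements", call. = FALSE)
  decode <- function(node, what) {
    enc <- xml2::xml_attr(node, "Encoding")
    endian <- tolower(xml2::xml_attr(node, "Endian") %||% "LittleEndian")
    dtype <- xml2::xml_attr(node, "DataType")
    order <- xml2::xml_attr(node, "ArrayIndexingOrder") %||% "RowMajorOrder"
    n0 <- as.integer(xml2::xml_attr(node, "Dim0"))
    txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (identical(enc, "GZipBase64Binary")) raw <- memDecompress(raw, type = "gzip")
    else if (!identical(enc, "Base64Binary"))
      stop("parse error in ", path, ": unsupported encoding '", enc, "'", call. = FALSE)
    endian <- if (grepl("big", endian, ignore.case = TRUE)) "big" else "little"
    vals <- switch(dtype,
      NIFTI_TYPE_FLOAT32 = readBin(raw, "double", n = length(raw) / 4L, size = 4L, endian = endian),
      NIFTI_TYPE_FLOAT64 = readBin(raw, "double", n = length(raw) / 8L, size = 8L, endian = endian),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", n = length(raw) / 4L, size = 4L, endian = endian),
      stop("parse error in ", path, ": unsupported DataType '", dtype, "'", call. = FALSE))
    matrix(vals, ncol = 3L, byrow = identical(order, "RowMajorOrder"))
  }
  intents <- vapply(arrays, function(a) xml2::xml_attr(a, "Intent"), "")
  ip <- match("NIFTI_INTENT_POINTSET", intents)
  it <- match("NIFTI_INTENT_TRIANGLE", intents)
  if (is.na(ip) || is.na(it))
    stop("parse error in ", path, ": need POINTSET and TRIANGLE arrays", call. = FALSE)
  V <- decode(arrays[[ip]], "vertices")
  F <- decode(arrays[[it]], "faces") + 1L
  storage.mode(F) <- "integer"
  validate_read_faces(F, nrow(V), path)
  surface_mesh(V, F)
}

write_gifti_surface <- function(mesh, path) {
  b64 <- function(raw) jsonlite::base64_enc(raw)
  vraw <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 4L, endian = "little")
  fraw <- writeBin(as.integer(t(mesh$faces - 1L)), raw(), size = 4L, endian = "little")
  da <- function(intent, dtype, dim0, data)
    paste0('  <DataArray Intent="', intent, '" DataType="', dtype,
           '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', dim0,
           '" Dim1="3" Encoding="Base64Binary" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
           "    <Data>", data, "</Data>\n  </DataArray>")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<!DOCTYPE GIFTI SYSTEM "http://www.nitrc.org/frs/download.php/115/gifti.dtd">\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    da("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32", n_vertices(mesh), b64(vraw)), "\n",
    da("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32", n_faces(mesh), b64(fraw)), "\n",
    "</GIFTI>\n")
  writeLines(xml, path, sep = "")
}

# ---- FreeSurfer binary surface -------------------------------------------

FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)

read_freesurfer_surface <- function(path, apply_offset = TRUE) {
  sz <- file.size(path)
  con <- file(path, "rb"); on.exit(close(con))
  magic <- as.integer(readBin(con, "raw", n = 3L))
  if (!identical(magic, FS_TRIANGLE_MAGIC))
    stop("parse error in ", path, " at byte 0: not a FreeSurfer triangle surface",
         call. = FALSE)
  # creation comment: terminated by "\n\n"
  prev <- as.raw(0); nread <- 3L
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L)
      stop("parse error in ", path, ": unterminated comment", call. = FALSE)
    nread <- nread + 1L
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  nv <- readBin(con, "integer", size = 4L, endian = "big")
  nf <- readBin(con, "integer", size = 4L, endian = "big")
  if (is.na(nv) || is.na(nf) || nv < 0L || nf < 0L)
    stop("parse error in ", path, " at byte ", nread, ": bad counts", call. = FALSE)
  V <- matrix(readBin(con, "double", n = 3L * nv, size = 4L, endian = "big"),
              ncol = 3L, byrow = TRUE)
  F <- matrix(readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big"),
              ncol = 3L, byrow = TRUE) + 1L
  validate_read_faces(F, nv, path)
  # optional tail: tagged volume-geometry text carrying the world offset
  offset <- c(0, 0, 0)
  tail_raw <- readBin(con, "raw", n = max(0L, sz))
  if (length(tail_raw)) {
    txt <- rawToChar(tail_raw[tail_raw != as.raw(0)], multiple = FALSE)
    m <- regmatches(txt, regexec(
      "cras\\s*=\\s*(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)\\s+(-?[0-9.eE+-]+)", txt))[[1]]
    if (length(m) == 4L) offset <- as.numeric(m[2:4])
  }
  mesh <- surface_mesh(V, F)
  if (apply_offset) mesh <- translate_surface(mesh, offset)
  else attr(mesh, "world_offset") <- offset
  mesh
}

write_freesurfer_surface <- function(mesh, path, offset = c(0, 0, 0)) {
  offset <- as_point3(offset, "offset")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(FS_TRIANGLE_MAGIC), con)
  writeChar("created by tdcsdir\n\n", con, eos = NULL)
  writeBin(as.integer(n_vertices(mesh)), con, size = 4L, endian = "big")
  writeBin(as.integer(n_faces(mesh)), con, size = 4L, endian = "big")
  V <- sweep(mesh$vertices, 2L, offset, "-")
  writeBin(as.numeric(t(V)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4L, endian = "big")
  if (any(offset != 0)) {
    writeBin(20L, con, size = 4L, endian = "big")   # volume-geometry tag
    writeChar(sprintf(
      "valid = 1  # volume info valid\nvolume = 256 256 256\ncras   = %.10g %.10g %.10g\n",
      offset[1], offset[2], offset[3]), con, eos = NULL)
  }
}
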