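# Triangle-mesh file I/O: STL (binary and ASCII), PLY (ascii and
# binary_little_endian), OBJ (v/f records). STL stores one vertex triple per
# facet corner, so the reader welds duplicates back together with an
# exact-coordinate weld (bitwise equality via hex-float keys); this keeps the
# vertex-based distance of a round-tripped mesh identical to the logical mesh
# without any tolerance-dependent topology changes.

.mesh_format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (!ext %in% c("stl", "ply", "obj"))
    stop(sprintf("unsupported-format: cannot infer mesh format from '%s'", path))
  ext
}

.weld_vertices <- function(verts, faces, name) {
  key <- paste(sprintf("%a", verts[, 1L]), sprintf("%a", verts[, 2L]),
               sprintf("%a", verts[, 3L]))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  triangle_mesh(verts[first, , drop = FALSE],
                matrix(remap[faces], ncol = 3L), name)
}

#' Read a triangle mesh from file
#'
#' Supports binary and ASCII STL, ascii and binary little-endian PLY, and OBJ
#' (`v`/`f` records only; polygonal faces are fan-triangulated). STL input is
#' vertex-welded on exact coordinate equality.
#'
#' @param path Path to the mesh file.
#' @param format One of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when `NULL`.
#' @param name Mesh label; defaults to the file name.
#' @return A `triangle_mesh`.
#' @export
read_mesh <- function(path, format = NULL, name = NULL) {
  if (is.null(format)) format <- .mesh_format_from_path(path)
  format <- match.arg(tolower(format), c("stl", "ply", "obj"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (!file.exists(path)) stop(sprintf("format-error: no such file '%s'", path))
  switch(format,
         stl = .read_stl(path, name),
         ply = .read_ply(path, name),
         obj = .read_obj(path, name))
}

#' Write a triangle mesh to file
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output path.
#' @param format One of `"stl"` (binary), `"stl_ascii"`, `"ply"` (ascii),
#'   `"obj"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (is.null(format)) format <- .mesh_format_from_path(path)
  format <- match.arg(tolower(format), c("stl", "stl_ascii", "ply", "obj"))
  switch(format,
         stl = .write_stl_binary(mesh, path),
         stl_ascii = .write_stl_ascii(mesh, path),
         ply = .write_ply_ascii(mesh, path),
         obj = .write_obj(mesh, path))
  invisible(path)
}

# ---- STL ----

.stl_is_ascii <- function(path) {
  h <- readBin(path, "raw", n = 512L)
  length(h) >= 5L && identical(h[1:5], charToRaw("solid")) &&
    length(grepRaw("facet", h, fixed = TRUE)) > 0L
}

.read_stl <- function(path, name) {
  if (.stl_is_ascii(path)) .read_stl_ascii(path, name) else .read_stl_binary(path, name)
}

.read_stl_binary <- function(path, name) {
  size <- file.size(path)
  con <- file(path, "rb"); on.exit(close(con))
  if (size < 84L)
    stop(sprintf("format-error: binary STL truncated at byte %d (need 84-byte header)", size))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  need <- 84 + n_tri * 50
  if (size < need)
    stop(sprintf("format-error: binary STL truncated at byte %.0f (expected %.0f)",
                 size, need))
  raw <- readBin(con, "raw", n = n_tri * 50L)
  dim(raw) <- c(50L, n_tri)
  coords <- readBin(as.vector(raw[1:48, ]), "numeric", n = 12L * n_tri,
                    size = 4L, endian = "little")
  m <- matrix(coords, nrow = 12L)          # per facet: normal + 3 vertices
  verts <- matrix(rbind(m[4:6, ], m[7:9, ], m[10:12, ]), ncol = 3L, byrow = TRUE)
  faces <- matrix(seq_len(3L * n_tri), ncol = 3L, byrow = TRUE)
  .weld_vertices(verts, faces, name)
}

.read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("format-error: ASCII STL has no complete facets")
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("format-error: non-numeric vertex in ASCII STL")
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  .weld_vertices(verts, faces, name)
}

.write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", paste("binary STL", mesh$name)))[1:80]
  writeBin(header, con)
  n_tri <- nrow(mesh$faces)
  writeBin(as.integer(n_tri), con, size = 4L, endian = "little")
  V <- mesh$vertices
  for (i in seq_len(n_tri)) {
    tri <- V[mesh$faces[i, ], , drop = FALSE]
    nrm <- .face_normal(tri)
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
}

.face_normal <- function(tri) {
  u <- tri[2L, ] - tri[1L, ]; v <- tri[3L, ] - tri[1L, ]
  n <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  len <- sqrt(sum(n^2))
  if (len < 1e-30) c(0, 0, 0) else n / len
}

.write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  V <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- V[mesh$faces[i, ], , drop = FALSE]
    nrm <- .face_normal(tri)
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

# ---- PLY ----

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_ply <- function(path, name) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format-error: PLY header unterminated")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 200L) stop("format-error: PLY header too long")
  }
  if (header[1L] != "ply") stop("format-error: missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1L]), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported-format: PLY format '%s'", fmt))

  elems <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elems[[cur]] <- list(count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <-
        if (tok[2L] == "list") list(list = TRUE, count_type = tok[3L],
                                    type = tok[4L], name = tok[5L])
        else list(list = FALSE, type = tok[2L], name = tok[3L])
    }
  }
  if (is.null(elems$vertex)) stop("format-error: PLY without vertex element")
  if (fmt == "ascii") .read_ply_ascii(con, elems, name)
  else .read_ply_binary(con, elems, name)
}

.read_ply_ascii <- function(con, elems, name) {
  rest <- readLines(con, warn = FALSE)
  rest <- rest[nzchar(trimws(rest))]
  pos <- 1L
  verts <- NULL; faces <- matrix(integer(), 0L, 3L)
  for (en in names(elems)) {
    el <- elems[[en]]
    n <- el$count
    block <- rest[pos:(pos + n - 1L)]; pos <- pos + n
    if (en == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      tab <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
      verts <- tab[, match(c("x", "y", "z"), pn), drop = FALSE]
    } else if (en == "face") {
      fl <- lapply(strsplit(trimws(block), "\\s+"), as.integer)
      faces <- do.call(rbind, lapply(fl, function(r) {
        k <- r[1L]; idx <- r[2:(1L + k)] + 1L
        if (k < 3L) stop("format-error: PLY face with <3 vertices")
        cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])  # fan triangulation
      }))
    }
  }
  triangle_mesh(verts, faces, name)
}

.read_ply_binary <- function(con, elems, name) {
  verts <- NULL; faces <- matrix(integer(), 0L, 3L)
  read_scalar <- function(type, n = 1L) {
    sz <- .ply_type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "numeric", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4L && grepl("^u", type)))
  }
  for (en in names(elems)) {
    el <- elems[[en]]
    if (en == "vertex") {
      pn <- vapply(el$props, `[[`, "", "name")
      if (any(vapply(el$props, `[[`, TRUE, "list")))
        stop("unsupported-format: list property on PLY vertex element")
      verts <- matrix(NA_real_, el$count, 3L)
      for (i in seq_len(el$count)) {
        row <- numeric(length(el$props))
        for (j in seq_along(el$props)) row[j] <- read_scalar(el$props[[j]]$type)
        verts[i, ] <- row[match(c("x", "y", "z"), pn)]
      }
    } else if (en == "face") {
      p <- el$props[[1L]]
      if (!p$list) stop("format-error: PLY face element without list property")
      out <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        k <- read_scalar(p$count_type)
        idx <- read_scalar(p$type, k) + 1L
        out[[i]] <- cbind(idx[1L], idx[2:(k - 1L)], idx[3:k])
      }
      faces <- do.call(rbind, out)
    } else {
      for (i in seq_len(el$count))
        for (p in el$props) {
          if (p$list) read_scalar(p$type, read_scalar(p$count_type))
          else read_scalar(p$type)
        }
    }
  }
  triangle_mesh(verts, faces, name)
}

.write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", mesh$name),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                       mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

# ---- OBJ ----

.read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L) stop("format-error: OBJ with no vertices")
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  faces <- matrix(integer(), 0L, 3L)
  if (length(flines) > 0L) {
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) {
      idx <- as.integer(sub("/.*", "", x[-1L]))
      idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
      cbind(idx[1L], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
    }))
  }
  triangle_mesh(verts, faces, name)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s", mesh$name), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
}
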