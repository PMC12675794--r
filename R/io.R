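#' Read and write triangle meshes
#'
#' Supports STL (ASCII and binary), PLY (ASCII and binary little-endian) and
#' OBJ (`v`/`f` records; material statements ignored). Coordinates are taken
#' to be millimetres by convention (none of these formats carries units).
#' Per-face layer labels persist through PLY via an integer face property
#' `layer` (0 = outer cortical, 1 = inner, 2 = fracture surface) and are
#' dropped with a warning on STL/OBJ export.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"obj"`; inferred from the file
#'   extension when `NULL`.
#' @return [read_mesh()] returns a [trimesh]; [write_mesh()] returns `path`
#'   invisibly.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         stl = read_stl(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: ", format))
}

#' @rdname read_mesh
#' @param mesh a [trimesh].
#' @param binary write the binary dialect where the format has one.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         stl = write_stl(mesh, path, binary),
         ply = write_ply(mesh, path, binary),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: ", format))
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  # Binary sniff: ASCII STL starts with "solid" and contains "facet" text;
  # a binary file's facet count must match its size.
  head_raw <- readBin(path, "raw", n = 84L)
  is_ascii <- FALSE
  if (length(head_raw) >= 5L &&
        identical(rawToChar(head_raw[1:5]), "solid")) {
    txt <- tryCatch(readLines(path, n = 20L, warn = FALSE),
                    error = function(e) character())
    is_ascii <- any(grepl("facet", txt, fixed = TRUE)) ||
      length(txt) <= 1L
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("empty STL mesh: ", path)
  weld_triangle_soup(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("malformed ASCII STL (vertex count not a multiple of 3): ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(x)) stop("malformed ASCII STL vertex line in ", path)
    x
  })
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + n * 50
  if (is.na(n) || n < 0L || file.size(path) < expected)
    stop("malformed binary STL: ", path)
  tri <- matrix(0, nrow = 3L * n, ncol = 3L)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    tri[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], ncol = 3,
                                            byrow = TRUE)
    readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  }
  tri
}

# Merge exactly coincident vertices of a triangle soup into an indexed mesh.
weld_triangle_soup <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces)
}

write_stl <- function(mesh, path, binary = FALSE) {
  if (any(mesh$labels != 0L))
    warning("STL cannot store layer labels; labels dropped on export")
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(nrm[i, ], t(v[f[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid cortifrac", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g",
                           p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid cortifrac", con)
  }
}

# ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hdr_line <- function() {
    chars <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) stop("unexpected end of PLY header: ", path)
      if (b == as.raw(10L)) break
      chars <- c(chars, b)
    }
    sub("\r$", "", rawToChar(chars))
  }
  if (read_hdr_line() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    ln <- read_hdr_line()
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property") {
      stopifnot(!is.null(cur))
      if (tok[2] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               item_type = tok[4])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt %||% "<missing>")
  type_info <- function(t) {
    switch(t,
           char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
           uchar = , uint8 = list(what = "integer", size = 1L,
                                  signed = FALSE),
           short = , int16 = list(what = "integer", size = 2L,
                                  signed = TRUE),
           ushort = , uint16 = list(what = "integer", size = 2L,
                                    signed = FALSE),
           int = , int32 = , uint = ,
           uint32 = list(what = "integer", size = 4L, signed = TRUE),
           float = , float32 = list(what = "numeric", size = 4L),
           double = , float64 = list(what = "numeric", size = 8L),
           stop("unsupported PLY type: ", t))
  }
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    pos <- 0L
    next_tokens <- function() {
      pos <<- pos + 1L
      as.numeric(strsplit(trimws(rest[pos]), "\\s+")[[1]])
    }
    parse_element <- function(el) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) rows[[i]] <- next_tokens()
      rows
    }
  } else {
    parse_element <- function(el) {
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- numeric()
        for (p in el$props) {
          if (p$list) {
            ci <- type_info(p$count_type)
            k <- readBin(con, ci$what, n = 1L, size = ci$size,
                         signed = if (ci$size < 4L) ci$signed else TRUE,
                         endian = "little")
            ii <- type_info(p$item_type)
            items <- readBin(con, ii$what, n = k, size = ii$size,
                             signed = if (ii$size < 4L) ii$signed else TRUE,
                             endian = "little")
            vals <- c(vals, k, items)
          } else {
            ti <- type_info(p$type)
            vals <- c(vals, readBin(con, ti$what, n = 1L, size = ti$size,
                                    signed = if (ti$size < 4L) ti$signed
                                             else TRUE,
                                    endian = "little"))
          }
        }
        rows[[i]] <- vals
      }
      rows
    }
  }
  verts <- NULL
  faces <- NULL
  labels <- NULL
  for (el in elements) {
    rows <- parse_element(el)
    if (el$name == "vertex") {
      nm <- vapply(el$props, `[[`, "", "name")
      xi <- match(c("x", "y", "z"), nm)
      if (anyNA(xi)) stop("PLY vertex element lacks x/y/z")
      verts <- t(vapply(rows, function(r) r[xi], numeric(3)))
    } else if (el$name == "face") {
      has_layer <- any(vapply(el$props, function(p)
        !p$list && p$name == "layer", logical(1)))
      faces <- t(vapply(rows, function(r) {
        k <- r[1]
        if (k != 3) stop("PLY face with ", k, " vertices; triangles only")
        r[2:4]
      }, numeric(3))) + 1
      if (has_layer)
        labels <- vapply(rows, function(r) as.integer(r[length(r)]),
                         integer(1))
    }
  }
  if (is.null(verts) || is.null(faces)) stop("PLY missing vertex/face data")
  trimesh(verts, faces, labels)
}

write_ply <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "property int layer",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.numeric(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
      writeBin(as.integer(mesh$labels[i]), con, size = 4L,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d %d", f[, 1], f[, 2], f[, 3],
                       mesh$labels), con)
  }
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("empty or malformed OBJ mesh: ", path)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) {
    x <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(x)) stop("malformed OBJ vertex line in ", path)
    x
  }, numeric(3)))
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- suppressWarnings(as.integer(sub("/.*$", "", p[-1])))
    if (length(idx) != 3L || anyNA(idx))
      stop("non-triangular or malformed OBJ face in ", path)
    idx
  }, integer(3)))
  trimesh(verts, faces)
}

write_obj <- function(mesh, path) {
  if (any(mesh$labels != 0L))
    warning("OBJ cannot store layer labels; labels dropped on export")
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
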