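# Readers and writers for the common surface-mesh interchange formats.
# PLY (ascii and binary little/big endian) and STL (ascii and binary) are
# read; all writers emit ascii with full double precision so that a
# write/read round trip reproduces coordinates bit-for-bit. Quads are
# triangulated on read; file-format indices (0-based for PLY/OBJ-relative
# conventions) are converted to the package's 1-based convention.

#' Read a triangle surface mesh
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"stl"`, `"obj"`, `"vtk"`.
#'   `"auto"` (default) dispatches on the file extension.
#' @return a [surface_mesh] (cleaned: duplicate vertices merged, degenerate
#'   faces dropped).
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "obj", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read mesh: file does not exist: ", path)
  if (file.info(path)$size == 0)
    stop("cannot read mesh: file is empty: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj", "vtk"))
      stop("cannot infer mesh format from extension of ", path)
    format <- ext
  }
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         vtk = read_vtk(path))
}

#' Write a triangle surface mesh
#'
#' @param mesh a [surface_mesh].
#' @param path output file path.
#' @param format one of `"auto"`, `"ply"`, `"stl"`, `"obj"`, `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path,
                       format = c("auto", "ply", "stl", "obj", "vtk")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0L)
    stop("refusing to write a mesh with no vertices")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj", "vtk"))
      stop("cannot infer mesh format from extension of ", path)
    format <- ext
  }
  switch(format,
         ply = write_ply(mesh, path),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path))
  invisible(path)
}

num <- function(x) sprintf("%.17g", x)

# ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header in ", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500L) stop("malformed PLY header in ", path)
  }
  if (!grepl("^ply", header[1]))
    stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]

  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex/face elements: ", path)

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    nf <- elements$face$count
    if (length(body) < nv + nf) stop("truncated PLY body in ", path)
    vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    verts <- t(vapply(vtok, function(s) as.numeric(s[1:3]), numeric(3)))
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- triangulate_polys(lapply(ftok, function(s) {
      cnt <- as.integer(s[1])
      as.integer(s[1 + seq_len(cnt)]) + 1L
    }))
  } else if (fmt %in% c("binary_little_endian", "binary_big_endian")) {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    res <- read_ply_binary(con, elements, endian)
    verts <- res$verts
    faces <- res$faces
  } else {
    stop("unsupported PLY format '", fmt, "' in ", path)
  }
  surface_mesh(verts, faces)
}

ply_type_info <- function(type) {
  switch(type,
         char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
         uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
         short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
         ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
         int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
         uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
         float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
         double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
         stop("unsupported PLY property type: ", type))
}

read_ply_binary <- function(con, elements, endian) {
  read_scalar <- function(type, n = 1L) {
    ti <- ply_type_info(type)
    readBin(con, what = ti$what, n = n, size = ti$size,
            signed = ti$signed, endian = endian)
  }
  verts <- NULL
  faces <- NULL
  for (el in elements) {
    props <- el$props
    if (el$name == "vertex" && !any(vapply(props, `[[`, TRUE, "list"))) {
      types <- vapply(props, `[[`, "", "type")
      if (length(unique(types)) == 1L) {
        # homogeneous vertex record: read as one block
        all_vals <- read_scalar(types[1], n = el$count * length(props))
        m <- matrix(all_vals, ncol = length(props), byrow = TRUE)
        names_p <- vapply(props, `[[`, "", "name")
        verts <- m[, match(c("x", "y", "z"), names_p), drop = FALSE]
        next
      }
    }
    # generic record-by-record path
    rows <- vector("list", el$count)
    for (i in seq_len(el$count)) {
      rec <- list()
      for (p in props) {
        if (p$list) {
          cnt <- read_scalar(p$count_type)
          rec[[p$name]] <- read_scalar(p$type, n = cnt)
        } else {
          rec[[p$name]] <- read_scalar(p$type)
        }
      }
      rows[[i]] <- rec
    }
    if (el$name == "vertex") {
      verts <- t(vapply(rows, function(r) c(r$x, r$y, r$z), numeric(3)))
    } else if (el$name == "face") {
      idx_name <- intersect(c("vertex_indices", "vertex_index"),
                            vapply(props, `[[`, "", "name"))[1]
      faces <- triangulate_polys(lapply(rows,
                                        function(r) r[[idx_name]] + 1L))
    }
  }
  list(verts = verts, faces = faces)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header",
             paste(num(v[, 1]), num(v[, 2]), num(v[, 3])),
             if (nrow(f) > 0L)
               paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  # binary STL: 80-byte header + uint32 count + 50-byte facet records; a
  # file starting with "solid" may still be binary, so check the size.
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  is_binary <- length(nfac) == 1L && !is.na(nfac) &&
    sz == 84 + 50 * as.numeric(nfac)
  if (is_binary) {
    tris <- matrix(0, nrow = 3L * nfac, ncol = 3L)
    for (i in seq_len(nfac)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "raw", n = 2L)
      tris[3L * (i - 1L) + 1:3, ] <- matrix(rec[4:12], ncol = 3,
                                            byrow = TRUE)
    }
    close(con)
  } else {
    close(con)
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed STL file: ", path)
    tris <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(s) as.numeric(s[2:4]), numeric(3)))
  }
  nfaces <- nrow(tris) / 3L
  faces <- matrix(seq_len(3L * nfaces), ncol = 3L, byrow = TRUE)
  surface_mesh(tris, faces)  # cleaning merges the duplicated vertices
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  out <- character(2 + 7 * nrow(f))
  out[1] <- "solid mesh"
  k <- 2L
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    out[k:(k + 6L)] <- c(
      paste("  facet normal", num(n[i, 1]), num(n[i, 2]), num(n[i, 3])),
      "    outer loop",
      paste("      vertex", num(tri[1, 1]), num(tri[1, 2]), num(tri[1, 3])),
      paste("      vertex", num(tri[2, 1]), num(tri[2, 2]), num(tri[2, 3])),
      paste("      vertex", num(tri[3, 1]), num(tri[3, 2]), num(tri[3, 3])),
      "    endloop",
      "  endfacet")
    k <- k + 7L
  }
  out[k] <- "endsolid mesh"
  writeLines(out, path)
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("no surface content (v/f records) in OBJ file: ", path)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(s) as.numeric(s[2:4]), numeric(3)))
  polys <- lapply(strsplit(trimws(fl), "\\s+"), function(s) {
    idx <- vapply(s[-1], function(tok)
      as.integer(strsplit(tok, "/")[[1]][1]), integer(1))
    # negative OBJ indices are relative to the end of the vertex list
    ifelse(idx < 0L, nrow(verts) + idx + 1L, idx)
  })
  surface_mesh(verts, triangulate_polys(polys))
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c(paste("v", num(v[, 1]), num(v[, 2]), num(v[, 3])),
               if (nrow(f) > 0L) paste("f", f[, 1], f[, 2], f[, 3])),
             path)
}

# ---- VTK legacy polydata ------------------------------------------------

read_vtk <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 5L || !grepl("vtk", txt[1], ignore.case = TRUE))
    stop("not a legacy VTK file: ", path)
  if (!any(grepl("^DATASET\\s+POLYDATA", txt, ignore.case = TRUE)))
    stop("VTK file is not POLYDATA: ", path)
  tok <- strsplit(trimws(paste(txt, collapse = " ")), "\\s+")[[1]]
  ip <- which(toupper(tok) == "POINTS")[1]
  if (is.na(ip)) stop("VTK file has no POINTS section: ", path)
  np <- as.integer(tok[ip + 1L])
  coords <- as.numeric(tok[ip + 2L + seq_len(3L * np)])
  verts <- matrix(coords, ncol = 3L, byrow = TRUE)
  ic <- which(toupper(tok) == "POLYGONS")[1]
  if (is.na(ic)) stop("VTK file has no POLYGONS section: ", path)
  ncell <- as.integer(tok[ic + 1L])
  vals <- as.integer(tok[ic + 2L + seq_len(as.integer(tok[ic + 2L]))])
  polys <- vector("list", ncell)
  pos <- 1L
  for (i in seq_len(ncell)) {
    cnt <- vals[pos]
    polys[[i]] <- vals[pos + seq_len(cnt)] + 1L
    pos <- pos + cnt + 1L
  }
  surface_mesh(verts, triangulate_polys(polys))
}

write_vtk <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0",
               "surface mesh", "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(v), "double"),
               paste(num(v[, 1]), num(v[, 2]), num(v[, 3])),
               paste("POLYGONS", nrow(f), 4L * nrow(f)),
               if (nrow(f) > 0L)
                 paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
}

# Fan-triangulate polygon index lists (1-based); validates index counts.
triangulate_polys <- function(polys) {
  tri <- lapply(polys, function(p) {
    if (length(p) < 3L) return(NULL)
    if (length(p) == 3L) return(matrix(p, 1L))
    cbind(p[1], p[2:(length(p) - 1L)], p[3:length(p)])
  })
  out <- do.call(rbind, tri)
  if (is.null(out)) out <- matrix(integer(0), 0L, 3L)
  storage.mode(out) <- "integer"
  out
}
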