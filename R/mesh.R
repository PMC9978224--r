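# Triangle surface mesh container and basic queries. Coordinates are in mm;
# face indices are 1-based (R convention) everywhere inside the package, and
# converted at the file-format boundary.

#' Construct a triangle surface mesh
#'
#' A `surface_mesh` holds one organ's triangulated surface: an `n x 3` matrix
#' of vertex coordinates (mm) and an `m x 3` integer matrix of 1-based vertex
#' indices. On construction, exact duplicate vertices are merged and
#' degenerate (zero-area or repeated-index) faces are dropped, so downstream
#' distance and ray queries never see a zero-area triangle.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param clean merge duplicate vertices and drop degenerate faces
#'   (default `TRUE`).
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   matrix(c(1L, 2L, 3L), 1))
#' mesh_area(m)
#' @export
surface_mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns")
  if (nrow(vertices) == 0L)
    stop("mesh has no vertices")
  if (any(!is.finite(vertices)))
    stop("mesh vertices contain non-finite coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L)
    stop("faces must have 3 columns (triangles)")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range: face references vertex ",
         max(faces), " but mesh has ", nrow(vertices), " vertices")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (clean) m <- clean_mesh(m)
  m
}

# Merge coordinate-identical vertices and drop degenerate faces.
clean_mesh <- function(mesh) {
  v <- mesh$vertices
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3L)
  if (nrow(f) > 0L) {
    repeated <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    f <- f[!repeated, , drop = FALSE]
    if (nrow(f) > 0L) {
      a <- face_areas(structure(list(vertices = v2, faces = f),
                                class = "surface_mesh"))
      f <- f[a > 1e-12, , drop = FALSE]
    }
  }
  structure(list(vertices = v2, faces = f), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' Per-face unit normals
#'
#' Normals follow the face winding (counter-clockwise winding seen from
#' outside gives outward normals). Meshes are treated as triangle soups;
#' winding consistency is the producer's responsibility.
#'
#' @param mesh a [surface_mesh].
#' @return an `m x 3` matrix of unit normals.
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Per-face areas (mm^2)
#' @param mesh a [surface_mesh].
#' @return numeric vector of face areas.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0L) return(numeric(0))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Total surface area (mm^2)
#' @param mesh a [surface_mesh].
#' @return total area.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Face centroids
#' @param mesh a [surface_mesh].
#' @return an `m x 3` matrix.
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Vertex centroid of a mesh
#' @param mesh a [surface_mesh].
#' @return length-3 vector (mm).
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Translate a mesh
#' @param mesh a [surface_mesh].
#' @param t length-3 translation (mm).
#' @return the translated mesh.
#' @export
translate_mesh <- function(mesh, t) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(t), "+")
  mesh
}
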