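# Correspondence-particle container. The canonical flattening of one
# subject is a length 3*M vector ordered organ-major, particle-minor, with
# (x, y, z) innermost; the ensemble is the (3*M) x N matrix whose columns
# are subjects. All statistics modules operate on this layout.

#' Construct a particle system
#'
#' @param coords `(3*M) x N` numeric matrix; column n is subject n's
#'   flattened particle vector (organ-major, particle-minor, xyz innermost).
#' @param organ_sizes named integer vector of particles per organ `M_k`;
#'   names are the organ labels, in flattening order.
#' @param subject_ids character vector of length N.
#' @param face_ids optional `M x N` integer matrix of the mesh face each
#'   particle currently lies on (bookkeeping for tangent projection).
#' @return an object of class `particle_system`.
#' @export
particle_system <- function(coords, organ_sizes, subject_ids,
                            face_ids = NULL) {
  coords <- as.matrix(coords)
  organ_sizes <- setNames(as.integer(organ_sizes), names(organ_sizes))
  if (is.null(names(organ_sizes)) || any(!nzchar(names(organ_sizes))))
    stop("organ_sizes must be named by organ label")
  M <- sum(organ_sizes)
  if (nrow(coords) != 3L * M)
    stop("coords must have 3 * sum(organ_sizes) rows")
  if (ncol(coords) != length(subject_ids))
    stop("coords must have one column per subject")
  structure(list(coords = coords, organ_sizes = organ_sizes,
                 subject_ids = as.character(subject_ids),
                 face_ids = face_ids),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", length(x$subject_ids), "subjects x",
      sum(x$organ_sizes), "particles (",
      paste(sprintf("%s: %d", names(x$organ_sizes), x$organ_sizes),
            collapse = ", "), ")\n")
  invisible(x)
}

n_subjects <- function(ps) length(ps$subject_ids)
n_organs <- function(ps) length(ps$organ_sizes)
total_particles <- function(ps) sum(ps$organ_sizes)

# Row indices of organ k's coordinate block in the flattened vector.
organ_rows <- function(ps, k) {
  sizes <- ps$organ_sizes
  off <- if (k == 1L) 0L else sum(sizes[seq_len(k - 1L)])
  3L * off + seq_len(3L * sizes[k])
}

# Particle index offsets (into 1..M) for organ k.
organ_particles <- function(ps, k) {
  sizes <- ps$organ_sizes
  off <- if (k == 1L) 0L else sum(sizes[seq_len(k - 1L)])
  off + seq_len(sizes[k])
}

#' Particle coordinates of one subject's organ
#' @param ps a [particle_system].
#' @param n subject index.
#' @param k organ index.
#' @return `M_k x 3` matrix.
#' @export
get_particles <- function(ps, n, k) {
  seg <- ps$coords[organ_rows(ps, k), n]
  matrix(seg, ncol = 3L, byrow = TRUE)
}

#' Replace particle coordinates of one subject's organ
#' @param ps a [particle_system].
#' @param n subject index.
#' @param k organ index.
#' @param mat `M_k x 3` matrix.
#' @return the modified system.
#' @export
set_particles <- function(ps, n, k, mat) {
  ps$coords[organ_rows(ps, k), n] <- as.vector(t(mat))
  ps
}

#' Write particle files
#'
#' ShapeWorks-style plain text: one "x y z" line per particle, one file per
#' (subject, organ), named `<subject>_<organ>_<M>.particles`, plus a sidecar
#' `organs.json` describing the organ partition.
#'
#' @param ps a [particle_system].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_particles <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- names(ps$organ_sizes)
  for (n in seq_len(n_subjects(ps))) {
    for (k in seq_len(n_organs(ps))) {
      pts <- get_particles(ps, n, k)
      fn <- sprintf("%s_%s_%d.particles", ps$subject_ids[n], labs[k],
                    ps$organ_sizes[k])
      writeLines(paste(num(pts[, 1]), num(pts[, 2]), num(pts[, 3])),
                 file.path(dir, fn))
    }
  }
  jsonlite::write_json(
    list(organs = labs, particles = unname(ps$organ_sizes),
         subjects = ps$subject_ids),
    file.path(dir, "organs.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Read particle files written by [write_particles()]
#' @param dir directory containing `.particles` files and `organs.json`.
#' @return a [particle_system].
#' @export
read_particles <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "organs.json"),
                              simplifyVector = TRUE)
  labs <- meta$organs
  sizes <- setNames(as.integer(meta$particles), labs)
  subj <- meta$subjects
  cols <- vector("list", length(subj))
  for (n in seq_along(subj)) {
    segs <- lapply(seq_along(labs), function(k) {
      fn <- file.path(dir, sprintf("%s_%s_%d.particles", subj[n], labs[k],
                                   sizes[k]))
      pts <- as.matrix(read.table(fn))
      if (nrow(pts) != sizes[k])
        stop("particle count mismatch in ", fn)
      as.vector(t(pts))
    })
    cols[[n]] <- unlist(segs)
  }
  particle_system(do.call(cbind, cols), sizes, subj)
}
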