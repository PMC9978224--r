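# Surface queries and ensemble alignment. Nearest-point queries are exact
# (brute force over all triangles, in compiled code); ties between
# equidistant faces resolve to the lowest face index for determinism.

#' Nearest point on a mesh surface
#'
#' Exact closest point over all triangles of the mesh, used to keep
#' correspondence particles on their organ's surface after every gradient
#' step.
#'
#' @param mesh a [surface_mesh].
#' @param p a length-3 point, or an `n x 3` matrix of points (mm).
#' @return a list with `point` (`n x 3` matrix of surface points), `face`
#'   (1-based face index of the closest triangle) and `distance` (mm). For a
#'   single input point, `point` is still a 1-row matrix.
#' @export
nearest_point_on_surface <- function(mesh, p) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  p <- rbind(p)
  storage.mode(p) <- "double"
  closest_points_cpp(p, mesh$vertices, mesh$faces)
}

#' Project a vector onto a face's tangent plane
#'
#' Removes the component of `v` along the unit normal of face `face_id`,
#' so that gradient steps stay (to first order) on the surface.
#'
#' @param mesh a [surface_mesh].
#' @param face_id 1-based face index.
#' @param v length-3 vector, or `n x 3` matrix of vectors (with `face_id`
#'   a vector of the same length).
#' @return the tangential component(s), same shape as `v`.
#' @export
tangent_project <- function(mesh, face_id, v) {
  n <- face_normals(mesh)[face_id, , drop = FALSE]
  v <- rbind(v)
  comp <- rowSums(v * n)
  out <- v - comp * n
  if (nrow(out) == 1L) as.numeric(out) else out
}

#' A multi-organ subject
#'
#' One subject of an ensemble: an ordered, labeled set of K organ surfaces in
#' a common coordinate frame. Organ labels and their order must be identical
#' across all subjects of an ensemble.
#'
#' @param subject_id character identifier.
#' @param organs named list of [surface_mesh] objects; names are the organ
#'   labels.
#' @return an object of class `multi_organ_subject`.
#' @export
multi_organ_subject <- function(subject_id, organs) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(organs), length(organs) >= 1L)
  if (is.null(names(organs)) || any(!nzchar(names(organs))))
    stop("organs must be a named list (organ labels)")
  for (o in organs) stopifnot(inherits(o, "surface_mesh"))
  structure(list(subject_id = subject_id, organs = organs),
            class = "multi_organ_subject")
}

#' @export
print.multi_organ_subject <- function(x, ...) {
  cat("multi_organ_subject", x$subject_id, "with", length(x$organs),
      "organs:", paste(names(x$organs), collapse = ", "), "\n")
  invisible(x)
}

# Assert that all subjects share organ count, labels and order.
check_ensemble <- function(subjects) {
  if (length(subjects) < 1L) stop("empty subject list")
  labs <- names(subjects[[1]]$organs)
  for (s in subjects) {
    stopifnot(inherits(s, "multi_organ_subject"))
    if (!identical(names(s$organs), labs))
      stop("inconsistent organ labels/order across subjects")
  }
  labs
}

#' Center an ensemble of multi-organ subjects
#'
#' Translates each subject's whole multi-organ complex so that its global
#' vertex centroid (equal-weight mean over the concatenated vertices of all
#' organs) sits at the origin. Relative organ poses within a subject are
#' untouched: alignment is translation-only so that between-organ pose
#' variation, which carries the anatomical signal, is preserved for the
#' statistics.
#'
#' @param subjects list of [multi_organ_subject].
#' @return list with `subjects` (centered) and `translations` (`N x 3`
#'   matrix of the applied translations, i.e. minus the original centroids).
#' @export
center_ensemble <- function(subjects) {
  check_ensemble(subjects)
  translations <- matrix(0, length(subjects), 3L)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    allv <- do.call(rbind, lapply(s$organs, `[[`, "vertices"))
    ctr <- colMeans(allv)
    s$organs <- lapply(s$organs, translate_mesh, t = -ctr)
    translations[i, ] <- -ctr
    out[[i]] <- s
  }
  list(subjects = out, translations = translations)
}
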