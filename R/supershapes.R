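# Synthetic multi-object ensembles built from Gielis supershapes. Each
# subject is a row of K supershape objects whose centroids sit on a parabola
# y = a x^2 (the between-objects pose factor, a ~ U(0, 0.001) by default)
# and whose per-object morphology is driven by one chi-square-distributed
# superformula exponent (the within-object shape factor). The generator
# records every latent draw so that mode-recovery tests can be phrased
# against known ground truth.

#' Superformula specification
#'
#' Parameters of the 2-D Gielis superformula
#' \deqn{r(\theta) = \left(\left|\cos(m\theta/4)/a\right|^{n_2} +
#'       \left|\sin(m\theta/4)/b\right|^{n_3}\right)^{-1/n_1}.}
#' A 3-D supershape is the spherical product of two such curves, one for
#' longitude and one for latitude. `m` controls the lobe count; `n1`
#' controls how bulbous or pinched the lobes are. Note that the curve only
#' closes over a full turn when `m` is even (or zero), so closed meshes
#' require even `m`.
#'
#' @param m lobe count (non-negative; even values give closed curves).
#' @param a,b denominators, must be positive.
#' @param n1,n2,n3 exponents; `n1` must be positive.
#' @return an object of class `supershape_spec`.
#' @export
supershape_spec <- function(m = 0, a = 1, b = 1, n1 = 2, n2 = 2, n3 = 2) {
  vals <- c(m = m, a = a, b = b, n1 = n1, n2 = n2, n3 = n3)
  if (any(!is.finite(vals)))
    stop("supershape parameters must be finite")
  if (a <= 0 || b <= 0) stop("superformula denominators a, b must be > 0")
  if (n1 <= 0) stop("superformula exponent n1 must be > 0")
  structure(as.list(vals), class = "supershape_spec")
}

#' Evaluate the superformula radius
#'
#' @param theta angle(s) in radians.
#' @param spec a [supershape_spec].
#' @return radius value(s), positive and finite.
#' @export
superformula_radius <- function(theta, spec) {
  stopifnot(inherits(spec, "supershape_spec"))
  base <- abs(cos(spec$m * theta / 4) / spec$a)^spec$n2 +
    abs(sin(spec$m * theta / 4) / spec$b)^spec$n3
  if (any(base <= 0))
    stop("superformula base is zero: radius undefined for these parameters")
  r <- base^(-1 / spec$n1)
  if (any(!is.finite(r)))
    stop("superformula produced a non-finite radius")
  r
}

#' Build a supershape surface mesh
#'
#' Spherical-product parameterization: with longitude radius
#' \eqn{r_1(\theta)} and latitude radius \eqn{r_2(\phi)},
#' \eqn{x = s\, r_1 \cos\theta\, r_2\cos\phi}, \eqn{y = s\, r_1
#' \sin\theta\, r_2\cos\phi}, \eqn{z = s\, r_2 \sin\phi}. The grid has
#' `resolution` longitude samples and `resolution - 1` interior latitude
#' rings plus two pole vertices, giving `resolution * (resolution - 1) + 2`
#' vertices. The result is star-shaped about the origin by construction,
#' with outward-winding faces.
#'
#' @param spec_theta longitude [supershape_spec].
#' @param spec_phi latitude [supershape_spec].
#' @param resolution grid size, at least 8.
#' @param scale radial scale in mm.
#' @return a [surface_mesh].
#' @export
build_supershape_mesh <- function(spec_theta, spec_phi, resolution = 32,
                                  scale = 20) {
  stopifnot(resolution >= 8)
  res <- as.integer(resolution)
  theta <- seq(-pi, pi, length.out = res + 1L)[-(res + 1L)]
  phi <- seq(-pi / 2, pi / 2, length.out = res + 1L)[c(-1L, -(res + 1L))]
  r1 <- superformula_radius(theta, spec_theta)
  r2 <- superformula_radius(phi, spec_phi)

  # interior ring vertices, ring-major (phi slow, theta fast)
  xy <- outer(r2 * cos(phi), r1)           # (res-1) x res
  verts <- cbind(as.vector(t(xy) * rep(cos(theta), res - 1L)),
                 as.vector(t(xy) * rep(sin(theta), res - 1L)),
                 rep(r2 * sin(phi), each = res))
  r2_s <- superformula_radius(-pi / 2, spec_phi)  # south pole radius
  r2_n <- superformula_radius(pi / 2, spec_phi)
  south <- c(0, 0, -r2_s)
  north <- c(0, 0, r2_n)
  verts <- rbind(verts, south, north) * scale
  i_south <- res * (res - 1L) + 1L
  i_north <- i_south + 1L

  vid <- function(i, j) (j - 1L) * res + ((i - 1L) %% res) + 1L  # theta i, ring j
  faces <- vector("list", res)
  # quad strips between rings, wound so normals point outward
  i <- seq_len(res)
  for (j in seq_len(res - 2L)) {
    a <- vid(i, j); b <- vid(i + 1L, j)
    c2 <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    faces[[j]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  # pole fans (south pole at ring below j = 1, north above j = res-1)
  faces[[res - 1L]] <- cbind(i_south, vid(i + 1L, 1L), vid(i, 1L))
  faces[[res]] <- cbind(i_north, vid(i, res - 1L), vid(i + 1L, res - 1L))
  surface_mesh(verts, do.call(rbind, faces))
}

#' Configuration for a synthetic multi-object ensemble
#'
#' @param n_subjects number of subjects N (>= 3).
#' @param n_objects objects per subject K (>= 2).
#' @param chi2_df degrees of freedom of the chi-square draw that drives the
#'   varying shape exponent.
#' @param chi2_scale multiplier applied to the chi-square draw.
#' @param pose_coeff_range interval for the parabola coefficient `a` in
#'   `y = a x^2` (default `c(0, 0.001)`, the study condition).
#' @param object_x_positions fixed x offsets (mm) of the object centroids;
#'   default evenly spaced at 60 mm.
#' @param lobes per-object lobe counts; default `4, 6, 8, ...` (even, so
#'   every mesh closes).
#' @param mesh_resolution supershape grid size.
#' @param scale object radial scale in mm.
#' @param seed master RNG seed.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_subjects = 20, n_objects = 3, chi2_df = 4,
                            chi2_scale = 0.25,
                            pose_coeff_range = c(0, 0.001),
                            object_x_positions = NULL, lobes = NULL,
                            mesh_resolution = 48, scale = 20, seed = 1) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (n_objects < 2) stop("n_objects must be >= 2")
  if (length(pose_coeff_range) != 2L || any(pose_coeff_range < 0) ||
      diff(pose_coeff_range) < 0)
    stop("pose_coeff_range must be a nondecreasing interval in [0, Inf)")
  if (is.null(object_x_positions))
    object_x_positions <- 60 * (seq_len(n_objects) - 1)
  if (length(object_x_positions) != n_objects)
    stop("object_x_positions must have one entry per object")
  if (is.null(lobes)) lobes <- 2L * (seq_len(n_objects) + 1L)
  if (length(lobes) != n_objects)
    stop("lobes must have one entry per object")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_objects = as.integer(n_objects),
                 chi2_df = chi2_df, chi2_scale = chi2_scale,
                 pose_coeff_range = as.numeric(pose_coeff_range),
                 object_x_positions = as.numeric(object_x_positions),
                 lobes = as.integer(lobes),
                 mesh_resolution = as.integer(mesh_resolution),
                 scale = scale, seed = as.integer(seed)),
            class = "ensemble_config")
}

# Deterministic per-subject substream: reseeding by counter makes each
# subject's draws independent of generation order.
subject_seed <- function(master, n) {
  as.integer((as.numeric(master) + 104729 * n) %% .Machine$integer.max)
}

#' Generate a synthetic supershape ensemble
#'
#' For subject n, object k is a supershape with lobe count `lobes[k]` whose
#' longitude exponent is `n1 = 1 + chi2_scale * chisq(chi2_df)` (an
#' independent draw per subject and object) and whose centroid is placed at
#' `(x_k, a_n * x_k^2, 0)` with one parabola coefficient `a_n ~
#' U(pose_coeff_range)` per subject. The ensemble is a pure function of the
#' config (including the seed).
#'
#' @param config an [ensemble_config].
#' @return a list with `subjects` (list of [multi_organ_subject]) and
#'   `manifest` (data frame of ground-truth latent draws, one row per
#'   subject/object).
#' @export
generate_synthetic_ensemble <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  K <- config$n_objects
  spec_phi <- supershape_spec()          # unit circle latitude profile
  subjects <- vector("list", config$n_subjects)
  manifest <- vector("list", config$n_subjects)
  for (n in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, n))
    a_n <- runif(1, config$pose_coeff_range[1], config$pose_coeff_range[2])
    chi <- rchisq(K, df = config$chi2_df)
    organs <- vector("list", K)
    for (k in seq_len(K)) {
      n1 <- 1 + config$chi2_scale * chi[k]
      spec_theta <- supershape_spec(m = config$lobes[k], n1 = n1,
                                    n2 = 3, n3 = 3)
      mesh <- build_supershape_mesh(spec_theta, spec_phi,
                                    resolution = config$mesh_resolution,
                                    scale = config$scale)
      x_k <- config$object_x_positions[k]
      organs[[k]] <- translate_mesh(mesh, c(x_k, a_n * x_k^2, 0))
    }
    names(organs) <- sprintf("object%d", seq_len(K))
    subjects[[n]] <- multi_organ_subject(sprintf("subject%02d", n), organs)
    manifest[[n]] <- data.frame(
      subject = sprintf("subject%02d", n),
      object = sprintf("object%d", seq_len(K)),
      chi2_value = chi, n1 = 1 + config$chi2_scale * chi,
      pose_a = a_n, lobes = config$lobes,
      x_position = config$object_x_positions)
  }
  list(subjects = subjects, manifest = do.call(rbind, manifest))
}

#' Write a synthetic ensemble to disk
#'
#' One directory per subject containing `<subject>_<organ>.ply`, plus
#' `manifest.json` (ground-truth draws) and a YAML echo of the config.
#'
#' @param ensemble result of [generate_synthetic_ensemble()].
#' @param config the [ensemble_config] used.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_ensemble <- function(ensemble, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in ensemble$subjects) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    for (lab in names(s$organs))
      write_mesh(s$organs[[lab]],
                 file.path(sdir, paste0(s$subject_id, "_", lab, ".ply")))
  }
  jsonlite::write_json(ensemble$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}
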