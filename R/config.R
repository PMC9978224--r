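# Experiment configuration and the reproducible pipeline driver:
# generate (or load) -> center -> optimize -> analyze -> metrics, with a
# config echo, a stage MANIFEST and a run log in every output directory so
# a run is reproducible from its artifacts alone.

config_schema <- list(
  top = c("output_dir", "mode", "input_dir", "synthetic", "optimizer",
          "analysis", "metrics", "log_level"),
  synthetic = c("n_subjects", "n_objects", "chi2_df", "chi2_scale",
                "pose_coeff_range", "object_x_positions", "lobes",
                "mesh_resolution", "scale", "seed"),
  optimizer = c("particles_per_organ", "iterations_per_split_level",
                "init_iterations_per_split_level",
                "alpha_global", "alpha_within", "alpha_between",
                "alpha_reg_start", "alpha_reg_end", "step_size",
                "backtrack_factor", "grow_factor", "max_backtracks",
                "tau_surf", "seed", "convergence_tol",
                "convergence_window"),
  analysis = c("sweep_modes", "sweep_sigmas"),
  metrics = c("enabled", "p_max", "specificity_samples", "seed"))

check_keys <- function(given, allowed, section) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", section, ": ",
         paste(unknown, collapse = ", "))
}

#' Load and validate a run configuration
#'
#' Reads a YAML experiment configuration, rejects unknown keys (listing
#' them), fills defaults, and validates every field by constructing the
#' corresponding [ensemble_config()] and [optimizer_config()] objects (so
#' an invalid value fails with an error naming the field).
#'
#' @param path YAML file path.
#' @return an object of class `run_config`: the normalized raw list
#'   (`raw`), plus built `ensemble` (or `input_dir`), `optimizer`,
#'   `analysis` and `metrics` entries.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

build_run_config <- function(raw) {
  if (is.null(raw$output_dir)) stop("config must set output_dir")
  check_keys(raw, config_schema$top, "top level")
  for (sec in c("synthetic", "optimizer", "analysis", "metrics"))
    if (!is.null(raw[[sec]]))
      check_keys(raw[[sec]], config_schema[[sec]], sec)
  if (is.null(raw$input_dir) && is.null(raw$synthetic))
    stop("config must set either input_dir or synthetic")
  raw$mode <- if (is.null(raw$mode)) "mlmo" else raw$mode
  raw$log_level <- if (is.null(raw$log_level)) "INFO" else raw$log_level

  ensemble <- if (!is.null(raw$synthetic))
    do.call(ensemble_config, raw$synthetic)
  opt_args <- if (is.null(raw$optimizer)) list() else raw$optimizer
  opt_args$mode <- raw$mode
  optimizer <- do.call(optimizer_config, opt_args)

  analysis <- list(sweep_modes = 1L, sweep_sigmas = c(-2, -1, 0, 1, 2))
  analysis[names(raw$analysis)] <- raw$analysis
  metrics <- list(enabled = TRUE, p_max = 5L, specificity_samples = 1000L,
                  seed = 1L)
  metrics[names(raw$metrics)] <- raw$metrics

  # normalized echo: defaults made explicit so reruns need only the echo
  raw$synthetic <- if (!is.null(ensemble)) unclass(ensemble)
  raw$optimizer <- unclass(optimizer)[setdiff(names(unclass(optimizer)),
                                              "mode")]
  raw$analysis <- analysis
  raw$metrics <- metrics
  structure(list(raw = raw, output_dir = raw$output_dir,
                 input_dir = raw$input_dir, mode = raw$mode,
                 ensemble = ensemble, optimizer = optimizer,
                 analysis = analysis, metrics = metrics,
                 log_level = raw$log_level),
            class = "run_config")
}

#' Write a run configuration back to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

# Read an ensemble from a directory of mesh files named
# <subject>_<organ>.<ext> (flat, or one subdirectory per subject).
read_mesh_ensemble <- function(dir) {
  if (!dir.exists(dir))
    stop("input mesh directory does not exist: ", dir)
  files <- list.files(dir, pattern = "\\.(ply|stl|obj|vtk)$",
                      recursive = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("no mesh files found under ", dir)
  base <- sub("\\.[^.]+$", "", basename(files))
  parts <- regmatches(base, regexpr("_[^_]+$", base))
  subj <- sub("_[^_]+$", "", base)
  organ <- sub("^_", "", parts)
  subjects <- sort(unique(subj))
  organs <- sort(unique(organ))
  lapply(subjects, function(s) {
    meshes <- lapply(organs, function(o) {
      f <- files[subj == s & organ == o]
      if (length(f) != 1L)
        stop("expected exactly one mesh for subject ", s, " organ ", o)
      read_mesh(f)
    })
    names(meshes) <- organs
    multi_organ_subject(s, meshes)
  })
}

log_line <- function(con, level, run_level, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (levels[[level]] < levels[[run_level]]) return(invisible())
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level,
                "] ", paste0(..., collapse = ""))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible()
}

#' Run a full experiment
#'
#' Drives the pipeline: load or generate the ensemble, center it, optimize
#' correspondence particles, fit the shared PCA and MLCA models, write
#' eigenvalue CSVs, mode sweeps and (optionally) metric curves. The output
#' directory receives the exact config echo, the package version, a
#' `MANIFEST.json` of completed stages and `run.log`; a rerun from the
#' echo alone reproduces the artifacts.
#'
#' @param config a `run_config` from [load_config()], or a path to a YAML
#'   config.
#' @return invisibly, a list with `status` (0 on success), `dir`,
#'   `particles`, `trace`, `mlca`, `shared`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  completed <- character(0)
  manifest_path <- file.path(out, "MANIFEST.json")
  write_manifest <- function() jsonlite::write_json(
    list(completed_stages = completed,
         version = as.character(utils::packageVersion("mlmoshape"))),
    manifest_path, auto_unbox = FALSE)
  logcon <- file(file.path(out, "run.log"), "w")
  on.exit(close(logcon))
  lvl <- if (identical(config$log_level, "DEBUG")) "DEBUG" else "INFO"

  write_config(config, file.path(out, "config.yaml"))
  writeLines(paste0("mlmoshape ",
                    as.character(utils::packageVersion("mlmoshape"))),
             file.path(out, "VERSION"))
  log_line(logcon, "INFO", lvl, "config echoed; md5 ",
           unname(tools::md5sum(file.path(out, "config.yaml"))),
           "; optimizer seed ", config$optimizer$seed)

  # stage: data
  subjects <- if (!is.null(config$ensemble)) {
    log_line(logcon, "INFO", lvl, "generating synthetic ensemble (N = ",
             config$ensemble$n_subjects, ", K = ",
             config$ensemble$n_objects, ")")
    ens <- generate_synthetic_ensemble(config$ensemble)
    write.csv(ens$manifest, file.path(out, "ground_truth_manifest.csv"),
              row.names = FALSE)
    ens$subjects
  } else {
    log_line(logcon, "INFO", lvl, "reading meshes from ",
             config$input_dir)
    read_mesh_ensemble(config$input_dir)
  }
  subjects <- center_ensemble(subjects)$subjects
  completed <- c(completed, "data")
  write_manifest()

  # stage: optimize
  log_line(logcon, "INFO", lvl, "optimizing (mode = ", config$mode, ")")
  fit <- optimize_particles(subjects, config$optimizer)
  write_particles(fit$particles, file.path(out, "particles"))
  write.csv(fit$trace, file.path(out, "energy_trace.csv"),
            row.names = FALSE)
  if (lvl == "DEBUG")
    for (i in seq_len(nrow(fit$trace)))
      log_line(logcon, "DEBUG", lvl, "level ", fit$trace$level[i],
               " iter ", fit$trace$iteration[i], " Q ",
               format(fit$trace$q_after[i]))
  completed <- c(completed, "optimize")
  write_manifest()

  # stage: analyze
  mlca <- fit_mlca(fit$particles)
  shared <- fit_shared_pca(fit$particles)
  write_eigen_csvs(mlca, shared, out)
  write_decomposition_csvs(fit$particles, file.path(out, "decomposition"))
  sweep_dir <- file.path(out, "sweeps")
  dir.create(sweep_dir, showWarnings = FALSE)
  for (m in seq_len(config$analysis$sweep_modes)) {
    if (m <= length(mlca$between$values))
      write_sweep(mode_sweep(mlca, "between", m,
                             config$analysis$sweep_sigmas),
                  fit$particles, sweep_dir, sprintf("between_mode%d", m))
    for (lab in names(mlca$within))
      if (m <= length(mlca$within[[lab]]$values))
        write_sweep(mode_sweep(mlca, "within", m,
                               config$analysis$sweep_sigmas, organ = lab),
                    fit$particles, sweep_dir,
                    sprintf("within_%s_mode%d", lab, m))
  }
  completed <- c(completed, "analyze")
  write_manifest()

  # stage: metrics
  if (isTRUE(config$metrics$enabled)) {
    log_line(logcon, "INFO", lvl, "computing model-quality metrics")
    run_metric_stage(fit$particles, config$metrics, out)
    completed <- c(completed, "metrics")
    write_manifest()
  }
  log_line(logcon, "INFO", lvl, "done; artifacts in ", out)
  invisible(list(status = 0L, dir = out, particles = fit$particles,
                 trace = fit$trace, mlca = mlca, shared = shared))
}

# Each sweep column becomes one .particles file per organ.
write_sweep <- function(sweep, ps, dir, stem) {
  for (j in seq_len(ncol(sweep))) {
    ps2 <- ps
    ps2$coords <- matrix(sweep[, j], ncol = 1L)
    ps2$subject_ids <- sprintf("%s_sigma%s", stem, colnames(sweep)[j])
    labs <- names(ps$organ_sizes)
    for (k in seq_along(labs)) {
      pts <- get_particles(ps2, 1L, k)
      writeLines(paste(num(pts[, 1]), num(pts[, 2]), num(pts[, 3])),
                 file.path(dir, sprintf("%s_sigma%s_%s.particles", stem,
                                        colnames(sweep)[j], labs[k])))
    }
  }
}

run_metric_stage <- function(ps, mcfg, out) {
  pmax_of <- function(model) max(1L, min(mcfg$p_max,
                                         length(model$values)))
  mlca <- fit_mlca(ps)
  shared <- fit_shared_pca(ps)
  specs <- list(list(sub = "shared", organ = NULL, model = shared),
                list(sub = "between", organ = NULL,
                     model = mlca$between))
  for (lab in names(mlca$within))
    specs[[length(specs) + 1L]] <- list(sub = "within", organ = lab,
                                        model = mlca$within[[lab]])
  for (sp in specs) {
    pm <- pmax_of(sp$model)
    tag <- if (is.null(sp$organ)) sp$sub
    else paste0(sp$sub, "_", sp$organ)
    write_metric_csv(data.frame(P = seq_len(pm),
                                value = compactness(sp$model,
                                                    seq_len(pm))),
                     "compactness", tag, out)
    write_metric_csv(generalization(ps, sp$sub, seq_len(pm),
                                    organ = sp$organ),
                     "generalization", tag, out)
    write_metric_csv(specificity(ps, sp$sub, seq_len(pm),
                                 T = mcfg$specificity_samples,
                                 seed = mcfg$seed, organ = sp$organ),
                     "specificity", tag, out)
  }
}
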