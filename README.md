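# mlmoshape

Multi-level multi-organ particle-based statistical shape modeling in R.

## The problem

Statistical shape models describe a population of anatomical surfaces by
a dense set of *correspondence particles*: M ordered landmarks placed so
that particle m marks the same anatomical location on every subject.
Particle-based shape modeling (PSM) learns this placement by minimizing
an entropy objective that trades off statistical compactness across
subjects against uniform coverage of each surface.

For articulated, multi-organ anatomy (a spine, a hindfoot, a hip) the
standard *global* extension concatenates all organs into one shape
vector. That entangles two very different kinds of variation — the
morphology of each organ and the relative pose between organs — in every
eigenmode, and its covariance grows with the total particle count.

`mlmoshape` implements a multi-level alternative (MLMO). Each particle is
split exactly as

    z = offset  +  (z − organ centroid)   +  (organ centroid − global centroid)
         global      within-organ shape        between-organs pose

and the correspondence objective is posed in the disentangled subspaces:

    Q = α_W Σ_k H(Z_k^W) + α_B H(Z^B) − Σ_k Σ_n H(X_{n,k})

with one Gaussian entropy per within-organ subspace (3M_k dimensions),
one for the between-organs subspace (3K dimensions, independent of the
particle counts), and a Parzen sampling entropy per surface. Multilevel
component analysis (MLCA) of the optimized particles then yields K + 1
mutually orthogonal subspaces whose modes are pure morphology or pure
pose. The package is intended for researchers in computational anatomy
and morphometrics who need interpretable shape-and-pose statistics for
multi-object complexes.

It provides, in supporting roles: plain-text mesh I/O (PLY, STL, OBJ,
VTK polydata), exact nearest-point and ray-casting kernels (compiled),
a Gielis-supershape synthetic ensemble generator with recorded ground
truth, the global/shared-space PSM baseline, subspace-aware model-quality
metrics (compactness, generalization, specificity), joint coverage-area
measurement, and a YAML-driven experiment pipeline with a thin CLI
(`inst/cli/mlmoshape.R`).

## A worked example

Generate a small synthetic ensemble (4 subjects, 2 supershape objects on
a parabolic pose curve), optimize correspondences in MLMO mode, and look
at the disentangled spectra:

```r
library(mlmoshape)

cfg <- ensemble_config(n_subjects = 4, n_objects = 2,
                       mesh_resolution = 16, seed = 3)
ens <- generate_synthetic_ensemble(cfg)
subjects <- center_ensemble(ens$subjects)$subjects

oc <- optimizer_config(particles_per_organ = 16, mode = "mlmo",
                       iterations_per_split_level = 20, seed = 1)
fit <- optimize_particles(subjects, oc)
mlca <- fit_mlca(fit$particles)

round(mlca$within$object1$values / sum(mlca$within$object1$values), 3)
#> [1] 0.984 0.012 0.004
round(mlca$between$values / sum(mlca$between$values), 3)
#> [1] 0.999 0.001 0.000
dominant_mode_count(mlca$between$values)
#> [1] 1
```

Each spectrum concentrates in a single dominant mode — exactly one
within-object shape factor (the planted chi-square exponent draw) and
one between-objects pose factor (the planted parabola coefficient
`a ~ U(0, 0.001)`), which is the disentanglement the multi-level
objective is built to deliver; a global-mode run of the same data mixes
these factors across its eigenmodes. The small residual shares reflect
the coarse 16-point meshes and the short toy optimization.

Mode sweeps and metrics:

```r
sweep <- mode_sweep(mlca, "between", mode = 1, sigmas = c(-2, 0, 2))
generalization(fit$particles, "between", P = 1:3)
specificity(fit$particles, "within", P = 1:2, organ = "object1")
```

The same pipeline runs from a YAML config, writing particles, eigenvalue
CSVs, mode sweeps, metric curves and a reproducible config echo:

```r
run_experiment("config.yaml")
```

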