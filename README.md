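# mstdflow

Tools for studying how the primate dorsal stream could encode self-motion:
simulation of instantaneous optic-flow fields, a speed- and direction-tuned
model MT population, a non-negative matrix factorization (NNMF) model of area
MSTd, accuracy-optimized neural networks for self-motion estimation, linear
decoding of self-motion from model populations, and the tuning-curve
statistics used to compare model units with recorded MSTd neurons.

## Who this is for

Computational neuroscientists comparing *reconstruction-driven* models of
MSTd (NNMF over MT afferents) with *accuracy-driven* models (networks trained
to estimate self-motion), and anyone needing a self-contained, seeded
generator of optic-flow stimulus ensembles with ground-truth labels.

## The models

An observer translating with velocity **T** (m/s) and rotating with **R**
(deg/s) past a scene with depth map *Z(x, y)* produces the instantaneous
retinal flow

```
(ẋ, ẏ) = (1/Z) [ -f 0 x ; 0 -f y ] T  +  (1/f) [ xy -(f²+x²) fy ; f²+y² -xy -fx ] R
```

on a 15 × 15 pinhole-camera grid (f = 1 cm, 90° field of view).  A population
of 9,000 model MT units (8 von Mises direction channels × 5 log-normal speed
channels × 225 positions) turns each field into a non-negative activation
vector.  The NNMF model factorizes the stimulus × MT matrix `A ≈ H W` with
non-negative factors — `H` are the MSTd unit activations, `W` the MT→MSTd
weights — concatenating 14 independent 64-basis fits into an 896-unit
population.  Responses to novel stimuli are `H_test = A_test Wᵀ`.  Tuning is
characterized by population-vector preferences, heading/rotation tuning
indices (HTI/RTI), half-maximum tuning widths, peak heading discriminability,
axis-proximity tables, and Vinje–Gallant sparseness.

## Worked example

Fit a small MSTd population and characterize its heading tuning:

```r
library(mstdflow)

ds  <- make_tr360(seed = 1, n_frontoparallel = 1350, n_ground = 270)
a   <- mt_activations(ds["train"])
mod <- mstd_nnmf(a, k = 16, repeats = 2, seed = 1)
mod
#> NNMF model of MSTd: 32 units (2 fits x 16 basis vectors) over 9000 MT units
#>   algorithm: mu; final reconstruction MSE 0.01405 - 0.01409

tp   <- make_test_protocol("T")
resp <- predict(mod, tp)                 # 514 x 32 responses
hti  <- tuning_index(resp, tp$meta$directions)
round(median(hti), 3)
#> [1] 0.496

pref <- population_vector_preference(resp, tp$meta$directions)
axis_proximity_table(pref, "T")
#>       axis count  n percent
#> 1  lateral     3 32   9.375
#> 2 fore-aft     0 32   0.000
#> 3 vertical    15 32  46.875
```

The median HTI says the typical model unit is moderately heading-selective
(0 = untuned, 1 = responds to a single heading); the axis table shows the
population's preference anisotropy — many units prefer vertical self-motion,
almost none fore-aft.  At the full population size (`k = 64, repeats = 14`,
fitted on the 6,030-sample training split) the median HTI is ≈ 0.54.

## Package tour

| area | entry points |
|---|---|
| flow simulation | `optic_flow()`, `depth_map()`, `frontoparallel_scene()`, `ground_scene()` |
| datasets | `make_tr360()`, `make_benhamed()`, `make_test_protocol()`, `make_heading_protocol()`, `write_flow_dataset()` |
| MT front end | `mt_params()`, `mt_activations()`, `direction_tuning()`, `speed_tuning()` |
| MSTd model | `mstd_nnmf()`, `nnmf_fit()`, `mstd_responses()`, S3 methods (`predict`, `coef`, `summary`, `plot`, ...) |
| networks | `flownet_spec()`, `build_network()`, `train_network()`, `published_architecture()`, `hyperparameter_search()`, `lesioned_readout()` |
| decoding | `error_metrics()`, `linear_decode_cv()`, `linear_decode_eval()`, `pca_baseline()` |
| tuning statistics | `tuning_index()`, `population_vector_preference()`, `tuning_width()`, `peak_discriminability()`, `interpolate_rf()`, `sparseness_report()`, `axis_proximity_table()`, `tuning_summary()` |

See the vignette (`vignettes/mstd-models.Rmd`) for the models, their
assumptions, numerical choices, and known limitations.
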