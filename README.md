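# dcehabitats

Voxel-wise pharmacokinetic analysis of dynamic contrast-enhanced (DCE) MRI
for preclinical brain-tumour studies, built around *haemodynamic habitats*:
instead of summarising a tumour by the mean of a kinetic parameter, each
parametric map is partitioned into necrotic / low / medium / high regions,
and habitat pixel counts and means are carried into cohort statistics.
This keeps treatment effects visible when they act by moving tissue between
habitats (e.g. collapse of highly permeable regions, growth of necrosis)
rather than by shifting a global mean.

## What it computes

For a 4D dual-echo spoiled gradient-echo series with a tumour mask:

1. **Relaxometry** — pre-contrast T1 by inversion-recovery
   (`fit_t1_ir()`) or variable flip angle (`fit_t1_vfa()`); two-echo T2\*
   correction (`correct_t2star()`); SPGR signal-to-concentration conversion
   (`signal_to_concentration()`).
2. **Arterial input function** — hybrid gamma-variate + bi-exponential
   bolus model (`aif_eval()`, `fit_aif()`), population averaging with
   AUC/smoothness screening (`build_population_aif()`).
3. **Kinetic modelling** — five models fitted per voxel by bounded
   nonlinear least squares (`fit_pixel()`, `fit_map()`):

   | model | free parameters | fit space |
   |-------|-----------------|-----------|
   | TM    | Ktrans, ve | concentration |
   | ETM   | Ktrans, ve, vp | concentration |
   | SSM   | Ktrans, ve, τi | signal (two-site water exchange) |
   | 2CXM  | Fp, PS, ve, vp | concentration |
   | SSM2  | Ktrans, ve, vp, τi | signal (three-site, vascular) |

   The Tofts convolution is
   `Ct(t) = Ktrans ∫ Cp(τ) exp(−kep (t−τ)) dτ` with `kep = Ktrans/ve`;
   the 2CXM uses the bi-exponential two-compartment impulse response with
   `Ktrans = Fp·PS/(Fp+PS)`; the shutter-speed models evaluate the SPGR
   signal from the eigenvalues of the water exchange–relaxation matrix.
   Voxels fitting with R² < 0.7 are gated as necrotic and zeroed.
4. **Habitats** — Ward/Euclidean hierarchical clustering of each map into
   k = 3 value clusters plus the necrotic cluster
   (`cluster_parameter_map()`, `summarise_maps()`), tumour volume from the
   mask (`tumour_volume()`).
5. **Cohort statistics** — Pearson correlations of habitat measures with
   tumour volume (`correlate_clusters_with_volume()`), exact Wilcoxon
   rank-sum comparisons of percent change from baseline between treated and
   control groups (`compare_groups()`), and a model-selection rule
   (`select_models()`).
6. **Digital phantom** — ellipsoidal tumours with habitat structure and
   necrotic core, forward-simulated dual-echo signal with Rician noise,
   and full treated/control cohorts (`make_phantom()`, `simulate_dce()`,
   `simulate_cohort()`), used throughout the tests.

## Worked example

```r
library(dcehabitats)

acq <- dce_acquisition()          # 180 frames at 5.37 s, TR 14 ms, flip 12
k   <- relax_constants()          # r1 = 3.8 /s/mM, T10 = 1900 ms
aif <- default_aif()              # bolus at t0 = 1 min

# a ~112-voxel digital tumour: necrotic core + low/med/high rims
ph  <- make_phantom(phantom_spec())
dat <- simulate_dce(ph$truth, ph$mask, aif, acq, k,
                    model = "TM", noise_sigma = 0.02, seed = 1)

cfg <- run_config(models = "TM", acq = acq, aif = aif, k = k)
res <- run_subject(cfg, list(data = dat, mask = ph$mask))

res$volume$volume_cc
#> [1] 0.0142582
res$habitats$TM$clusters$Ktrans$counts
#> necrotic      low      med     high
#>       22       34       34       22
res$habitats$TM$clusters$Ktrans$means
#>        low        med       high
#> 0.05005342 0.15004552 0.40469882
```

The phantom planted 22 necrotic voxels and rims at Ktrans =
0.05/0.15/0.4 min⁻¹; the pipeline recovers the habitat counts exactly and
the habitat means to well under the noise level. `run_cohort()` repeats
this over a manifest of subjects and timepoints and emits the correlation,
model-selection and group-comparison tables.

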