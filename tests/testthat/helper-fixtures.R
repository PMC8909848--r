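# Shared fixtures: standard acquisition, relaxation constants and input
# function used across the suite; small phantom builders.

std_acq <- function(...) dce_acquisition(...)
std_k <- function() relax_constants()
std_aif <- function() default_aif()

# ~112-voxel tumour on the default 32 x 32 x 4 grid
small_phantom <- function(...) make_phantom(phantom_spec(...))

# ~504-voxel fully perfused tumour (no necrotic core)
perfused_phantom <- function() {
  make_phantom(phantom_spec(
    dims = c(32, 32, 8), radii_mm = c(2.3, 2.6, 2.55),
    fractions = c(necrotic = 0, low = 1 / 3, med = 1 / 3, high = 1 / 3)))
}

# compact cohort phantom for treated/control runs; near-isotropic in voxel
# units so discrete volume growth tracks the growth model
cohort_pspec <- function(noise_sigma = 0.02) {
  phantom_spec(dims = c(22, 22, 6), radii_mm = c(1.1, 1.3, 2.1),
               noise_sigma = noise_sigma)
}

# median relative error of a fitted map vs truth over given voxels
map_rel_err <- function(pmaps, truth, voxels, par) {
  stats::median(abs(pmaps$maps[[par]][voxels] - truth[[par]][voxels]) /
                  truth[[par]][voxels])
}

# build a long cohort-style table row block
table_rows <- function(subject, group, timepoint, volume_cc, model,
                       parameter, counts, overall_mean = NA) {
  data.frame(subject = subject, group = group, timepoint = timepoint,
             volume_cc = volume_cc, model = model, parameter = parameter,
             cluster = c("necrotic", "low", "med", "high", "overall_mean"),
             value = c(counts, overall_mean),
             stringsAsFactors = FALSE)
}
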