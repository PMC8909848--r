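#' Digital tumour phantom specification
#'
#' An ellipsoidal tumour embedded in a small imaging grid, partitioned
#' radially (inside out) into a necrotic core and low/med/high perfusion
#' rims with fixed kinetic ground truths per region. Defaults use a
#' desk-scale 32 x 32 x 4 grid with the acquisition's voxel geometry and
#' region truths in plausible glioblastoma ranges; the necrotic region has
#' zero uptake.
#'
#' @param dims grid dimensions (voxels), length 3.
#' @param voxdim_mm voxel size (mm), length 3.
#' @param centre ellipsoid centre (voxel coordinates); default grid centre.
#' @param radii_mm ellipsoid semi-axes (mm).
#' @param fractions named region fractions `(necrotic, low, med, high)`
#'   summing to <= 1 (remainder trimmed from the outermost rim).
#' @param truths named list of per-region parameter truths; each entry is
#'   `c(low = ..., med = ..., high = ...)` or a scalar applied to all rims.
#' @param noise_sigma Rician noise level as a fraction of the mean baseline
#'   first-echo signal.
#' @param seed RNG seed for the noise stream.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(32, 32, 4),
                         voxdim_mm = c(0.234, 0.469, 1.16),
                         centre = NULL,
                         radii_mm = c(1.4, 1.6, 1.6),
                         fractions = c(necrotic = 0.2, low = 0.3,
                                       med = 0.3, high = 0.2),
                         truths = list(
                           Ktrans = c(low = 0.05, med = 0.15, high = 0.4),
                           ve = c(low = 0.15, med = 0.25, high = 0.45),
                           vp = 0.02, taui = 0.5,
                           Fp = c(low = 20, med = 40, high = 80),
                           PS = c(low = 8, med = 20, high = 45)),
                         noise_sigma = 0.02, seed = 1) {
  stopifnot(length(dims) == 3, length(voxdim_mm) == 3,
            all(c("necrotic", "low", "med", "high") %in% names(fractions)),
            sum(fractions) <= 1 + 1e-9, all(fractions >= 0),
            noise_sigma >= 0)
  centre <- centre %||% (dims + 1) / 2
  structure(list(dims = dims, voxdim_mm = voxdim_mm, centre = centre,
                 radii_mm = radii_mm, fractions = fractions,
                 truths = truths, noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

#' Build ground-truth parameter maps from a phantom specification
#'
#' Deterministic: voxels inside the ellipsoid are sorted by normalised
#' radius and assigned inside-out to necrotic core, then low, med and high
#' rims in the specified proportions.
#'
#' @param spec a [phantom_spec()].
#' @return List: `region` (3D integer array, 0 outside, 1 necrotic,
#'   2/3/4 = low/med/high), `mask` (logical), `truth` (named list of 3D
#'   truth maps, zero in the necrotic core), `spec`.
#' @export
make_phantom <- function(spec) {
  d <- spec$dims
  cx <- (seq_len(d[1]) - spec$centre[1]) * spec$voxdim_mm[1]
  cy <- (seq_len(d[2]) - spec$centre[2]) * spec$voxdim_mm[2]
  cz <- (seq_len(d[3]) - spec$centre[3]) * spec$voxdim_mm[3]
  u2 <- outer(outer((cx / spec$radii_mm[1])^2,
                    (cy / spec$radii_mm[2])^2, `+`),
              (cz / spec$radii_mm[3])^2, `+`)
  mask <- u2 <= 1
  if (!any(mask)) stop("tumour ellipsoid contains no voxels")
  r_vox <- spec$radii_mm / spec$voxdim_mm
  if (any(spec$centre - r_vox < 0.5) || any(spec$centre + r_vox > d + 0.5))
    stop("tumour ellipsoid exceeds the imaging grid")
  idx <- which(mask)
  n <- length(idx)
  ord <- order(u2[idx])
  fr <- spec$fractions[c("necrotic", "low", "med", "high")]
  counts <- floor(fr * n + 0.5)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  counts["high"] <- counts["high"] + (n - sum(counts))
  region <- array(0L, d)
  codes <- rep(1:4, times = counts)
  region[idx[ord]] <- codes
  rim <- c("low", "med", "high")
  truth <- lapply(spec$truths, function(tv) {
    m <- array(0, d)
    vals <- if (length(tv) == 1) stats::setNames(rep(tv, 3), rim) else tv
    for (g in 1:3) m[region == g + 1] <- vals[[rim[g]]]
    m
  })
  list(region = region, mask = mask, truth = truth, spec = spec)
}

# Analytic mean baseline first-echo signal for a phantom (noise reference).
.baseline_echo1 <- function(acq, k, M0, r2star_per_ms) {
  spgr_signal(k$R10, acq$TR_ms, acq$flip_deg, M0) *
    exp(-acq$TE1_ms * r2star_per_ms)
}

#' Simulate a dual-echo dynamic DCE acquisition from truth maps
#'
#' Forward chain: kinetic model -> tissue concentration -> SPGR signal (for
#' the water-exchange models the signal is generated directly) -> per-echo
#' T2* decay -> Rician noise. Baseline frames are contrast-free by
#' construction. Voxels sharing a truth parameter set are simulated once.
#'
#' @param truth named list of 3D truth maps (from [make_phantom()]).
#' @param mask logical tumour mask.
#' @param aif an [aif_params()] input function.
#' @param acq a [dce_acquisition()].
#' @param k a [relax_constants()].
#' @param model forward model id (default `"TM"`).
#' @param noise_sigma Rician noise sd as a fraction of the mean baseline
#'   first-echo signal.
#' @param seed RNG seed.
#' @param M0 equilibrium signal scale.
#' @param r2star_per_ms baseline T2* decay rate (ms^-1).
#' @return List: `echo1`, `echo2` (4D arrays), plus `acq`, `M0`,
#'   `r2star_per_ms`, `sigma` (absolute noise sd).
#' @export
simulate_dce <- function(truth, mask, aif, acq, k, model = "TM",
                         noise_sigma = 0, seed = 1, M0 = 1000,
                         r2star_per_ms = 0.04) {
  d <- dim(mask)
  t <- time_grid_min(acq)
  nt <- length(t)
  Cp <- aif_eval(aif, t)
  spec <- model_spec(model)
  need <- spec$free
  pm <- sapply(need, function(nm) as.numeric(truth[[nm]]))  # voxels x par
  key <- apply(pm, 1, paste, collapse = "|")
  sig0 <- matrix(spgr_signal(k$R10, acq$TR_ms, acq$flip_deg, M0),
                 nrow = prod(d), ncol = nt)
  for (ky in unique(key[as.logical(mask)])) {
    v <- which(key == ky & as.logical(mask))
    p <- as.list(pm[v[1], ])
    curve <- if (spec$space == "concentration") {
      Ct <- forward_model(model, p, t, Cp)
      concentration_to_signal(Ct, acq, k, M0)
    } else {
      if (p$Ktrans == 0 || all(unlist(p) == 0))
        rep(spgr_signal(k$R10, acq$TR_ms, acq$flip_deg, M0), nt)
      else forward_model(model, p, t, Cp, acq, k, M0)
    }
    sig0[v, ] <- matrix(curve, nrow = length(v), ncol = nt, byrow = TRUE)
  }
  e1 <- sig0 * exp(-acq$TE1_ms * r2star_per_ms)
  e2 <- sig0 * exp(-acq$TE2_ms * r2star_per_ms)
  sigma <- noise_sigma * .baseline_echo1(acq, k, M0, r2star_per_ms)
  if (sigma > 0) {
    with_seed(seed, {
      e1 <- sqrt((e1 + stats::rnorm(length(e1), 0, sigma))^2 +
                   stats::rnorm(length(e1), 0, sigma)^2)
      e2 <- sqrt((e2 + stats::rnorm(length(e2), 0, sigma))^2 +
                   stats::rnorm(length(e2), 0, sigma)^2)
    })
  }
  dim(e1) <- c(d, nt); dim(e2) <- c(d, nt)
  list(echo1 = e1, echo2 = e2, acq = acq, M0 = M0,
       r2star_per_ms = r2star_per_ms, sigma = sigma)
}

#' Cohort simulation specification
#'
#' Treated/control groups imaged across timepoints. Tumour volume follows a
#' per-timepoint multiplicative growth model (with subject-level log-normal
#' jitter); from the first post-baseline timepoint onward the treated group
#' additionally receives multiplicative changes to the kinetic truths, an
#' additive increase of the necrotic fraction (eroding the perfused
#' habitats proportionally, i.e. diffuse treatment-induced cell death), and
#' its own volume growth multiplier.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param timepoints timepoint labels; first is baseline.
#' @param growth control volume multiplier per timepoint step.
#' @param treated_growth treated volume multiplier per step.
#' @param effects named list of treated multipliers (`Ktrans`, `Fp`, `ve`)
#'   and `necrotic_add` (additive fraction).
#' @param subject_sd log-normal sd of subject-level jitter on truths and
#'   growth.
#' @param seed cohort RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 4,
                        timepoints = c("T0", "T3", "T6", "T8"),
                        growth = 1.5, treated_growth = 1.1,
                        effects = list(Ktrans = 0.6, Fp = 0.6, ve = 1.2,
                                       necrotic_add = 0.15),
                        subject_sd = 0.1, seed = 1) {
  stopifnot(n_per_group >= 2, length(timepoints) >= 2,
            growth > 0, treated_growth > 0)
  structure(list(n_per_group = n_per_group, timepoints = timepoints,
                 growth = growth, treated_growth = treated_growth,
                 effects = effects, subject_sd = subject_sd, seed = seed),
            class = "cohort_spec")
}

#' Simulate a treated/control cohort of phantom subjects
#'
#' One phantom per subject per timepoint. Returns the datasets in memory
#' together with a ground-truth cohort table and a manifest; optionally
#' writes NIfTI volumes, JSON sidecars and a manifest CSV to `dir`.
#'
#' @param cspec a [cohort_spec()].
#' @param pspec baseline [phantom_spec()].
#' @param aif an [aif_params()].
#' @param acq a [dce_acquisition()].
#' @param k a [relax_constants()].
#' @param model forward-simulation model id.
#' @param dir optional output directory for NIfTI/CSV export.
#' @return List: `subjects` (list of records with `subject`, `group`,
#'   `timepoint`, `data` (simulate_dce output), `mask`, `truth`,
#'   `volume_cc`), `manifest` (data frame), `truth_table` (data frame of
#'   per-region truth means and necrotic fractions).
#' @export
simulate_cohort <- function(cspec, pspec, aif, acq, k, model = "TM",
                            dir = NULL) {
  groups <- rep(c("treated", "control"), each = cspec$n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "treated", "J", "C"),
                 c(seq_len(cspec$n_per_group), seq_len(cspec$n_per_group)))
  sbase <- cspec$seed %% 20000L   # keep derived seeds inside 32-bit range
  subjects <- list()
  manifest <- list()
  truth_rows <- list()
  for (s in seq_along(ids)) {
    jit <- with_seed(sbase * 1000 + s,
                     stats::rlnorm(3, 0, cspec$subject_sd))
    base_truth <- pspec$truths
    base_truth$Ktrans <- base_truth$Ktrans * jit[1]
    base_truth$Fp <- base_truth$Fp * jit[2]
    for (tp_i in seq_along(cspec$timepoints)) {
      tp <- cspec$timepoints[tp_i]
      treated_now <- groups[s] == "treated" && tp_i > 1
      g <- if (groups[s] == "treated" && tp_i > 1)
        cspec$treated_growth else cspec$growth
      gjit <- with_seed(sbase * 1000 + s * 17 + tp_i,
                        stats::rlnorm(1, 0, cspec$subject_sd / 2))
      vol_mult <- jit[3]^0.3 * (g * gjit)^(tp_i - 1)
      fr <- pspec$fractions
      truths <- base_truth
      if (treated_now) {
        eff <- cspec$effects
        truths$Ktrans <- truths$Ktrans * (eff$Ktrans %||% 1)
        truths$Fp <- truths$Fp * (eff$Fp %||% 1)
        truths$ve <- pmin(truths$ve * (eff$ve %||% 1), 0.9)
        add <- eff$necrotic_add %||% 0
        live <- 1 - fr[["necrotic"]]
        fr[c("low", "med", "high")] <-
          fr[c("low", "med", "high")] * (live - add) / live
        fr[["necrotic"]] <- fr[["necrotic"]] + add
      }
      ps <- phantom_spec(
        dims = pspec$dims, voxdim_mm = pspec$voxdim_mm,
        radii_mm = pspec$radii_mm * vol_mult^(1 / 3),
        fractions = fr, truths = truths,
        noise_sigma = pspec$noise_sigma,
        seed = sbase * 100000 + s * 1000 + tp_i)
      ph <- make_phantom(ps)
      dat <- simulate_dce(ph$truth, ph$mask, aif, acq, k, model = model,
                          noise_sigma = ps$noise_sigma, seed = ps$seed)
      vol <- tumour_volume(ph$mask, pspec$voxdim_mm)
      subjects[[length(subjects) + 1]] <- list(
        subject = ids[s], group = groups[s], timepoint = tp,
        data = dat, mask = ph$mask, truth = ph$truth, region = ph$region,
        volume_cc = vol$volume_cc)
      manifest[[length(manifest) + 1]] <- data.frame(
        subject = ids[s], group = groups[s], timepoint = tp,
        volume_cc = vol$volume_cc, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject = ids[s], group = groups[s], timepoint = tp,
        volume_cc = vol$volume_cc,
        necrotic_fraction = mean(ph$region[ph$mask] == 1L),
        mean_Ktrans = mean(ph$truth$Ktrans[ph$mask]),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth_table <- do.call(rbind, truth_rows)
  out <- list(subjects = subjects, manifest = manifest,
              truth_table = truth_table)
  if (!is.null(dir)) export_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk (NIfTI + sidecars + manifest)
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rec in cohort$subjects) {
    stem <- file.path(dir, paste0(rec$subject, "_", rec$timepoint))
    RNifti::writeNifti(rec$data$echo1, paste0(stem, "_echo1.nii"))
    RNifti::writeNifti(rec$data$echo2, paste0(stem, "_echo2.nii"))
    RNifti::writeNifti(array(as.integer(rec$mask), dim(rec$mask)),
                       paste0(stem, "_mask.nii"))
    acq <- rec$data$acq
    jsonlite::write_json(acq[setdiff(names(acq), "voxdim_mm")],
                         paste0(stem, "_acq.json"), auto_unbox = TRUE)
    paths <- c(paths, stem)
  }
  mf <- cohort$manifest
  mf$path_stem <- paths
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
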