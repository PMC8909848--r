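#' Pipeline run configuration
#'
#' Collects the settings of the end-to-end analysis: which kinetic models
#' to fit, relaxometry constants (fixed-T1 mode uses a single tumour R10
#' for every voxel; per-pixel mode accepts a T1 map), the population AIF,
#' the necrosis gate and the habitat cluster count.
#'
#' @param models character vector of model ids (default `"TM"`).
#' @param acq a [dce_acquisition()].
#' @param aif an [aif_params()] (population AIF).
#' @param k a [relax_constants()].
#' @param r2_threshold necrosis gate in (0, 1), default 0.7.
#' @param k_clusters habitat cluster count, default 3.
#' @param t1_mode `"fixed"` (scalar R10 for all voxels) or `"per-pixel"`.
#' @param taub SSM2 blood-water lifetime (s).
#' @param seed seed recorded in run reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(models = "TM", acq = dce_acquisition(),
                       aif = default_aif(), k = relax_constants(),
                       r2_threshold = 0.7, k_clusters = 3,
                       t1_mode = c("fixed", "per-pixel"), taub = 0.2,
                       seed = 1) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, k_clusters >= 1)
  structure(list(models = models, acq = acq, aif = aif, k = k,
                 r2_threshold = r2_threshold, k_clusters = k_clusters,
                 t1_mode = match.arg(t1_mode), taub = taub, seed = seed),
            class = "run_config")
}

#' Run the full single-subject analysis chain
#'
#' T2* correction (frame-wise, per voxel) -> concentration conversion /
#' signal-space preparation -> per-model voxel-wise kinetic fitting with
#' necrosis gating -> habitat clustering -> tumour volume. Deterministic
#' given the configuration.
#'
#' @param cfg a [run_config()].
#' @param subject list with `data` (fields `echo1`, `echo2`, 4D arrays) and
#'   `mask` (logical 3D), e.g. one record from [simulate_cohort()], or with
#'   a precomputed `s0` 4D array in place of the echoes.
#' @return List: `maps` (per model), `habitats` (per model, from
#'   [summarise_maps()]), `volume`, `table` (long data frame of counts and
#'   means per parameter/cluster), `gate_log`.
#' @export
run_subject <- function(cfg, subject) {
  mask <- subject$mask
  if (!is.null(subject$data$s0)) {
    s0 <- subject$data$s0
  } else {
    tc <- correct_t2star(subject$data$echo1, subject$data$echo2,
                         cfg$acq$TE1_ms, cfg$acq$TE2_ms)
    s0 <- tc$S0
    s0[!is.finite(s0)] <- 0
  }
  stopifnot(all(dim(s0)[1:3] == dim(mask)))
  vol <- tumour_volume(mask, cfg$acq$voxdim_mm)
  maps <- list(); habitats <- list(); rows <- list(); gate_log <- list()
  for (m in cfg$models) {
    pm <- fit_map(s0, mask, m, cfg$aif, cfg$acq, cfg$k,
                  r2_threshold = cfg$r2_threshold, taub = cfg$taub)
    hb <- summarise_maps(pm, mask, k = cfg$k_clusters)
    maps[[m]] <- pm
    habitats[[m]] <- hb
    gate_log[[m]] <- c(n_voxels = sum(mask),
                       n_necrotic = sum(pm$necrotic[mask]),
                       mean_r2_fitted = mean(pm$r2[mask & !pm$necrotic]))
    sm <- hb$summary
    sm$model <- m
    rows[[m]] <- sm
  }
  table <- do.call(rbind, rows)
  table$volume_cc <- vol$volume_cc
  rownames(table) <- NULL
  list(maps = maps, habitats = habitats, volume = vol, table = table,
       gate_log = gate_log)
}

#' Run the cohort-level analysis
#'
#' Applies [run_subject()] to every dataset (failures are isolated and
#' reported, the cohort continues), assembles the long cohort table, then
#' computes volume correlations per model, the model-selection rule, and
#' treated-vs-control percent-change comparisons.
#'
#' @param cfg a [run_config()].
#' @param cohort output of [simulate_cohort()], or a list with `subjects`
#'   records each holding `subject`, `group`, `timepoint`, `data`, `mask`.
#' @param compare named list of measures for group comparison; each entry
#'   `list(parameter = , cluster = )`. Default: necrotic and high-Ktrans
#'   habitat counts.
#' @return List: `table` (cohort table), `correlations` (per model),
#'   `r2_by_model`, `selected` (model subset, `NULL` when < 3 subjects),
#'   `comparisons` (per model x measure), `failures`.
#' @export
run_cohort <- function(cfg, cohort,
                       compare = list(
                         necrotic = list(parameter = "Ktrans",
                                         cluster = "necrotic"),
                         ktrans_high = list(parameter = "Ktrans",
                                            cluster = "high"))) {
  subs <- cohort$subjects
  if (length(subs) == 0) stop("empty cohort manifest")
  rows <- list(); failures <- list()
  r2_acc <- list()
  for (rec in subs) {
    res <- tryCatch(run_subject(cfg, rec), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[paste(rec$subject, rec$timepoint)]] <- conditionMessage(res)
      next
    }
    tb <- res$table
    tb$subject <- rec$subject
    tb$group <- rec$group %||% NA_character_
    tb$timepoint <- rec$timepoint %||% NA_character_
    rows[[length(rows) + 1]] <- tb
    for (m in cfg$models)
      r2_acc[[m]] <- c(r2_acc[[m]], res$gate_log[[m]][["mean_r2_fitted"]])
  }
  if (length(rows) == 0) stop("all subjects failed: ",
                              paste(unlist(failures), collapse = "; "))
  table <- do.call(rbind, rows)
  r2_by_model <- vapply(r2_acc, mean, 0, na.rm = TRUE)
  correlations <- NULL; selected <- NULL
  if (length(unique(table$subject)) >= 3) {
    correlations <- lapply(stats::setNames(cfg$models, cfg$models),
                           function(m)
                             correlate_clusters_with_volume(table, m))
    selected <- tryCatch(
      suppressWarnings(select_models(correlations, r2_by_model)),
      error = function(e) character(0))
  } else {
    warning("fewer than 3 subjects: correlation stage skipped")
  }
  comparisons <- list()
  if (!is.null(table$group) && length(unique(table$timepoint)) > 1 &&
      all(c("treated", "control") %in% table$group)) {
    for (m in cfg$models) {
      for (nm in names(compare)) {
        cm <- compare[[nm]]
        comparisons[[paste(m, nm, sep = ".")]] <- tryCatch(
          compare_groups(table, cm$parameter, cm$cluster, m),
          error = function(e) conditionMessage(e))
      }
    }
  }
  list(table = table, correlations = correlations,
       r2_by_model = r2_by_model, selected = selected,
       comparisons = comparisons, failures = failures)
}

#' Read a subject's DCE dataset from NIfTI files
#'
#' Expects `<stem>_echo1.nii`, `<stem>_echo2.nii`, `<stem>_mask.nii` and a
#' `<stem>_acq.json` sidecar, as written by [export_cohort()].
#'
#' @param stem path stem.
#' @return A subject record usable with [run_subject()].
#' @export
read_dce_subject <- function(stem) {
  acqj <- jsonlite::read_json(paste0(stem, "_acq.json"), simplifyVector = TRUE)
  acq <- do.call(dce_acquisition, c(acqj[c("TR_ms", "TE1_ms", "TE2_ms",
                                           "flip_deg", "dt_s", "n_frames",
                                           "n_baseline")]))
  e1 <- array(as.numeric(RNifti::readNifti(paste0(stem, "_echo1.nii"))),
              dim = dim(RNifti::readNifti(paste0(stem, "_echo1.nii"))))
  e2 <- array(as.numeric(RNifti::readNifti(paste0(stem, "_echo2.nii"))),
              dim = dim(e1))
  msk <- RNifti::readNifti(paste0(stem, "_mask.nii"))
  mask <- array(as.numeric(msk) > 0.5, dim = dim(msk))
  list(data = list(echo1 = e1, echo2 = e2), mask = mask, acq = acq)
}

#' Write fitted parameter maps as NIfTI volumes
#'
#' One file per parameter plus the R^2 map and the necrosis mask.
#'
#' @param pmaps a `parameter_maps` object.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Written paths, invisibly.
#' @export
write_parameter_maps <- function(pmaps, dir, prefix = pmaps$model) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save1 <- function(arr, nm) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".nii"))
    arr[!is.finite(arr)] <- 0
    RNifti::writeNifti(arr, p)
    p
  }
  for (nm in names(pmaps$maps)) paths <- c(paths, save1(pmaps$maps[[nm]], nm))
  paths <- c(paths, save1(pmaps$r2, "r2"),
             save1(array(as.numeric(pmaps$necrotic), dim(pmaps$necrotic)),
                   "necrotic"))
  invisible(paths)
}
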