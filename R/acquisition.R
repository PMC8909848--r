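#' DCE acquisition metadata
#'
#' Bundles the timing and excitation parameters of a dynamic spoiled
#' gradient-echo (SPGR) acquisition with dual-echo readout, plus voxel
#' geometry. Defaults reproduce a typical preclinical 9.4 T protocol:
#' TR/TE1/TE2 = 14/2.25/4.76 ms, 12 degree flip, 180 frames at 5.37 s,
#' with contrast injection after one minute of baseline (11 frames).
#'
#' @param TR_ms repetition time (ms).
#' @param TE1_ms,TE2_ms first and second echo times (ms); `TE2_ms > TE1_ms`.
#' @param flip_deg excitation flip angle (degrees).
#' @param dt_s frame interval (s).
#' @param n_frames number of dynamic frames.
#' @param n_baseline number of pre-bolus baseline frames.
#' @param voxdim_mm voxel dimensions (mm), length 3.
#' @return An object of class `dce_acquisition`.
#' @export
dce_acquisition <- function(TR_ms = 14, TE1_ms = 2.25, TE2_ms = 4.76,
                            flip_deg = 12, dt_s = 5.37, n_frames = 180,
                            n_baseline = 11,
                            voxdim_mm = c(0.234, 0.469, 1.16)) {
  stopifnot(TR_ms > 0, TE1_ms > 0, TE2_ms > TE1_ms,
            flip_deg > 0, flip_deg < 90,
            dt_s > 0, n_frames >= 2, n_baseline >= 1,
            length(voxdim_mm) == 3, all(voxdim_mm > 0))
  structure(list(TR_ms = TR_ms, TE1_ms = TE1_ms, TE2_ms = TE2_ms,
                 flip_deg = flip_deg, dt_s = dt_s, n_frames = n_frames,
                 n_baseline = n_baseline, voxdim_mm = voxdim_mm),
            class = "dce_acquisition")
}

#' Frame times in minutes
#'
#' @param acq a [dce_acquisition()].
#' @return Numeric vector of frame mid-times (min), starting at 0.
#' @export
time_grid_min <- function(acq) {
  (seq_len(acq$n_frames) - 1) * acq$dt_s / 60
}

#' Relaxation constants for concentration conversion
#'
#' @param r1 contrast-agent longitudinal relaxivity (s^-1 mM^-1). Default
#'   3.8, typical for gadopentetate at 9.4 T.
#' @param R10 pre-contrast longitudinal relaxation rate 1/T1 (s^-1). Default
#'   corresponds to a tumour T1 of 1900 ms.
#' @return An object of class `relax_constants`.
#' @export
relax_constants <- function(r1 = 3.8, R10 = 1 / 1.9) {
  stopifnot(r1 > 0, R10 > 0)
  structure(list(r1 = r1, R10 = R10), class = "relax_constants")
}
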