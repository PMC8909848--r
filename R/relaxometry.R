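#' Spoiled gradient-echo signal equation
#'
#' `S = M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))` with
#' `E1 = exp(-TR * R1)`.
#'
#' @param R1_s longitudinal relaxation rate (s^-1); may be a vector.
#' @param TR_ms repetition time (ms).
#' @param flip_deg flip angle (degrees).
#' @param M0 equilibrium signal scale.
#' @return Signal, same length as `R1_s`.
#' @export
spgr_signal <- function(R1_s, TR_ms, flip_deg, M0 = 1) {
  a <- flip_deg * pi / 180
  E1 <- exp(-TR_ms / 1000 * R1_s)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Fit T1 from a magnitude inversion-recovery series
#'
#' Fits the magnitude inversion-recovery model
#' `|M0 * (1 - 2 * exp(-TI/T1))|` by bounded Levenberg-Marquardt least
#' squares over a small deterministic grid of starting values (polarity of
#' the early-TI points is resolved implicitly by the magnitude model).
#'
#' @param TI_ms inversion times (ms), strictly increasing, length >= 3.
#' @param S magnitude signal at each TI (non-negative).
#' @return A list of class `t1_fit` with `T1_ms`, `M0`, `rss`.
#' @export
fit_t1_ir <- function(TI_ms, S) {
  stopifnot(length(TI_ms) == length(S), length(S) >= 3,
            all(diff(TI_ms) > 0), all(S >= 0))
  if (stats::sd(S) == 0)
    stop("degenerate series: signal constant across inversion times")
  model <- function(p, TI) abs(p[2] * (1 - 2 * exp(-TI / p[1])))
  M0_init <- max(S)
  # null point TI* = T1*ln(2); seed from the minimum-signal TI plus a spread
  T1_seeds <- unique(clamp(c(TI_ms[which.min(S)] / log(2),
                             500, 1500, 3000), 50, 10000))
  best <- NULL
  for (T1_0 in T1_seeds) {
    fit <- minpack.lm::nls.lm(
      par = c(T1 = T1_0, M0 = M0_init),
      lower = c(50, 1e-9), upper = c(10000, Inf),
      fn = function(p) model(p, TI_ms) - S,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(T1_ms = unname(fit$par[1]), M0 = unname(fit$par[2]),
                   rss = rss, info = fit$info)
  }
  if (best$info == 0)
    stop("inversion-recovery fit failed to converge")
  structure(best[c("T1_ms", "M0", "rss")], class = "t1_fit")
}

#' Fit T1 from a variable-flip-angle SPGR series
#'
#' Initialises from the linearised SPGR form (`S/sin(a)` vs `S/tan(a)`) and
#' refines by nonlinear least squares.
#'
#' @param flip_deg flip angles (degrees), at least two distinct values.
#' @param S signal at each flip angle (positive).
#' @param TR_ms repetition time (ms).
#' @return A list of class `t1_fit` with `T1_ms`, `M0`, `rss`.
#' @export
fit_t1_vfa <- function(flip_deg, S, TR_ms) {
  stopifnot(length(flip_deg) == length(S), TR_ms > 0)
  if (length(unique(flip_deg)) < 2)
    stop("underdetermined: need at least two distinct flip angles")
  if (any(S <= 0)) stop("non-positive signal in flip-angle series")
  if (any(flip_deg <= 0 | flip_deg >= 90)) stop("flip angles must be in (0, 90)")
  a <- flip_deg * pi / 180
  co <- stats::coef(stats::lm(I(S / sin(a)) ~ I(S / tan(a))))
  E1_0 <- clamp(unname(co[2]), 1e-6, 1 - 1e-6)
  T1_0 <- clamp(-TR_ms / log(E1_0), 50, 10000)
  M0_0 <- max(abs(unname(co[1]) / (1 - E1_0)), max(S))
  fit <- minpack.lm::nls.lm(
    par = c(T1 = T1_0, M0 = M0_0),
    lower = c(50, 1e-9), upper = c(10000, Inf),
    fn = function(p) spgr_signal(1000 / p[1], TR_ms, flip_deg, p[2]) - S,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(T1_ms = unname(fit$par[1]), M0 = unname(fit$par[2]),
                 rss = sum(fit$fvec^2)),
            class = "t1_fit")
}

#' Two-echo T2* correction
#'
#' Closed-form extrapolation of a dual-echo gradient-echo signal to TE = 0:
#' `R2* = log(S1/S2) / (TE2 - TE1)` and `S0 = S1 * exp(TE1 * R2*)`.
#' Vectorised over voxels/frames. Non-positive inputs propagate as `NA`;
#' `S2 > S1` (noise regime) yields a negative rate and is flagged.
#'
#' @param S1,S2 signal at the first and second echo (same shape).
#' @param TE1_ms,TE2_ms echo times (ms), `TE2_ms > TE1_ms > 0`.
#' @return List with `S0`, `R2star_per_ms`, and logical `negative` flag
#'   (same shape as the inputs).
#' @export
correct_t2star <- function(S1, S2, TE1_ms, TE2_ms) {
  stopifnot(TE2_ms > TE1_ms, TE1_ms > 0)
  bad <- !(S1 > 0 & S2 > 0)
  r <- log(S1 / S2) / (TE2_ms - TE1_ms)
  r[bad] <- NA_real_
  S0 <- S1 * exp(TE1_ms * r)
  S0[bad] <- NA_real_
  neg <- !bad & r < 0
  if (is.array(S1)) {
    dim(r) <- dim(S1); dim(S0) <- dim(S1); dim(neg) <- dim(S1)
  }
  list(S0 = S0, R2star_per_ms = r, negative = neg)
}

#' Convert an SPGR signal time course to contrast-agent concentration
#'
#' Inverts the SPGR signal equation per frame using the pre-bolus baseline
#' mean and a known pre-contrast rate `R10`, then applies the linear
#' relaxivity relation `C(t) = (R1(t) - R10) / r1`.
#'
#' @param S signal time series (one voxel).
#' @param n_baseline number of pre-bolus frames used to estimate the scale.
#' @param acq a [dce_acquisition()] (uses `TR_ms`, `flip_deg`).
#' @param k a [relax_constants()].
#' @return Concentration (mM) per frame; frames where the SPGR inversion is
#'   out of range are `NA` with a logical `flagged` attribute.
#' @export
signal_to_concentration <- function(S, n_baseline, acq, k) {
  stopifnot(n_baseline >= 3, length(S) >= n_baseline)
  Sb <- mean(S[seq_len(n_baseline)])
  if (!(Sb > 0)) stop("baseline mean must be positive")
  a <- acq$flip_deg * pi / 180
  M0 <- Sb / spgr_signal(k$R10, acq$TR_ms, acq$flip_deg)
  # E1 = (M0 sin a - S) / (M0 sin a - S cos a)
  E1 <- (M0 * sin(a) - S) / (M0 * sin(a) - S * cos(a))
  ok <- is.finite(E1) & E1 > 0 & E1 < 1
  R1 <- rep(NA_real_, length(S))
  R1[ok] <- -log(E1[ok]) / acq$TR_ms * 1000   # s^-1
  C <- (R1 - k$R10) / k$r1
  attr(C, "flagged") <- !ok
  C
}

#' Forward SPGR signal from a concentration time course
#'
#' Inverse companion of [signal_to_concentration()]:
#' `S(t) = spgr(R10 + r1 * C(t)) * M0`.
#'
#' @param C concentration (mM) per frame.
#' @param acq a [dce_acquisition()].
#' @param k a [relax_constants()].
#' @param M0 equilibrium signal scale.
#' @return Signal per frame.
#' @export
concentration_to_signal <- function(C, acq, k, M0 = 1000) {
  spgr_signal(k$R10 + k$r1 * C, acq$TR_ms, acq$flip_deg, M0)
}
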