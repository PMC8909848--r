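#' Fit a kinetic model to one voxel's time course
#'
#' Bounded Levenberg-Marquardt least squares with deterministic multi-start
#' (base initial values and two perturbations at 0.5x and 2x, clipped to
#' bounds; best residual sum of squares kept). The coefficient of
#' determination is computed as `R^2 = 1 - SSres/SStot` with `SStot` taken
#' about the observed curve's own mean; a curve with (near-)zero total
#' variance has `R^2 = 0` by convention (no contrast uptake pattern).
#' Voxels with `R^2` below the threshold are flagged necrotic and all
#' parameters set to zero; solver non-convergence is flagged separately.
#'
#' @param model model id (see [model_spec()]).
#' @param curve observed series: concentration (mM) for TM/ETM/2CXM,
#'   TE-0-extrapolated signal for SSM/SSM2.
#' @param t time grid (min).
#' @param Cp plasma concentration at `t` (mM).
#' @param acq a [dce_acquisition()] (needed for signal-space models and the
#'   baseline count).
#' @param k a [relax_constants()].
#' @param init,bounds optional overrides of [pk_bounds()] values.
#' @param r2_threshold necrosis gate (default 0.7).
#' @param multistart use 3 deterministic starts (default TRUE).
#' @param taub blood-water lifetime (s) for SSM2.
#' @return List of class `pixel_fit`: `params` (full set incl. derived
#'   `kep`/`Ktrans`), `r2`, `necrotic`, `converged`, `rss`.
#' @export
fit_pixel <- function(model, curve, t, Cp, acq = NULL, k = NULL,
                      init = NULL, bounds = NULL, r2_threshold = 0.7,
                      multistart = TRUE, taub = 0.2) {
  stopifnot(all(is.finite(curve)), length(curve) == length(t))
  spec <- model_spec(model)
  b <- pk_bounds()
  if (!is.null(bounds)) {
    b$lower[names(bounds$lower)] <- bounds$lower
    b$upper[names(bounds$upper)] <- bounds$upper
  }
  if (!is.null(init)) b$init[names(init)] <- unlist(init)
  free <- spec$free
  lower <- b$lower[free]; upper <- b$upper[free]; p0 <- b$init[free]
  stopifnot(all(p0 >= lower & p0 <= upper))

  M0 <- 1
  if (spec$space == "signal") {
    nb <- acq$n_baseline
    M0 <- mean(curve[seq_len(nb)]) / spgr_signal(k$R10, acq$TR_ms,
                                                 acq$flip_deg)
  }
  resid_fn <- function(p) {
    pl <- as.list(p); names(pl) <- free
    if (!is.null(pl$ve) && !is.null(pl$vp) && pl$ve + pl$vp > 1)
      return(rep(1e6 * (pl$ve + pl$vp), length(curve)))
    pred <- forward_model(model, pl, t, Cp, acq, k, M0, taub = taub)
    pred - curve
  }
  starts <- if (multistart) list(p0, clamp(p0 * 0.5, lower, upper),
                                 clamp(p0 * 2, lower, upper)) else list(p0)
  if (multistart && length(free) >= 3) {
    # higher-dimensional models have rougher landscapes (tracer-kinetic
    # parameter trade-offs); add a strong- and a weak-uptake start
    strong <- c(Ktrans = 1, ve = 0.5, vp = 0.05, taui = 1.5,
                Fp = 100, PS = 50)
    weak <- c(Ktrans = 0.02, ve = 0.08, vp = 0.01, taui = 0.15,
              Fp = 8, PS = 3)
    starts <- c(starts, list(clamp(strong[free], lower, upper),
                             clamp(weak[free], lower, upper)))
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-13,
                                     ptol = 1e-13)
  if (multistart && "taui" %in% free) {
    # water-exchange landscape: the kinetics x exchange coupling is
    # multi-basined. Staged strategy: fit the kinetic parameters with the
    # intracellular lifetime pinned, then release taui from that seed
    # (plus a fast-leak start).
    kin <- setdiff(free, "taui")
    staged <- tryCatch({
      fit0 <- minpack.lm::nls.lm(
        par = p0[kin], lower = lower[kin], upper = upper[kin],
        fn = function(pk) {
          pl <- as.list(c(pk, p0["taui"])); names(pl) <- c(kin, "taui")
          forward_model(model, pl, t, Cp, acq, k, M0, taub = taub) - curve
        }, control = ctrl)
      s <- p0; s[kin] <- fit0$par
      s
    }, error = function(e) NULL)
    if (!is.null(staged))
      starts <- c(starts, list(staged,
                               { s2 <- staged; s2["taui"] <- 2; s2 }))
    s_leak <- c(Ktrans = 0.8, ve = 0.1, vp = 0.01, taui = 0.3)[free]
    starts <- c(starts, list(clamp(s_leak, lower, upper)))
  }
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
    converged <- converged || (fit$info %in% 1:4)
  }
  # polish: restart from the incumbent until the residual stops improving
  # (fresh trust region; helps traverse flat parameter-trade-off valleys)
  if (!is.null(best)) {
    for (round in 1:3) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                           fn = resid_fn, control = ctrl),
        error = function(e) NULL)
      if (is.null(fit)) break
      rss <- sum(fit$fvec^2)
      if (rss >= best$rss * (1 - 1e-10)) break
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  full_zero <- list(Ktrans = 0, ve = 0, kep = 0, vp = 0, taui = 0,
                    Fp = 0, PS = 0)
  if (is.null(best) || !converged) {
    return(structure(list(params = full_zero, r2 = 0, necrotic = TRUE,
                          converged = FALSE, rss = NA_real_),
                     class = "pixel_fit"))
  }
  pl <- as.list(best$par); names(pl) <- free
  sstot <- sum((curve - mean(curve))^2)
  r2 <- if (sstot <= 1e-12 * max(mean(curve)^2, 1) * length(curve))
    0 else 1 - best$rss / sstot
  necrotic <- r2 < r2_threshold
  params <- if (necrotic) full_zero else {
    out <- full_zero
    out[names(pl)] <- pl
    d <- derive_secondary(out[c("Ktrans", "ve", "vp", "taui", "Fp", "PS")],
                          model)
    out[names(d)] <- d
    out
  }
  structure(list(params = params, r2 = r2, necrotic = necrotic,
                 converged = TRUE, rss = best$rss),
            class = "pixel_fit")
}

#' Fit a kinetic model over all voxels of a masked 4D series
#'
#' Applies [fit_pixel()] to every voxel inside the tumour mask. The input is
#' the TE-0-extrapolated (T2*-corrected) signal; for concentration-space
#' models each voxel is first converted with [signal_to_concentration()].
#' Deterministic: fixed initial values, no randomness.
#'
#' @param s0_4d 4D array (x, y, z, frame) of TE-0 signal.
#' @param mask logical 3D tumour mask.
#' @param model model id.
#' @param aif an [aif_params()] population input function.
#' @param acq a [dce_acquisition()].
#' @param k a [relax_constants()].
#' @param r2_threshold necrosis gate (default 0.7).
#' @param taub blood-water lifetime (s) for SSM2.
#' @return List of class `parameter_maps`: `maps` (named list of 3D arrays
#'   for the model's parameters incl. derived ones), `r2` map, `necrotic`
#'   logical map, `model`, `voxdim_mm`.
#' @export
fit_map <- function(s0_4d, mask, model, aif, acq, k, r2_threshold = 0.7,
                    taub = 0.2) {
  stopifnot(length(dim(s0_4d)) == 4, all(dim(s0_4d)[1:3] == dim(mask)))
  if (!any(mask)) stop("empty tumour mask")
  spec <- model_spec(model)
  t <- time_grid_min(acq)
  stopifnot(dim(s0_4d)[4] == length(t))
  Cp <- aif_eval(aif, t)
  idx <- which(mask)
  nvox <- prod(dim(mask))
  par_names <- union(spec$free, c("Ktrans", "kep"))
  par_names <- intersect(c("Ktrans", "kep", "ve", "vp", "taui", "Fp", "PS"),
                         par_names)
  maps <- lapply(par_names, function(nm) {
    m <- array(NA_real_, dim(mask)); m
  })
  names(maps) <- par_names
  r2map <- array(NA_real_, dim(mask))
  necmap <- array(FALSE, dim(mask))
  flat <- matrix(s0_4d, nrow = nvox)
  for (v in idx) {
    sig <- flat[v, ]
    curve <- if (spec$space == "concentration") {
      C <- signal_to_concentration(sig, acq$n_baseline, acq, k)
      C[!is.finite(C)] <- 0
      as.numeric(C)
    } else sig
    fit <- fit_pixel(model, curve, t, Cp, acq, k,
                     r2_threshold = r2_threshold, taub = taub)
    for (nm in par_names) maps[[nm]][v] <- fit$params[[nm]]
    r2map[v] <- fit$r2
    necmap[v] <- fit$necrotic
  }
  structure(list(maps = maps, r2 = r2map, necrotic = necmap,
                 model = model, voxdim_mm = acq$voxdim_mm, mask = mask),
            class = "parameter_maps")
}
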