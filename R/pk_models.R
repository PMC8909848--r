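#' Kinetic model specification
#'
#' The five tracer-kinetic models and their free parameters:
#' \describe{
#'   \item{TM}{Tofts: `Ktrans`, `ve`; concentration space.}
#'   \item{ETM}{extended Tofts: `Ktrans`, `ve`, `vp`; concentration space.}
#'   \item{SSM}{shutter-speed (two-site water exchange): `Ktrans`, `ve`,
#'     `taui`; signal space.}
#'   \item{2CXM}{two-compartment exchange: `Fp`, `PS`, `ve`, `vp`;
#'     concentration space.}
#'   \item{SSM2}{second-generation shutter-speed (three-site exchange with a
#'     vascular compartment): `Ktrans`, `ve`, `vp`, `taui`; signal space.}
#' }
#'
#' @param model_id one of `"TM"`, `"ETM"`, `"SSM"`, `"2CXM"`, `"SSM2"`.
#' @return List with `id`, `free` (free parameter names), `space`
#'   (`"concentration"` or `"signal"`).
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, c("TM", "ETM", "SSM", "2CXM", "SSM2"))
  switch(model_id,
    TM    = list(id = "TM",    free = c("Ktrans", "ve"),
                 space = "concentration"),
    ETM   = list(id = "ETM",   free = c("Ktrans", "ve", "vp"),
                 space = "concentration"),
    SSM   = list(id = "SSM",   free = c("Ktrans", "ve", "taui"),
                 space = "signal"),
    `2CXM` = list(id = "2CXM", free = c("Fp", "PS", "ve", "vp"),
                 space = "concentration"),
    SSM2  = list(id = "SSM2",  free = c("Ktrans", "ve", "vp", "taui"),
                 space = "signal"))
}

#' Default fit bounds and initial values
#'
#' `Ktrans` in \[0, 5\] min^-1 (init 0.1), `ve`, `vp` in \[0, 1\] (init 0.2,
#' 0.02), `taui` in \[0.05, 5\] s (init 0.5), `Fp` in \[0, 300\]
#' mL/100 g/min (init 30), `PS` in \[0, 100\] mL/100 g/min (init 10).
#'
#' @return List with `lower`, `upper`, `init` named vectors.
#' @export
pk_bounds <- function() {
  list(lower = c(Ktrans = 0, ve = 1e-3, vp = 0, taui = 0.05,
                 Fp = 1e-2, PS = 0),
       upper = c(Ktrans = 5, ve = 1, vp = 1, taui = 5, Fp = 300, PS = 100),
       init  = c(Ktrans = 0.1, ve = 0.2, vp = 0.02, taui = 0.5,
                 Fp = 30, PS = 10))
}

# Tofts tissue concentration. p: list/vector with Ktrans (min^-1), ve.
tm_conc <- function(Ktrans, ve, t, Cp) {
  if (Ktrans == 0) return(numeric(length(t)))
  stopifnot(ve > 0)
  Ktrans * exp_conv(Cp, t, Ktrans / ve)
}

etm_conc <- function(Ktrans, ve, vp, t, Cp) {
  vp * Cp + tm_conc(Ktrans, ve, t, Cp)
}

# Two-compartment exchange model tissue concentration.
# Fp, PS in mL/100 g/min (tissue density 1 g/mL), ve, vp fractions.
# Impulse response (per tissue volume), derived from the compartmental ODEs:
#   h(t) = (Fp'/vp) [ (l+ vp - Fp') e^{-l- t} - (l- vp - Fp') e^{-l+ t} ]
#          / (l+ - l-),
# with l+- the eigenvalues of the exchange matrix and Fp' = Fp/100 (min^-1).
cxm_conc <- function(Fp, PS, ve, vp, t, Cp) {
  Fpf <- Fp / 100; PSf <- PS / 100
  if (Fpf <= 0) return(numeric(length(t)))
  # guard degenerate volume fractions (solver may touch the box bounds)
  ve <- max(ve, 1e-6); vp <- max(vp, 1e-6)
  s <- (Fpf + PSf) / vp + PSf / ve
  pr <- Fpf * PSf / (vp * ve)
  disc <- sqrt(max(s^2 - 4 * pr, 0))
  lp <- (s + disc) / 2
  lm <- (s - disc) / 2
  if (lp - lm < 1e-12 * lp) lm <- lp * (1 - 1e-9)   # guard repeated root
  wplus <- lp * vp - Fpf
  wminus <- lm * vp - Fpf
  (Fpf / vp) * (wplus * exp_conv(Cp, t, lm) -
                wminus * exp_conv(Cp, t, lp)) / (lp - lm)
}

# SPGR steady-state factor for rate R1 (s^-1), vectorised.
.spgr_frac <- function(R1_s, TR_s, cosa, sina) {
  E <- exp(-TR_s * R1_s)
  sina * (1 - E) / (1 - cosa * E)
}

# Shutter-speed model: SPGR signal under two-site transcytolemmal water
# exchange. Water populations: extracellular pe = ve, intracellular
# pi = 1 - ve; tau_e = taui * pe / pi (detailed balance). Apparent rates are
# the eigenvalues of the 2x2 exchange-relaxation matrix; apparent fractions
# follow from the population vector. All relaxation/exchange rates in s^-1;
# kinetics (Ktrans/ve) in min^-1 on the minute time grid.
ssm_signal <- function(Ktrans, ve, taui, t, Cp, acq, k, M0 = 1) {
  stopifnot(ve > 0, ve < 1, taui > 0)
  Ct <- tm_conc(Ktrans, ve, t, Cp)
  pe <- ve; pi_ <- 1 - ve
  taue <- taui * pe / pi_
  R1i <- k$R10
  R1e <- k$R10 + k$r1 * Ct / ve
  c1 <- R1i + 1 / taui
  c2 <- R1e + 1 / taue
  disc <- sqrt((c1 - c2)^2 + 4 / (taui * taue))
  lp <- (c1 + c2 + disc) / 2
  lm <- (c1 + c2 - disc) / 2
  m1 <- R1i * pi_ + R1e * pe
  am <- (lp - m1) / (lp - lm)
  ap <- 1 - am
  TR_s <- acq$TR_ms / 1000
  a <- acq$flip_deg * pi / 180
  M0 * (am * .spgr_frac(lm, TR_s, cos(a), sin(a)) +
        ap * .spgr_frac(lp, TR_s, cos(a), sin(a)))
}

# Second-generation shutter-speed model: three water sites (blood b,
# extracellular-extravascular e, intracellular i) with blood-water lifetime
# taub (s). Eigenvalues of the 3x3 exchange-relaxation matrix via the
# trigonometric cubic formula (roots are real: the matrix is similar to a
# symmetric one); apparent fractions from the first three moments through a
# Vandermonde solve. Fully vectorised over frames.
ssm2_signal <- function(Ktrans, ve, vp, taui, t, Cp, acq, k, M0 = 1,
                        taub = 0.2) {
  stopifnot(ve > 0, taui > 0, vp >= 0, ve + vp < 1)
  if (vp == 0) return(ssm_signal(Ktrans, ve, taui, t, Cp, acq, k, M0))
  pb <- vp; pe <- ve; pi_ <- 1 - vp - ve
  Ct <- tm_conc(Ktrans, ve, t, Cp)
  R1b <- k$R10 + k$r1 * Cp
  R1e <- k$R10 + k$r1 * Ct / ve
  R1i <- k$R10
  k_be <- 1 / taub            # blood -> EES
  k_eb <- pb / (taub * pe)    # EES -> blood (detailed balance)
  k_ie <- 1 / taui            # intra -> EES
  k_ei <- pi_ / (taui * pe)   # EES -> intra
  d1 <- R1b + k_be
  d2 <- R1e + k_eb + k_ei
  d3 <- R1i + k_ie
  # characteristic cubic lambda^3 - T lambda^2 + Q lambda - D
  Tr <- d1 + d2 + d3
  Q <- d1 * d2 + d1 * d3 + d2 * d3 - k_eb * k_be - k_ie * k_ei
  D <- d1 * d2 * d3 - d1 * k_ie * k_ei - d3 * k_eb * k_be
  p <- Q - Tr^2 / 3
  q <- -2 * Tr^3 / 27 + Tr * Q / 3 - D
  rr <- sqrt(pmax(-p / 3, 1e-300))
  cosarg <- clamp(3 * q / (2 * p) / rr, -1, 1)
  th <- acos(cosarg)
  l1 <- 2 * rr * cos(th / 3) + Tr / 3
  l2 <- 2 * rr * cos((th - 2 * pi) / 3) + Tr / 3
  l3 <- 2 * rr * cos((th - 4 * pi) / 3) + Tr / 3
  # moments: m0 = 1, m1 = (A^T 1) . p = population-weighted R1,
  # m2 = (A^T 1) . (A p)
  m1 <- R1b * pb + R1e * pe + R1i * pi_
  Ap1 <- d1 * pb - k_eb * pe
  Ap2 <- -k_be * pb + d2 * pe - k_ie * pi_
  Ap3 <- -k_ei * pe + d3 * pi_
  m2 <- R1b * Ap1 + R1e * Ap2 + R1i * Ap3
  eps <- 1e-9 * pmax(abs(l1), 1)
  l2 <- ifelse(abs(l1 - l2) < eps, l2 + eps, l2)
  l3 <- ifelse(abs(l1 - l3) < eps | abs(l2 - l3) < eps, l3 + 2 * eps, l3)
  a1 <- (m2 - (l2 + l3) * m1 + l2 * l3) / ((l1 - l2) * (l1 - l3))
  a2 <- (m2 - (l1 + l3) * m1 + l1 * l3) / ((l2 - l1) * (l2 - l3))
  a3 <- 1 - a1 - a2
  TR_s <- acq$TR_ms / 1000
  ca <- cos(acq$flip_deg * pi / 180); sa <- sin(acq$flip_deg * pi / 180)
  M0 * (a1 * .spgr_frac(l1, TR_s, ca, sa) +
        a2 * .spgr_frac(l2, TR_s, ca, sa) +
        a3 * .spgr_frac(l3, TR_s, ca, sa))
}

#' Evaluate a kinetic model forward
#'
#' Returns the model output series: tissue concentration (mM) for TM, ETM
#' and 2CXM, or SPGR signal for the water-exchange models SSM and SSM2.
#'
#' @param model model id (see [model_spec()]).
#' @param p named list/vector of parameters (the model's free parameters;
#'   `Ktrans` and `Fp`/`PS` in min^-1 and mL/100 g/min, `taui` in seconds).
#' @param t time grid (min), increasing, starting at 0.
#' @param Cp plasma concentration at `t` (mM), e.g. from [aif_eval()].
#' @param acq a [dce_acquisition()]; required for signal-space models.
#' @param k a [relax_constants()]; required for signal-space models.
#' @param M0 equilibrium signal scale for signal-space models.
#' @param taub blood-water lifetime (s) for SSM2.
#' @return Numeric series, same length as `t`.
#' @export
forward_model <- function(model, p, t, Cp, acq = NULL, k = NULL, M0 = 1,
                          taub = 0.2) {
  stopifnot(t[1] == 0, !is.unsorted(t), length(Cp) == length(t))
  p <- as.list(p)
  switch(match.arg(model, c("TM", "ETM", "SSM", "2CXM", "SSM2")),
    TM = tm_conc(p$Ktrans, p$ve, t, Cp),
    ETM = etm_conc(p$Ktrans, p$ve, p$vp, t, Cp),
    `2CXM` = cxm_conc(p$Fp, p$PS, p$ve, p$vp, t, Cp),
    SSM = ssm_signal(p$Ktrans, p$ve, p$taui, t, Cp, acq, k, M0),
    SSM2 = ssm2_signal(p$Ktrans, p$ve, p$vp, p$taui, t, Cp, acq, k, M0,
                       taub = taub))
}

#' Complete derived kinetic parameters
#'
#' Fills `kep = Ktrans / ve` and, for the 2CXM, the transfer constant from
#' flow and permeability using the extraction-fraction convention
#' `Ktrans = E * Fp`, `E = PS / (PS + Fp)` (result in min^-1 with Fp, PS in
#' mL/100 g/min and tissue density 1 g/mL).
#'
#' @param p named list of parameters.
#' @param model model id.
#' @return `p` with `kep` (and `Ktrans` for 2CXM) filled in.
#' @export
derive_secondary <- function(p, model) {
  p <- as.list(p)
  if (model == "2CXM") {
    p$Ktrans <- if (p$PS + p$Fp > 0) (p$PS * p$Fp) / ((p$PS + p$Fp) * 100) else 0
  }
  if (!is.null(p$Ktrans) && p$Ktrans > 0 && (is.null(p$ve) || p$ve == 0))
    stop("kep undefined: Ktrans > 0 with ve = 0")
  p$kep <- if (!is.null(p$ve) && p$ve > 0) p$Ktrans / p$ve else 0
  p
}
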