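test_that("forward models honour their degenerate limits", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)

  expect_equal(forward_model("TM", list(Ktrans = 0, ve = 0.2), t, Cp),
               numeric(length(t)))
  expect_equal(forward_model("ETM", list(Ktrans = 0, ve = 0.2, vp = 0.05),
                             t, Cp),
               0.05 * Cp, tolerance = 1e-14)

  # TM with kep -> 0 and Cp = exp(-t): Ct = Ktrans (1 - exp(-t))
  t2 <- seq(0, 5, by = 0.01)
  ct <- forward_model("TM", list(Ktrans = 0.1, ve = 1e5), t2, exp(-t2))
  expect_lt(max(abs(ct - 0.1 * (1 - exp(-t2)))), 1e-5)
})

test_that("2CXM collapses to the one-compartment vascular model at PS = 0", {
  acq <- std_acq()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  p <- list(Fp = 40, PS = 0, ve = 0.2, vp = 0.05)
  ct <- forward_model("2CXM", p, t, Cp)
  one_cpt <- 0.40 * exp_conv(Cp, t, 0.40 / 0.05)
  expect_lt(max(abs(ct - one_cpt)) / max(one_cpt), 1e-10)
})

test_that("shutter-speed signal reaches both water-exchange limits", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  ctm <- forward_model("TM", list(Ktrans = 0.15, ve = 0.25), t, Cp)

  # fast-exchange limit: taui -> 0 gives the single-pool SPGR signal
  fast <- forward_model("SSM", list(Ktrans = 0.15, ve = 0.25, taui = 1e-4),
                        t, Cp, acq, k, M0 = 1000)
  fxl <- concentration_to_signal(ctm, acq, k, 1000)
  expect_lt(max(abs(fast - fxl) / fxl), 1e-3)

  # no-exchange limit: taui large gives population-weighted two-pool signal
  slow <- forward_model("SSM", list(Ktrans = 0.15, ve = 0.25, taui = 200),
                        t, Cp, acq, k, M0 = 1000)
  nxl <- 1000 * (0.75 * spgr_signal(k$R10, acq$TR_ms, acq$flip_deg) +
                   0.25 * spgr_signal(k$R10 + k$r1 * ctm / 0.25,
                                      acq$TR_ms, acq$flip_deg))
  expect_lt(max(abs(slow - nxl) / nxl), 2e-3)

  # taui is carried in seconds: halving it visibly moves the signal away
  # from the no-exchange limit while leaving baseline frames untouched
  mid <- forward_model("SSM", list(Ktrans = 0.15, ve = 0.25, taui = 0.5),
                       t, Cp, acq, k, M0 = 1000)
  expect_equal(mid[1:11], fast[1:11], tolerance = 1e-9)
  expect_gt(max(abs(mid - slow) / slow), 1e-3)
})

test_that("SSM2 reduces to SSM as the vascular fraction vanishes", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  s2 <- forward_model("SSM2",
                      list(Ktrans = 0.15, ve = 0.25, vp = 1e-9, taui = 0.5),
                      t, Cp, acq, k, M0 = 1000)
  s1 <- forward_model("SSM", list(Ktrans = 0.15, ve = 0.25, taui = 0.5),
                      t, Cp, acq, k, M0 = 1000)
  expect_lt(max(abs(s2 - s1) / s1), 1e-6)
})

test_that("derived parameters follow their defining ratios and limits", {
  p <- derive_secondary(list(Ktrans = 0.2, ve = 0.4), "TM")
  expect_equal(p$kep, 0.5)

  # 2CXM: Ktrans = E Fp -> PS (unit-aligned) as Fp -> infinity
  q <- derive_secondary(list(Fp = 1e7, PS = 50, ve = 0.3, vp = 0.05), "2CXM")
  expect_equal(q$Ktrans, 50 / 100, tolerance = 1e-5)
  q0 <- derive_secondary(list(Fp = 80, PS = 0, ve = 0.3, vp = 0.05), "2CXM")
  expect_equal(q0$Ktrans, 0)

  expect_error(derive_secondary(list(Ktrans = 0.2, ve = 0), "TM"),
               "kep undefined")
})

test_that("noiseless self-fits recover random truths for every model", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  ranges <- list(Ktrans = c(0.02, 1.5), ve = c(0.05, 0.6),
                 vp = c(0.005, 0.12), taui = c(0.1, 2),
                 Fp = c(10, 150), PS = c(3, 80))
  with_seed(301, {
    for (m in c("TM", "ETM", "SSM", "2CXM", "SSM2")) {
      free <- model_spec(m)$free
      for (i in 1:50) {
        truth <- lapply(ranges[free], function(rg)
          exp(stats::runif(1, log(rg[1]), log(rg[2]))))
        curve <- forward_model(m, truth, t, Cp, acq, k, M0 = 900)
        fit <- fit_pixel(m, curve, t, Cp, acq, k)
        rel <- abs(unlist(fit$params[free]) - unlist(truth)) / unlist(truth)
        expect_lt(max(rel), 0.01)
        expect_gt(fit$r2, 0.999)
      }
    }
  })
})

test_that("no-uptake noise is gated as necrotic with zeroed parameters", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  with_seed(302, {
    for (m in c("TM", "SSM")) {
      curve <- if (model_spec(m)$space == "signal")
        500 + stats::rnorm(length(t), 0, 10)
      else stats::rnorm(length(t), 0, 0.05)
      fit <- fit_pixel(m, curve, t, Cp, acq, k)
      expect_lt(fit$r2, 0.7)
      expect_true(fit$necrotic)
      expect_true(all(unlist(fit$params) == 0))
    }
  })
})

test_that("nested models: ETM never fits worse than TM, vp shrinks to zero", {
  acq <- std_acq(); k <- std_k()
  t <- time_grid_min(acq)
  Cp <- aif_eval(std_aif(), t)
  truth <- list(Ktrans = 0.25, ve = 0.35)
  clean <- forward_model("TM", truth, t, Cp)

  fit_e <- fit_pixel("ETM", clean, t, Cp, acq, k)
  expect_lte(fit_e$params$vp, 0.005)
  expect_lt(abs(fit_e$params$Ktrans - 0.25) / 0.25, 0.02)
  expect_lt(abs(fit_e$params$ve - 0.35) / 0.35, 0.02)

  with_seed(303, {
    for (i in 1:10) {
      noisy <- clean + stats::rnorm(length(t), 0, 0.02)
      rss_tm <- fit_pixel("TM", noisy, t, Cp, acq, k)$rss
      rss_etm <- fit_pixel("ETM", noisy, t, Cp, acq, k)$rss
      # slack = Levenberg-Marquardt stopping tolerance, not model error
      expect_lte(rss_etm, rss_tm * (1 + 1e-4))
    }
  })
})
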