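test_that("Pearson correlation matches hand-computed and limiting cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_lt(pearson(x, 2 * x + 1)$p, 1e-6)

  r <- pearson(x, c(1, 3, 2, 4))
  expect_equal(r$r, 0.8, tolerance = 1e-12)

  with_seed(501, {
    xx <- stats::rnorm(100)
    yy <- sample(xx)
    res <- pearson(xx, yy)
    expect_lt(abs(res$r), 0.25)
    expect_gt(res$p, 0.01)
  })
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("Pearson p agrees with a permutation reference on small samples", {
  with_seed(502, {
    x <- stats::rnorm(10)
    y <- 0.6 * x + stats::rnorm(10, 0, 0.8)
    res <- pearson(x, y)
    robs <- abs(stats::cor(x, y))
    perm <- mean(replicate(20000, abs(stats::cor(x, sample(y))) >= robs - 1e-12))
    expect_lt(abs(res$p - perm), 0.02)
  })
})

test_that("exact rank-sum p-values match enumeration landmarks", {
  expect_equal(as.numeric(wilcoxon_ranksum(1:3, 4:6)), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(as.numeric(wilcoxon_ranksum(c(-40, -35, -30, -45),
                                           c(5, 10, 0, 8))),
               2 / 70, tolerance = 1e-12)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum agrees with the independent implementation", {
  # stats::wilcox.test computes the exact distribution for untied data
  with_seed(503, {
    for (na in 2:6) for (nb in na:6) {
      a <- stats::rnorm(na); b <- stats::rnorm(nb)
      p_mine <- as.numeric(wilcoxon_ranksum(a, b))
      p_ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
      expect_equal(p_mine, p_ref, tolerance = 1e-12)
    }
  })
})

test_that("normal approximation tracks the exact rank-sum p", {
  with_seed(504, {
    ds <- replicate(200, {
      a <- stats::rnorm(6); b <- stats::rnorm(6)
      abs(as.numeric(wilcoxon_ranksum(a, b)) -
            as.numeric(wilcoxon_ranksum(a, b, exact_max = 0)))
    })
    expect_lt(stats::median(ds), 0.01)
    expect_lt(max(ds), 0.02)
  })
})

test_that("percent change follows its definition and flags zero baselines", {
  expect_equal(percent_change(10, 12), 20)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(0.2, 0.1), -50)
  expect_true(is.na(percent_change(0, 5)))
})

test_that("habitat counts correlate with volume when an effect is planted", {
  build_table <- function(nec_frac, vols) {
    do.call(rbind, lapply(seq_along(vols), function(i) {
      total <- 100
      nn <- round(nec_frac[i] * total)
      rest <- total - nn
      table_rows(sprintf("s%02d", i), "control", "T0", vols[i], "SSM",
                 "Ktrans", c(nn, rest - 2 * floor(rest / 3),
                             floor(rest / 3), floor(rest / 3)), 0.2)
    }))
  }
  with_seed(505, {
    vols <- stats::runif(35, 0.006, 0.04)
    planted <- build_table(0.2 + 5 * vols + stats::rnorm(35, 0, 0.03), vols)
    ct <- correlate_clusters_with_volume(planted, "SSM")
    nec <- ct[ct$cluster == "necrotic", ]
    expect_gt(nec$r, 0.5)
    expect_lt(nec$p, 0.05)

    null_tab <- build_table(rep(0.2, 35) + stats::rnorm(35, 0, 0.03), vols)
    ct0 <- correlate_clusters_with_volume(null_tab, "SSM")
    expect_lt(abs(ct0[ct0$cluster == "necrotic", "r"]), 0.3)
  })
  two <- build_table(c(0.2, 0.3), c(0.01, 0.02))
  expect_error(correlate_clusters_with_volume(two, "SSM"), "at least 3")
})

test_that("model selection applies all three gates deterministically", {
  mk <- function(nec_r, nec_p, kt_r) {
    data.frame(parameter = c("Ktrans", "Ktrans"),
               cluster = c("necrotic", "high"),
               r = c(nec_r, kt_r), p = c(nec_p, 0.5), n = 35)
  }
  tabs <- list(TM = mk(-0.23, 0.2, -0.02), ETM = mk(-0.23, 0.2, -0.05),
               SSM = mk(0.53, 1e-3, -0.25), `2CXM` = mk(0.54, 1e-3, -0.22),
               SSM2 = mk(0.24, 0.17, -0.11))
  r2s <- c(TM = 0.95, ETM = 0.956, SSM = 0.962, `2CXM` = 0.968, SSM2 = 0.96)
  expect_setequal(select_models(tabs, r2s), c("SSM", "2CXM"))

  # nothing qualifies: empty with a warning
  expect_warning(sel0 <- select_models(tabs["TM"], r2s["TM"]), "no model")
  expect_length(sel0, 0)

  # all identical and qualifying: all returned
  good <- list(TM = mk(0.6, 1e-3, -0.3), ETM = mk(0.6, 1e-3, -0.3))
  expect_setequal(select_models(good, c(TM = 0.97, ETM = 0.97)),
                  c("TM", "ETM"))
})

test_that("group comparison reproduces the exact most-extreme-split p", {
  subj <- sprintf("s%d", 1:8)
  grp <- rep(c("treated", "control"), each = 4)
  base <- do.call(rbind, lapply(1:8, function(i)
    table_rows(subj[i], grp[i], "T0", 0.01, "SSM", "Ktrans",
               c(10, 30, 30, 30), 0.2)))
  t3 <- do.call(rbind, lapply(1:8, function(i) {
    chg <- if (grp[i] == "treated") c(-40, -35, -30, -45)[i] else
      c(5, 10, 0, 8)[i - 4]
    table_rows(subj[i], grp[i], "T3", 0.012, "SSM", "Ktrans",
               c(10, 30, 30, 30) * (1 + chg / 100), 0.2)
  }))
  res <- compare_groups(rbind(base, t3), "Ktrans", "necrotic", "SSM")
  expect_equal(res$p, 2 / 70, tolerance = 1e-9)
  expect_lt(res$median_treated, res$median_control)

  # one group missing entirely -> error
  solo <- rbind(base, t3)
  solo <- solo[solo$group == "treated" | solo$timepoint == "T0", ]
  expect_error(compare_groups(solo, "Ktrans", "necrotic", "SSM"), ">= 2")
})

test_that("cohort statistics are invariant to table row order", {
  with_seed(506, {
    vols <- stats::runif(12, 0.006, 0.04)
    tab <- do.call(rbind, lapply(1:12, function(i)
      table_rows(sprintf("s%02d", i), "control", "T0", vols[i], "TM",
                 "Ktrans", c(round(30 * vols[i] * 25), 40, 30, 20), 0.2)))
    ct1 <- correlate_clusters_with_volume(tab, "TM")
    ct2 <- correlate_clusters_with_volume(tab[sample(nrow(tab)), ], "TM")
    expect_equal(ct1[order(ct1$cluster), c("r", "p")],
                 ct2[order(ct2$cluster), c("r", "p")],
                 ignore_attr = TRUE)
  })
})
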