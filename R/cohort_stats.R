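#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation; two-sided p from the t distribution with
#' `n - 2` degrees of freedom (via `stats::cor.test`).
#'
#' @param x,y numeric vectors, `n >= 3`, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact p by full enumeration of all `choose(n, n_a)` group assignments
#' (midranks, so ties are handled) when the pooled sample has at most
#' `exact_max` observations; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max largest pooled size for exact enumeration (default 12).
#' @return Two-sided p-value, with attributes `W` (rank sum of `a`) and
#'   `exact`.
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 12) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)])
  n <- na + nb
  if (n <= exact_max) {
    sets <- utils::combn(n, na)
    Wdist <- colSums(matrix(r[sets], nrow = na))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Wdist <= W + eps), mean(Wdist >= W - eps)))
    return(structure(p, W = W, exact = TRUE))
  }
  mu <- na * (n + 1) / 2
  ties <- table(pooled)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  structure(min(1, 2 * stats::pnorm(-abs(z))), W = W, exact = FALSE)
}

#' Percent change from baseline
#'
#' `100 * (value - baseline) / baseline`; `NA` (flagged) when the baseline
#' is zero, as happens when a baseline cluster is empty.
#'
#' @param baseline,value numeric (vectorised).
#' @return Percent change; `NA` where `baseline == 0`.
#' @export
percent_change <- function(baseline, value) {
  out <- 100 * (value - baseline) / baseline
  out[baseline == 0] <- NA_real_
  out
}

#' Correlate habitat measures with tumour volume across a cohort
#'
#' For one model, correlates tumour volume against each parameter's habitat
#' pixel counts (expressed as percent of tumour-mask voxels by default) and
#' against the overall non-necrotic mean, pooling all (subject, timepoint)
#' datasets.
#'
#' @param table cohort table (see [run_cohort()]): columns `subject`,
#'   `timepoint`, `volume_cc`, `model`, `parameter`, `cluster`, `value`.
#' @param model model id to select.
#' @param as_percent express counts as % of tumour voxels (default TRUE).
#' @return Data frame: `parameter`, `cluster`, `r`, `p`, `n`.
#' @export
correlate_clusters_with_volume <- function(table, model, as_percent = TRUE) {
  tb <- table[table$model == model, ]
  key <- interaction(tb$subject, tb$timepoint, drop = TRUE)
  if (length(unique(tb$subject)) < 3)
    stop("need at least 3 subjects for correlation analysis")
  totals <- tapply(
    tb$value[tb$cluster %in% c("necrotic", "low", "med", "high") &
               tb$parameter == tb$parameter[1]],
    key[tb$cluster %in% c("necrotic", "low", "med", "high") &
          tb$parameter == tb$parameter[1]],
    sum)
  out <- list()
  for (par in unique(tb$parameter)) {
    for (cl in c("necrotic", "low", "med", "high", "overall_mean")) {
      sub <- tb[tb$parameter == par & tb$cluster == cl, ]
      if (nrow(sub) < 3) next
      skey <- as.character(interaction(sub$subject, sub$timepoint,
                                       drop = TRUE))
      y <- sub$value
      if (as_percent && cl != "overall_mean")
        y <- 100 * y / as.numeric(totals[skey])
      res <- tryCatch(pearson(sub$volume_cc, y), error = function(e) NULL)
      if (is.null(res)) next
      out[[length(out) + 1]] <- data.frame(
        parameter = par, cluster = cl, r = res$r, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Select kinetic models for treatment-response assessment
#'
#' A model qualifies when (i) the necrotic-pixel count rises significantly
#' with tumour volume (`r > 0`, `p <= alpha`), (ii) the high-Ktrans habitat
#' count falls with volume (`r < 0`), and (iii) the mean tumour-ROI fit
#' `R^2` is at least `r2_min`.
#'
#' @param corr_tables named list (per model) of data frames from
#'   [correlate_clusters_with_volume()].
#' @param r2_by_model named numeric: mean fit R^2 per model.
#' @param r2_min mean-R^2 threshold (default 0.96).
#' @param alpha significance level (default 0.05).
#' @return Character vector of qualifying model ids (possibly empty, with a
#'   warning).
#' @export
select_models <- function(corr_tables, r2_by_model, r2_min = 0.96,
                          alpha = 0.05) {
  sel <- character(0)
  for (m in names(corr_tables)) {
    tb <- corr_tables[[m]]
    nec <- tb[tb$cluster == "necrotic", ][1, ]
    kth <- tb[tb$parameter == "Ktrans" & tb$cluster == "high", ][1, ]
    ok <- !is.na(nec$r) && nec$r > 0 && nec$p <= alpha &&
      !is.na(kth$r) && kth$r < 0 &&
      !is.na(r2_by_model[[m]]) && r2_by_model[[m]] >= r2_min
    if (isTRUE(ok)) sel <- c(sel, m)
  }
  if (length(sel) == 0) warning("no model satisfies the selection rule")
  sel
}

#' Compare treated vs control percent change at a timepoint
#'
#' Computes each subject's percent change from baseline in the chosen
#' measure, then applies the two-sided Wilcoxon rank-sum test between
#' groups. Subjects missing a baseline entry are dropped with a message.
#'
#' @param table cohort table with columns `subject`, `group`, `timepoint`,
#'   `model`, `parameter`, `cluster`, `value`.
#' @param parameter,cluster,model measure selectors.
#' @param timepoint timepoint(s) to test (default: all non-baseline).
#' @param baseline baseline timepoint label (default `"T0"`).
#' @return Data frame: `timepoint`, `p`, `n_treated`, `n_control`,
#'   `median_treated`, `median_control` (percent changes).
#' @export
compare_groups <- function(table, parameter, cluster, model,
                           timepoint = NULL, baseline = "T0") {
  tb <- table[table$model == model & table$parameter == parameter &
                table$cluster == cluster, ]
  if (nrow(tb) == 0) stop("no rows match the requested measure")
  tps <- timepoint %||% setdiff(unique(tb$timepoint), baseline)
  base <- tb[tb$timepoint == baseline, ]
  out <- list()
  for (tp in tps) {
    cur <- tb[tb$timepoint == tp, ]
    merged <- merge(base[, c("subject", "group", "value")],
                    cur[, c("subject", "value")],
                    by = "subject", suffixes = c("_base", "_tp"))
    dropped <- setdiff(cur$subject, base$subject)
    if (length(dropped))
      message("dropping subjects without baseline: ",
              paste(dropped, collapse = ", "))
    merged$pct <- percent_change(merged$value_base, merged$value_tp)
    merged <- merged[is.finite(merged$pct), ]
    trt <- merged$pct[merged$group == "treated"]
    ctl <- merged$pct[merged$group == "control"]
    if (length(trt) < 2 || length(ctl) < 2)
      stop("need >= 2 subjects per group with baseline at ", tp)
    p <- wilcoxon_ranksum(trt, ctl)
    out[[tp]] <- data.frame(
      timepoint = tp, p = as.numeric(p),
      n_treated = length(trt), n_control = length(ctl),
      median_treated = stats::median(trt),
      median_control = stats::median(ctl),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "note") <- "p-values are uncorrected for multiple testing"
  res
}
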