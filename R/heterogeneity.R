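#' Ward hierarchical clustering of a 1D feature
#'
#' Agglomerative clustering with Ward's minimum-variance linkage and
#' Euclidean distance (via `stats::hclust(method = "ward.D2")`), with the
#' dendrogram cut at `k` clusters. Deterministic for a given input order.
#'
#' @param values numeric vector.
#' @param k number of clusters, `1 <= k <= length(values)`.
#' @return Integer cluster labels (arbitrary ids, `1..k`).
#' @export
ward_cluster_1d <- function(values, k) {
  stopifnot(is.numeric(values), k >= 1)
  if (k > length(values)) stop("k exceeds number of observations")
  if (k == 1) return(rep(1L, length(values)))
  hc <- stats::hclust(stats::dist(values), method = "ward.D2")
  stats::cutree(hc, k = k)
}

# Exhaustive minimum within-cluster-SS partition of a 1D sample into k
# groups. In one dimension the optimum is contiguous in sorted order, so all
# contiguous compositions are enumerated. Independent oracle for tests.
optimal_partition_1d <- function(values, k) {
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL
  for (j in seq_len(ncol(cuts))) {
    bnd <- c(0, cuts[, j], n)
    ss <- 0
    lab <- integer(n)
    for (g in seq_len(k)) {
      seg <- v[(bnd[g] + 1):bnd[g + 1]]
      ss <- ss + sum((seg - mean(seg))^2)
      lab[(bnd[g] + 1):bnd[g + 1]] <- g
    }
    if (is.null(best) || ss < best$ss) best <- list(ss = ss, lab = lab)
  }
  out <- integer(n)
  out[ord] <- best$lab
  out
}

#' Cluster one parameter map into necrotic/low/med/high habitats
#'
#' Non-necrotic tumour voxels are Ward-clustered into `k` groups labelled
#' `low`, `med`, `high` by ascending cluster mean (ties broken by cluster
#' size, larger first). Necrotic voxels never enter the clustering.
#'
#' @param pmap 3D parameter map.
#' @param mask logical tumour mask.
#' @param necrotic_mask logical mask of R^2-gated voxels (subset of `mask`).
#' @param k number of value clusters (default 3).
#' @return List of class `cluster_map`: `labels` (3D integer array, 0 =
#'   outside, 1 = necrotic, 2 = low, 3 = med, 4 = high), `counts` (named:
#'   necrotic/low/med/high), `means` (named, `NA` for empty or necrotic
#'   clusters), `overall_mean` (non-necrotic voxels).
#' @export
cluster_parameter_map <- function(pmap, mask, necrotic_mask, k = 3) {
  stopifnot(all(dim(pmap) == dim(mask)), all(dim(mask) == dim(necrotic_mask)))
  if (any(necrotic_mask & !mask)) stop("necrotic mask not inside tumour mask")
  labels <- array(0L, dim(mask))
  labels[necrotic_mask] <- 1L
  live <- mask & !necrotic_mask
  vals <- pmap[live]
  lab_names <- c("low", "med", "high")
  counts <- c(necrotic = sum(necrotic_mask), low = 0L, med = 0L, high = 0L)
  means <- c(low = NA_real_, med = NA_real_, high = NA_real_)
  if (length(vals) > 0) {
    if (length(vals) < k) {
      warning("fewer non-necrotic voxels than clusters; all labelled low")
      labels[live] <- 2L
      counts["low"] <- length(vals)
      means["low"] <- mean(vals)
    } else {
      cl <- ward_cluster_1d(vals, k)
      mu <- tapply(vals, cl, mean)
      sz <- tapply(vals, cl, length)
      ord <- order(mu, -sz)           # ascending mean; ties: larger = lower
      rank_of <- integer(length(mu))
      rank_of[as.integer(names(mu))[ord]] <- seq_along(ord)
      lvl <- rank_of[cl]
      labels[live] <- 1L + lvl
      for (g in seq_len(k)) {
        nm <- lab_names[g]
        counts[nm] <- sum(lvl == g)
        means[nm] <- if (any(lvl == g)) mean(vals[lvl == g]) else NA_real_
      }
    }
  }
  structure(list(labels = labels, counts = counts, means = means,
                 overall_mean = if (length(vals)) mean(vals) else NA_real_),
            class = "cluster_map")
}

#' Tumour volume from a mask
#'
#' Voxel count times voxel volume; `cc = mm^3 / 1000`.
#'
#' @param mask logical 3D mask (non-empty).
#' @param voxdim_mm voxel dimensions (mm), length 3.
#' @return List with `volume_cc`, `n_voxels`, `voxel_volume_cc`.
#' @export
tumour_volume <- function(mask, voxdim_mm) {
  n <- sum(mask)
  if (n == 0) stop("empty tumour mask")
  vv <- prod(voxdim_mm) / 1000
  list(volume_cc = n * vv, n_voxels = n, voxel_volume_cc = vv)
}

#' Habitat summary of all parameter maps of one model fit
#'
#' Clusters each parameter map into habitats and reports counts, habitat
#' means and the overall non-necrotic mean per parameter.
#'
#' @param pmaps a `parameter_maps` object from [fit_map()].
#' @param mask logical tumour mask (defaults to the fit mask).
#' @param k number of value clusters (default 3).
#' @return List with `clusters` (named list of `cluster_map`) and `summary`
#'   (long data frame: parameter, cluster, count, mean).
#' @export
summarise_maps <- function(pmaps, mask = pmaps$mask, k = 3) {
  stopifnot(inherits(pmaps, "parameter_maps"))
  clusters <- list()
  rows <- list()
  for (nm in names(pmaps$maps)) {
    cm <- cluster_parameter_map(pmaps$maps[[nm]], mask, pmaps$necrotic, k)
    clusters[[nm]] <- cm
    rows[[nm]] <- data.frame(
      parameter = nm,
      cluster = c("necrotic", "low", "med", "high", "overall_mean"),
      count = c(as.integer(cm$counts), NA_integer_),
      value = c(cm$counts[["necrotic"]], cm$counts[["low"]],
                cm$counts[["med"]], cm$counts[["high"]], cm$overall_mean),
      mean = c(NA, cm$means[["low"]], cm$means[["med"]], cm$means[["high"]],
               cm$overall_mean),
      stringsAsFactors = FALSE)
  }
  list(clusters = clusters, summary = do.call(rbind, rows))
}
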