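test_that("Ward clustering separates well-spaced value groups exactly", {
  v <- c(1, 1, 1, 5, 5, 5, 9, 9, 9)
  lab <- ward_cluster_1d(v, 3)
  expect_equal(length(unique(lab)), 3)
  expect_equal(as.integer(table(lab)), c(3L, 3L, 3L))
  expect_equal(length(unique(lab[v == 1])), 1)
  expect_equal(length(unique(lab[v == 5])), 1)
  expect_equal(length(unique(lab[v == 9])), 1)

  expect_equal(ward_cluster_1d(v, 1), rep(1L, 9))
  expect_error(ward_cluster_1d(1:3, 4), "exceeds")

  # all-identical input: total membership conserved
  lab0 <- ward_cluster_1d(rep(2, 7), 3)
  expect_equal(length(lab0), 7)
  expect_lte(length(unique(lab0)), 3)
})

test_that("Ward clustering agrees with the exhaustive optimum when separated", {
  with_seed(401, {
    for (i in 1:50) {
      n <- sample(6:10, 1)
      centers <- c(0, 10, 20) + stats::runif(3, -2, 2)
      assign_c <- c(1:3, sample(1:3, n - 3, replace = TRUE))
      v <- stats::rnorm(n, centers[assign_c], 0.3)
      a <- ward_cluster_1d(v, 3)
      b <- dcehabitats:::optimal_partition_1d(v, 3)
      # identical partitions up to label permutation
      expect_equal(length(unique(paste(a, b))), length(unique(a)))
    }
  })
})

test_that("habitat labelling recovers planted regions and conserves counts", {
  dims <- c(10, 10, 2)
  mask <- array(FALSE, dims); mask[2:9, 2:9, ] <- TRUE
  idx <- which(mask)
  pmap <- array(0, dims)
  nec <- array(FALSE, dims)
  groups <- rep(1:4, length.out = length(idx))
  pmap[idx[groups == 2]] <- 0.05
  pmap[idx[groups == 3]] <- 0.2
  pmap[idx[groups == 4]] <- 0.6
  nec[idx[groups == 1]] <- TRUE

  cm <- cluster_parameter_map(pmap, mask, nec, k = 3)
  expect_equal(sum(cm$counts), sum(mask))
  expect_equal(unname(cm$counts["necrotic"]), sum(groups == 1))
  expect_equal(unname(cm$counts[c("low", "med", "high")]),
               as.integer(table(groups)[2:4]))
  expect_equal(unname(cm$means), c(0.05, 0.2, 0.6))
  expect_true(cm$means["low"] < cm$means["med"])
  expect_true(cm$means["med"] < cm$means["high"])
  # necrotic voxels carry label 1 and never enter the habitat means
  expect_true(all(cm$labels[nec] == 1L))
  expect_equal(cm$overall_mean, mean(pmap[mask & !nec]))
})

test_that("habitat labelling tolerates noise around planted levels", {
  with_seed(402, {
    dims <- c(12, 12, 2)
    mask <- array(TRUE, dims)
    nec <- array(FALSE, dims)
    truth_lvl <- sample(1:3, prod(dims), replace = TRUE)
    sep <- 0.15
    pmap <- array(c(0.05, 0.2, 0.35)[truth_lvl] +
                    stats::rnorm(prod(dims), 0, 0.1 * sep), dims)
    cm <- cluster_parameter_map(pmap, mask, nec, k = 3)
    assigned <- cm$labels - 1L
    expect_gte(mean(assigned == truth_lvl), 0.95)
  })
})

test_that("counts and means are invariant to voxel ordering", {
  with_seed(403, {
    v <- stats::rnorm(60, rep(c(0, 5, 10), each = 20), 0.4)
    dims <- c(60, 1, 1)
    mask <- array(TRUE, dims); nec <- array(FALSE, dims)
    cm1 <- cluster_parameter_map(array(v, dims), mask, nec, 3)
    perm <- sample(60)
    cm2 <- cluster_parameter_map(array(v[perm], dims), mask, nec, 3)
    expect_equal(cm1$counts, cm2$counts)
    expect_equal(cm1$means, cm2$means)
  })
})

test_that("tumour volume is voxel count times voxel volume", {
  dims <- c(10, 10, 4)
  mask <- array(FALSE, dims); mask[which(array(TRUE, dims))[1:100]] <- TRUE
  vd <- c(0.234, 0.469, 1.16)
  res <- tumour_volume(mask, vd)
  expect_equal(res$volume_cc, 100 * prod(vd) / 1000, tolerance = 1e-12)
  expect_equal(res$n_voxels, 100)

  one <- array(FALSE, c(2, 2, 2)); one[1] <- TRUE
  expect_equal(tumour_volume(one, c(1, 1, 1))$volume_cc, 0.001)

  mask2 <- mask; mask2[which(array(TRUE, dims))[101:200]] <- TRUE
  expect_equal(tumour_volume(mask2, vd)$volume_cc, 2 * res$volume_cc)
  expect_error(tumour_volume(array(FALSE, dims), vd), "empty")
})

test_that("map summaries handle all-necrotic and uniform maps", {
  dims <- c(6, 6, 1)
  mask <- array(TRUE, dims)
  pm <- structure(list(
    maps = list(Ktrans = array(0, dims)),
    r2 = array(0, dims), necrotic = array(TRUE, dims),
    model = "TM", voxdim_mm = c(1, 1, 1), mask = mask),
    class = "parameter_maps")
  sm <- summarise_maps(pm, mask)
  cm <- sm$clusters$Ktrans
  expect_equal(unname(cm$counts), c(36L, 0L, 0L, 0L))
  expect_true(all(is.na(cm$means)))
  expect_true(is.na(cm$overall_mean))

  pm$necrotic <- array(FALSE, dims)
  pm$maps$Ktrans <- array(0.3, dims)
  sm2 <- summarise_maps(pm, mask)
  expect_equal(sm2$clusters$Ktrans$overall_mean, 0.3)
  expect_equal(sum(sm2$clusters$Ktrans$counts), 36)
})
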