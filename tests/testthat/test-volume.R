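test_that("text and NIfTI volumes round-trip with geometry intact", {
  vol <- brain_volume(array(1, c(4, 4, 4)), subject_id = "ones")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_volume(vol, txt)
  back <- read_volume(txt, subject_id = "ones")
  expect_equal(length(back$intensities), 64)
  expect_equal(back$voxel_size, c(1, 1, 1))
  expect_equal(back$intensities, vol$intensities)

  set.seed(1)
  vol2 <- brain_volume(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                       voxel_size = c(1.5, 2, 2.5), subject_id = "r")
  txt2 <- withr::local_tempfile(fileext = ".txt")
  write_volume(vol2, txt2)
  back2 <- read_volume(txt2)
  expect_equal(back2$intensities, vol2$intensities, tolerance = 1e-10)
  expect_equal(back2$voxel_size, vol2$voxel_size)

  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol2, nii)
  back3 <- read_volume(nii)
  expect_equal(back3$intensities, vol2$intensities, tolerance = 1e-6)
  expect_equal(back3$voxel_size, vol2$voxel_size, tolerance = 1e-6)
})

test_that("malformed volumes are rejected with informative errors", {
  nii4d <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), nii4d)
  expect_error(read_volume(nii4d), class = "salnet_error_shape")

  expect_error(read_volume("no/such/file.nii"), class = "salnet_error_input")

  bad <- array(1, c(3, 3, 3)); bad[1:2] <- NaN
  expect_error(brain_volume(bad), regexp = "2 non-finite",
               class = "salnet_error_validation")
  expect_error(brain_volume(array(1, c(3, 3, 3)), voxel_size = c(1, 0, 1)),
               class = "salnet_error_validation")
})

test_that("supervoxel partition follows the near-cubic integer edge rule", {
  # independent enumeration of the documented rule: all integer triples,
  # near-cubic filter, minimal volume mismatch, lexicographic tie-break
  oracle_edges <- function(target, voxel = c(1, 1, 1)) {
    g <- expand.grid(e1 = 1:25, e2 = 1:25, e3 = 1:25)
    mm <- cbind(g$e1 * voxel[1], g$e2 * voxel[2], g$e3 * voxel[3])
    g <- g[apply(mm, 1, max) / apply(mm, 1, min) <= 1.2, ]
    diff <- abs(g$e1 * g$e2 * g$e3 * prod(voxel) - target)
    g <- g[order(diff, g$e1, g$e2, g$e3), ]
    unname(unlist(g[1, ]))
  }
  expect_equal(oracle_edges(3000), c(14, 14, 15))
  expect_equal(oracle_edges(1000), c(10, 10, 10))

  vol <- brain_volume(array(0, c(30, 30, 30)))
  p <- partition_supervoxels(vol, 3000)
  expect_equal(p$box_shape_voxels, c(14L, 14L, 15L))
  expect_equal(p$n_boxes, 8L)
  expect_equal(p$box_volume_mm3, 2940)
  # boxes disjoint, equal size, raster order with x fastest
  expect_equal(p$boxes$x0[1:2], c(0, 14))
  sizes <- (p$boxes$x1 - p$boxes$x0) * (p$boxes$y1 - p$boxes$y0) *
    (p$boxes$z1 - p$boxes$z0)
  expect_true(all(sizes == prod(p$box_shape_voxels)))

  p2 <- partition_supervoxels(brain_volume(array(0, c(10, 10, 10))), 1000)
  expect_equal(p2$n_boxes, 1L)
  expect_equal(p2$box_shape_voxels, c(10L, 10L, 10L))

  expect_error(partition_supervoxels(brain_volume(array(0, c(9, 9, 9))), 1000),
               class = "salnet_error_degenerate_partition")
})

test_that("a brain mask drops boxes below the in-mask fraction", {
  vol <- brain_volume(array(0, c(10, 10, 10)))
  mask <- array(0, c(10, 10, 10))
  mask[1:5, , ] <- 1  # left half in-mask
  p <- partition_supervoxels(vol, 125, mask = mask, mask_min_frac = 0.5)
  full <- partition_supervoxels(vol, 125)
  expect_equal(full$n_boxes, 8L)
  expect_equal(p$n_boxes, 4L)
})

test_that("correlation network matches the Pearson formula", {
  set.seed(7)
  base <- array(rnorm(1000), c(10, 10, 10))
  vol <- brain_volume(base)
  p <- partition_supervoxels(vol, 125)  # 8 boxes of 5^3
  # construct box contents explicitly
  x <- rnorm(125)
  ints <- array(0, c(10, 10, 10))
  ints[1:5, 1:5, 1:5] <- x                   # box 1
  ints[6:10, 1:5, 1:5] <- x                  # box 2: identical pattern
  ints[1:5, 6:10, 1:5] <- -(x - mean(x)) + 2 # box 3: mean-centered sign flip
  ints[6:10, 6:10, 1:5] <- rnorm(125)
  ints[, , 6:10] <- rnorm(500)
  net <- build_correlation_network(brain_volume(ints), p)
  expect_equal(net$weights[1, 2], 1)
  expect_equal(net$weights[1, 3], -1)
  expect_true(all(abs(net$weights) <= 1 + 1e-12))
  expect_equal(diag(net$weights), rep(0, 8), ignore_attr = TRUE)

  # direct two-pass covariance oracle on box pairs
  vecs <- sapply(1:8, function(b) {
    bx <- p$boxes[b, ]
    as.vector(ints[(bx$x0 + 1):bx$x1, (bx$y0 + 1):bx$y1, (bx$z0 + 1):bx$z1])
  })
  for (a in 1:4) for (b in (a + 1):5) {
    xa <- vecs[, a] - mean(vecs[, a]); xb <- vecs[, b] - mean(vecs[, b])
    r <- sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2))
    expect_equal(net$weights[a, b], r, tolerance = 1e-12)
  }

  # independent standard-normal boxes stay near zero at n = 2940
  set.seed(11)
  big <- brain_volume(array(rnorm(30^3), c(30, 30, 30)))
  bignet <- build_correlation_network(big, partition_supervoxels(big, 3000))
  expect_true(all(abs(bignet$weights[upper.tri(bignet$weights)]) < 0.1))
})

test_that("constant boxes warn and keep the node with zero weights", {
  ints <- array(rnorm(1000), c(10, 10, 10))
  ints[1:5, 1:5, 1:5] <- 3  # constant box 1
  vol <- brain_volume(ints)
  p <- partition_supervoxels(vol, 125)
  expect_warning(net <- build_correlation_network(vol, p),
                 regexp = "constant")
  expect_equal(length(net$node_ids), 8L)
  expect_equal(net$weights[1, ], rep(0, 8), ignore_attr = TRUE)
})

test_that("correlations are invariant to affine intensity rescaling and
           equivariant under box relabeling", {
  set.seed(3)
  ints <- array(rnorm(1000), c(10, 10, 10))
  vol <- brain_volume(ints)
  p <- partition_supervoxels(vol, 125)
  net <- build_correlation_network(vol, p)
  scaled <- build_correlation_network(brain_volume(2.7 * ints + 11), p)
  expect_equal(net$weights, scaled$weights, tolerance = 1e-12)

  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  p_perm <- p
  p_perm$boxes <- p$boxes[perm, ]
  p_perm$boxes$box <- seq_len(8)
  net_perm <- build_correlation_network(vol, p_perm)
  expect_equal(unname(net_perm$weights), unname(net$weights[perm, perm]),
               tolerance = 1e-12)
})

test_that("networks round-trip through dense and edge-list files", {
  set.seed(5)
  W <- matrix(runif(36, -1, 1), 6, 6); W <- (W + t(W)) / 2; diag(W) <- 0
  net <- correlation_network(W, subject_id = "s1")
  dense <- withr::local_tempfile(fileext = ".tsv")
  edges <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, dense, "dense")
  write_network(net, edges, "edgelist")
  expect_equal(read_network(dense, "dense")$weights, net$weights,
               tolerance = 1e-10)
  expect_equal(read_network(edges, "edgelist")$weights, net$weights,
               tolerance = 1e-10)
})
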