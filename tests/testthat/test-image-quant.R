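test_that("thresholding trivial cases", {
  m <- matrix(c(0, 0, 100, 100), 2)
  mask <- thresholdImage(m, "otsu")
  expect_identical(bareMask(mask), m == 100)

  m2 <- matrix(c(40, 40, 60, 60), 2)
  mask2 <- thresholdImage(m2, "fixed", value = 50)
  expect_identical(bareMask(mask2), m2 == 60)

  expect_error(thresholdImage(matrix(5, 3, 3), "otsu"), "constant image")
  expect_error(thresholdImage(m2, "fixed"), "requires a threshold value")
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(21)
  for (rep in 1:20) {
    x <- matrix(c(rnorm(600, 100, 20), rnorm(400, 500, 60)), 50)
    expect_equal(otsuThreshold(x), otsuOracle(x))
  }
  # threshold falls between the class means of a two-Gaussian image
  x <- matrix(c(rnorm(5000, 100, 20), rnorm(500, 800, 50)), 55)
  thr <- otsuThreshold(x)
  expect_gt(thr, 100)
  expect_lt(thr, 800)
})

test_that("Otsu mask is invariant under increasing affine transforms", {
  set.seed(31)
  x <- matrix(c(rnorm(800, 100, 30), rnorm(200, 900, 50)), 40)
  m0 <- thresholdImage(x, "otsu")
  for (ab in list(c(2, 0), c(0.5, 10), c(3, -50))) {
    m1 <- thresholdImage(ab[1] * x + ab[2], "otsu")
    expect_identical(bareMask(m0), bareMask(m1))
  }
})

test_that("labelling trivial geometries and the particle floor", {
  # one 10x10 px square at 0.1 um/px = 1.0 um^2
  mask <- matrix(FALSE, 20, 20); mask[5:14, 5:14] <- TRUE
  cs <- labelClusters(mask, 0.1)
  expect_equal(nClusters(cs), 1L)
  expect_equal(clusterTable(cs)$area_um2, 1.0)

  # a single isolated pixel (0.01 um^2) falls below the floor
  mask1 <- matrix(FALSE, 10, 10); mask1[5, 5] <- TRUE
  cs1 <- labelClusters(mask1, 0.1)
  expect_equal(nClusters(cs1), 0L)
  expect_equal(cs1@droppedPixels, 1L)
  expect_equal(cs1@droppedClusters, 1L)

  # corner-touching squares: one component under 8-connectivity, two under 4
  mask2 <- matrix(FALSE, 12, 12)
  mask2[2:5, 2:5] <- TRUE
  mask2[6:9, 6:9] <- TRUE
  expect_equal(nClusters(labelClusters(mask2, 0.2, connectivity = 8L)), 1L)
  expect_equal(nClusters(labelClusters(mask2, 0.2, connectivity = 4L)), 2L)

  # empty mask is fine
  expect_equal(nClusters(labelClusters(matrix(FALSE, 5, 5), 0.1)), 0L)
})

test_that("labelling matches the flood-fill oracle on random masks", {
  set.seed(17)
  for (rep in 1:30) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    for (conn in c(4L, 8L)) {
      cs <- labelClusters(mask, 0.1, connectivity = conn, min_area_um2 = 0)
      oracle <- floodFillLabel(mask, conn)
      expect_equal(nClusters(cs), max(oracle))
      expect_true(samePartition(labelMatrix(cs), oracle))
    }
  }
})

test_that("area accounting and pixel-size scaling hold exactly", {
  set.seed(13)
  mask <- matrix(runif(80 * 80) < 0.2, 80, 80)
  cs <- labelClusters(mask, 0.1, min_area_um2 = 0.2)
  expect_equal(sum(clusterTable(cs)$pixel_count) + cs@droppedPixels,
               sum(mask))

  a <- labelClusters(mask, 0.1, min_area_um2 = 0)
  b <- labelClusters(mask, 0.2, min_area_um2 = 0)
  expect_equal(nClusters(a), nClusters(b))
  expect_equal(clusterTable(b)$area_um2, 4 * clusterTable(a)$area_um2)
  expect_identical(clusterTable(a)$pixel_count,
                   clusterTable(b)$pixel_count)
})

test_that("end-to-end noiseless recovery: counts exact, areas in the quantization band", {
  sim <- simulateImage(smallImageConfig(noise_sd = 0), seed = 23)
  q <- quantifyImage(sim$image)
  expect_equal(q$summary$n_clusters, nrow(sim$clusters))
  got <- clusterTable(q$clusters)
  # match measured to ground-truth clusters by centroid proximity
  for (i in seq_len(nrow(got))) {
    d <- sqrt((sim$clusters$centroid_x - got$centroid_x[i])^2 +
              (sim$clusters$centroid_y - got$centroid_y[i])^2)
    j <- which.min(d)
    area_px <- sim$clusters$area_um2[j] / 0.01
    band <- 2 * sqrt(pi * area_px) * 1.5 * 0.01  # ~ perimeter quantization
    expect_lt(abs(got$area_um2[i] - sim$clusters$area_um2[j]), band)
  }
})

test_that("ring scoring: uniform cell, synthetic ring, dispersed control", {
  img <- MitoImage(matrix(100, 200, 200), 0.1)
  r <- ringScore(img, r_um = 4, width_um = 2, cell_radius_um = 9)
  expect_equal(r$score, 1.0)
  expect_false(r$present)

  # noiseless ring preset: annulus carries high-intensity clusters
  sim <- simulateImage(imagePreset("gvbd_ring", noise_sd = 0), seed = 4)
  rs <- ringScore(sim$image, r_um = 13, width_um = 6, cell_radius_um = 35,
                  nucleus_radius_um = 12)
  expect_gt(rs$score, 1.5)
  expect_true(rs$present)

  # direct pixel-mean computation agrees with the reported score
  px <- imagePixels(sim$image)
  d <- MitoPulse:::distanceUm(dim(px), sim$image@meta$center_px, 0.1)
  ann <- d >= 13 & d <= 19
  cyto <- d <= 35 & !ann & d >= 12
  expect_equal(rs$score, mean(px[ann]) / mean(px[cyto]))

  expect_error(ringScore(img, r_um = 40, width_um = 5,
                         cell_radius_um = 9), "outside the cell|empty")
})

test_that("dispersed sections rarely score as ringed", {
  present <- vapply(1:100, function(s) {
    sim <- simulateImage(imagePreset("dispersed"), seed = s)
    ringScore(sim$image, r_um = 13, width_um = 6, cell_radius_um = 35,
              nucleus_radius_um = 12)$present
  }, logical(1))
  expect_gte(sum(!present), 95)
})

test_that("pattern classification follows the printed group regimes", {
  expect_equal(classifyPattern(4.7, 66), "aggregated")
  expect_equal(classifyPattern(2.6, 102), "dispersed")
  expect_equal(classifyPattern(3.5, 85), "intermediate")
  expect_equal(classifyPattern(4.7, 102), "intermediate")
  sim <- simulateImage(imagePreset("aggregated"), seed = 6)
  expect_equal(quantifyImage(sim$image)$pattern, "aggregated")
})
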