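test_that("gaussianSmooth preserves constants and matches the convolution oracle", {
  cimg <- SpacedImage(matrix(3.7, 12, 12), spacing = 0.2)
  sm <- gaussianSmooth(cimg, 1)
  expect_equal(imgValues(sm), imgValues(cimg), tolerance = 1e-12)
  expect_identical(pixelSpacing(sm), pixelSpacing(cimg))

  ## unit impulse integrates to 1 away from borders
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm2 <- gaussianSmooth(SpacedImage(imp), 1)
  expect_equal(sum(imgValues(sm2)), 1, tolerance = 1e-9)
  expect_equal(which.max(imgValues(sm2)), 11L + 10L * 21L)

  set.seed(1)
  img <- matrix(rnorm(256), 16, 16)
  got <- imgValues(gaussianSmooth(SpacedImage(img), 1.3))
  k1 <- exp(-(-6:6)^2 / (2 * 1.3^2)); k1 <- k1 / sum(k1)
  expect_equal(got, oracleConv2(img, outer(k1, k1)), tolerance = 1e-6)
  expect_error(gaussianSmooth(SpacedImage(img), -1), "sigma")
})

test_that("gaussianSmooth handles 3D stacks separably", {
  set.seed(2)
  arr <- array(rnorm(5 * 8 * 8), c(5, 8, 8))
  sm <- gaussianSmooth(SpacedImage(arr, spacing = c(0.4, 0.2, 0.2)), 1)
  expect_identical(dim(sm), dim(arr))
  ## constant stack is preserved
  sm2 <- gaussianSmooth(SpacedImage(array(2, c(4, 6, 6))), 1)
  expect_equal(max(abs(imgValues(sm2) - 2)), 0, tolerance = 1e-12)
})

test_that("objectness filter responds to ridges, not flats or blobs", {
  expect_equal(max(imgValues(objectnessFilter(SpacedImage(matrix(5, 20, 20))))),
               0)
  ## Gaussian ridge along a column
  n <- 41
  x <- seq_len(n)
  ridge <- outer(rep(1, n), exp(-(x - 21)^2 / (2 * 1.5^2)))
  respR <- imgValues(objectnessFilter(SpacedImage(ridge)))
  inner <- respR[5:37, , drop = FALSE]
  peakCols <- apply(inner, 1L, which.max)
  expect_true(all(abs(peakCols - 21) <= 1))
  ## isotropic blob of equal peak gets a weaker maximal response
  blob <- exp(-((matrix(x, n, n) - 21)^2 + (t(matrix(x, n, n)) - 21)^2) /
                (2 * 1.5^2))
  respB <- imgValues(objectnessFilter(SpacedImage(blob)))
  expect_gt(max(respR), max(respB))
  ## rotation by 90 degrees (transpose) gives the transposed response
  respT <- imgValues(objectnessFilter(SpacedImage(t(ridge))))
  expect_equal(respT, t(respR), tolerance = 1e-9)
  ## 3D input is rejected
  expect_error(objectnessFilter(SpacedImage(array(0, c(2, 5, 5)))), "2D")
})

test_that("local adaptive threshold matches its windowed-statistics oracle", {
  ## constant image: strict inequality fails everywhere
  cm <- localAdaptiveThreshold(SpacedImage(matrix(4, 10, 10)),
                               thresholdParams(3L, 1))
  expect_false(any(imgValues(cm)))
  ## single hot pixel with a window covering the whole image
  hot <- matrix(0, 32, 32); hot[7, 9] <- 100
  m <- localAdaptiveThreshold(SpacedImage(hot), thresholdParams(200L, 1))
  expect_true(imgValues(m)[7, 9])
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  got <- imgValues(localAdaptiveThreshold(SpacedImage(img),
                                          thresholdParams(5L, 1)))
  expect_identical(got, oracleAdaptiveThreshold(img, 5L, 1))
  ## invariance to adding a constant
  got2 <- imgValues(localAdaptiveThreshold(SpacedImage(img + 17.3),
                                           thresholdParams(5L, 1)))
  expect_identical(got2, got)
})

test_that("morphological opening removes thin structures and is idempotent", {
  disc <- discMask(25, 6)
  op <- morphologicalOpen(disc, 2)
  expect_lte(sum(imgValues(disc)) - sum(imgValues(op)), 12)
  expect_true(all(imgValues(op) <= imgValues(disc)))    # subset
  ## single pixel and thin line vanish
  one <- matrix(FALSE, 15, 15); one[8, 8] <- TRUE
  expect_false(any(imgValues(morphologicalOpen(BinaryMask(one), 2))))
  line <- matrix(FALSE, 15, 30); line[8, 5:24] <- TRUE
  expect_false(any(imgValues(morphologicalOpen(BinaryMask(line), 2))))
  ## idempotence on a random mask
  set.seed(4)
  rnd <- BinaryMask(matrix(runif(40 * 40) < 0.5, 40, 40))
  o1 <- morphologicalOpen(rnd, 2)
  o2 <- morphologicalOpen(o1, 2)
  expect_identical(imgValues(o1), imgValues(o2))
})

test_that("largestComponent picks the maximal 8-connected component", {
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE         # 64 px
  m[25:29, 25:29] <- TRUE       # 25 px
  lc <- largestComponent(BinaryMask(m))
  expect_equal(sum(imgValues(lc)), 64)
  expect_true(all(which(imgValues(lc)) %in% which(m)))
  ## identity on a single component
  single <- BinaryMask(m & (row(m) < 20))
  expect_identical(imgValues(largestComponent(single)), imgValues(single))
  ## random blobs against the flood-fill oracle
  set.seed(5)
  rnd <- matrix(runif(30 * 30) < 0.35, 30, 30)
  lab <- oracleLabel2d(rnd)
  sizes <- tabulate(lab)
  expWinner <- lab == which.max(sizes)
  got <- imgValues(largestComponent(BinaryMask(rnd)))
  expect_equal(sum(got), max(sizes))
  expect_identical(got, expWinner)
  expect_error(largestComponent(BinaryMask(matrix(FALSE, 4, 4))), "empty")
})

test_that("combineMasks is a pixelwise union with shape checking", {
  a <- discMask(20, 5, center = 8)
  empty <- BinaryMask(matrix(FALSE, 20, 20))
  expect_identical(imgValues(combineMasks(a, empty)), imgValues(a))
  expect_identical(imgValues(combineMasks(a, a)), imgValues(a))
  b <- discMask(20, 3, center = 16)
  expect_equal(sum(imgValues(combineMasks(a, b))),
               sum(imgValues(a)) + sum(imgValues(b)))
  expect_error(combineMasks(a, BinaryMask(matrix(FALSE, 10, 10))),
               "shape")
})

test_that("skeleton endpoints find structure termini", {
  bar <- matrix(FALSE, 9, 26); bar[5, 4:23] <- TRUE
  ep <- skeletonEndpoints(BinaryMask(bar))
  expect_equal(nrow(ep), 2L)
  expect_true(all(abs(ep[, 2] - c(4, 23)) <= 1))
  ## filled disc degenerates to at most one endpoint
  epd <- skeletonEndpoints(discMask(21, 7))
  expect_lte(nrow(epd), 1L)
  ## T shape has three termini
  tee <- matrix(FALSE, 21, 21)
  tee[5, 3:19] <- TRUE; tee[4:6, 3:19][, 1] <- FALSE
  tee <- matrix(FALSE, 21, 21)
  tee[5:7, 3:19] <- TRUE          # horizontal bar, 3 px thick
  tee[5:17, 10:12] <- TRUE        # vertical stem
  ept <- skeletonEndpoints(BinaryMask(tee))
  expect_equal(nrow(ept), 3L)
  ## empty mask: empty endpoint set
  expect_equal(nrow(skeletonEndpoints(BinaryMask(matrix(FALSE, 5, 5)))),
               0L)
})
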