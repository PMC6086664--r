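test_that("buildCostMap inverts the edge map up to a constant", {
  z <- SpacedImage(matrix(0, 6, 6))
  cm <- buildCostMap(z)
  expect_equal(max(imgValues(cm)) - min(imgValues(cm)), 0)
  set.seed(10)
  e <- SpacedImage(matrix(runif(64), 8, 8))
  cm2 <- buildCostMap(e)
  expect_equal(which.min(imgValues(cm2)), which.max(imgValues(e)))
  expect_equal(imgValues(cm2) + imgValues(e),
               matrix(max(imgValues(e)) + 1e-6, 8, 8), tolerance = 1e-12)
})

test_that("livewireTrace finds minimum-cost paths with deterministic geometry", {
  uni <- SpacedImage(matrix(1, 8, 8))
  p0 <- livewireTrace(uni, c(3, 3), c(3, 3))
  expect_equal(nrow(p0@path), 1L)
  expect_equal(pathLengthEuclidean(p0), 0)
  ## uniform cost: diagonal run
  p <- livewireTrace(uni, c(1, 1), c(4, 4))
  expect_equal(nrow(p@path), 4L)
  expect_equal(pathLengthEuclidean(p@path, c(1, 1)), 3 * sqrt(2))
  ## path endpoints
  expect_equal(p@path[1, ], c(row = 1L, col = 1L))
  expect_equal(p@path[4, ], c(row = 4L, col = 4L))
  expect_error(livewireTrace(uni, c(50, 1), c(2, 2)), "inside")
})

test_that("livewire path cost equals the igraph Dijkstra oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:10) {
    cost <- matrix(runif(16 * 16, 0.01, 2), 16, 16)
    start <- c(sample(16, 1), sample(16, 1))
    stopPix <- cbind(sample(16, 2), sample(16, 2))
    got <- livewireTrace(SpacedImage(cost), start, stopPix)
    expect_equal(got@cost,
                 oracleLivewireCost(cost, start, stopPix),
                 tolerance = 1e-10)
  }
})

test_that("livewire cost is symmetric under start/stop reversal", {
  set.seed(12)
  cost <- SpacedImage(matrix(runif(100, 0.1, 1), 10, 10))
  a <- livewireTrace(cost, c(2, 3), c(9, 8))
  b <- livewireTrace(cost, c(9, 8), c(2, 3))
  expect_equal(a@cost, b@cost, tolerance = 1e-12)
})

test_that("adding a constant shifts the cost consistently and keeps a unique optimum", {
  ## cheap L-shaped corridor: the optimum is unique, so a constant
  ## offset cannot re-route the trace
  cost <- matrix(10, 10, 10)
  cost[1, 1:10] <- 0.01
  cost[1:10, 10] <- 0.01
  a <- livewireTrace(SpacedImage(cost), c(1, 1), c(10, 10))
  b <- livewireTrace(SpacedImage(cost + 5), c(1, 1), c(10, 10))
  expect_identical(a@path, b@path)
  geomLen <- pathLengthEuclidean(a@path, c(1, 1))
  expect_equal(b@cost - a@cost, 5 * geomLen, tolerance = 1e-9)
})

test_that("plane assignment equals the exhaustive enumeration oracle", {
  set.seed(14)
  for (rep in 1:20) {
    M <- sample(2:6, 1)
    nz <- sample(3:5, 1)
    prof <- matrix(runif(M * nz), M, nz)
    zs <- sample(nz, 1)
    reach <- max(1, zs - (M - 1)):min(nz, zs + (M - 1))
    ze <- sample(reach, 1)
    got <- CytoQuant:::.zAssignDP(prof, zs, ze, zStep = 1L)
    ora <- oracleZAssign(prof, zs, ze, zStep = 1L)
    expect_equal(sum(prof[cbind(seq_len(M), got)]), ora$score,
                 tolerance = 1e-12)
  }
  expect_error(CytoQuant:::.zAssignDP(matrix(1, 3, 6), 1L, 6L, 1L),
               "unreachable")
})

test_that("3D tracing recovers straight bright segments", {
  ## straight bright segment in a dark volume
  vol <- array(0, c(7, 30, 30))
  zs <- round(seq(2, 6, length.out = 21))
  rs <- 5:25
  cs <- round(seq(5, 25, length.out = 21))
  for (i in 1:21) vol[zs[i], rs[i], cs[i]] <- 1
  img <- SpacedImage(vol)
  p <- traceFilopodium3d(img, start = c(zs[1], rs[1], cs[1]),
                         end = c(zs[21], rs[21], cs[21]))
  truth <- cbind(zs, rs, cs)
  dev <- apply(p@path, 1L, function(v)
    min(sqrt(colSums((t(truth) - as.numeric(v))^2))))
  expect_lte(max(dev), sqrt(2))
  ## single bright plane: the traced path stays in that plane
  vol2 <- array(0, c(5, 20, 20))
  vol2[3, 10, ] <- 1
  p2 <- traceFilopodium3d(SpacedImage(vol2), c(3, 10, 2), c(3, 10, 18))
  expect_true(all(p2@path[, 1] == 3L))
})

test_that("traceFilopodia2d respects body exclusion and the min-length filter", {
  res <- makeCellImage(standardCellSpec())
  full <- CytoQuant:::.segmentCellFull(res$image)
  seg <- full$seg
  ## a tip placed inside the body yields no trace
  bodyPix <- which(imgValues(bodyMask(seg)), arr.ind = TRUE)
  seg2 <- new("CellSegmentation", body = bodyMask(seg),
              combined = combinedMask(seg),
              tips = bodyPix[1, , drop = FALSE])
  expect_length(traceFilopodia2d(seg2, full$edge), 0L)
  ## no tips: empty list
  seg3 <- new("CellSegmentation", body = bodyMask(seg),
              combined = combinedMask(seg),
              tips = matrix(integer(), 0, 2))
  expect_length(traceFilopodia2d(seg3, full$edge), 0L)
})
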