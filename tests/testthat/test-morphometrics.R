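test_that("Euclidean path length follows the geometry", {
  expect_equal(pathLengthEuclidean(matrix(c(5, 5), 1), c(1, 1)), 0)
  coll <- cbind(1:11, rep(3, 11))
  expect_equal(pathLengthEuclidean(coll, c(0.5, 0.5)), 5)
  diag3 <- cbind(1:4, 1:4)
  expect_equal(pathLengthEuclidean(diag3, c(1, 1)), 3 * sqrt(2))
  ## reversal invariance and additivity under concatenation
  set.seed(30)
  steps <- matrix(sample(c(-1L, 0L, 1L), 40, replace = TRUE), 20, 2)
  path <- apply(rbind(c(50L, 50L), steps), 2L, cumsum)
  path <- path[!duplicated(path), ]
  sp <- c(0.3, 0.7)
  expect_equal(pathLengthEuclidean(path, sp),
               pathLengthEuclidean(path[nrow(path):1, ], sp))
  k <- 8L
  expect_equal(pathLengthEuclidean(path[1:k, ], sp) +
                 pathLengthEuclidean(path[k:nrow(path), ], sp),
               pathLengthEuclidean(path, sp))
})

test_that("cell metrics summarize trace lengths", {
  mk <- function(len) {
    tr <- new("FilopodiumTrace",
              path = cbind(1:2, 1:2), spacing = c(1, 1),
              lengthUm = len, tip = c(1L, 1L), cellId = "c")
    tr
  }
  m <- cellMetrics(lapply(c(10, 20, 30), mk))
  expect_equal(m$count, 3L)
  expect_equal(m$meanLengthUm, 20)
  expect_equal(m$cumLengthUm, 60)
  expect_true(m$hasFilopodia)
  m0 <- cellMetrics(list())
  expect_equal(unlist(m0[1, 1:3]), c(count = 0, meanLengthUm = 0,
                                     cumLengthUm = 0))
  expect_false(m0$hasFilopodia)
  ## cumulative equals an independent summation on many traces
  set.seed(31)
  lens <- runif(1000, 0.5, 30)
  mm <- cellMetrics(lapply(lens, mk))
  expect_equal(mm$cumLengthUm, sum(lens), tolerance = 1e-9)
})

test_that("roundness measures the principal-axis ratio", {
  expect_equal(roundness(discMask(101, 40)), 1, tolerance = 0.02)
  expect_equal(roundness(ellipseMask(101, 40, 20)), 0.5, tolerance = 0.02)
  rect <- matrix(FALSE, 60, 60); rect[11:50, 11:20] <- TRUE
  expect_equal(roundness(BinaryMask(rect)), 0.25, tolerance = 0.02)
  ## rotation by 90 degrees and uniform scaling are invariant
  ell <- ellipseMask(101, 40, 20)
  expect_equal(roundness(BinaryMask(t(imgValues(ell)))), roundness(ell),
               tolerance = 1e-9)
  expect_equal(roundness(BinaryMask(imgValues(ell), spacing = 0.25)),
               roundness(ell), tolerance = 1e-9)
  expect_error(roundness(BinaryMask(matrix(FALSE, 5, 5))), "empty")
})

test_that("screen hit calling applies the inclusive two-sided rule", {
  rec <- data.frame(gene = c("ror2", "x"),
                    rel_number = c(1.20, 1.19),
                    rel_length = c(1.47, 2.0))
  res <- screenHits(rec, thresholds = c(1.20, 1.25))
  expect_identical(res$hits$gene, "ror2")    # 1.20 >= 1.20 inclusive
  expect_false("x" %in% res$hits$gene)       # fails one criterion
  expect_error(screenHits(rec[0, ]), "empty")
})

test_that("percentile thresholds match the sort-and-interpolate oracle", {
  set.seed(32)
  tab <- data.frame(gene = sprintf("g%03d", 1:100),
                    rel_number = rlnorm(100, 0, 0.2),
                    rel_length = rlnorm(100, 0, 0.2))
  res <- screenHits(tab, percentile = 85)
  ## type-7 interpolation oracle
  q7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(unname(res$thresholds["number"]), q7(tab$rel_number, 0.85),
               tolerance = 1e-12)
  expect_equal(unname(res$thresholds["length"]), q7(tab$rel_length, 0.85),
               tolerance = 1e-12)
  expTrue <- tab$rel_number >= res$thresholds["number"] &
    tab$rel_length >= res$thresholds["length"]
  expect_identical(res$hits$gene, tab$gene[expTrue])
  ## percentile extremes
  expect_equal(nrow(screenHits(tab, percentile = 0)$hits), 100L)
  top <- screenHits(tab, percentile = 100)$hits
  expect_lte(nrow(top), 1L)
})

test_that("planted screen hits are recalled perfectly", {
  res <- makeScreenTable(nGenes = 120, nHits = 6, hitMargin = 0.2,
                         seed = 9)
  called <- screenHits(res$records, percentile = 85)
  expect_true(all(res$records$gene[res$truth] %in% called$hits$gene))
  ## without planted hits and a stringent percentile, at most one call
  res0 <- makeScreenTable(nGenes = 100, nHits = 0, seed = 10)
  called0 <- screenHits(res0$records, percentile = 99)
  expect_lte(nrow(called0$hits), 1L)
})
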