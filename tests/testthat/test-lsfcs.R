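## short synthetic records keep these unit tests fast; the acceptance
## suite exercises the full 390 s protocol

shortSpec <- function(kind = "spot1", seed = 1L, durationS = 40, ...) {
  fcsSimSpec(fcsSpeciesTable(kind), seed = seed, durationS = durationS,
             ...)
}

test_that("membrane trace extraction integrates the membrane window", {
  ## static flat-topped membrane: 100 counts on pixels 47..53
  img <- matrix(0, 200, 100)
  img[, 47:53] <- 100
  rec <- lineScanRecord(img)
  tr <- extractMembraneTrace(rec, window = 3L)
  expect_true(all(imgValues(tr) == 700))
  ## blank image: extraction error
  expect_error(extractMembraneTrace(lineScanRecord(matrix(0, 100, 100))),
               "detectable")
})

test_that("membrane fluctuation compensation tracks a drifting membrane", {
  spec <- shortSpec(seed = 2L, membraneDriftPx = 10,
                    backgroundPerPixel = 0)
  sim <- simulateLsfcs(spec, shotNoise = FALSE)
  tr <- imgValues(extractMembraneTrace(sim$red))
  ## expected windowed signal from the per-line rate: drift must not
  ## modulate the integrated intensity beyond 1%
  rate <- rowSums(sim$red@image)
  ratio <- tr / rate
  expect_lt((max(ratio) - min(ratio)) / mean(ratio), 0.01)
})

test_that("the multi-tau correlator equals the direct-sum oracle", {
  set.seed(60)
  n <- 4096
  x <- rpois(n, 50) + rep(c(0, 6), each = 8)[1 + (seq_len(n) %% 16)]
  y <- rpois(n, 40) + x * 0.1
  a <- intensityTrace(x, 0.01); b <- intensityTrace(y, 0.01)
  cc <- correlate(a, b, nSegments = 0)
  sched <- CytoQuant:::.multiTauSchedule(n)
  expect_equal(cc@G, oracleCorrelate(x, y, sched), tolerance = 1e-10)
  ## two identical traces: cross-correlation equals the autocorrelation
  auto <- correlate(a, nSegments = 0)
  cross <- correlate(a, intensityTrace(x, 0.01), nSegments = 0)
  expect_equal(cross@G, auto@G, tolerance = 1e-12)
  ## smallest lag of a two-level synthetic signal reflects its variance
  expect_gt(auto@G[1], 0)
  ## constant trace: undefined
  expect_error(correlate(intensityTrace(rep(5, 1000), 0.01)),
               "zero variance")
})

test_that("white-noise traces decorrelate at all positive lags", {
  set.seed(61)
  x <- intensityTrace(rpois(20000, 100), 0.002)
  cc <- correlate(x, nSegments = 0)
  nOv <- 20000 - 1
  expect_true(all(abs(cc@G) < 3 / sqrt(nOv) * 1.5 + 3e-4))
})

test_that("the diffusion model fit is self-consistent", {
  G0 <- 0.05; tD <- 0.04; S <- 5
  lag <- exp(seq(log(2e-3), log(10), length.out = 40))
  G <- G0 / sqrt((1 + lag / tD) * (1 + lag / (S^2 * tD)))
  cv <- new("CorrelationCurve", lag = lag, G = G,
            se = rep(NA_real_, 40), pair = "RR")
  for (off in c(TRUE, FALSE)) {
    f <- fitMembraneDiffusion(cv, w0 = 0.25, S = S, offset = off)
    expect_equal(f@G0, G0, tolerance = 1e-6)
    expect_equal(f@tauD, tD, tolerance = 1e-6)
    expect_equal(f@D, 0.25^2 / (4 * tD), tolerance = 1e-6)
    expect_equal(f@C, 1 / (G0 * pi * 0.25^2 * S), tolerance = 1e-6)
  }
  ## noisy replicates: small bias in D
  set.seed(62)
  Ds <- replicate(20, {
    Gn <- G * (1 + rnorm(40, 0, 0.03))
    cvn <- new("CorrelationCurve", lag = lag, G = Gn,
               se = rep(NA_real_, 40), pair = "RR")
    fitMembraneDiffusion(cvn, w0 = 0.25, S = S)@D
  })
  expect_lt(abs(mean(Ds) / (0.25^2 / (4 * tD)) - 1), 0.05)
})

test_that("correlation amplitude scales inversely with surface density", {
  Aeff <- pi * 0.25^2 * 5
  for (dens in c(10, 37, 100)) {
    sp <- fcsSpeciesTable("spot1")
    sp$density <- dens
    spec <- fcsSimSpec(sp, seed = 70L + dens, durationS = 60)
    sim <- simulateLsfcs(spec)
    f <- fitMembraneDiffusion(correlate(extractMembraneTrace(sim$red)))
    expect_lt(abs(f@G0 * dens * Aeff - 1), 0.25)
  }
})

test_that("slower species yield longer diffusion times in every replicate", {
  for (s in 1:3) {
    fastSim <- simulateLsfcs(shortSpec("spot1", seed = 80L + s,
                                       durationS = 60))
    slowSim <- simulateLsfcs(shortSpec("spot2-bound", seed = 90L + s,
                                       durationS = 60))
    fFast <- fitMembraneDiffusion(
      correlate(extractMembraneTrace(fastSim$red)))
    fSlow <- fitMembraneDiffusion(
      correlate(extractMembraneTrace(slowSim$red)))
    expect_gt(fSlow@tauD, fFast@tauD)
  }
})

test_that("cross-correlation amplitude reports the bound fraction", {
  ## fully dual-labelled: fraction ~ 1
  sim <- simulateLsfcs(shortSpec("spot2-bound", seed = 100L,
                                 durationS = 60))
  tg <- extractMembraneTrace(sim$green)
  tr <- extractMembraneTrace(sim$red)
  gg <- correlate(tg); rr <- correlate(tr); gr <- correlate(tg, tr)
  expect_gt(crossCorrelationFraction(gg, rr, gr), 0.8)
  ## independent species: fraction ~ 0
  spInd <- data.frame(D = c(0.28, 0.28), density = c(30, 30),
                      brightGreen = c(20, 0), brightRed = c(0, 20))
  f0 <- vapply(101:103, function(s) {
    sim0 <- simulateLsfcs(fcsSimSpec(spInd, seed = s, durationS = 60))
    tg0 <- extractMembraneTrace(sim0$green)
    tr0 <- extractMembraneTrace(sim0$red)
    crossCorrelationFraction(correlate(tg0), correlate(tr0),
                             correlate(tg0, tr0))
  }, 0)
  expect_lt(mean(f0), 0.15)
  ## half-bound mixture: fraction near 0.5
  spMix <- data.frame(D = c(0.28, 0.28, 0.28),
                      density = c(15, 15, 15),
                      brightGreen = c(20, 0, 20),
                      brightRed = c(0, 20, 20))
  fr <- vapply(1:3, function(s) {
    simM <- simulateLsfcs(fcsSimSpec(spMix, seed = 110L + s,
                                     durationS = 60))
    tgM <- extractMembraneTrace(simM$green)
    trM <- extractMembraneTrace(simM$red)
    crossCorrelationFraction(correlate(tgM), correlate(trM),
                             correlate(tgM, trM))
  }, 0)
  expect_lt(abs(mean(fr) - 0.5), 0.15)
})

test_that("a frozen sample gives a flat correlation function", {
  sp <- data.frame(D = 0, density = 30, brightGreen = 0, brightRed = 20)
  sim <- simulateLsfcs(fcsSimSpec(sp, seed = 120L, durationS = 30))
  tr <- extractMembraneTrace(sim$red)
  cc <- correlate(tr, nSegments = 0)
  ## shot noise only: no decay trend between early and late lags
  early <- mean(cc@G[1:4])
  late <- mean(cc@G[(length(cc@G) - 3):length(cc@G)])
  expect_lt(abs(early - late), 5e-4)
})

test_that("the lsFCS generator is deterministic and validates input", {
  a <- simulateLsfcs(shortSpec(seed = 130L, durationS = 10))
  b <- simulateLsfcs(shortSpec(seed = 130L, durationS = 10))
  expect_identical(a$red@image, b$red@image)
  expect_identical(a$green@image, b$green@image)
  bad <- fcsSpeciesTable("spot1"); bad$density <- 0
  expect_error(fcsSimSpec(bad), "positive density")
})
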