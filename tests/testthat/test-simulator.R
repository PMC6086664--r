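test_that("the hexagonal lattice matches the closed-form packing count", {
  cfg <- simConfig(domainWidth = 100, domainHeight = 100,
                   initialBandUm = 30)
  lat <- buildLattice(cfg)
  r <- 8
  nRows <- floor((100 - 2 * r) / (r * sqrt(3))) + 1
  perEven <- floor((100 - 2 * r) / (2 * r)) + 1
  perOdd <- floor((100 - 3 * r) / (2 * r)) + 1
  nEven <- ceiling(nRows / 2); nOdd <- nRows - nEven
  expect_equal(nrow(lat@pos), nEven * perEven + nOdd * perOdd)
  ## occupied centres at least one diameter apart
  occ <- lat@pos[lat@role != 0L, ]
  expect_gte(min(dist(occ)), 16 - 1e-9)
  ## producers on the margin row only
  expect_true(all(lat@marginDist[lat@role == 1L] == 0))
  expect_true(all(lat@marginDist[lat@role == 2L] > 0))
  expect_error(buildLattice(simConfig(domainWidth = 10,
                                      domainHeight = 10)), "smaller")
})

test_that("signaling deposit frequency matches the geometric band oracle", {
  cfg <- tinySimConfig(lFiloMean = 20, lFiloSd = 5, seed = NA)
  lat <- buildLattice(cfg)
  prod <- which(lat@role == 1L)
  origin <- lat@pos[prod[4], ]
  receivers <- lat@pos[lat@role == 2L, , drop = FALSE]
  pHit <- oracleBandHitProb(origin, receivers, 8, 2, 20, 5)
  set.seed(33)
  n <- 4000
  hits <- 0L
  for (i in seq_len(n)) {
    ev <- attemptSignaling(lat, prod[4], cfg)$event
    if (ev$outcome == "deposited") hits <- hits + 1L
  }
  se <- sqrt(pHit * (1 - pHit) / n)
  expect_lt(abs(hits / n - pHit), 3 * se + 1e-3)
})

test_that("deposition obeys the +/-2 um surface band", {
  cfg <- tinySimConfig(seed = NA)
  lat <- buildLattice(cfg)
  prod <- which(lat@role == 1L)[4]
  set.seed(34)
  for (i in 1:300) {
    ev <- attemptSignaling(lat, prod, cfg)$event
    rec <- lat@pos[lat@role == 2L, , drop = FALSE]
    d <- sqrt((rec[, 1] - ev$tip[1])^2 + (rec[, 2] - ev$tip[2])^2)
    inBand <- abs(min(d) - 8) <= 2
    expect_equal(ev$outcome == "deposited", inBand)
    ## tip geometry: origin + length * direction
    expect_equal(unname(sqrt(sum((ev$tip - lat@pos[prod, ])^2))),
                 ev$length, tolerance = 1e-9)
  }
})

test_that("insertion grows the tissue and the morphogen ledger accounts for it", {
  cfg <- tinySimConfig(seed = NA)
  lat <- buildLattice(cfg)
  lat@wnt[lat@role == 2L] <- seq_len(sum(lat@role == 2L))
  recBefore <- sum(lat@role == 2L)
  totBefore <- sum(lat@wnt)
  set.seed(35)
  t2 <- insertCell(lat, which(lat@role == 2L)[5], cfg)
  expect_equal(sum(t2@role == 2L), recBefore + 1L)
  expect_equal(sum(t2@wnt) - totBefore, t2@insertGain - lat@insertGain)
  ## full lattice: skipped with a message
  cfgFull <- tinySimConfig(initialBandUm = 1000, seed = NA)
  full <- buildLattice(cfgFull)
  expect_true(all(full@role != 0L))
  expect_message(t3 <- insertCell(full, which(full@role == 2L)[1],
                                  cfgFull), "skipped")
  expect_identical(t3@role, full@role)
})

test_that("migration swaps a uniformly chosen receiving neighbour", {
  cfg <- tinySimConfig(initialBandUm = 100, seed = NA)
  lat <- buildLattice(cfg)
  lat@wnt[lat@role == 2L] <- seq_len(sum(lat@role == 2L)) * 1.0
  ## interior receiver with 6 receiver neighbours
  cand <- which(lat@role == 2L &
                  vapply(seq_len(nrow(lat@pos)), function(i) {
                    nb <- lat@neighbors[i, ]; nb <- nb[nb != 0]
                    length(nb) == 6 && all(lat@role[nb] == 2L)
                  }, TRUE))
  i <- cand[1]
  ## involution: the same RNG choice twice restores the state
  set.seed(36)
  t1 <- migrateCell(lat, i, cfg)
  set.seed(36)
  t2 <- migrateCell(t1, i, cfg)
  expect_identical(t2@wnt, lat@wnt)
  expect_equal(sum(t1@wnt), sum(lat@wnt))
  ## neighbour frequencies are uniform (multinomial, 3 SE)
  nb <- lat@neighbors[i, ]; nb <- nb[nb != 0]
  set.seed(37)
  ndraw <- 2400
  countsN <- setNames(integer(6), as.character(nb))
  for (k in seq_len(ndraw)) {
    tk <- migrateCell(lat, i, cfg)
    j <- which(tk@wnt != lat@wnt)
    j <- j[j != i]
    countsN[as.character(j)] <- countsN[as.character(j)] + 1L
  }
  expected <- ndraw / 6
  se <- sqrt(ndraw * (1 / 6) * (5 / 6))
  expect_true(all(abs(countsN - expected) <= 3 * se))
})

test_that("decay floors at zero and empties in ceiling(W/amount) events", {
  cfg <- tinySimConfig(seed = NA)
  lat <- buildLattice(cfg)
  i <- which(lat@role == 2L)[1]
  lat@wnt[i] <- 5
  t1 <- decayWnt(lat, i, cfg)
  expect_equal(t1@wnt[i], 4)
  expect_equal(t1@decays - lat@decays, 1)
  t0 <- lat; t0@wnt[i] <- 0
  expect_equal(decayWnt(t0, i, cfg)@wnt[i], 0)
  expect_equal(decayWnt(t0, i, cfg)@decays, t0@decays)
  tt <- lat
  k <- 0L
  while (tt@wnt[i] > 0) { tt <- decayWnt(tt, i, cfg); k <- k + 1L }
  expect_equal(k, 5L)
})

test_that("a zero-probability step leaves the state unchanged", {
  cfg <- tinySimConfig(pFilo = 0, pInsert = 0, pMigrate = 0, pDecay = 0,
                       seed = NA)
  lat <- buildLattice(cfg)
  t1 <- simStep(lat, cfg)
  expect_identical(t1@wnt, lat@wnt)
  expect_identical(t1@role, lat@role)
  expect_equal(t1@stepCount, lat@stepCount + 1L)
})

test_that("compiled event loop reproduces the R reference bit for bit", {
  cfg <- tinySimConfig(durationMin = 1, seed = 41L)
  lat <- buildLattice(cfg)
  set.seed(41)
  tR <- lat
  suppressMessages(for (s in 1:60) tR <- simStep(tR, cfg))
  resC <- runSimulation(cfg, tissue = lat)
  expect_identical(tR@role, resC$tissue@role)
  expect_identical(tR@wnt, resC$tissue@wnt)
  expect_identical(c(tR@deposits, tR@insertGain, tR@decays),
                   c(resC$tissue@deposits, resC$tissue@insertGain,
                     resC$tissue@decays))
})

test_that("the morphogen ledger balances exactly at every step", {
  cfg <- tinySimConfig(durationMin = 3, seed = 42L)
  res <- runSimulation(cfg, keepLedger = TRUE)
  with(res$ledger, expect_equal(deposits + insertGain - decays,
                                receiverTotal, tolerance = 0))
})

test_that("expected morphogen input is monotone in the cytoneme frequency", {
  totals <- sapply(c(0.05, 0.15, 0.45), function(p) {
    mean(vapply(1:6, function(s)
      runSimulation(tinySimConfig(pFilo = p, durationMin = 2,
                                  seed = 100L + s))$totalWnt, 0))
  })
  expect_true(all(diff(totals) > 0))
})

test_that("without decay and growth the input scales linearly in pFilo", {
  base <- function(p, s)
    runSimulation(simConfig(domainWidth = 150, domainHeight = 150,
                            durationMin = 3, pFilo = p, pInsert = 0,
                            pMigrate = 0, pDecay = 0, initialBandUm = 60,
                            seed = s))$totalWnt
  seeds <- 200L + 1:10
  t1 <- vapply(seeds, function(s) base(0.1, s), 0)
  t2 <- vapply(seeds, function(s) base(0.2, s), 0)
  ratio <- mean(t2) / mean(t1)
  se <- ratio * sqrt(stats::var(t1) / (10 * mean(t1)^2) +
                       stats::var(t2) / (10 * mean(t2)^2))
  expect_lt(abs(ratio - 2), 3 * se + 0.05)
})

test_that("the morphogen profile is graded away from the source", {
  ## full study protocol, wild type, pooled over 10 seeds; bins aligned
  ## to four lattice rows. Adjacent bin pairs must be non-increasing in
  ## at least 95% of cases, up to Monte-Carlo noise in the almost-empty
  ## far tail (0.02 units vs a peak around 14).
  rowBin <- 4 * 8 * sqrt(3) / 2
  pool <- do.call(rbind, lapply(1:10, function(s) {
    res <- runSimulation(simPreset("wt", seed = 800L + s))
    tis <- res$tissue
    rec <- tis@role == 2L
    data.frame(bin = floor(tis@marginDist[rec] / rowBin),
               w = tis@wnt[rec])
  }))
  m <- tapply(pool$w, pool$bin, mean)
  expect_gt(max(m), 5)
  expect_gte(mean(diff(m) <= 0.02), 0.95)
})

test_that("runs are deterministic under a fixed seed", {
  cfg <- tinySimConfig(durationMin = 2, seed = 77L)
  a <- runSimulation(cfg, keepLedger = TRUE)
  b <- runSimulation(cfg, keepLedger = TRUE)
  expect_identical(a$tissue@wnt, b$tissue@wnt)
  expect_identical(a$ledger, b$ledger)
})

test_that("conditionRatio is exact for identical configs and errors on zero input", {
  cfg <- tinySimConfig(durationMin = 1)
  set.seed(50)
  res <- conditionRatio(cfg, cfg, nReps = 3, bootstrap = 19)
  expect_equal(res$ratioPct, 100, tolerance = 1e-12)
  z <- tinySimConfig(durationMin = 1, pFilo = 0)
  set.seed(51)
  expect_error(conditionRatio(cfg, z, nReps = 2, bootstrap = 19), "zero")
})

test_that("packaged presets encode the reference signaling probabilities", {
  expect_equal(simPreset("wt")@pFilo, 1 / 30, tolerance = 1e-12)
  expect_equal(simPreset("ror2")@pFilo, 0.0537)
  expect_equal(simPreset("ror2_3i")@pFilo, 0.0113)
})
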