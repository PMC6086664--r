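#' @include AllClasses.R
NULL

## angle distribution encoding shared with the C++ event loop
.angleDistCode <- function(cfg) {
  match(cfg@angleDist, c("uniform-halfplane", "von-mises")) - 1L
}

.simPar <- function(cfg) {
  list(pFilo = cfg@pFilo, pInsert = cfg@pInsert, pMigrate = cfg@pMigrate,
       pDecay = cfg@pDecay, lFiloMean = cfg@lFiloMean,
       lFiloSd = cfg@lFiloSd, cellRadius = cfg@cellRadius,
       tipTol = cfg@tipTol, reseedTol = cfg@reseedTol,
       depositAmount = cfg@depositAmount, decayAmount = cfg@decayAmount,
       angleKappa = cfg@angleKappa, angleDist = .angleDistCode(cfg))
}

#' Build the fixed hexagonal cell lattice
#'
#' Precomputes the candidate cell positions (hexagonal close packing with
#' centre spacing twice the cell radius, non-periodic, fully inside the
#' domain), places one row of producer cells along the bottom margin,
#' fills an initial band of receiving cells above it and leaves the
#' remaining positions empty for growth.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{Tissue}.
#' @export
buildLattice <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  r <- cfg@cellRadius
  W <- cfg@domainWidth; H <- cfg@domainHeight
  if (W < 2 * r || H < 2 * r)
    stop("domain smaller than one cell")
  rowSpacing <- r * sqrt(3)
  nRows <- floor((H - 2 * r) / rowSpacing) + 1
  xs <- ys <- rowIdx <- list()
  for (k in seq_len(nRows) - 1) {
    off <- if (k %% 2 == 0) r else 2 * r
    x <- seq(off, W - r, by = 2 * r)
    xs[[k + 1]] <- x
    ys[[k + 1]] <- rep(r + k * rowSpacing, length(x))
    rowIdx[[k + 1]] <- rep(k, length(x))
  }
  pos <- cbind(x = unlist(xs), y = unlist(ys))
  rowIdx <- unlist(rowIdx)
  n <- nrow(pos)
  marginDist <- pos[, 2] - r
  ## neighbours: same row (adjacent columns) or adjacent rows, centre
  ## distance within one diameter (+ tolerance)
  nb <- matrix(0L, n, 6L)
  cnt <- integer(n)
  tol2 <- (2 * r * 1.001)^2
  byRow <- split(seq_len(n), rowIdx)
  for (k in seq_along(byRow)) {
    for (m in k:min(k + 1, length(byRow))) {
      ii <- byRow[[k]]; jj <- byRow[[m]]
      dx <- outer(pos[ii, 1], pos[jj, 1], `-`)
      dy <- outer(pos[ii, 2], pos[jj, 2], `-`)
      hit <- which(dx^2 + dy^2 <= tol2 &
                     (dx^2 + dy^2) > 1e-9, arr.ind = TRUE)
      for (h in seq_len(nrow(hit))) {
        a <- ii[hit[h, 1]]; b <- jj[hit[h, 2]]
        if (m == k && a >= b) next            # each same-row pair once
        cnt[a] <- cnt[a] + 1L; nb[a, cnt[a]] <- b
        cnt[b] <- cnt[b] + 1L; nb[b, cnt[b]] <- a
      }
    }
  }
  role <- integer(n)
  role[rowIdx == 0] <- 1L                     # marginal producers
  role[rowIdx > 0 & marginDist <= cfg@initialBandUm] <- 2L
  new("Tissue", pos = pos, marginDist = marginDist, role = role,
      wnt = numeric(n), neighbors = nb, stepCount = 0L,
      deposits = 0, insertGain = 0, decays = 0, config = cfg)
}

## ---------------------------------------------------------------------------
## Reference (R) implementations of the single Monte-Carlo events. These
## consume the global RNG in exactly the order documented in the C++ event
## loop, so simStep() iterated in R reproduces runSimulation() bit for bit.
## ---------------------------------------------------------------------------

.drawAngle <- function(cfg) {
  if (.angleDistCode(cfg) == 0L) return(pi * stats::runif(1))
  kappa <- cfg@angleKappa
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  repeat {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0) break
    if (log(cc / u2) + 1 - cc >= 0) break
  }
  u3 <- stats::runif(1)
  pi / 2 + (if (u3 - 0.5 >= 0) 1 else -1) * acos(f)
}

.drawLength <- function(cfg) {
  repeat {
    L <- cfg@lFiloMean + cfg@lFiloSd * stats::rnorm(1)
    if (L > 0) return(L)
  }
}

.pickIndex <- function(n) min(floor(stats::runif(1) * n) + 1L, n)

#' Single cytoneme signaling event
#'
#' Forms one virtual filopodium from a producer cell: the angle is drawn
#' from the configured distribution (directed into the receiving tissue),
#' the length from a Gaussian truncated at zero. If the filopodium tip
#' lands within \code{tipTol} of the surface of the nearest receiving
#' cell, that cell's morphogen content is increased by
#' \code{depositAmount}; otherwise the filopodium is deleted and nothing
#' changes.
#'
#' @param tissue a \linkS4class{Tissue}.
#' @param cell index of a producer cell.
#' @param cfg the simulation config (defaults to the tissue's).
#' @return list with the updated \code{tissue} and an \code{event} record
#'   (origin, angle, length, tip, outcome, target).
#' @export
attemptSignaling <- function(tissue, cell, cfg = tissue@config) {
  if (tissue@role[cell] != 1L) stop("'cell' is not a producer")
  th <- .drawAngle(cfg)
  L <- .drawLength(cfg)
  tip <- tissue@pos[cell, ] + L * c(cos(th), sin(th))
  rec <- which(tissue@role == 2L)
  outcome <- "deleted"; target <- NA_integer_
  if (length(rec)) {
    d2 <- (tissue@pos[rec, 1] - tip[1])^2 +
      (tissue@pos[rec, 2] - tip[2])^2
    j <- rec[which.min(d2)]
    if (abs(sqrt(min(d2)) - cfg@cellRadius) <= cfg@tipTol) {
      tissue@wnt[j] <- tissue@wnt[j] + cfg@depositAmount
      tissue@deposits <- tissue@deposits + cfg@depositAmount
      outcome <- "deposited"; target <- j
    }
  }
  list(tissue = tissue,
       event = list(origin = cell, angle = th, length = L, tip = tip,
                    outcome = outcome, target = target))
}

#' Cell insertion (division / intercalation) event
#'
#' Finds the empty lattice position nearest to the inserting cell, moves
#' the intervening cells one position outward along a lattice path towards
#' it (producers are never moved), and fills the vacated position with a
#' duplicate (morphogen content copied) of a uniformly chosen receiving
#' cell whose margin distance is within \code{reseedTol} of the vacated
#' position's. Skipped (with a message) when the lattice is full.
#'
#' @inheritParams attemptSignaling
#' @return the updated \linkS4class{Tissue} (an \code{insertGain}
#'   attribute on the call is tracked in the tissue ledger).
#' @export
insertCell <- function(tissue, cell, cfg = tissue@config) {
  if (tissue@role[cell] != 2L) stop("'cell' is not a receiver")
  empty <- which(tissue@role == 0L)
  if (!length(empty)) {
    message("insertion skipped: lattice is full")
    return(tissue)
  }
  d2 <- (tissue@pos[empty, 1] - tissue@pos[cell, 1])^2 +
    (tissue@pos[empty, 2] - tissue@pos[cell, 2])^2
  e <- empty[which.min(d2)]
  ## greedy lattice path cell -> e, never stepping on a producer
  path <- cell
  cur <- cell
  ok <- TRUE
  while (cur != e) {
    nbs <- tissue@neighbors[cur, ]
    nbs <- nbs[nbs != 0L]
    nbs <- nbs[tissue@role[nbs] != 1L]
    if (!length(nbs)) { ok <- FALSE; break }
    dcur <- sum((tissue@pos[cur, ] - tissue@pos[e, ])^2)
    dn <- (tissue@pos[nbs, 1] - tissue@pos[e, 1])^2 +
      (tissue@pos[nbs, 2] - tissue@pos[e, 2])^2
    j <- which(dn < dcur)
    if (!length(j) || length(path) > nrow(tissue@pos)) { ok <- FALSE; break }
    nxt <- nbs[which.min(dn)]
    path <- c(path, nxt)
    cur <- nxt
  }
  if (!ok) {
    message("insertion skipped: no lattice path to an empty position")
    return(tissue)
  }
  for (j in rev(seq_along(path))[-length(path)]) {
    tissue@role[path[j]] <- tissue@role[path[j - 1]]
    tissue@wnt[path[j]] <- tissue@wnt[path[j - 1]]
  }
  p0 <- path[1]
  tissue@role[p0] <- 0L; tissue@wnt[p0] <- 0
  m0 <- tissue@marginDist[p0]
  cand <- which(tissue@role == 2L &
                  abs(tissue@marginDist - m0) <= cfg@reseedTol)
  newWnt <- if (length(cand)) tissue@wnt[cand[.pickIndex(length(cand))]]
            else 0
  tissue@role[p0] <- 2L
  tissue@wnt[p0] <- newWnt
  tissue@insertGain <- tissue@insertGain + newWnt
  tissue
}

#' Cell migration (nearest-neighbour swap) event
#'
#' The cell swaps contents (morphogen and role) with a uniformly chosen
#' occupied receiving neighbour; a cell without such a neighbour stays
#' put. Occupancy and total morphogen are unchanged.
#'
#' @inheritParams attemptSignaling
#' @return the updated \linkS4class{Tissue}.
#' @export
migrateCell <- function(tissue, cell, cfg = tissue@config) {
  nbs <- tissue@neighbors[cell, ]
  nbs <- nbs[nbs != 0L]
  nbs <- nbs[tissue@role[nbs] == 2L]
  if (!length(nbs)) return(tissue)
  j <- nbs[.pickIndex(length(nbs))]
  tmp <- tissue@wnt[cell]
  tissue@wnt[cell] <- tissue@wnt[j]
  tissue@wnt[j] <- tmp
  tissue
}

#' Morphogen decay event
#'
#' Decreases the cell's morphogen content by \code{decayAmount}, floored
#' at zero; the effective decrement is added to the decay ledger.
#'
#' @inheritParams attemptSignaling
#' @return the updated \linkS4class{Tissue}.
#' @export
decayWnt <- function(tissue, cell, cfg = tissue@config) {
  dec <- min(tissue@wnt[cell], cfg@decayAmount)
  tissue@wnt[cell] <- tissue@wnt[cell] - dec
  tissue@decays <- tissue@decays + dec
  tissue
}

#' One simulation step (reference implementation)
#'
#' Visits every lattice position in index order. Producers attempt a
#' signaling event with probability \code{pFilo}; receivers independently
#' attempt insertion (\code{pInsert}), migration (\code{pMigrate}) and
#' decay (\code{pDecay}). This R implementation consumes the RNG exactly
#' as the compiled event loop in \code{\link{runSimulation}} and is meant
#' for small tissues and testing.
#'
#' @param tissue a \linkS4class{Tissue}.
#' @param cfg the simulation config (defaults to the tissue's).
#' @return the updated \linkS4class{Tissue} with its step counter
#'   incremented.
#' @export
simStep <- function(tissue, cfg = tissue@config) {
  n <- nrow(tissue@pos)
  for (i in seq_len(n)) {
    ri <- tissue@role[i]
    if (ri == 0L) next
    if (ri == 1L) {
      if (stats::runif(1) < cfg@pFilo)
        tissue <- attemptSignaling(tissue, i, cfg)$tissue
    } else {
      if (stats::runif(1) < cfg@pInsert)
        tissue <- insertCell(tissue, i, cfg)
      if (stats::runif(1) < cfg@pMigrate)
        tissue <- migrateCell(tissue, i, cfg)
      if (stats::runif(1) < cfg@pDecay)
        tissue <- decayWnt(tissue, i, cfg)
    }
  }
  tissue@stepCount <- tissue@stepCount + 1L
  tissue
}

#' Morphogen gradient profile
#'
#' Mean morphogen content of the receiving cells binned by distance from
#' the producer margin.
#'
#' @param tissue a \linkS4class{Tissue}.
#' @param binWidth bin width, micrometres.
#' @return data.frame with columns \code{binCenter}, \code{meanWnt},
#'   \code{nCells}.
#' @export
gradientProfile <- function(tissue, binWidth = 25) {
  rec <- tissue@role == 2L
  if (!any(rec))
    return(data.frame(binCenter = numeric(), meanWnt = numeric(),
                      nCells = integer()))
  d <- tissue@marginDist[rec]
  w <- tissue@wnt[rec]
  bin <- floor(d / binWidth)
  agg <- tapply(w, bin, mean)
  cnt <- tapply(w, bin, length)
  data.frame(binCenter = (as.numeric(names(agg)) + 0.5) * binWidth,
             meanWnt = as.numeric(agg),
             nCells = as.integer(cnt))
}

#' Run a cytoneme transport simulation
#'
#' Executes \code{durationMin * 60 / dt} Monte-Carlo steps with the
#' compiled event loop (bit-identical to iterating \code{\link{simStep}}),
#' starting from a freshly built lattice (or a supplied initial tissue).
#' If the config carries a seed, the RNG is seeded first; runs are fully
#' deterministic given config and seed.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param tissue optional initial \linkS4class{Tissue} (built from
#'   \code{cfg} when missing).
#' @param keepLedger record the per-step morphogen ledger (deposits,
#'   insertion gains, decays, receiver total).
#' @return list with \code{tissue} (final state), \code{profile}
#'   (\code{\link{gradientProfile}}), \code{ledger} (per-step data.frame,
#'   NULL unless \code{keepLedger}), \code{counts} (event tallies) and
#'   \code{totalWnt} (final receiver-tissue morphogen).
#' @export
runSimulation <- function(cfg, tissue = NULL, keepLedger = FALSE) {
  stopifnot(is(cfg, "SimConfig"))
  if (is.null(tissue)) tissue <- buildLattice(cfg)
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  nsteps <- as.integer(round(cfg@durationMin * 60 / cfg@dt))
  res <- .cq_sim_run(tissue@pos, tissue@marginDist, tissue@role,
                     tissue@wnt, tissue@neighbors, nsteps, .simPar(cfg),
                     keepLedger)
  out <- tissue
  out@role <- res$role
  out@wnt <- res$wnt
  out@stepCount <- tissue@stepCount + nsteps
  out@deposits <- tissue@deposits + res$deposits
  out@insertGain <- tissue@insertGain + res$insertGain
  out@decays <- tissue@decays + res$decays
  out@config <- cfg
  validObject(out)
  ledger <- NULL
  if (keepLedger && nsteps > 0) {
    ledger <- data.frame(step = seq_len(nsteps),
                         deposits = res$ledger[, 1],
                         insertGain = res$ledger[, 2],
                         decays = res$ledger[, 3],
                         receiverTotal = res$ledger[, 4])
  }
  list(tissue = out, profile = gradientProfile(out), ledger = ledger,
       counts = res$counts,
       totalWnt = sum(res$wnt[res$role == 2L]))
}

#' Ratio of receiver-tissue morphogen between two conditions
#'
#' Runs paired simulations under two configs (equal geometry, typically
#' differing only in the cytoneme formation probability) with matched
#' seeds, and reports the mean per-pair ratio of total receiver morphogen,
#' as a percentage, with a bootstrap confidence interval.
#'
#' @param cfgA,cfgB \linkS4class{SimConfig}s for numerator and
#'   denominator.
#' @param nReps number of replicate pairs, >= 2.
#' @param seeds optional integer vector of per-pair seeds (drawn from the
#'   current RNG when missing).
#' @param bootstrap number of bootstrap resamples for the interval.
#' @return list with \code{ratioPct}, \code{ci} (2.5/97.5 percentiles),
#'   \code{ratios} (per pair), \code{totalsA}, \code{totalsB}.
#' @export
conditionRatio <- function(cfgA, cfgB, nReps = 20, seeds = NULL,
                           bootstrap = 199) {
  stopifnot(is(cfgA, "SimConfig"), is(cfgB, "SimConfig"), nReps >= 2)
  if (is.null(seeds))
    seeds <- sample.int(.Machine$integer.max - 1L, nReps)
  if (length(seeds) != nReps) stop("need one seed per replicate")
  latA <- buildLattice(cfgA)
  latB <- buildLattice(cfgB)
  totalsA <- totalsB <- numeric(nReps)
  for (i in seq_len(nReps)) {
    ca <- cfgA; ca@seed <- as.integer(seeds[i])
    cb <- cfgB; cb@seed <- as.integer(seeds[i])
    totalsA[i] <- runSimulation(ca, tissue = latA)$totalWnt
    totalsB[i] <- runSimulation(cb, tissue = latB)$totalWnt
  }
  if (any(totalsB == 0))
    stop("zero receiver morphogen in a denominator run")
  ratios <- 100 * totalsA / totalsB
  bs <- vapply(seq_len(bootstrap), function(b) {
    j <- sample.int(nReps, nReps, replace = TRUE)
    mean(ratios[j])
  }, numeric(1))
  list(ratioPct = mean(ratios),
       ci = stats::quantile(bs, c(0.025, 0.975)),
       ratios = ratios, totalsA = totalsA, totalsB = totalsB)
}

#' Packaged simulation presets
#'
#' Three shipped conditions differing in the per-step cytoneme formation
#' probability: wild type (\code{"wt"}, pFilo = 1/30), enhanced receptor
#' activity (\code{"ror2"}, pFilo = 0.0537 = 1.61 x 1/30) and
#' kinase-dead receptor (\code{"ror2_3i"}, pFilo = 0.0113 =
#' 0.338 x 1/30).
#'
#' @param name one of \code{"wt"}, \code{"ror2"}, \code{"ror2_3i"}.
#' @param ... \linkS4class{SimConfig} fields overriding the preset (e.g.
#'   \code{seed}).
#' @return a \linkS4class{SimConfig}.
#' @export
simPreset <- function(name = c("wt", "ror2", "ror2_3i"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "sim-presets", paste0(name, ".yaml"),
                      package = "CytoQuant", mustWork = TRUE)
  readSimConfig(path, ...)
}
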