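## Brute-force reference implementations ("oracles") kept deliberately
## independent of the package's code paths.

## reflected ("symmetric") index, period 2n
oracleReflect <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  if (j >= n) 2L * n - 1L - j + 1L else j + 1L
}

## nested-loop 2D convolution with reflected borders
oracleConv2 <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -kr:kr) for (dc in -kc:kc) {
      rr <- oracleReflect(r + dr, nr)
      cc <- oracleReflect(c + dc, nc)
      acc <- acc + img[rr, cc] * kernel[kr + 1L + dr, kc + 1L + dc]
    }
    out[r, c] <- acc
  }
  out
}

## per-pixel windowed mean/sd threshold (population sd), reflected borders
oracleAdaptiveThreshold <- function(img, radius, k) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- numeric((2 * radius + 1)^2)
    i <- 0L
    for (dr in -radius:radius) for (dc in -radius:radius) {
      i <- i + 1L
      vals[i] <- img[oracleReflect(r + dr, nr), oracleReflect(c + dc, nc)]
    }
    mu <- mean(vals)
    sd_ <- sqrt(mean(vals^2) - mu^2)
    out[r, c] <- img[r, c] > mu + k * sd_
  }
  out
}

## flood-fill component labeling (8-connected), label by first encounter
## in column-major order
oracleLabel2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (idx in which(mask)) {
    if (lab[idx] > 0L) next
    nxt <- nxt + 1L
    queue <- idx
    lab[idx] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

## igraph Dijkstra on the livewire pixel graph: symmetric mean-endpoint
## node costs, 8-connectivity. Returns min distance from start to any
## stop pixel.
oracleLivewireCost <- function(cost, start, stopPix) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      from <- c(from, id(r, c)); to <- c(to, id(rr, cc))
      w <- c(w, 0.5 * (cost[r, c] + cost[rr, cc]) *
               if (dr != 0 && dc != 0) sqrt(2) else 1)
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::E(g)$weight <- w
  d <- igraph::distances(g, v = id(start[1], start[2]),
                         to = vapply(seq_len(nrow(stopPix)), function(i)
                           id(stopPix[i, 1], stopPix[i, 2]), 0L),
                         mode = "out")
  min(d)
}

## direct (O(n * lags)) correlator on the package's multi-tau grid:
## independent pair-averaging and symmetric normalization
oracleCorrelate <- function(x, y, schedule) {
  binMeans <- function(v, bin) {
    m <- length(v) %/% bin
    vapply(seq_len(m), function(i) mean(v[((i - 1) * bin + 1):(i * bin)]),
           0)
  }
  vapply(schedule, function(s) {
    bin <- s[1L]; k <- s[2L]
    xb <- binMeans(x, bin); yb <- binMeans(y, bin)
    n <- length(xb)
    xs <- xb[1:(n - k)]; ys <- yb[(k + 1):n]
    mean(xs * ys) / (mean(xs) * mean(ys)) - 1
  }, 0)
}

## exhaustive enumeration of admissible plane assignments
oracleZAssign <- function(profile, zStart, zEnd, zStep = 1L) {
  M <- nrow(profile); nz <- ncol(profile)
  best <- -Inf; bestZ <- NULL
  rec <- function(i, z, acc, path) {
    if (i == M) {
      if (z == zEnd && acc > best) {
        best <<- acc; bestZ <<- path
      }
      return(invisible(NULL))
    }
    for (zn in max(1L, z - zStep):min(nz, z + zStep))
      rec(i + 1L, zn, acc + profile[i + 1L, zn], c(path, zn))
  }
  rec(1L, zStart, profile[1L, zStart], zStart)
  list(score = best, z = bestZ)
}

## numeric integration of the probability that a cytoneme tip lands in
## the deposition band of some receiver (angle uniform on (0, pi),
## length ~ N(mean, sd) truncated at 0); nearest-centre rule
oracleBandHitProb <- function(origin, receivers, radius, tol, lMean, lSd,
                              nAngle = 400, nLen = 400) {
  th <- (seq_len(nAngle) - 0.5) / nAngle * pi
  qs <- (seq_len(nLen) - 0.5) / nLen
  ## truncated-normal quantiles
  p0 <- stats::pnorm(0, lMean, lSd)
  L <- stats::qnorm(p0 + qs * (1 - p0), lMean, lSd)
  hit <- 0
  for (a in th) {
    tipx <- origin[1] + L * cos(a)
    tipy <- origin[2] + L * sin(a)
    d2 <- outer(tipx, receivers[, 1], `-`)^2 +
      outer(tipy, receivers[, 2], `-`)^2
    nearest <- sqrt(apply(d2, 1L, min))
    hit <- hit + sum(abs(nearest - radius) <= tol)
  }
  hit / (nAngle * nLen)
}
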