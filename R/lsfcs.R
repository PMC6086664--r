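#' @include AllClasses.R
NULL

#' Extract the membrane intensity trace from an x-t pseudo image
#'
#' Per scan line, the membrane crossing is located as the intensity
#' centroid of the pixels reaching at least half of the line maximum
#' (robust to flat-topped and Gaussian profiles); lines without a
#' detectable peak inherit the previous line's centre. The centre
#' trajectory is median-filtered (membrane fluctuation compensation) and
#' the intensity is integrated over a fixed +/- \code{window} pixels
#' around it.
#'
#' @param rec a \linkS4class{LineScanRecord}.
#' @param window half-width of the integration window, pixels.
#' @param medianWindow odd length of the running-median filter applied to
#'   the centre trajectory, lines.
#' @return an \linkS4class{IntensityTrace} sampled at the line period.
#' @export
extractMembraneTrace <- function(rec, window = 5L, medianWindow = 5L) {
  stopifnot(is(rec, "LineScanRecord"))
  img <- rec@image
  n <- nrow(img); npx <- ncol(img)
  pk <- max.col(img, ties.method = "first")
  pkVal <- img[cbind(seq_len(n), pk)]
  mu <- rowMeans(img)
  ## a membrane peak must clearly exceed the mean line level (which is
  ## dominated by background plus the spread-out membrane signal)
  detectable <- pkVal >= pmax(5, 3 * mu + 5)
  if (mean(detectable) <= 0.5)
    stop("membrane not detectable in more than 50% of scan lines")
  W <- img * (img >= 0.5 * pkVal)
  ctr <- as.numeric(W %*% seq_len(npx)) / rowSums(W)
  ctr[!detectable] <- NA
  ## carry the previous centre into undetected lines (and the first
  ## detected centre backwards over any leading gap)
  if (anyNA(ctr)) {
    filled <- !is.na(ctr)
    idx <- cummax(ifelse(filled, seq_len(n), 0L))
    first <- which(filled)[1L]
    idx[idx == 0L] <- first
    ctr <- ctr[idx]
  }
  if (n >= medianWindow && medianWindow >= 3)
    ctr <- stats::runmed(ctr, medianWindow)
  ci <- pmin(pmax(round(ctr), 1L), npx)
  tot <- numeric(n)
  rows <- seq_len(n)
  for (off in -window:window) {
    idx <- pmin(pmax(ci + off, 1L), npx)
    tot <- tot + img[cbind(rows, idx)]
  }
  intensityTrace(tot, dt = rec@linePeriodS)
}

## multi-tau lag schedule: 8 unit lags, then 4 lags per doubling stage
## (5..8 in binned units). Returns a list of (bin, k) pairs.
.multiTauSchedule <- function(n, minTail = 32L) {
  out <- list()
  for (k in 1:8)
    if (n - k >= minTail) out[[length(out) + 1L]] <- c(1L, k)
  bin <- 2L
  while (floor(n / bin) - 8L >= minTail) {
    for (k in 5:8) out[[length(out) + 1L]] <- c(bin, k)
    bin <- bin * 2L
  }
  out
}

.binPairMeans <- function(x) {
  m <- length(x) %/% 2L
  (x[2 * seq_len(m) - 1L] + x[2 * seq_len(m)]) / 2
}

## symmetrically normalized fluctuation correlation of two series at an
## integer lag: <x y_k> / (<x><y_k>) - 1 with the means taken over the
## overlapping segments
.corrAtLag <- function(x, y, k) {
  n <- length(x)
  xs <- x[seq_len(n - k)]
  ys <- y[seq_len(n - k) + k]
  m1 <- mean(xs); m2 <- mean(ys)
  mean(xs * ys) / (m1 * m2) - 1
}

.multiTauCorr <- function(a, b, schedule) {
  G <- numeric(length(schedule))
  curBin <- 1L
  xa <- a; xb <- b
  for (i in seq_along(schedule)) {
    bin <- schedule[[i]][1L]; k <- schedule[[i]][2L]
    while (curBin < bin) {
      xa <- .binPairMeans(xa)
      xb <- .binPairMeans(xb)
      curBin <- curBin * 2L
    }
    G[i] <- .corrAtLag(xa, xb, k)
  }
  G
}

#' Auto- or cross-correlate two intensity traces
#'
#' Computes \eqn{G(\tau) = \langle \delta F_a(t)\, \delta F_b(t+\tau)
#' \rangle / (\langle F_a \rangle \langle F_b \rangle)} on a multi-tau
#' (quasi-logarithmic) lag grid: 8 lags at the raw line period, then 4
#' lags per doubling of the averaging bin, each computed on the
#' pair-averaged series with symmetric normalization over the overlapping
#' segments. Lag zero is excluded. Per-lag standard errors are estimated
#' by splitting the traces into contiguous segments.
#'
#' @param a,b \linkS4class{IntensityTrace}s of equal length and sampling
#'   (\code{b} defaults to \code{a}, giving the autocorrelation).
#' @param pair label for the curve (guessed as "AA" when \code{a} and
#'   \code{b} are identical).
#' @param nSegments number of segments for the error estimate (0
#'   disables).
#' @return a \linkS4class{CorrelationCurve}.
#' @export
correlate <- function(a, b = a, pair = NULL, nSegments = 8L) {
  stopifnot(is(a, "IntensityTrace"), is(b, "IntensityTrace"))
  va <- a@values; vb <- b@values
  if (length(va) != length(vb)) stop("traces must have equal length")
  if (abs(a@dt - b@dt) > 1e-12) stop("traces must share a sampling interval")
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("constant trace: correlation undefined (zero variance)")
  n <- length(va)
  sched <- .multiTauSchedule(n)
  if (!length(sched)) stop("trace too short to correlate")
  G <- .multiTauCorr(va, vb, sched)
  lag <- vapply(sched, function(s) s[1L] * s[2L], numeric(1)) * a@dt
  se <- rep(NA_real_, length(sched))
  if (nSegments >= 2L) {
    segLen <- n %/% nSegments
    if (segLen >= 64L) {
      segG <- matrix(NA_real_, nSegments, length(sched))
      subSched <- .multiTauSchedule(segLen)
      keep <- seq_len(min(length(subSched), length(sched)))
      for (s in seq_len(nSegments)) {
        ii <- seq_len(segLen) + (s - 1L) * segLen
        if (stats::var(va[ii]) > 0 && stats::var(vb[ii]) > 0)
          segG[s, keep] <- .multiTauCorr(va[ii], vb[ii],
                                         sched[keep])
      }
      ok <- colSums(!is.na(segG)) >= 2L
      se[ok] <- apply(segG[, ok, drop = FALSE], 2L, stats::sd,
                      na.rm = TRUE) /
        sqrt(colSums(!is.na(segG[, ok, drop = FALSE])))
    }
  }
  if (is.null(pair)) pair <- if (identical(va, vb)) "AA" else "AB"
  new("CorrelationCurve", lag = lag, G = G, se = se,
      pair = as.character(pair))
}

#' Fit the one-component 2D membrane diffusion model
#'
#' Weighted least squares of
#' \deqn{G(\tau) = G_0 (1 + \tau/\tau_D)^{-1/2}
#'   (1 + \tau/(S^2 \tau_D))^{-1/2} + G_\infty}
#' to a correlation curve (weights 1/se^2 when per-lag errors are
#' available; lags without an error estimate get the smallest available
#' weight). The free baseline \eqn{G_\infty} absorbs the small
#' finite-record offset of the correlation estimator; disable it with
#' \code{offset = FALSE} for strict two-parameter fitting. The diffusion
#' coefficient is derived as \eqn{D = w_0^2 / (4 \tau_D)} and the area
#' density as \eqn{C = 1 / (G_0 A_{eff})} with
#' \eqn{A_{eff} = \pi w_0 (S w_0)}.
#'
#' @param curve a \linkS4class{CorrelationCurve} with at least 8 lags.
#' @param w0 lateral focus waist, micrometres.
#' @param S axial-to-lateral focus ratio.
#' @param offset fit a free correlation baseline (default TRUE).
#' @param maxLagFactor fit only lags up to this multiple of the
#'   half-decay time of the curve (at least 12 points are always kept;
#'   \code{Inf} uses every lag). Far-tail lags carry little information
#'   about the diffusion time but all of the slow systematic errors of
#'   long-lag correlation estimates, so a bounded window makes the fit
#'   both less biased and less variable.
#' @return a \linkS4class{DiffusionFit}.
#' @export
fitMembraneDiffusion <- function(curve, w0 = 0.25, S = 5, offset = TRUE,
                                 maxLagFactor = 7) {
  stopifnot(is(curve, "CorrelationCurve"))
  if (length(curve@lag) < 8L) stop("need at least 8 lag points")
  if (w0 <= 0 || S <= 0) stop("'w0' and 'S' must be positive")
  lag <- curve@lag
  G <- curve@G
  G0start <- mean(G[1:3])
  if (!is.finite(G0start) || G0start <= 0)
    stop("fit failed: non-positive correlation amplitude")
  below <- which(G < G0start / 2)
  tDhalf <- if (length(below)) max(lag[below[1L]], lag[2L])
            else stats::median(lag)
  tDstart <- tDhalf
  if (is.finite(maxLagFactor)) {
    keep <- lag <= maxLagFactor * tDhalf
    if (sum(keep) >= 12L) {
      lag <- lag[keep]
      G <- G[keep]
      curve <- new("CorrelationCurve", lag = lag, G = G,
                   se = curve@se[keep], pair = curve@pair)
    }
  }
  dat <- data.frame(lag = lag, G = G)
  w <- 1 / curve@se^2
  if (any(is.finite(w))) {
    w[!is.finite(w)] <- min(w[is.finite(w)])
  } else {
    w <- rep(1, nrow(dat))
  }
  S2 <- S^2
  fit <- tryCatch(
    if (offset) {
      minpack.lm::nlsLM(
        G ~ G0 / sqrt((1 + lag / tD) * (1 + lag / (S2 * tD))) + Ginf,
        data = dat,
        start = list(G0 = G0start, tD = tDstart, Ginf = 0),
        weights = w,
        lower = c(G0 = 1e-12, tD = 1e-9, Ginf = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        G ~ G0 / sqrt((1 + lag / tD) * (1 + lag / (S2 * tD))),
        data = dat, start = list(G0 = G0start, tD = tDstart),
        weights = w,
        lower = c(G0 = 1e-12, tD = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e)
      stop("diffusion fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  co <- summary(fit)$coefficients
  G0 <- co["G0", "Estimate"]; tD <- co["tD", "Estimate"]
  seG0 <- co["G0", "Std. Error"]; seTD <- co["tD", "Std. Error"]
  Ginf <- if (offset) co["Ginf", "Estimate"] else 0
  D <- w0^2 / (4 * tD)
  Aeff <- pi * w0 * (S * w0)
  C <- 1 / (G0 * Aeff)
  ## assign slots directly: an argument named C would partially match
  ## the Class argument of new()
  out <- new("DiffusionFit")
  out@G0 <- G0; out@tauD <- tD; out@D <- D; out@C <- C
  out@w0 <- w0; out@S <- S; out@offset <- Ginf
  out@se <- c(G0 = seG0, tauD = seTD, D = D * seTD / tD,
              C = C * seG0 / G0)
  out@converged <- TRUE
  validObject(out)
  out
}

#' Bound fraction from dual-colour cross-correlation amplitudes
#'
#' Model-free amplitude estimate (mean of the first \code{nAmp} lags of
#' each curve); the bound-fraction proxy is the cross-correlation
#' amplitude over the smaller of the two autocorrelation amplitudes,
#' clipped to [0, 1].
#'
#' @param gg,rr,gr autocorrelation (green, red) and cross-correlation
#'   \linkS4class{CorrelationCurve}s on the same lag grid.
#' @param nAmp number of leading lags averaged into the amplitude.
#' @return bound fraction in [0, 1].
#' @export
crossCorrelationFraction <- function(gg, rr, gr, nAmp = 4L) {
  for (cv in list(gg, rr, gr)) stopifnot(is(cv, "CorrelationCurve"))
  if (!isTRUE(all.equal(gg@lag, rr@lag)) ||
      !isTRUE(all.equal(gg@lag, gr@lag)))
    stop("curves must share a lag grid")
  amp <- function(cv) mean(cv@G[seq_len(min(nAmp, length(cv@G)))])
  aGG <- amp(gg); aRR <- amp(rr)
  if (aGG <= 0 || aRR <= 0)
    stop("non-positive autocorrelation amplitude")
  min(max(amp(gr) / min(aGG, aRR), 0), 1)
}
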