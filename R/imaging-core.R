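#' @include AllClasses.R
NULL

## --------------------------------------------------------------------------
## Internal helpers: reflected borders and 2D convolution
## --------------------------------------------------------------------------

## Reflected ("symmetric", edge pixel duplicated) index map: positions
## 1..n extended to arbitrary integer i. Period 2n, so windows larger than
## the image keep reflecting.
reflectIndex <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

padReflect <- function(m, rpad, cpad = rpad) {
  ri <- reflectIndex(seq.int(1L - rpad, nrow(m) + rpad), nrow(m))
  ci <- reflectIndex(seq.int(1L - cpad, ncol(m) + cpad), ncol(m))
  m[ri, ci, drop = FALSE]
}

## Convolution with reflected borders via EBImage::filter2 on a padded copy
## (the pad is at least the kernel radius, so filter2's own wrap-around
## never reaches the retained centre).
conv2Reflect <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  p <- padReflect(m, kr, kc)
  f <- EBImage::filter2(p, kernel, boundary = "circular")
  f[(kr + 1L):(kr + nrow(m)), (kc + 1L):(kc + ncol(m)), drop = FALSE]
}

gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## --------------------------------------------------------------------------
## Operators
## --------------------------------------------------------------------------

#' Gaussian low-pass filter
#'
#' Smooths a 2D or 3D image with a unit-sum sampled Gaussian kernel
#' (separable, reflected borders). Shape and spacing are preserved; a
#' constant image maps to itself.
#'
#' @param img a \linkS4class{SpacedImage}.
#' @param sigma Gaussian standard deviation in pixels, > 0 (applied along
#'   every axis).
#' @return a smoothed \linkS4class{SpacedImage}.
#' @examples
#' img <- SpacedImage(matrix(rnorm(64, 10), 8, 8))
#' sm <- gaussianSmooth(img, sigma = 1)
#' @export
gaussianSmooth <- function(img, sigma = 1) {
  stopifnot(is(img, "SpacedImage"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  A <- img@values
  k1 <- gaussianKernel1d(sigma)
  if (length(dim(A)) == 2L) {
    out <- conv2Reflect(A, outer(k1, k1))
  } else {
    np <- dim(A)[1]
    out <- A
    k2 <- outer(k1, k1)
    for (p in seq_len(np))
      out[p, , ] <- conv2Reflect(A[p, , ], k2)
    ## separable pass along the plane axis with reflected plane indices
    acc <- array(0, dim(A))
    r <- (length(k1) - 1L) %/% 2L
    for (j in seq_along(k1)) {
      off <- j - r - 1L
      src <- reflectIndex(seq_len(np) + off, np)
      acc <- acc + k1[j] * out[src, , , drop = FALSE]
    }
    out <- acc
  }
  SpacedImage(out, spacing = img@spacing, channel = img@channel)
}

#' Hessian-eigenvalue objectness (ridge) filter
#'
#' Enhances thin bright line-like structures in a 2D image from the
#' eigenvalues of the Gaussian-scale Hessian (|lambda1| <= |lambda2|),
#' following the vesselness family of filters. Intensities are normalized
#' to [0, 1] before differentiation so that \code{gamma} has a fixed
#' meaning. For line-like structures (\code{order = 2}) the response is
#' zero wherever lambda2 >= 0 (no bright ridge) and otherwise
#' \deqn{\exp(-R_b^2 / 2\beta^2) (1 - \exp(-S^2 / 2\gamma^2)),}
#' with blobness \eqn{R_b = |\lambda_1| / |\lambda_2|} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}. Second derivatives are
#' scale-normalized (multiplied by sigma^2). \code{alpha} is accepted for
#' interface completeness; it only enters the 3D members of this filter
#' family and is inert in 2D.
#'
#' @param img a 2D \linkS4class{SpacedImage}.
#' @param params an \linkS4class{ObjectnessParams} object.
#' @return a non-negative response \linkS4class{SpacedImage} of the same
#'   shape.
#' @export
objectnessFilter <- function(img, params = objectnessParams()) {
  stopifnot(is(img, "SpacedImage"), is(params, "ObjectnessParams"))
  A <- img@values
  if (length(dim(A)) != 2L)
    stop("objectnessFilter supports 2D images only; ",
         "trace 3D data via the maximum-intensity-projection route")
  rng <- max(A) - min(A)
  if (rng == 0) {
    return(SpacedImage(array(0, dim(A)), spacing = img@spacing,
                       channel = img@channel))
  }
  A <- (A - min(A)) / rng
  s <- params@sigma
  r <- max(2L, ceiling(4 * s))
  x <- seq.int(-r, r)
  G <- exp(-x^2 / (2 * s^2))
  G <- G / sum(G)                        # unit-sum 1D Gaussian
  ## 1D derivative kernels (sampled analytic derivatives, same
  ## normalization as G)
  d1 <- -x / s^2 * G
  d2 <- (x^2 - s^2) / s^4 * G
  ## scale-normalized Hessian entries; row = first axis, col = second
  Hrr <- s^2 * conv2Reflect(A, outer(d2, G))
  Hcc <- s^2 * conv2Reflect(A, outer(G, d2))
  Hrc <- s^2 * conv2Reflect(A, outer(d1, d1))
  ## eigenvalues of [[Hrr, Hrc], [Hrc, Hcc]]
  tr2 <- (Hrr + Hcc) / 2
  delta <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
  e1 <- tr2 + delta
  e2 <- tr2 - delta
  big <- ifelse(abs(e1) >= abs(e2), e1, e2)       # lambda2: |.| larger
  small <- ifelse(abs(e1) >= abs(e2), e2, e1)     # lambda1
  Sn2 <- e1^2 + e2^2
  structureness <- 1 - exp(-Sn2 / (2 * params@gamma^2))
  absBig <- pmax(abs(big), .Machine$double.xmin)
  Rb2 <- (small / absBig)^2
  blobTerm <- exp(-Rb2 / (2 * params@beta^2))
  V <- if (params@order == 2L) {
    ifelse(big < 0, blobTerm * structureness, 0)
  } else {
    ## blob-like: both eigenvalues negative, isotropy rewarded
    ifelse(big < 0 & small < 0, (1 - blobTerm) * structureness, 0)
  }
  dim(V) <- dim(A)
  SpacedImage(V, spacing = img@spacing, channel = img@channel)
}

#' Local adaptive threshold
#'
#' Marks a pixel foreground iff its value strictly exceeds the regional
#' mean plus \code{stdMultiplier} times the regional (population) standard
#' deviation, computed over a square window of radius \code{windowRadius}
#' with reflected borders. Invariant to adding a constant to the image.
#'
#' @param img a 2D \linkS4class{SpacedImage}.
#' @param params a \linkS4class{ThresholdParams} object.
#' @return a \linkS4class{BinaryMask}.
#' @export
localAdaptiveThreshold <- function(img, params = thresholdParams()) {
  stopifnot(is(img, "SpacedImage"), is(params, "ThresholdParams"))
  A <- img@values
  if (length(dim(A)) != 2L)
    stop("localAdaptiveThreshold supports 2D images only")
  r <- params@windowRadius
  k <- params@stdMultiplier
  P <- padReflect(A, r)
  n <- (2 * r + 1)^2
  boxSum <- function(M) {
    cs <- apply(M, 2L, cumsum)
    cs <- rbind(0, cs)
    rowsum_ <- cs[seq_len(nrow(A)) + 2L * r + 1L, , drop = FALSE] -
      cs[seq_len(nrow(A)), , drop = FALSE]
    cs2 <- t(apply(rowsum_, 1L, cumsum))
    cs2 <- cbind(0, cs2)
    cs2[, seq_len(ncol(A)) + 2L * r + 1L, drop = FALSE] -
      cs2[, seq_len(ncol(A)), drop = FALSE]
  }
  s1 <- boxSum(P)
  s2 <- boxSum(P^2)
  mu <- s1 / n
  v <- pmax(s2 / n - mu^2, 0)
  fg <- A > mu + k * sqrt(v)
  dim(fg) <- dim(A)
  BinaryMask(fg, spacing = img@spacing)
}

#' Morphological opening with a disc structuring element
#'
#' Erosion followed by dilation with a disc of the given radius; removes
#' structures narrower than the element. The result is a subset of the
#' input and opening is idempotent.
#'
#' @param mask a 2D \linkS4class{BinaryMask}.
#' @param radius disc radius in pixels, >= 1.
#' @return an opened \linkS4class{BinaryMask}.
#' @export
morphologicalOpen <- function(mask, radius = 2L) {
  stopifnot(is(mask, "BinaryMask"))
  if (radius < 1) stop("'radius' must be >= 1")
  if (length(dim(mask@values)) != 2L)
    stop("morphologicalOpen supports 2D masks only")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  m <- mask@values * 1
  out <- EBImage::opening(m, brush)
  BinaryMask(out > 0.5, spacing = mask@spacing)
}

#' Largest connected component
#'
#' Extracts the connected component with the greatest pixel count
#' (8-connectivity in 2D, 26 in 3D). Ties are broken deterministically in
#' favour of the component containing the lexicographically smallest
#' (row, col[, plane]) pixel.
#'
#' @param mask a \linkS4class{BinaryMask} with at least one foreground
#'   pixel.
#' @return a \linkS4class{BinaryMask} holding exactly one component.
#' @export
largestComponent <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  v <- mask@values
  if (!any(v)) stop("empty mask: no connected component to extract")
  d <- dim(v)
  lab <- .cq_label(as.logical(v), as.integer(d))
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## compare the (row, col[, plane])-lexicographically smallest pixel of
    ## each tied component
    keyOf <- function(lb) {
      idx <- which(lab == lb)
      coord <- arrayInd(idx, d)
      if (length(d) == 3L) coord <- coord[, c(2L, 3L, 1L), drop = FALSE]
      o <- do.call(order, lapply(seq_len(ncol(coord)),
                                 function(j) coord[, j]))
      coord[o[1L], ]
    }
    keys <- lapply(best, keyOf)
    o <- do.call(order, lapply(seq_len(length(keys[[1L]])),
                               function(j) vapply(keys, `[`, 0, j)))
    best <- best[o[1L]]
  }
  out <- array(lab == best, d)
  BinaryMask(out, spacing = mask@spacing)
}

#' Pixelwise union of two masks
#'
#' @param body,filopodia \linkS4class{BinaryMask}s of identical shape.
#' @return their union as a \linkS4class{BinaryMask}.
#' @export
combineMasks <- function(body, filopodia) {
  stopifnot(is(body, "BinaryMask"), is(filopodia, "BinaryMask"))
  if (!identical(dim(body@values), dim(filopodia@values)))
    stop("mask shapes differ")
  BinaryMask(body@values | filopodia@values, spacing = body@spacing)
}

## 2D shift with zero padding (helper for thinning / endpoint detection)
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr
  okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

## the 8 neighbours P2..P9 in clockwise order starting north
neighborStack <- function(m) {
  list(N  = shiftMat(m, -1L,  0L), NE = shiftMat(m, -1L,  1L),
       E  = shiftMat(m,  0L,  1L), SE = shiftMat(m,  1L,  1L),
       S  = shiftMat(m,  1L,  0L), SW = shiftMat(m,  1L, -1L),
       W  = shiftMat(m,  0L, -1L), NW = shiftMat(m, -1L, -1L))
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels a 2D mask down to its 1-pixel-wide 8-connected
#' skeleton.
#'
#' @param mask a 2D \linkS4class{BinaryMask}.
#' @return the skeleton as a \linkS4class{BinaryMask}.
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- mask@values
  if (length(dim(m)) != 2L) stop("skeletonize supports 2D masks only")
  dim(m) <- dim(mask@values)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighborStack(m)
      B <- Reduce(`+`, nb)
      seqc <- c(nb$N, nb$NE, nb$E, nb$SE, nb$S, nb$SW, nb$W, nb$NW, nb$N)
      dim(seqc) <- c(length(m), 9L)
      A <- rowSums(!seqc[, 1:8, drop = FALSE] & seqc[, 2:9, drop = FALSE])
      dim(A) <- dim(m)
      if (sub == 1L) {
        c3 <- !(nb$N & nb$E & nb$S)
        c4 <- !(nb$E & nb$S & nb$W)
      } else {
        c3 <- !(nb$N & nb$E & nb$W)
        c4 <- !(nb$N & nb$S & nb$W)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  BinaryMask(m, spacing = mask@spacing)
}

#' Skeleton endpoints: candidate filopodia tips
#'
#' Skeletonizes a 2D mask and returns every skeleton pixel with exactly one
#' 8-connected skeleton neighbour.
#'
#' @param mask a 2D \linkS4class{BinaryMask}.
#' @return integer matrix with one (row, col) endpoint per row (0 rows for
#'   an empty mask), ordered lexicographically.
#' @export
skeletonEndpoints <- function(mask) {
  skel <- skeletonize(mask)@values
  if (!any(skel))
    return(matrix(integer(), 0L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  nb <- neighborStack(skel)
  cnt <- Reduce(`+`, nb)
  ep <- skel & cnt == 1L
  coord <- which(ep, arr.ind = TRUE)
  coord <- coord[order(coord[, 1L], coord[, 2L]), , drop = FALSE]
  colnames(coord) <- c("row", "col")
  storage.mode(coord) <- "integer"
  coord
}
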