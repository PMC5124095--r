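#' Threshold a volume into a carbonate mask
#'
#' Separates carbonate from the air/water background. `method = "otsu"`
#' picks, over a 256-bin histogram, the threshold maximizing the
#' between-class variance; `method = "fixed"` uses `value` directly
#' (mask = values > value). If the histogram does not separate into two
#' classes (Otsu effectiveness below `minEffectiveness`), the function warns
#' and falls back to `value` when supplied, or to the mid-range otherwise.
#'
#' @param vol a [CTVolume-class] or a 3-D numeric array.
#' @param method "otsu" or "fixed".
#' @param value threshold for `method = "fixed"` (and the fallback for a
#'   degenerate Otsu histogram).
#' @param minEffectiveness minimum acceptable ratio of between-class to
#'   total variance for Otsu (default 0.5).
#' @return A logical 3-D array (TRUE = carbonate), with the threshold used
#'   in attribute `"threshold"`.
#' @examples
#' a <- array(c(rep(20, 500), rep(150, 500)), c(10, 10, 10))
#' th <- attr(thresholdCarbonate(CTVolume(a, 50)), "threshold")
#' th > 20 && th < 150
#' @export
thresholdCarbonate <- function(vol, method = c("otsu", "fixed"), value = NULL,
                               minEffectiveness = 0.5) {
  method <- match.arg(method)
  vals <- if (is(vol, "CTVolume")) vol@values else vol
  stopifnot(length(dim(vals)) == 3L)
  if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' requires a threshold value")
    th <- value
  } else {
    rng <- range(vals)
    if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
      warning("constant volume: no carbonate mode found; returning empty mask")
      mask <- array(FALSE, dim(vals))
      attr(mask, "threshold") <- rng[1]
      return(mask)
    }
    th <- .otsuThreshold(vals)
    eff <- attr(th, "effectiveness")
    if (eff < minEffectiveness) {
      fallback <- if (!is.null(value)) value else mean(rng)
      warning(sprintf(
        "histogram appears unimodal (Otsu effectiveness %.2f); falling back to fixed threshold %.4g",
        eff, fallback))
      th <- fallback
    }
  }
  mask <- vals > th
  attr(mask, "threshold") <- as.numeric(th)
  mask
}

.otsuThreshold <- function(vals, nbins = 256L) {
  rng <- range(vals)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(vals, br, all.inside = TRUE), nbins = nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  # with well-separated modes sigmaB is flat across the inter-mode gap;
  # take the middle of the plateau, not its first bin
  plateau <- which(sigmaB >= max(sigmaB) * (1 - 1e-9))
  k <- plateau[ceiling(length(plateau) / 2)]
  th <- br[k + 1L]  # upper edge of the chosen bin: mask = vals > th
  sigmaT <- sum(p * (mids - muT)^2)
  attr(th, "effectiveness") <- if (sigmaT > 0) sigmaB[k] / sigmaT else 0
  th
}

#' Solid hull of a carbonate mask
#'
#' Defines "the block plus its internal voids": a morphological closing
#' with a Euclidean ball of the given physical radius seals tunnel
#' apertures, then cavities not 6-connected to the grid boundary are
#' flood-filled. With radius 0, only fully enclosed cavities are included;
#' tunnels open to a face remain outside the hull.
#'
#' @param mask logical 3-D array (TRUE = carbonate).
#' @param closingRadiusUm radius of the closing ball, micrometres (>= 0).
#'   The default 500 covers typical annelid borehole apertures.
#' @param pitchUm voxel pitch of the mask, micrometres.
#' @return Logical 3-D array: the hull.
#' @export
solidHull <- function(mask, closingRadiusUm = 500, pitchUm) {
  stopifnot(length(dim(mask)) == 3L, closingRadiusUm >= 0, pitchUm > 0)
  d <- dim(mask)
  rVox <- closingRadiusUm / pitchUm
  # pad so the dilated mask can never touch the grid boundary (the erosion
  # would otherwise fail to shrink it back there)
  pad <- as.integer(ceiling(rVox) + 2L)
  dp <- d + 2L * pad
  m <- array(FALSE, dp)
  ix <- pad + seq_len(d[1]); iy <- pad + seq_len(d[2]); iz <- pad + seq_len(d[3])
  m[ix, iy, iz] <- mask
  if (rVox > 0) {
    # closing = erode(dilate(mask)); both via the squared EDT. The erosion
    # radius carries a half-voxel slack: discrete ball dilation/erosion are
    # not exact inverses and would otherwise leave one-voxel fillet lines
    # along convex block edges. Original mask voxels are always retained,
    # so the slack cannot bite into the block itself.
    dist2fg <- cpp_sqedt(as.integer(m), dp)
    dil <- dist2fg <= rVox^2
    dist2bg <- cpp_sqedt(as.integer(!dil), dp)
    m <- array(dist2bg > (rVox + 0.5)^2, dp)
    m[ix, iy, iz] <- m[ix, iy, iz] | mask
  }
  outside <- cpp_flood_outside(as.integer(!m), dp)
  hull <- array(!as.logical(outside), dp)
  hull[ix, iy, iz]
}
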