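#' Rigid registration of the post-scan to the pre-scan frame
#'
#' The two scans are acquired at different pitches and with the block in a
#' different pose, so the post (moving) volume must be aligned to the pre
#' (fixed) frame before voxels can be compared. Both volumes are thresholded
#' into binary block masks, the masks are Gaussian-blurred, and the six
#' rigid parameters (translation in fixed-grid voxels, three Euler angles in
#' degrees) are found by maximizing normalized cross-correlation (NCC) with
#' Nelder-Mead, initialized from the centre-of-mass offset plus optional
#' extra starts. Intensity calibration is irrelevant because only masks are
#' correlated.
#'
#' @param moving,fixed [CTVolume-class] objects, each containing one
#'   dominant solid object.
#' @param blurSigmaVox Gaussian blur of the masks, voxels of each grid.
#' @param maxIter Nelder-Mead iteration budget per start.
#' @param sampleTarget approximate number of fixed-grid voxels used per NCC
#'   evaluation (the grid is strided down to this size).
#' @param extraStarts optional list of additional 6-parameter starting
#'   points `c(tx, ty, tz, rx, ry, rz)` (voxels / degrees) added to the
#'   centre-of-mass start.
#' @param minNcc registrations ending below this NCC are treated as failed
#'   (no overlap) and raise an error.
#' @param trim two-pass trimming (default TRUE): after a first registration,
#'   voxels where the blurred masks disagree by more than `trimThreshold`
#'   are excluded (these are the regions genuinely changed by accretion,
#'   grazing or boring) and the transform is re-optimized on the unchanged
#'   structure. Without it, colonization-induced shape change pulls the
#'   optimum off the true pose by a substantial fraction of a voxel.
#' @param trimThreshold blurred-mask disagreement (0..1) above which a voxel
#'   is excluded in the second pass.
#' @return A [RigidTransform-class] mapping fixed-frame physical
#'   coordinates to moving-frame coordinates, with the achieved NCC in
#'   `fitMetric`.
#' @seealso [resampleTo] to apply the result.
#' @export
registerRigid <- function(moving, fixed, blurSigmaVox = 2, maxIter = 400,
                          sampleTarget = 120000, extraStarts = list(),
                          minNcc = 0.2, trim = TRUE, trimThreshold = 0.3) {
  stopifnot(is(moving, "CTVolume"), is(fixed, "CTVolume"))
  movMask <- thresholdCarbonate(moving)
  fixMask <- thresholdCarbonate(fixed)
  if (!any(movMask) || !any(fixMask))
    stop("registration failed: no solid object found in one of the volumes")
  movBlur <- cpp_gaussian_blur(as.numeric(movMask), dim(movMask), blurSigmaVox)
  fixBlur <- cpp_gaussian_blur(as.numeric(fixMask), dim(fixMask), blurSigmaVox)
  comPhys <- function(maskVec, d, pitch, origin) {
    idx <- which(array(as.logical(maskVec), d), arr.ind = TRUE)
    origin + (colMeans(idx) - 1) * pitch
  }
  comFix <- comPhys(fixMask, dim(fixMask), fixed@pitchUm, fixed@origin)
  comMov <- comPhys(movMask, dim(movMask), moving@pitchUm, moving@origin)
  ctr <- fixed@origin + (dim(fixMask) - 1) / 2 * fixed@pitchUm
  dFix <- dim(fixMask)
  stride <- max(1L, as.integer(ceiling((prod(dFix) / sampleTarget)^(1 / 3))))
  objective <- function(par, keep = integer(0)) {
    -cpp_ncc_rigid(movBlur, dim(movMask), moving@pitchUm, moving@origin,
                   fixBlur, dFix, fixed@pitchUm, fixed@origin,
                   rotDeg = par[4:6], transUm = par[1:3] * fixed@pitchUm,
                   centerUm = ctr, stride = stride, background = 0,
                   keep = keep)
  }
  init <- c((comMov - comFix) / fixed@pitchUm, 0, 0, 0)
  starts <- c(list(init), lapply(extraStarts, function(s) init + s))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, objective, method = "Nelder-Mead",
                        control = list(maxit = maxIter, reltol = 1e-12))
    # restart once from the optimum to escape a collapsed simplex
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxIter, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # final pass at full sampling: strided NCC is not translation-invariant
  # and would leave a sub-voxel aliasing bias
  objectiveFull <- function(par, keep = integer(0)) {
    -cpp_ncc_rigid(movBlur, dim(movMask), moving@pitchUm, moving@origin,
                   fixBlur, dFix, fixed@pitchUm, fixed@origin,
                   rotDeg = par[4:6], transUm = par[1:3] * fixed@pitchUm,
                   centerUm = ctr, stride = 1L, background = 0, keep = keep)
  }
  keep <- integer(0)
  if (trim) {
    # exclude regions genuinely changed between the scans (accretion,
    # grazing, boring) plus a blur-width margin, re-optimize on the rest
    par <- best$par
    movOnFix <- cpp_resample_rigid(
      movBlur, dim(movMask), moving@pitchUm, moving@origin,
      dFix, fixed@pitchUm, fixed@origin,
      rotDeg = par[4:6], transUm = par[1:3] * fixed@pitchUm,
      centerUm = ctr, background = 0)
    excl <- abs(movOnFix - fixBlur) > trimThreshold
    margin <- ceiling(2 * blurSigmaVox) + 1
    dist2excl <- cpp_sqedt(as.integer(excl), dFix)
    keepMask <- dist2excl > margin^2
    if (sum(keepMask) <= 0.25 * length(keepMask)) keep <- integer(0)
    else keep <- as.integer(keepMask)
  }
  best <- stats::optim(best$par, objectiveFull, keep = keep,
                       method = "Nelder-Mead",
                       control = list(maxit = maxIter, reltol = 1e-10))
  ncc <- -best$value
  if (!is.finite(ncc) || ncc < minNcc)
    stop(sprintf(
      "registration failed: best mask NCC %.3f < %.3f (volumes may not overlap)",
      ncc, minNcc))
  rigidTransform(translation = best$par[1:3], rotation = best$par[4:6],
                 centerUm = ctr, pitchUm = fixed@pitchUm, fitMetric = ncc)
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' Trilinear interpolation of `vol` at the transform-mapped positions of
#' every target voxel; positions falling outside the moving field of view
#' get `background`.
#'
#' @param vol the moving [CTVolume-class].
#' @param transform a [RigidTransform-class] mapping target physical
#'   coordinates to `vol` coordinates (e.g. from [registerRigid]).
#' @param target a [CTVolume-class] defining the output grid and pitch.
#' @param background value for out-of-field voxels; `NULL` (default) uses
#'   the median of the moving volume's corner voxels.
#' @return A [CTVolume-class] on the target grid.
#' @export
resampleTo <- function(vol, transform, target, background = NULL) {
  stopifnot(is(vol, "CTVolume"), is(transform, "RigidTransform"),
            is(target, "CTVolume"))
  if (is.null(background)) {
    d <- dim(vol@values)
    corners <- vol@values[c(1, d[1]), c(1, d[2]), c(1, d[3])]
    background <- stats::median(corners)
  }
  out <- cpp_resample_rigid(
    as.numeric(vol@values), dim(vol@values), vol@pitchUm, vol@origin,
    dim(target@values), target@pitchUm, target@origin,
    rotDeg = transform@rotation,
    transUm = transform@translation * transform@pitchUm,
    centerUm = transform@centerUm, background = background)
  CTVolume(array(out, dim(target@values)), pitchUm = target@pitchUm,
           origin = target@origin, metadata = vol@metadata)
}
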