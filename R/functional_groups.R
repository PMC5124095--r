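#' Volumetric functional-group metrics from a label volume
#'
#' Voxel count of the respective label multiplied by the voxel volume.
#' `accretionVolume` measures new carbonate on the block surface,
#' `macroboringVolume` the void space excavated within the remaining block,
#' and `grazingVolume` the external volume scraped off the block.
#'
#' @param labels a [LabelVolume-class].
#' @return Volume, cm^3 (always >= 0).
#' @export
accretionVolume <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  labelCounts(labels)[["accretion"]] * voxelVolumeCm3(labels)
}

#' @rdname accretionVolume
#' @export
macroboringVolume <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  labelCounts(labels)[["macroboring_void"]] * voxelVolumeCm3(labels)
}

#' @rdname accretionVolume
#' @export
grazingVolume <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  labelCounts(labels)[["grazed"]] * voxelVolumeCm3(labels)
}

#' Microboring mass loss from pre/post density volumes
#'
#' Microborers dissolve skeleton from within at scales below the scan
#' resolution, so they appear as a bulk density drop of the non-bored,
#' non-grazed block: (mean pre-density - mean post-density over the
#' `original_remaining` region) x (volume of that region).
#'
#' The post-scan is resampled onto the pre grid, which blurs mask
#' boundaries by partial-volume interpolation while the pre-scan is on its
#' native grid; `boundaryErode` (voxels, default 1) therefore erodes the
#' region over which the *means* are taken, while the multiplying volume
#' stays the full region. Set it to 0 to average over the full region.
#'
#' Apparent density gain (secondary precipitation) yields a negative value;
#' it is reported signed unless `clamp = TRUE`.
#'
#' @param preDensity,postDensity density volumes (g cm^-3) registered on
#'   the pre-scan grid, e.g. from [attenuationToDensity].
#' @param labels a [LabelVolume-class] on the same grid.
#' @param boundaryErode erosion radius (voxels) applied to the averaging
#'   region as a partial-volume guard.
#' @param clamp clamp negative mass loss to zero.
#' @return Mass loss, grams.
#' @export
microboringMassLoss <- function(preDensity, postDensity, labels,
                                boundaryErode = 1, clamp = FALSE) {
  stopifnot(is(preDensity, "CTVolume"), is(postDensity, "CTVolume"),
            is(labels, "LabelVolume"))
  d <- dim(labels@labels)
  stopifnot(identical(dim(preDensity@values), d),
            identical(dim(postDensity@values), d))
  region <- labels@labels == .LABEL_LEGEND[["original_remaining"]]
  if (!any(region)) stop("no original_remaining voxels: cannot estimate microboring")
  avgRegion <- region
  if (boundaryErode > 0) {
    dist2out <- cpp_sqedt(as.integer(!region), d)
    eroded <- array(dist2out > boundaryErode^2, d)
    if (any(eroded)) avgRegion <- eroded
  }
  dPre <- mean(preDensity@values[avgRegion])
  dPost <- mean(postDensity@values[avgRegion])
  loss <- (dPre - dPost) * sum(region) * voxelVolumeCm3(labels)
  if (clamp) max(0, loss) else loss
}

#' Standardized functional-group rates for one BAR
#'
#' Divides each functional-group metric by the initial (pre-scan) surface
#' area of the block, base plane excluded -- the standardization used for
#' all CT-derived metrics. The final (post-scan) surface area is also
#' computed (that one is the denominator for incubation rates, a different
#' convention). Annualized rates (x 365 / deploymentDays) are included in
#' the `as.data.frame` output.
#'
#' @param labels a [LabelVolume-class].
#' @param preDensity,postDensity density volumes on the pre grid (for the
#'   microboring term); pass `NULL` to skip it (reported as 0).
#' @param deploymentDays deployment duration, days.
#' @param basePlaneZ z-index of the base plane to exclude from surface
#'   areas; default is the lowest occupied pre-block slab.
#' @param boundaryErode,clampMicroboring passed to [microboringMassLoss].
#' @return A [FunctionalGroupRates-class].
#' @export
summarizeRates <- function(labels, preDensity = NULL, postDensity = NULL,
                           deploymentDays, basePlaneZ = NULL,
                           boundaryErode = 1, clampMicroboring = FALSE) {
  stopifnot(is(labels, "LabelVolume"), deploymentDays > 0)
  lab <- labels@labels
  preBlock <- lab == .LABEL_LEGEND[["original_remaining"]] |
    lab == .LABEL_LEGEND[["macroboring_void"]] |
    lab == .LABEL_LEGEND[["grazed"]]
  postBlock <- lab == .LABEL_LEGEND[["original_remaining"]] |
    lab == .LABEL_LEGEND[["accretion"]]
  if (is.null(basePlaneZ)) {
    occ <- which(apply(preBlock, 3, any))
    basePlaneZ <- occ[1]
  }
  saInitial <- surfaceArea(preBlock, labels@pitchUm,
                           excludeBasePlane = basePlaneZ)
  saFinal <- surfaceArea(postBlock, labels@pitchUm,
                         excludeBasePlane = basePlaneZ)
  micro <- 0
  if (!is.null(preDensity) && !is.null(postDensity))
    micro <- microboringMassLoss(preDensity, postDensity, labels,
                                 boundaryErode = boundaryErode,
                                 clamp = clampMicroboring)
  new("FunctionalGroupRates",
      accretionCm3PerCm2 = accretionVolume(labels) / saInitial,
      macroboringCm3PerCm2 = macroboringVolume(labels) / saInitial,
      grazingCm3PerCm2 = grazingVolume(labels) / saInitial,
      microboringGPerCm2 = micro / saInitial,
      initialSurfaceAreaCm2 = saInitial, finalSurfaceAreaCm2 = saFinal,
      deploymentDays = deploymentDays)
}

#' Run the full scan-pair pipeline on one BAR
#'
#' Convenience wrapper: thresholds both scans, registers the post scan to
#' the pre frame, resamples it, builds solid hulls, partitions the voxels,
#' converts attenuation to density through the session calibrations and
#' summarizes the standardized rates.
#'
#' @param pre,post [CTVolume-class] attenuation volumes.
#' @param preCal,postCal [DensityCalibration-class] for each scan session
#'   (phantoms are analysed per session); `NULL` skips densitometry and the
#'   microboring term.
#' @param closingRadiusUm hull closing radius, micrometres (see
#'   [solidHull]).
#' @param deploymentDays deployment duration, days.
#' @param basePlaneZ passed to [summarizeRates].
#' @param ... further arguments to [registerRigid].
#' @return A list with elements `transform` ([RigidTransform-class]),
#'   `labels` ([LabelVolume-class]) and `rates`
#'   ([FunctionalGroupRates-class]).
#' @export
quantifyBarPair <- function(pre, post, preCal = NULL, postCal = NULL,
                            closingRadiusUm = 500, deploymentDays = 662,
                            basePlaneZ = NULL, ...) {
  transform <- registerRigid(post, pre, ...)
  postOnPre <- resampleTo(post, transform, pre)
  preMask <- thresholdCarbonate(pre)
  postMask <- thresholdCarbonate(postOnPre)
  preHull <- solidHull(preMask, closingRadiusUm, pre@pitchUm)
  postHull <- solidHull(postMask, closingRadiusUm, pre@pitchUm)
  labels <- partitionVoxels(preMask, postMask, preHull, postHull,
                            pre@pitchUm)
  preDensity <- postDensity <- NULL
  if (!is.null(preCal) && !is.null(postCal)) {
    preDensity <- attenuationToDensity(pre, preCal)
    postDensity <- attenuationToDensity(postOnPre, postCal)
  }
  rates <- summarizeRates(labels, preDensity, postDensity,
                          deploymentDays = deploymentDays,
                          basePlaneZ = basePlaneZ)
  list(transform = transform, labels = labels, rates = rates)
}
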