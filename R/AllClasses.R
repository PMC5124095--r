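#' CTVolume: a reconstructed micro-CT attenuation volume
#'
#' A 3-D scalar grid of X-ray attenuation with an isotropic voxel pitch
#' (micrometres) and a physical origin (position of voxel `[1,1,1]`, in
#' micrometres). Physical coordinate of voxel `(i,j,k)` (1-based) is
#' `origin + (i-1, j-1, k-1) * pitchUm`.
#'
#' @slot values 3-D numeric array of attenuation (or density, after
#'   calibration).
#' @slot pitchUm voxel edge length, micrometres (> 0).
#' @slot origin physical position of the first voxel centre, micrometres.
#' @slot metadata free-form list (scan session, calibration id, ...).
#' @export
setClass("CTVolume",
  representation(values = "array", pitchUm = "numeric",
                 origin = "numeric", metadata = "list"),
  prototype(pitchUm = 1, origin = c(0, 0, 0), metadata = list()))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L || any(dim(object@values) < 1L))
    msg <- c(msg, "values must be a non-empty 3-D array")
  if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
      object@pitchUm <= 0)
    msg <- c(msg, "pitchUm must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "attenuation values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param values 3-D numeric array.
#' @param pitchUm isotropic voxel pitch, micrometres.
#' @param origin physical position of voxel `[1,1,1]`, micrometres.
#' @param metadata free-form list.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(0, c(4, 4, 4)), pitchUm = 59.51)
#' pitchUm(v)
#' @export
CTVolume <- function(values, pitchUm, origin = c(0, 0, 0), metadata = list()) {
  new("CTVolume", values = values, pitchUm = as.numeric(pitchUm),
      origin = as.numeric(origin), metadata = metadata)
}

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels at %.2f um pitch (%.2f x %.2f x %.2f cm)\n",
              d[1], d[2], d[3], object@pitchUm,
              d[1] * object@pitchUm * 1e-4, d[2] * object@pitchUm * 1e-4,
              d[3] * object@pitchUm * 1e-4))
  cat(sprintf("  value range [%.3g, %.3g]\n",
              min(object@values), max(object@values)))
})

#' DensityCalibration: attenuation-to-density line from phantoms
#'
#' Linear map from X-ray attenuation to calcium carbonate density
#' (g cm^-3) fitted by least squares to aragonite density phantoms:
#' `density = slope * attenuation + intercept`.
#'
#' @slot slope g cm^-3 per attenuation unit (> 0: denser material
#'   attenuates more).
#' @slot intercept g cm^-3.
#' @slot rSquared coefficient of determination of the phantom fit.
#' @slot nPhantoms number of phantoms used (>= 2).
#' @export
setClass("DensityCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nPhantoms = "integer"))

setValidity("DensityCalibration", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "slope must be a single positive number")
  if (object@nPhantoms < 2L)
    msg <- c(msg, "at least 2 phantoms are required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DensityCalibration", function(object) {
  cat(sprintf(
    "DensityCalibration: density = %.6g * attenuation + %.6g g/cm^3 (r^2 = %.4f, n = %d)\n",
    object@slope, object@intercept, object@rSquared, object@nPhantoms))
})

#' @describeIn DensityCalibration-class intercept and slope as a named vector.
#' @param object a `DensityCalibration`.
#' @export
setMethod("coef", "DensityCalibration", function(object) {
  c(intercept = object@intercept, slope = object@slope)
})

#' RigidTransform: rigid map between two scan frames
#'
#' Maps physical coordinates of the target (fixed) frame to physical
#' coordinates of the moving frame: `x_mov = R (x_fix - c) + c + t`, with
#' rotation `R` composed as Rz * Ry * Rx from three Euler angles (degrees)
#' and `c` the rotation centre. The translation is stored in voxels of the
#' target grid; `pitchUm` is the target pitch used for that conversion.
#'
#' @slot translation 3-vector, voxels of the target grid.
#' @slot rotation 3 Euler angles, degrees (applied as Rz Ry Rx).
#' @slot centerUm rotation centre, physical micrometres.
#' @slot pitchUm target-grid pitch used to express the translation.
#' @slot fitMetric final similarity value of the registration (NA when the
#'   transform was constructed directly).
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "numeric",
                 centerUm = "numeric", pitchUm = "numeric",
                 fitMetric = "numeric"),
  prototype(fitMetric = NA_real_))

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3L || length(object@rotation) != 3L ||
      length(object@centerUm) != 3L)
    return("translation, rotation and centerUm must be 3-vectors")
  if (any(!is.finite(c(object@translation, object@rotation, object@centerUm))))
    return("transform parameters must be finite")
  if (object@pitchUm <= 0) return("pitchUm must be positive")
  TRUE
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: t = (%.3f, %.3f, %.3f) voxels @ %.2f um, rot = (%.3f, %.3f, %.3f) deg",
              object@translation[1], object@translation[2], object@translation[3],
              object@pitchUm, object@rotation[1], object@rotation[2],
              object@rotation[3]))
  if (is.finite(object@fitMetric))
    cat(sprintf(", NCC = %.4f", object@fitMetric))
  cat("\n")
})

#' LabelVolume: per-voxel functional-group partition
#'
#' Classification of every voxel of the registered pre-scan grid into
#' `background` (0), `original_remaining` (1), `accretion` (2),
#' `macroboring_void` (3) and `grazed` (4). Labels are disjoint and
#' exhaustive by construction.
#'
#' @slot labels 3-D integer array of codes 0..4.
#' @slot pitchUm voxel pitch of the pre-scan grid, micrometres.
#' @export
setClass("LabelVolume",
  representation(labels = "array", pitchUm = "numeric"))

.LABEL_LEGEND <- c(background = 0L, original_remaining = 1L, accretion = 2L,
                   macroboring_void = 3L, grazed = 4L)

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3-D array")
  if (!all(object@labels %in% 0:4))
    return("label codes must be in 0..4")
  if (object@pitchUm <= 0) return("pitchUm must be positive")
  TRUE
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume on the pre-scan grid:\n")
  cnt <- labelCounts(object)
  vv <- voxelVolumeCm3(object)
  for (nm in names(cnt))
    cat(sprintf("  %-18s %10d voxels  %.5g cm^3\n", nm, cnt[[nm]],
                cnt[[nm]] * vv))
})

#' BarSimSpec: specification for one synthetic BAR pair
#'
#' Describes a clean carbonate block and the modifications imposed on it
#' during a simulated deployment, plus the acquisition differences between
#' the pre- and post-scans (voxel pitches, rigid misalignment, noise).
#' Defaults emulate a 5 x 2 x 1 cm massive-coral block scanned at 59.51 um
#' (pre) and 64.23 um (post).
#'
#' @slot blockDimsCm physical block size (x, y, z), cm.
#' @slot prePitchUm,postPitchUm voxel pitches of the two scans, micrometres.
#' @slot baseDensityGcc bulk carbonate density of the clean block, g cm^-3.
#' @slot accretionPatches list of patches, each a list with `face`
#'   ("top", "xmin", "xmax", "ymin", "ymax"), `center` (fractional (u, v)
#'   position on the face), `size` (voxels, (w, h)), `thickness` (voxels)
#'   and `density` (g cm^-3).
#' @slot boreholes list of tunnels, each a list with `face`, `entry`
#'   (fractional (u, v) on the face), `direction` (3-vector, defaults to the
#'   inward normal), `radiusUm` (> 50) and `lengthUm`.
#' @slot grazedRegions list of slabs, each a list with `face`, `depth`
#'   (voxels) and optional `footprint` (fractional (u0, u1, v0, v1)).
#' @slot microboringDensityDropFrac fractional density loss of the remaining
#'   original carbonate, in [0, 1).
#' @slot rigidOffset list with `translation` (voxels of the pre grid) and
#'   `rotation` (Euler degrees) applied to the post scan.
#' @slot noiseSd additive Gaussian attenuation noise s.d. (both scans).
#' @slot calibrationSlope,calibrationIntercept the attenuation-to-density
#'   line the simulated scanner realises (phantoms of the same session
#'   recover it).
#' @slot backgroundAttenuation attenuation of air/water, well below the
#'   carbonate mode.
#' @slot marginVoxels background margin around the block on the pre grid.
#' @slot seed integer RNG seed.
#' @export
setClass("BarSimSpec",
  representation(blockDimsCm = "numeric", prePitchUm = "numeric",
                 postPitchUm = "numeric", baseDensityGcc = "numeric",
                 accretionPatches = "list", boreholes = "list",
                 grazedRegions = "list",
                 microboringDensityDropFrac = "numeric",
                 rigidOffset = "list", noiseSd = "numeric",
                 calibrationSlope = "numeric",
                 calibrationIntercept = "numeric",
                 backgroundAttenuation = "numeric",
                 marginVoxels = "integer", seed = "integer"))

setValidity("BarSimSpec", function(object) {
  msg <- character()
  if (length(object@blockDimsCm) != 3L || any(object@blockDimsCm <= 0))
    msg <- c(msg, "blockDimsCm must be 3 positive numbers")
  if (object@prePitchUm <= 0 || object@postPitchUm <= 0)
    msg <- c(msg, "pitches must be positive")
  if (object@baseDensityGcc <= 0)
    msg <- c(msg, "baseDensityGcc must be positive")
  for (b in object@boreholes) {
    if (b$radiusUm <= 50)
      msg <- c(msg, "borehole radiusUm must exceed 50 (diameter > 100 um defines macroboring)")
    if (b$lengthUm <= 0) msg <- c(msg, "borehole lengthUm must be positive")
  }
  for (p in object@accretionPatches)
    if (p$thickness <= 0 || any(p$size <= 0) || p$density <= 0)
      msg <- c(msg, "accretion patch thickness, size and density must be positive")
  for (g in object@grazedRegions)
    if (g$depth <= 0) msg <- c(msg, "grazed depth must be positive")
  if (object@microboringDensityDropFrac < 0 ||
      object@microboringDensityDropFrac >= 1)
    msg <- c(msg, "microboringDensityDropFrac must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@marginVoxels < 2L)
    msg <- c(msg, "at least a 2-voxel background margin is required")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: exact imposed modifications of a synthetic BAR
#'
#' Voxel-counted volumes of each imposed modification on the pre-scan grid
#' (before noise), the imposed microboring mass loss, the initial surface
#' area (base excluded) and the rigid transform relating the two scans.
#'
#' @slot accretionVolumeCm3,macroboringVolumeCm3,grazingVolumeCm3 exact
#'   voxel-counted volumes, cm^3.
#' @slot microboringMassLossG imposed density drop x remaining volume, g.
#' @slot initialSurfaceAreaCm2 pre-scan surface area, base plane excluded.
#' @slot voxelCounts named integer vector of exact voxel counts.
#' @slot transform the [RigidTransform-class] applied to the post scan.
#' @export
setClass("GroundTruth",
  representation(accretionVolumeCm3 = "numeric",
                 macroboringVolumeCm3 = "numeric",
                 grazingVolumeCm3 = "numeric",
                 microboringMassLossG = "numeric",
                 initialSurfaceAreaCm2 = "numeric",
                 voxelCounts = "integer",
                 transform = "RigidTransform"))

setValidity("GroundTruth", function(object) {
  v <- c(object@accretionVolumeCm3, object@macroboringVolumeCm3,
         object@grazingVolumeCm3)
  if (any(v < 0)) return("volumes must be >= 0")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: accretion %.5g, macroboring %.5g, grazing %.5g cm^3; microboring %.5g g; SA %.3f cm^2\n",
    object@accretionVolumeCm3, object@macroboringVolumeCm3,
    object@grazingVolumeCm3, object@microboringMassLossG,
    object@initialSurfaceAreaCm2))
})

#' FunctionalGroupRates: standardized carbonate-budget metrics for one BAR
#'
#' The four functional-group metrics standardized to the initial (pre-scan)
#' surface area of the block, plus the two surface areas and the deployment
#' duration. Annualized fields multiply by 365 / deploymentDays.
#'
#' @slot accretionCm3PerCm2,macroboringCm3PerCm2,grazingCm3PerCm2 volumetric
#'   metrics per initial surface area, cm^3 cm^-2.
#' @slot microboringGPerCm2 density-loss metric, g cm^-2 (signed unless
#'   clamped).
#' @slot initialSurfaceAreaCm2,finalSurfaceAreaCm2 cm^2, base excluded.
#' @slot deploymentDays duration, days.
#' @export
setClass("FunctionalGroupRates",
  representation(accretionCm3PerCm2 = "numeric",
                 macroboringCm3PerCm2 = "numeric",
                 grazingCm3PerCm2 = "numeric",
                 microboringGPerCm2 = "numeric",
                 initialSurfaceAreaCm2 = "numeric",
                 finalSurfaceAreaCm2 = "numeric",
                 deploymentDays = "numeric"))

setValidity("FunctionalGroupRates", function(object) {
  msg <- character()
  if (object@initialSurfaceAreaCm2 <= 0 || object@finalSurfaceAreaCm2 <= 0)
    msg <- c(msg, "surface areas must be positive")
  if (object@deploymentDays <= 0)
    msg <- c(msg, "deploymentDays must be positive")
  if (any(c(object@accretionCm3PerCm2, object@macroboringCm3PerCm2,
            object@grazingCm3PerCm2) < 0))
    msg <- c(msg, "volumetric metrics must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FunctionalGroupRates", function(object) {
  cat("FunctionalGroupRates (per initial surface area):\n")
  cat(sprintf("  accretion   %.5g cm^3/cm^2\n", object@accretionCm3PerCm2))
  cat(sprintf("  macroboring %.5g cm^3/cm^2\n", object@macroboringCm3PerCm2))
  cat(sprintf("  grazing     %.5g cm^3/cm^2\n", object@grazingCm3PerCm2))
  cat(sprintf("  microboring %.5g g/cm^2\n", object@microboringGPerCm2))
  cat(sprintf("  SA initial %.3f cm^2, final %.3f cm^2; %g days deployed\n",
              object@initialSurfaceAreaCm2, object@finalSurfaceAreaCm2,
              object@deploymentDays))
})

#' @describeIn FunctionalGroupRates-class one-row data.frame, including
#'   annualized (`*_per_yr`) fields.
#' @param x a `FunctionalGroupRates`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "FunctionalGroupRates", function(x, ...) {
  ann <- 365 / x@deploymentDays
  data.frame(
    accretion_cm3_cm2 = x@accretionCm3PerCm2,
    macroboring_cm3_cm2 = x@macroboringCm3PerCm2,
    grazing_cm3_cm2 = x@grazingCm3PerCm2,
    microboring_g_cm2 = x@microboringGPerCm2,
    accretion_cm3_cm2_yr = x@accretionCm3PerCm2 * ann,
    macroboring_cm3_cm2_yr = x@macroboringCm3PerCm2 * ann,
    grazing_cm3_cm2_yr = x@grazingCm3PerCm2 * ann,
    microboring_g_cm2_yr = x@microboringGPerCm2 * ann,
    initial_surface_area_cm2 = x@initialSurfaceAreaCm2,
    final_surface_area_cm2 = x@finalSurfaceAreaCm2,
    deployment_days = x@deploymentDays)
})

#' GLMResult: one fitted pH-response model
#'
#' @slot family "gaussian_identity" or "gamma_log".
#' @slot coefficients intercept and slope versus pH (on the link scale).
#' @slot se standard errors of the coefficients.
#' @slot pValue Wald p-value for the slope.
#' @slot shift value added to responses before a gamma fit (0 if none);
#'   predictions are back-shifted.
#' @slot n number of observations.
#' @slot fit the underlying [stats::glm] object.
#' @export
setClass("GLMResult",
  representation(family = "character", coefficients = "numeric",
                 se = "numeric", pValue = "numeric", shift = "numeric",
                 n = "integer", fit = "ANY"))

setValidity("GLMResult", function(object) {
  if (!object@family %in% c("gaussian_identity", "gamma_log"))
    return("family must be gaussian_identity or gamma_log")
  if (length(object@coefficients) != 2L)
    return("coefficients must be (intercept, slope)")
  TRUE
})

setMethod("show", "GLMResult", function(object) {
  cat(sprintf("GLMResult [%s]: intercept %.4g (se %.3g), slope %.4g (se %.3g), p = %.3g, n = %d",
              object@family, object@coefficients[1], object@se[1],
              object@coefficients[2], object@se[2], object@pValue, object@n))
  if (object@shift != 0) cat(sprintf(", shift = %.4g", object@shift))
  cat("\n")
})

#' CrossingEstimate: pH at which net 24-h calcification crosses zero
#'
#' @slot phAtZero root of the fitted pooled model's prediction in pH.
#' @slot ciLow,ciHigh percentile bootstrap interval.
#' @slot nPooled number of pooled observations.
#' @slot nBoot bootstrap replicates.
#' @export
setClass("CrossingEstimate",
  representation(phAtZero = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nPooled = "integer", nBoot = "integer"))

setValidity("CrossingEstimate", function(object) {
  if (!(object@ciLow <= object@phAtZero && object@phAtZero <= object@ciHigh))
    return("ciLow <= phAtZero <= ciHigh must hold")
  TRUE
})

setMethod("show", "CrossingEstimate", function(object) {
  cat(sprintf("CrossingEstimate: net calcification = 0 at pH %.3f (95%% CI %.3f-%.3f, n = %d, %d bootstrap draws)\n",
              object@phAtZero, object@ciLow, object@ciHigh, object@nPooled,
              object@nBoot))
})
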