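#' Fit the densitometry calibration line
#'
#' Least-squares line `density = slope * attenuation + intercept` through
#' the phantom measurements, the standard way micro-CT attenuation is
#' converted to calcium carbonate density. Requires at least two phantoms
#' with distinct mean attenuations; the fit is invariant to phantom order.
#'
#' @param phantoms either a data.frame with columns `mean_attenuation` and
#'   `density_gcc` (e.g. from [readPhantomTable]), or the list returned by
#'   [makePhantomSet] (mean attenuations are computed from the volumes).
#' @return A [DensityCalibration-class].
#' @examples
#' cal <- fitDensitometry(data.frame(mean_attenuation = c(100, 200),
#'                                   density_gcc = c(1.5, 2.5)))
#' coef(cal)  # intercept 0.5, slope 0.01
#' @export
fitDensitometry <- function(phantoms) {
  if (is.list(phantoms) && !is.data.frame(phantoms) &&
      all(vapply(phantoms, function(p) is(p$volume, "CTVolume"), logical(1)))) {
    phantoms <- data.frame(
      mean_attenuation = vapply(phantoms, function(p) mean(voxelData(p$volume)),
                                numeric(1)),
      density_gcc = vapply(phantoms, function(p) p$density, numeric(1)))
  }
  stopifnot(is.data.frame(phantoms),
            all(c("mean_attenuation", "density_gcc") %in% names(phantoms)))
  x <- phantoms$mean_attenuation
  y <- phantoms$density_gcc
  if (length(x) < 2L)
    stop("calibration is underdetermined: at least 2 phantoms are required")
  if (diff(range(x)) < .Machine$double.eps * max(abs(x), 1))
    stop("singular fit: phantom attenuations are identical")
  fit <- stats::lm(y ~ x)
  # for a simple regression r^2 = cor(x, y)^2 (summary.lm warns on an
  # exact two-point fit)
  r2 <- if (length(x) == 2L) 1 else stats::cor(x, y)^2
  new("DensityCalibration", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), rSquared = r2,
      nPhantoms = length(x))
}

#' Convert an attenuation volume to carbonate density
#'
#' Voxelwise affine map through a phantom calibration. Density is physical,
#' so values mapped below zero (background noise dipping under the
#' intercept) are clamped to 0 by default.
#'
#' @param vol a [CTVolume-class] of attenuation.
#' @param cal a [DensityCalibration-class].
#' @param clamp clamp negative densities to zero (default TRUE).
#' @return A [CTVolume-class] whose values are g cm^-3; monotone
#'   non-decreasing in the input attenuation.
#' @export
attenuationToDensity <- function(vol, cal, clamp = TRUE) {
  stopifnot(is(vol, "CTVolume"), is(cal, "DensityCalibration"))
  validObject(cal)
  dens <- cal@slope * vol@values + cal@intercept
  if (clamp) dens[dens < 0] <- 0
  CTVolume(dens, pitchUm = vol@pitchUm, origin = vol@origin,
           metadata = c(vol@metadata, list(units = "g/cm^3")))
}
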