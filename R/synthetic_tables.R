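#' Generate a synthetic closed-chamber incubation table
#'
#' Emulates light/dark chamber runs of blocks plus paired no-block blanks:
#' the generating rates are inverted through the alkalinity-anomaly and
#' oxygen-flux equations to produce the initial/final readings, a common
#' blank drift is added to every chamber, and measurement noise on top.
#' Inverting the records through [processIncubations] recovers the true
#' rates exactly at zero noise and in expectation otherwise.
#'
#' @param trueLightRate,trueDarkRate generating calcification rates,
#'   umol CaCO3 cm^-2 h^-1 (positive = calcification).
#' @param truePhoto,trueResp generating net photosynthesis and dark
#'   respiration, ug O2 cm^-2 min^-1 (respiration as positive consumption).
#' @param chamberVolumeL chamber volume, litres (default 0.640).
#' @param surfaceAreaCm2 block surface area, cm^2 (> 0).
#' @param durationsMin light and dark run durations, minutes (defaults 80
#'   and 140).
#' @param blankDrift additive drift seen by every chamber including blanks:
#'   scalar or `c(at = , o2 = )` (umol kg^-1 and mg L^-1 per run).
#' @param noiseSd measurement noise s.d.: scalar or `c(at = , o2 = )`.
#' @param seed RNG seed.
#' @param nBlocks number of replicate block chambers.
#' @param nBlanks number of blank chambers per phase (default 2).
#' @param treatmentPh chamber pH level, recorded on every row.
#' @param seawaterDensityKgL converts chamber volume to seawater mass.
#' @param atInitial,o2Initial initial readings.
#' @return A data.frame of incubation records, one row per chamber run,
#'   with columns chamber_id, bar_id, is_blank, phase, at_initial,
#'   at_final, o2_initial, o2_final, chamber_volume_l,
#'   seawater_density_kg_l, duration_min, surface_area_cm2, treatment_ph.
#' @export
makeIncubationSet <- function(trueLightRate, trueDarkRate, truePhoto,
                              trueResp, chamberVolumeL = 0.640,
                              surfaceAreaCm2, durationsMin = c(80, 140),
                              blankDrift = 0, noiseSd = 0, seed = 1L,
                              nBlocks = 1L, nBlanks = 2L, treatmentPh = 7.9,
                              seawaterDensityKgL = 1.023,
                              atInitial = 2300, o2Initial = 6.5) {
  stopifnot(all(durationsMin > 0), chamberVolumeL > 0)
  if (surfaceAreaCm2 <= 0) stop("surface area must be positive")
  drift <- if (length(blankDrift) == 1L)
    c(at = blankDrift, o2 = blankDrift) else blankDrift
  noise <- if (length(noiseSd) == 1L) c(at = noiseSd, o2 = noiseSd) else noiseSd
  set.seed(seed)
  massKg <- chamberVolumeL * seawaterDensityKgL
  rows <- list()
  add <- function(phase, isBlank, barId, durMin) {
    rate <- if (phase == "light") trueLightRate else trueDarkRate
    o2rate <- if (phase == "light") truePhoto else -trueResp
    durH <- durMin / 60
    dAt <- if (isBlank) 0 else -rate * 2 * surfaceAreaCm2 * durH / massKg
    dO2 <- if (isBlank) 0 else
      o2rate * surfaceAreaCm2 * durMin / (1000 * chamberVolumeL)
    dAt <- dAt + drift[["at"]] + rnorm(1, sd = noise[["at"]])
    dO2 <- dO2 + drift[["o2"]] + rnorm(1, sd = noise[["o2"]])
    rows[[length(rows) + 1L]] <<- data.frame(
      chamber_id = sprintf("%s_%s_%d", if (isBlank) "blank" else "bar",
                           phase, barId),
      bar_id = if (isBlank) NA_integer_ else barId,
      is_blank = isBlank, phase = phase,
      at_initial = atInitial, at_final = atInitial + dAt,
      o2_initial = o2Initial, o2_final = o2Initial + dO2,
      chamber_volume_l = chamberVolumeL,
      seawater_density_kg_l = seawaterDensityKgL,
      duration_min = durMin,
      surface_area_cm2 = if (isBlank) NA_real_ else surfaceAreaCm2,
      treatment_ph = treatmentPh)
  }
  for (phase in c("light", "dark")) {
    durMin <- durationsMin[if (phase == "light") 1L else 2L]
    for (i in seq_len(nBlocks)) add(phase, FALSE, i, durMin)
    for (i in seq_len(nBlanks)) add(phase, TRUE, i, durMin)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic pH-response table
#'
#' Draws responses from the stated family around the linear predictor
#' `intercept + slope * pH`, emulating the scatter of per-block response
#' metrics against chamber or field pH.
#'
#' @param intercept,slope linear predictor coefficients (response scale).
#' @param n number of observations (>= 3).
#' @param phRange pH interval sampled uniformly; must lie within
#'   `[7.0, 8.3]`.
#' @param noiseSd gaussian: residual s.d.; gamma: s.d. of the response
#'   around its mean (shape = mean^2 / noiseSd^2).
#' @param family "gaussian" (identity) or "gamma"; a gamma draw with a
#'   non-positive linear predictor is an error (shift responses instead).
#' @param seed RNG seed (draws are seed-reproducible).
#' @return data.frame with columns `ph` and `response`.
#' @examples
#' tab <- makePhResponseTable(-39, 5, n = 10, noiseSd = 0, seed = 2)
#' # response crosses 0 exactly at pH 39/5 = 7.8
#' range(tab$response[tab$ph < 7.8])
#' @export
makePhResponseTable <- function(intercept, slope, n, phRange = c(7.0, 8.3),
                                noiseSd = 0, family = c("gaussian", "gamma"),
                                seed = 1L) {
  family <- match.arg(family)
  if (n < 3) stop("at least 3 observations are required")
  if (phRange[1] < 7.0 - 1e-9 || phRange[2] > 8.3 + 1e-9 ||
      phRange[1] >= phRange[2])
    stop("phRange must be an interval within [7.0, 8.3]")
  set.seed(seed)
  ph <- sort(runif(n, phRange[1], phRange[2]))
  mu <- intercept + slope * ph
  response <- if (family == "gaussian") {
    mu + rnorm(n, sd = noiseSd)
  } else {
    if (any(mu <= 0))
      stop("gamma family requires a positive linear predictor over the pH range; shift the response first")
    if (noiseSd == 0) mu else {
      shape <- mu^2 / noiseSd^2
      rgamma(n, shape = shape, rate = shape / mu)
    }
  }
  data.frame(ph = ph, response = response)
}
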