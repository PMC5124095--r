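#' Blank-correct an incubation delta
#'
#' Chamber incubations drift even without a block (gas exchange with
#' chamber walls, water handling); paired no-block blanks from the same
#' phase and pH level measure that drift, and their mean is subtracted from
#' each sample delta.
#'
#' @param sampleDelta measured final - initial change of the sample
#'   chamber.
#' @param blankDeltas the corresponding blank chamber deltas (same phase
#'   and pH level; at least one).
#' @return Corrected delta: `sampleDelta - mean(blankDeltas)`.
#' @examples
#' blankCorrect(-20, c(-4, -6))  # -15
#' @export
blankCorrect <- function(sampleDelta, blankDeltas) {
  if (length(blankDeltas) < 1L || all(is.na(blankDeltas)))
    stop("no blanks available for this phase/pH level")
  sampleDelta - mean(blankDeltas, na.rm = TRUE)
}

#' Calcification rate by the alkalinity anomaly technique
#'
#' Each mole of CaCO3 precipitated removes two moles of total alkalinity,
#' so `G = -(deltaAt / 2) * mass / (surfaceArea * duration)`. An alkalinity
#' decline gives positive calcification; a rise gives net dissolution
#' (negative G).
#'
#' @param deltaAtUmolKg blank-corrected alkalinity change (final -
#'   initial), umol kg^-1.
#' @param seawaterMassKg seawater mass in the chamber, kg (chamber volume
#'   x seawater density).
#' @param surfaceAreaCm2 block surface area (post-deployment), cm^2.
#' @param durationH incubation duration, hours.
#' @return Calcification rate, umol CaCO3 cm^-2 h^-1.
#' @examples
#' calcificationRate(-20, 0.656, 30, 1.3333)  # ~ +0.164
#' @export
calcificationRate <- function(deltaAtUmolKg, seawaterMassKg, surfaceAreaCm2,
                              durationH) {
  if (any(surfaceAreaCm2 <= 0)) stop("surface area must be positive")
  if (any(durationH <= 0)) stop("duration must be positive")
  -(deltaAtUmolKg / 2) * seawaterMassKg / (surfaceAreaCm2 * durationH)
}

#' Oxygen flux from a chamber incubation
#'
#' `flux = deltaO2 * 1000 * volume / (surfaceArea * duration)`: positive in
#' the light is net photosynthesis, negative in the dark is respiration
#' (conventionally reported as its positive magnitude of O2 consumption).
#'
#' @param deltaO2MgL blank-corrected O2 change (final - initial), mg L^-1.
#' @param chamberVolumeL chamber volume, litres.
#' @param surfaceAreaCm2 block surface area, cm^2.
#' @param durationMin incubation duration, minutes.
#' @return O2 flux, ug O2 cm^-2 min^-1.
#' @examples
#' oxygenFlux(1, 0.640, 30, 80)  # 640/2400 = 0.2667
#' @export
oxygenFlux <- function(deltaO2MgL, chamberVolumeL, surfaceAreaCm2,
                       durationMin) {
  if (any(surfaceAreaCm2 <= 0)) stop("surface area must be positive")
  if (any(durationMin <= 0)) stop("duration must be positive")
  deltaO2MgL * 1000 * chamberVolumeL / (surfaceAreaCm2 * durationMin)
}

#' 24-h net calcification from light and dark rates
#'
#' Daily mean assuming 11 h of daylight and 13 h of night:
#' `(11 * gLight + 13 * gDark) / 24`. A convex combination, so the result
#' always lies between the two inputs.
#'
#' @param gLight,gDark light and dark calcification rates on the same
#'   per-area-per-hour basis.
#' @return 24-h mean calcification rate, same units.
#' @export
netDailyCalcification <- function(gLight, gDark) {
  (11 * gLight + 13 * gDark) / 24
}

#' Process an incubation record table into per-block chamber rates
#'
#' Applies the full chamber workflow to a record table (such as one from
#' [makeIncubationSet] or read from CSV): per phase and pH level, the mean
#' blank deltas are subtracted from each sample chamber's alkalinity and O2
#' changes, rates are computed by [calcificationRate] and [oxygenFlux]
#' against the post-deployment surface area, and light/dark rates are
#' combined into the 11 h / 13 h weighted daily mean.
#'
#' @param records data.frame with the columns documented in
#'   [makeIncubationSet].
#' @return data.frame with one row per block: bar_id, treatment_ph,
#'   g_light, g_dark, g_24h (umol CaCO3 cm^-2 h^-1), p_net and r_dark
#'   (ug O2 cm^-2 min^-1; r_dark is positive O2 consumption).
#' @export
processIncubations <- function(records) {
  need <- c("is_blank", "phase", "at_initial", "at_final", "o2_initial",
            "o2_final", "chamber_volume_l", "duration_min",
            "surface_area_cm2", "treatment_ph")
  if (!all(need %in% names(records)))
    stop("records are missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  if (is.null(records$seawater_density_kg_l))
    records$seawater_density_kg_l <- 1.023
  records$d_at <- records$at_final - records$at_initial
  records$d_o2 <- records$o2_final - records$o2_initial
  samples <- records[!records$is_blank, ]
  out <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    bl <- records[records$is_blank & records$phase == s$phase &
                    records$treatment_ph == s$treatment_ph, ]
    if (nrow(bl) == 0L)
      stop("no blanks for phase '", s$phase, "' at pH ", s$treatment_ph)
    dAt <- blankCorrect(s$d_at, bl$d_at)
    dO2 <- blankCorrect(s$d_o2, bl$d_o2)
    g <- calcificationRate(dAt, s$chamber_volume_l * s$seawater_density_kg_l,
                           s$surface_area_cm2, s$duration_min / 60)
    f <- oxygenFlux(dO2, s$chamber_volume_l, s$surface_area_cm2,
                    s$duration_min)
    out[[i]] <- data.frame(bar_id = s$bar_id, treatment_ph = s$treatment_ph,
                           phase = s$phase, g = g, o2 = f)
  }
  long <- do.call(rbind, out)
  bars <- unique(long[, c("bar_id", "treatment_ph")])
  res <- lapply(seq_len(nrow(bars)), function(i) {
    b <- bars[i, ]
    sub <- long[long$bar_id == b$bar_id &
                  long$treatment_ph == b$treatment_ph, ]
    gl <- sub$g[sub$phase == "light"]
    gd <- sub$g[sub$phase == "dark"]
    pn <- sub$o2[sub$phase == "light"]
    rd <- sub$o2[sub$phase == "dark"]
    data.frame(bar_id = b$bar_id, treatment_ph = b$treatment_ph,
               g_light = if (length(gl)) mean(gl) else NA_real_,
               g_dark = if (length(gd)) mean(gd) else NA_real_,
               g_24h = if (length(gl) && length(gd))
                 netDailyCalcification(mean(gl), mean(gd)) else NA_real_,
               p_net = if (length(pn)) mean(pn) else NA_real_,
               r_dark = if (length(rd)) -mean(rd) else NA_real_)
  })
  do.call(rbind, res)
}
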