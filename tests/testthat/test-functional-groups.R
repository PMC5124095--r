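# hand-built label volume with known counts
makeLabels <- function(pitchUm = 64) {
  lab <- array(0L, c(30, 20, 15))
  lab[5:24, 5:16, 4:12] <- 1L                 # original remaining
  lab[10:19, 8:17 - 3, 13:15] <- 2L           # accretion patch 10 x 10 x 3
  lab[7:9, 7:9, 5:9] <- 3L                    # macroboring 3 x 3 x 5
  lab[20:24, 5:16, 4:12] <- 4L                # grazed end 5 x 12 x 9
  new("LabelVolume", labels = lab, pitchUm = pitchUm)
}

test_that("volumetric metrics are voxel counts times voxel volume", {
  lv <- makeLabels(64)
  vv <- (64e-4)^3
  expect_equal(accretionVolume(lv), 300 * vv)   # ~7.86e-5 cm^3
  expect_equal(accretionVolume(lv), 7.86e-5, tolerance = 1e-3)
  expect_equal(macroboringVolume(lv), 45 * vv)
  expect_equal(grazingVolume(lv), 540 * vv)
})

test_that("an unchanged block has zero functional-group metrics", {
  m <- array(FALSE, c(15, 12, 10)); m[3:13, 3:10, 3:8] <- TRUE
  lv <- partitionVoxels(m, m, m, m, pitchUm = 100)
  expect_equal(accretionVolume(lv), 0)
  expect_equal(macroboringVolume(lv), 0)
  expect_equal(grazingVolume(lv), 0)
  dens <- CTVolume(array(1.8, dim(m)), pitchUm = 100)
  rates <- summarizeRates(lv, dens, dens, deploymentDays = 658)
  expect_equal(rates@accretionCm3PerCm2, 0)
  expect_equal(rates@macroboringCm3PerCm2, 0)
  expect_equal(rates@grazingCm3PerCm2, 0)
  expect_equal(rates@microboringGPerCm2, 0)
})

test_that("microboring mass loss is mean density drop times volume", {
  lv <- makeLabels(100)
  nRem <- sum(voxelData(lv) == 1L)
  pre <- CTVolume(array(1.80, dim(voxelData(lv))), pitchUm = 100)
  post <- CTVolume(array(1.62, dim(voxelData(lv))), pitchUm = 100)
  got <- microboringMassLoss(pre, post, lv)
  expect_equal(got, (1.80 - 1.62) * nRem * (100e-4)^3, tolerance = 1e-12)
  # identical densities give exactly zero; sign convention and clamping
  expect_equal(microboringMassLoss(pre, pre, lv), 0)
  expect_lt(microboringMassLoss(post, pre, lv), 0)
  expect_equal(microboringMassLoss(post, pre, lv, clamp = TRUE), 0)
  # the uniform 1.80 -> 1.62 drop over 2 cm^3 worked example
  expect_equal((1.80 - 1.62) * 2.0, 0.36)
})

test_that("microboring estimation needs surviving original carbonate", {
  lab <- array(0L, c(5, 5, 5))
  lv <- new("LabelVolume", labels = lab, pitchUm = 100)
  d <- CTVolume(array(1.8, c(5, 5, 5)), pitchUm = 100)
  expect_error(microboringMassLoss(d, d, lv), "original_remaining")
})

test_that("surface areas match analytic cuboid values", {
  # 5 x 2 x 1 cm block at 250 um pitch
  m <- array(FALSE, c(208, 88, 48))
  m[5:204, 5:84, 5:44] <- TRUE
  expect_lt(abs(surfaceArea(m, 250) / 34 - 1), 0.05)
  expect_lt(abs(surfaceArea(m, 250, excludeBasePlane = 5) / 24 - 1), 0.05)
  expect_error(surfaceArea(array(FALSE, c(4, 4, 4)), 100), "empty")
})

test_that("surface area of a sphere matches 4 pi r^2", {
  m <- sphereMask(25)  # r = 0.5 cm at 200 um pitch
  expect_lt(abs(surfaceArea(m, 200) / (4 * pi * 0.25) - 1), 0.03)
})

test_that("rates standardize by the initial surface area", {
  lv <- makeLabels(100)
  rates <- summarizeRates(lv, deploymentDays = 658)
  sa <- rates@initialSurfaceAreaCm2
  expect_equal(rates@macroboringCm3PerCm2, macroboringVolume(lv) / sa)
  expect_equal(rates@accretionCm3PerCm2, accretionVolume(lv) / sa)
  # the worked division: 0.048 cm^3 over 24 cm^2
  expect_equal(0.048 / 24, 0.002)
  df <- as.data.frame(rates)
  expect_equal(df$macroboring_cm3_cm2_yr,
               df$macroboring_cm3_cm2 * 365 / 658)
})

test_that("volumetric metrics scale linearly with imposed modifications", {
  mk <- function(scale) {
    spec <- barSimSpec(blockDimsCm = c(1.0, 0.5, 0.4), prePitchUm = 100,
                       postPitchUm = 100,
                       accretionPatches = list(list(face = "top",
                                                    center = c(0.3, 0.5),
                                                    size = c(20, 10),
                                                    thickness = 3 * scale,
                                                    density = 1.6)),
                       boreholes = list(list(face = "top",
                                             entry = c(0.7, 0.5),
                                             radiusUm = 400,
                                             lengthUm = 1500 * scale)),
                       grazedRegions = list(list(face = "ymax",
                                                 depth = 2 * scale)),
                       microboringDensityDropFrac = 0, noiseSd = 0,
                       rigidOffset = list(translation = c(0, 0, 0),
                                          rotation = c(0, 0, 0)))
    pair <- makeBarPair(spec)
    preMask <- thresholdCarbonate(pair$pre)
    postMask <- thresholdCarbonate(pair$post)
    lv <- partitionVoxels(preMask, postMask, solidHull(preMask, 500, 100),
                          solidHull(postMask, 500, 100), 100)
    c(accretionVolume(lv), macroboringVolume(lv), grazingVolume(lv))
  }
  one <- mk(1)
  two <- mk(2)
  # doubling thickness/length/depth should double each volume within 5%
  # (the borehole doubles only its cylindrical part, so compare loosely)
  expect_lt(abs(two[1] / one[1] - 2), 0.1)
  expect_lt(abs(two[3] / one[3] - 2), 0.1)
  expect_gt(two[2] / one[2], 1.7)
})

test_that("standardized rates are pitch-invariant for physical features", {
  mk <- function(pre, post) {
    spec <- barSimSpec(blockDimsCm = c(1.0, 0.5, 0.4), prePitchUm = pre,
                       postPitchUm = post, accretionPatches = list(),
                       boreholes = list(list(face = "top",
                                             entry = c(0.5, 0.5),
                                             radiusUm = 400,
                                             lengthUm = 2000)),
                       grazedRegions = list(),
                       microboringDensityDropFrac = 0, noiseSd = 0,
                       rigidOffset = list(translation = c(0, 0, 0),
                                          rotation = c(0, 0, 0)))
    pair <- makeBarPair(spec)
    preMask <- thresholdCarbonate(pair$pre)
    postMask <- thresholdCarbonate(pair$post)
    lv <- partitionVoxels(preMask, postMask,
                          solidHull(preMask, 500, pre),
                          solidHull(postMask, 500, pre), pre)
    summarizeRates(lv, deploymentDays = 658)@macroboringCm3PerCm2
  }
  expect_lt(abs(mk(59.51, 59.51) / mk(64.23, 64.23) - 1), 0.10)
})

test_that("microboring is insensitive to resolved macroboring tunnels", {
  mk <- function(withBore) {
    spec <- barSimSpec(blockDimsCm = c(1.0, 0.5, 0.4), prePitchUm = 100,
                       postPitchUm = 100, accretionPatches = list(),
                       boreholes = if (withBore)
                         list(list(face = "top", entry = c(0.5, 0.5),
                                   radiusUm = 400, lengthUm = 2500))
                       else list(),
                       grazedRegions = list(),
                       microboringDensityDropFrac = 0.10, noiseSd = 0,
                       rigidOffset = list(translation = c(0, 0, 0),
                                          rotation = c(0, 0, 0)))
    pair <- makeBarPair(spec)
    preMask <- thresholdCarbonate(pair$pre)
    postMask <- thresholdCarbonate(pair$post)
    lv <- partitionVoxels(preMask, postMask,
                          solidHull(preMask, 500, 100),
                          solidHull(postMask, 500, 100), 100)
    cal <- twoPointCal()
    micro <- microboringMassLoss(attenuationToDensity(pair$pre, cal),
                                 attenuationToDensity(pair$post, cal), lv)
    micro / sum(voxelData(lv) == 1L)  # per remaining voxel
  }
  expect_lt(abs(mk(TRUE) / mk(FALSE) - 1), 0.05)
})
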