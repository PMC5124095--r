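test_that("noiseless phantoms invert the calibration line exactly", {
  ph <- makePhantomSet(c(1.5, 2.5), slope = 0.01, intercept = 0.5,
                       noiseSd = 0)
  expect_equal(mean(voxelData(ph[[1]]$volume)), 100)
  expect_equal(mean(voxelData(ph[[2]]$volume)), 200)
})

test_that("phantom generation rejects degenerate density lists", {
  expect_error(makePhantomSet(1.5, 0.01, 0.5), "underdetermined")
  expect_error(makePhantomSet(c(2, 2), 0.01, 0.5), "underdetermined")
})

test_that("noisy phantom means stay within the standard-error bound", {
  ph <- makePhantomSet(c(1.5, 2.5), slope = 0.01, intercept = 0.5,
                       noiseSd = 2, seed = 3)
  n <- prod(dim(voxelData(ph[[1]]$volume)))
  for (i in 1:2) {
    noiseless <- (ph[[i]]$density - 0.5) / 0.01
    expect_lt(abs(mean(voxelData(ph[[i]]$volume)) - noiseless),
              3 * 2 / sqrt(n))
  }
})

test_that("an unmodified block survives the scan pair unchanged", {
  spec <- barSimSpec(blockDimsCm = c(0.8, 0.5, 0.3), prePitchUm = 100,
                     postPitchUm = 108, accretionPatches = list(),
                     boreholes = list(), grazedRegions = list(),
                     microboringDensityDropFrac = 0, noiseSd = 0,
                     rigidOffset = list(translation = c(0, 0, 0),
                                        rotation = c(0, 0, 0)))
  pair <- makeBarPair(spec)
  expect_equal(pair$truth@accretionVolumeCm3, 0)
  expect_equal(pair$truth@macroboringVolumeCm3, 0)
  expect_equal(pair$truth@grazingVolumeCm3, 0)
  expect_equal(pair$truth@microboringMassLossG, 0)
  # post equals pre after resampling back onto the pre grid, within
  # interpolation tolerance
  postOnPre <- resampleTo(pair$post,
                          rigidTransform(pitchUm = pitchUm(pair$pre)),
                          pair$pre)
  preMask <- thresholdCarbonate(pair$pre)
  postMask <- thresholdCarbonate(postOnPre)
  expect_lt(abs(sum(postMask) / sum(preMask) - 1), 0.02)
  # disagreement is confined to the interpolated boundary shell
  expect_lt(sum(xor(preMask, postMask)) / sum(preMask), 0.05)
})

test_that("borehole carving matches an independent capsule recount", {
  # axis-aligned tunnel, radius 4 voxels x length 50 voxels at 100 um pitch
  spec <- barSimSpec(blockDimsCm = c(1.0, 0.6, 0.6), prePitchUm = 100,
                     postPitchUm = 100, accretionPatches = list(),
                     boreholes = list(list(face = "top", entry = c(0.5, 0.5),
                                           radiusUm = 400, lengthUm = 5000)),
                     grazedRegions = list(),
                     microboringDensityDropFrac = 0, noiseSd = 0,
                     rigidOffset = list(translation = c(0, 0, 0),
                                        rotation = c(0, 0, 0)))
  pair <- makeBarPair(spec)
  count <- pair$truth@voxelCounts[["macroboring"]]
  # analytic cylinder pi r^2 L, allowing voxelization slack
  expect_lt(abs(count / (pi * 4^2 * 50) - 1), 0.06)
  # independent brute-force recount of carved voxels from the volumes:
  # carved = block voxels of the clean scan that are background after
  # modification
  carved <- sum(voxelData(pair$preClean) > 50 & voxelData(pair$modified) < 50)
  expect_identical(as.integer(count), as.integer(carved))
})

test_that("a rectangular grazed slab counts exactly", {
  # 2-voxel slab over the full 100 x 50 top face
  spec <- barSimSpec(blockDimsCm = c(1.0, 0.5, 0.3), prePitchUm = 100,
                     postPitchUm = 100, accretionPatches = list(),
                     boreholes = list(),
                     grazedRegions = list(list(face = "top", depth = 2)),
                     microboringDensityDropFrac = 0, noiseSd = 0,
                     rigidOffset = list(translation = c(0, 0, 0),
                                        rotation = c(0, 0, 0)))
  pair <- makeBarPair(spec)
  expect_identical(pair$truth@voxelCounts[["grazed"]], 100L * 50L * 2L)
  expect_equal(pair$truth@grazingVolumeCm3, 10000 * (100e-4)^3)
})

test_that("modifications out of bounds are rejected", {
  expect_error(makeBarPair(barSimSpec(
    blockDimsCm = c(0.5, 0.3, 0.2), prePitchUm = 100, postPitchUm = 100,
    accretionPatches = list(), grazedRegions = list(),
    boreholes = list(list(face = "top", entry = c(0.5, 0.5),
                          radiusUm = 300, lengthUm = 9000)))),
    "outside the simulation grid")
  expect_error(makeBarPair(barSimSpec(
    blockDimsCm = c(0.5, 0.3, 0.2), prePitchUm = 100, postPitchUm = 100,
    boreholes = list(), grazedRegions = list(),
    accretionPatches = list(list(face = "top", center = c(0.5, 0.5),
                                 size = c(10, 6), thickness = 20,
                                 density = 1.6)))),
    "outside the simulation grid")
})

test_that("spec invariants are enforced", {
  expect_error(barSimSpec(boreholes = list(
    list(face = "top", entry = c(0.5, 0.5), radiusUm = 40,
         lengthUm = 1000))), "50")
  expect_error(barSimSpec(microboringDensityDropFrac = 1.2), "\\[0, 1\\)")
  expect_error(barSimSpec(noiseSd = -1), "noiseSd")
})

test_that("generation is deterministic and conserves the original block", {
  spec <- smallBarSpec(seed = 9)
  a <- makeBarPair(spec)
  b <- makeBarPair(spec)
  expect_identical(voxelData(a$pre), voxelData(b$pre))
  expect_identical(voxelData(a$post), voxelData(b$post))
  # conservation on the pre grid: block = remaining + carved + grazed
  ct <- a$truth@voxelCounts
  expect_identical(ct[["block"]],
                   ct[["remaining"]] + ct[["macroboring"]] + ct[["grazed"]])
  # accretion voxels are disjoint from the original block: counted outside
  expect_gt(ct[["accretion"]], 0L)
  expect_identical(sum(voxelData(a$preClean) > 50) , ct[["block"]])
})

test_that("macroboring truth grows strictly with borehole radius", {
  vols <- vapply(c(300, 400, 500), function(r) {
    spec <- barSimSpec(blockDimsCm = c(1.0, 0.6, 0.4), prePitchUm = 100,
                       postPitchUm = 100, accretionPatches = list(),
                       grazedRegions = list(), noiseSd = 0,
                       boreholes = list(list(face = "top",
                                             entry = c(0.5, 0.5),
                                             radiusUm = r, lengthUm = 2500)))
    makeBarPair(spec)$truth@macroboringVolumeCm3
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("zero-rate, zero-drift incubations show no deltas", {
  rec <- makeIncubationSet(0, 0, 0, 0, surfaceAreaCm2 = 30, noiseSd = 0)
  expect_equal(rec$at_final - rec$at_initial, rep(0, nrow(rec)))
  expect_equal(rec$o2_final - rec$o2_initial, rep(0, nrow(rec)))
})

test_that("incubation generation rejects non-positive surface area", {
  expect_error(makeIncubationSet(1, 0, 1, 1, surfaceAreaCm2 = 0), "positive")
})

test_that("pH response tables honour their input contracts", {
  expect_error(makePhResponseTable(-39, 5, n = 0), "at least 3")
  expect_error(makePhResponseTable(-39, 5, n = 10, phRange = c(6.5, 8)),
               "7.0")
  expect_error(makePhResponseTable(39, -5, n = 10, family = "gamma"),
               "positive linear predictor")
  # noiseless gaussian responses sit exactly on the line through pH 7.8
  tab <- makePhResponseTable(-39, 5, n = 20, noiseSd = 0, seed = 4)
  expect_equal(tab$response, 5 * (tab$ph - 7.8), tolerance = 1e-12)
  # seed reproducibility
  expect_identical(makePhResponseTable(-39, 5, 15, noiseSd = 1, seed = 8),
                   makePhResponseTable(-39, 5, 15, noiseSd = 1, seed = 8))
})

test_that("OLS on generated gaussian tables covers the true slope", {
  hits <- 0L
  for (s in 1:100) {
    tab <- makePhResponseTable(-39, 5, n = 60, noiseSd = 1,
                               family = "gaussian", seed = s)
    fit <- stats::lm(response ~ ph, tab)
    ci <- stats::confint(fit, "ph", level = 0.95)
    if (ci[1] <= 5 && 5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
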