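cleanSpec <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                      seed = 1, prePitchUm = 100, postPitchUm = 100,
                      noiseSd = 5) {
  barSimSpec(blockDimsCm = c(0.8, 0.5, 0.4), prePitchUm = prePitchUm,
             postPitchUm = postPitchUm, accretionPatches = list(),
             boreholes = list(), grazedRegions = list(),
             microboringDensityDropFrac = 0, noiseSd = noiseSd,
             rigidOffset = list(translation = translation,
                                rotation = rotation), seed = seed)
}

test_that("registering a volume to itself is the identity", {
  pair <- makeBarPair(cleanSpec(seed = 5))
  tr <- registerRigid(pair$pre, pair$pre)
  expect_lt(max(abs(tr@translation)), 0.1)
  expect_lt(max(abs(tr@rotation)), 0.1)
  expect_gt(tr@fitMetric, 0.99)
})

test_that("a known integer offset is recovered within half a voxel", {
  pair <- makeBarPair(cleanSpec(translation = c(3, -2, 1), seed = 6))
  tr <- registerRigid(pair$post, pair$pre)
  expect_true(all(abs(tr@translation - c(3, -2, 1)) < 0.5))
  expect_true(all(abs(tr@rotation) < 0.5))
})

test_that("registration without an overlapping object fails loudly", {
  pair <- makeBarPair(cleanSpec(seed = 7, noiseSd = 0))
  flat <- CTVolume(array(20, dim(voxelData(pair$pre))), pitchUm = 100)
  expect_error(suppressWarnings(registerRigid(flat, pair$pre)),
               "no solid object")
})

test_that("rigid transforms compose, invert and map points consistently", {
  tr <- rigidTransform(c(3.2, -1.1, 0.7), c(2, -1.5, 1), centerUm = c(100, 80, 60),
                       pitchUm = 59.51)
  inv <- invertRigid(tr)
  id <- composeRigid(inv, tr)
  expect_lt(max(abs(id@translation)), 1e-6)
  expect_lt(max(abs(id@rotation)), 1e-6)
  pts <- matrix(rnorm(30, 0, 500), ncol = 3)
  expect_equal(transformPoints(inv, transformPoints(tr, pts)), pts,
               tolerance = 1e-9)
})

test_that("resampling through the identity returns the input exactly", {
  v <- CTVolume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), pitchUm = 50)
  id <- rigidTransform(pitchUm = 50)
  out <- resampleTo(v, id, v, background = 0)
  expect_equal(voxelData(out), voxelData(v), tolerance = 1e-12)
})

test_that("integer translations shift voxels exactly", {
  d <- c(12, 10, 8)
  v <- CTVolume(array(rnorm(prod(d)), d), pitchUm = 50)
  tr <- rigidTransform(translation = c(2, -1, 3), pitchUm = 50)
  out <- resampleTo(v, tr, v, background = -99)
  # out[i] = v[i + t] where in range
  expect_equal(voxelData(out)[1:10, 2:10, 1:5],
               voxelData(v)[3:12, 1:9, 4:8], tolerance = 1e-12)
  expect_true(all(voxelData(out)[11:12, , ] == -99))
})

test_that("cross-pitch resampling conserves above-threshold volume", {
  spec <- cleanSpec(translation = c(2.5, -1.5, 1), rotation = c(1, -0.5, 0.5),
                    prePitchUm = 59.51, postPitchUm = 64.23, seed = 8)
  pair <- makeBarPair(spec)
  tr <- registerRigid(pair$post, pair$pre)
  postOnPre <- resampleTo(pair$post, tr, pair$pre)
  vPre <- sum(thresholdCarbonate(pair$post)) * voxelVolumeCm3(pair$post)
  vPost <- sum(thresholdCarbonate(postOnPre)) * voxelVolumeCm3(postOnPre)
  expect_lt(abs(vPost / vPre - 1), 0.02)
})

test_that("Otsu thresholds fall strictly between well-separated modes", {
  vals <- array(c(rnorm(4000, 20, 3), rnorm(4000, 150, 5)), c(20, 20, 20))
  mask <- thresholdCarbonate(CTVolume(vals, 50))
  th <- attr(mask, "threshold")
  expect_gt(th, 40)
  expect_lt(th, 130)
  # exhaustive check: no single-class threshold does better
  expect_equal(sum(mask), sum(vals > th))
})

test_that("fixed thresholds are applied verbatim", {
  vals <- array(seq(0, 170, length.out = 4^3), c(4, 4, 4))
  mask <- thresholdCarbonate(CTVolume(vals, 50), method = "fixed", value = 85)
  expect_identical(as.logical(mask), as.logical(vals > 85))
})

test_that("an all-background volume yields an empty mask with a warning", {
  v <- CTVolume(array(20, c(6, 6, 6)), pitchUm = 50)
  expect_warning(mask <- thresholdCarbonate(v), "constant|unimodal")
  expect_false(any(mask))
})

test_that("solid hull keeps enclosed cavities even at radius zero", {
  m <- array(FALSE, c(20, 20, 20))
  m[4:17, 4:17, 4:17] <- TRUE
  m[8:12, 8:12, 8:12] <- FALSE  # fully enclosed cavity
  hull <- solidHull(m, 0, pitchUm = 100)
  expect_true(all(hull[8:12, 8:12, 8:12]))
  expect_identical(sum(hull), sum(m) + 125L)
})

test_that("open boreholes are sealed only by a sufficient closing radius", {
  m <- array(FALSE, c(40, 30, 30))
  m[3:38, 3:28, 3:28] <- TRUE
  # radius-4-voxel tunnel open to the x-max face
  g <- expand.grid(x = 15:40, y = 1:30, z = 1:30)
  inside <- (g$y - 15)^2 + (g$z - 15)^2 <= 16
  m[as.matrix(g[inside, ])] <- FALSE
  block <- array(FALSE, c(40, 30, 30)); block[3:38, 3:28, 3:28] <- TRUE
  carvedMask <- block & !m
  hullClosed <- solidHull(m, closingRadiusUm = 600, pitchUm = 100)
  hullOpen <- solidHull(m, closingRadiusUm = 0, pitchUm = 100)
  # closing seals the tunnel from roughly one closing radius below the
  # face inward; the shallow mouth segment communicates with the exterior
  deep <- carvedMask
  deep[32:40, , ] <- FALSE  # keep only voxels > 6 voxels below the face
  expect_true(all(hullClosed[deep]))
  expect_gt(sum(hullClosed[carvedMask]), 0.7 * sum(carvedMask))
  # without closing the open tunnel is reachable from outside: excluded
  expect_false(any(hullOpen[carvedMask] & !m[carvedMask]))
})

test_that("an unchanged block partitions entirely to original_remaining", {
  m <- array(FALSE, c(15, 12, 10))
  m[3:13, 3:10, 3:8] <- TRUE
  lv <- partitionVoxels(m, m, m, m, pitchUm = 100)
  cnt <- labelCounts(lv)
  expect_identical(cnt[["original_remaining"]], sum(m))
  expect_identical(cnt[["accretion"]], 0L)
  expect_identical(cnt[["macroboring_void"]], 0L)
  expect_identical(cnt[["grazed"]], 0L)
  expect_identical(sum(cnt), as.integer(prod(dim(m))))
})

test_that("partitioning an empty pre mask is an error", {
  e <- array(FALSE, c(5, 5, 5))
  expect_error(partitionVoxels(e, e, e, e, 100), "empty pre")
})

test_that("an accretion-only deployment partitions to accretion alone", {
  spec <- barSimSpec(blockDimsCm = c(0.8, 0.5, 0.3), prePitchUm = 100,
                     postPitchUm = 100,
                     accretionPatches = list(list(face = "top",
                                                  center = c(0.5, 0.5),
                                                  size = c(20, 10),
                                                  thickness = 3,
                                                  density = 1.6)),
                     boreholes = list(), grazedRegions = list(),
                     microboringDensityDropFrac = 0, noiseSd = 0,
                     rigidOffset = list(translation = c(0, 0, 0),
                                        rotation = c(0, 0, 0)))
  pair <- makeBarPair(spec)
  preMask <- thresholdCarbonate(pair$pre)
  postMask <- thresholdCarbonate(pair$post)
  lv <- partitionVoxels(preMask, postMask,
                        solidHull(preMask, 500, 100),
                        solidHull(postMask, 500, 100), 100)
  cnt <- labelCounts(lv)
  expect_identical(cnt[["accretion"]], 20L * 10L * 3L)
  expect_identical(cnt[["grazed"]], 0L)
  expect_identical(cnt[["macroboring_void"]], 0L)
})

test_that("label volumes serialize to NRRD plus legend and back", {
  m <- array(FALSE, c(10, 8, 6)); m[3:8, 3:6, 2:5] <- TRUE
  lv <- partitionVoxels(m, m, m, m, pitchUm = 64.23)
  p <- withr::local_tempfile(fileext = ".nrrd")
  writeLabelVolume(lv, p)
  r <- readLabelVolume(p)
  expect_identical(voxelData(r), voxelData(lv))
  expect_equal(pitchUm(r), 64.23)
  expect_true(file.exists(paste0(p, ".legend.json")))
})
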