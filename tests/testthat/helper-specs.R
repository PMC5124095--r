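# shared fixtures: everything is generated in code at test time

twoPointCal <- function() {
  fitDensitometry(data.frame(mean_attenuation = c(100, 200),
                             density_gcc = c(1.5, 2.5)))
}

# a small but fully featured BAR spec at the study pitches
smallBarSpec <- function(seed = 42, ...) {
  barSimSpec(blockDimsCm = c(1.2, 0.5, 0.3),
             accretionPatches = list(
               list(face = "top", center = c(0.3, 0.5), size = c(24, 12),
                    thickness = 4, density = 1.6)),
             boreholes = list(
               list(face = "top", entry = c(0.65, 0.5), radiusUm = 350,
                    lengthUm = 2000)),
             grazedRegions = list(
               list(face = "ymax", depth = 3,
                    footprint = c(0.15, 0.65, 0.2, 0.9))),
             seed = seed, ...)
}

# deterministic variations for a batch of synthetic deployments; offsets up
# to 5 voxels translation and 2 degrees rotation, features >= 3 voxels across
batchBarSpec <- function(i) {
  faces <- c("top", "xmax", "ymin", "xmin")
  offT <- list(c(2.5, -1.5, 1), c(5, -4, 3), c(-3, 2, -2), c(0.5, 4.5, -1),
               c(-4.5, -0.5, 2.5))[[(i - 1) %% 5 + 1]]
  offR <- list(c(0.8, -0.5, 0.6), c(2, -1, 1.5), c(-1.5, 0.7, -2),
               c(0.3, 1.8, 0.9), c(-0.9, -1.2, 0.4))[[(i - 1) %% 5 + 1]]
  barSimSpec(
    blockDimsCm = c(1.2, 0.5, 0.3),
    accretionPatches = list(
      list(face = faces[(i - 1) %% 4 + 1],
           center = c(0.3 + 0.03 * (i %% 3), 0.5),
           size = c(20 + 2 * (i %% 4), 10 + (i %% 3)),
           thickness = 4 + (i %% 2), density = 1.6)),
    boreholes = list(
      list(face = "top", entry = c(0.6 + 0.02 * (i %% 4), 0.45),
           radiusUm = 350 + 25 * (i %% 3), lengthUm = 1800 + 100 * (i %% 4)),
      list(face = "ymin", entry = c(0.25 + 0.05 * (i %% 3), 0.55),
           radiusUm = 400, lengthUm = 1500)),
    grazedRegions = list(
      list(face = "ymax", depth = 3 + (i %% 2),
           footprint = c(0.15, 0.6 + 0.05 * (i %% 3), 0.2, 0.9))),
    microboringDensityDropFrac = 0.03 + 0.01 * (i %% 4),
    rigidOffset = list(translation = offT, rotation = offR),
    seed = 1000 + i)
}

relErr <- function(got, truth) abs(got / truth - 1)

# voxelized sphere mask of radius rVox in a cube with 5-voxel margin
sphereMask <- function(rVox) {
  n <- as.integer(2 * ceiling(rVox) + 11)
  g <- seq_len(n) - (n + 1) / 2
  array(outer(outer(g^2, g^2, "+"), g^2, "+") <= rVox^2, c(n, n, n))
}
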