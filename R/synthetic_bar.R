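#' Specify a synthetic BAR deployment
#'
#' Builds a [BarSimSpec-class] with defaults emulating the study
#' conditions: a 5 x 2 x 1 cm massive-coral carbonate block (bulk density
#' 1.8 g cm^-3) scanned at 59.51 um before and 64.23 um after deployment,
#' colonized by accretion patches, annelid-like capsule boreholes
#' (> 100 um diameter), external grazing scars and a uniform microboring
#' density loss, with a small rigid pose change between scans and additive
#' scanner noise. Accretion is restricted to exposed faces ("top", "xmin",
#' "xmax", "ymin", "ymax"); the underside is the epoxy-mounted base.
#'
#' @param blockDimsCm,prePitchUm,postPitchUm,baseDensityGcc,accretionPatches,boreholes,grazedRegions,microboringDensityDropFrac,rigidOffset,noiseSd,calibrationSlope,calibrationIntercept,backgroundAttenuation,marginVoxels,seed
#'   see [BarSimSpec-class].
#' @return A validated [BarSimSpec-class].
#' @examples
#' spec <- barSimSpec(blockDimsCm = c(1, 0.5, 0.3), prePitchUm = 100,
#'                    postPitchUm = 108, boreholes = list(), noiseSd = 0)
#' spec@blockDimsCm
#' @export
barSimSpec <- function(blockDimsCm = c(5, 2, 1),
                       prePitchUm = 59.51, postPitchUm = 64.23,
                       baseDensityGcc = 1.8,
                       accretionPatches = list(
                         list(face = "top", center = c(0.3, 0.5),
                              size = c(24, 12), thickness = 4, density = 1.6),
                         list(face = "xmax", center = c(0.5, 0.6),
                              size = c(10, 8), thickness = 3, density = 1.7)),
                       boreholes = list(
                         list(face = "top", entry = c(0.62, 0.45),
                              radiusUm = 250, lengthUm = 2200),
                         list(face = "ymin", entry = c(0.75, 0.55),
                              radiusUm = 300, lengthUm = 1800)),
                       grazedRegions = list(
                         list(face = "ymax", depth = 3,
                              footprint = c(0.15, 0.65, 0.2, 0.9))),
                       microboringDensityDropFrac = 0.05,
                       rigidOffset = list(translation = c(2.5, -1.5, 1),
                                          rotation = c(0.8, -0.5, 0.6)),
                       noiseSd = 5,
                       calibrationSlope = 0.01, calibrationIntercept = 0.5,
                       backgroundAttenuation = 20,
                       marginVoxels = 8L, seed = 1L) {
  new("BarSimSpec", blockDimsCm = as.numeric(blockDimsCm),
      prePitchUm = prePitchUm, postPitchUm = postPitchUm,
      baseDensityGcc = baseDensityGcc, accretionPatches = accretionPatches,
      boreholes = boreholes, grazedRegions = grazedRegions,
      microboringDensityDropFrac = microboringDensityDropFrac,
      rigidOffset = rigidOffset, noiseSd = noiseSd,
      calibrationSlope = calibrationSlope,
      calibrationIntercept = calibrationIntercept,
      backgroundAttenuation = backgroundAttenuation,
      marginVoxels = as.integer(marginVoxels), seed = as.integer(seed))
}

# face geometry on the block index ranges rng = list(x=, y=, z=)
# outAxis: grid axis normal to the face; outSign: outward direction;
# uAxis/vAxis: in-face axes; surf: index of the outermost block layer
.faceInfo <- function(face, rng) {
  switch(face,
    top = list(outAxis = 3L, outSign = 1L, uAxis = 1L, vAxis = 2L,
               surf = rng$z[2]),
    xmin = list(outAxis = 1L, outSign = -1L, uAxis = 2L, vAxis = 3L,
                surf = rng$x[1]),
    xmax = list(outAxis = 1L, outSign = 1L, uAxis = 2L, vAxis = 3L,
                surf = rng$x[2]),
    ymin = list(outAxis = 2L, outSign = -1L, uAxis = 1L, vAxis = 3L,
                surf = rng$y[1]),
    ymax = list(outAxis = 2L, outSign = 1L, uAxis = 1L, vAxis = 3L,
                surf = rng$y[2]),
    stop("unknown face '", face, "' (base face is not exposed)"))
}

.axisRange <- function(rng, axis) switch(axis, rng$x, rng$y, rng$z)

.fracToIndex <- function(rng, frac) {
  rng[1] + round(frac * (rng[2] - rng[1]))
}

.checkInGrid <- function(lo, hi, d, what) {
  if (any(lo < 1L) || any(hi > d))
    stop(what, " extends outside the simulation grid")
}

#' Generate one synthetic BAR scan pair with ground truth
#'
#' Builds the clean pre-deployment block on the pre-scan grid, imposes the
#' specified modifications (grazing slabs removed, capsule boreholes carved,
#' microboring density drop applied to the remaining original carbonate,
#' accretion patches added on exposed faces), records exact voxel-counted
#' ground truth, then produces the post-deployment scan by applying the
#' rigid pose change, resampling trilinearly to the post pitch, and adding
#' Gaussian scanner noise to both scans. Ground truth is recorded on the
#' pre-scan grid before noise. A voxel claimed by both a grazing slab and a
#' borehole counts as grazed (the slab removes it first).
#'
#' @param spec a [BarSimSpec-class].
#' @return A list: `pre` and `post` ([CTVolume-class] at their respective
#'   pitches), `truth` ([GroundTruth-class]), plus the noiseless `preClean`
#'   and `modified` volumes on the pre grid (handy for oracle checks).
#' @examples
#' spec <- barSimSpec(blockDimsCm = c(0.6, 0.4, 0.3), prePitchUm = 200,
#'                    postPitchUm = 216, accretionPatches = list(),
#'                    boreholes = list(), grazedRegions = list(),
#'                    microboringDensityDropFrac = 0, noiseSd = 0)
#' pair <- makeBarPair(spec)
#' pair$truth
#' @export
makeBarPair <- function(spec) {
  stopifnot(is(spec, "BarSimSpec"))
  validObject(spec)
  m <- spec@marginVoxels
  nb <- pmax(1L, as.integer(round(spec@blockDimsCm * 1e4 / spec@prePitchUm)))
  d <- nb + 2L * m
  rng <- list(x = c(m + 1L, m + nb[1]), y = c(m + 1L, m + nb[2]),
              z = c(m + 1L, m + nb[3]))
  B <- array(FALSE, d)
  B[rng$x[1]:rng$x[2], rng$y[1]:rng$y[2], rng$z[1]:rng$z[2]] <- TRUE

  # grazing slabs
  G <- array(FALSE, d)
  for (g in spec@grazedRegions) {
    fi <- .faceInfo(g$face, rng)
    fp <- if (is.null(g$footprint)) c(0, 1, 0, 1) else g$footprint
    uR <- .axisRange(rng, fi$uAxis)
    vR <- .axisRange(rng, fi$vAxis)
    u0 <- .fracToIndex(uR, fp[1]); u1 <- .fracToIndex(uR, fp[2])
    v0 <- .fracToIndex(vR, fp[3]); v1 <- .fracToIndex(vR, fp[4])
    depth <- as.integer(g$depth)
    aIdx <- fi$surf - fi$outSign * (seq_len(depth) - 1L)
    idx <- list(NULL, NULL, NULL)
    idx[[fi$outAxis]] <- aIdx
    idx[[fi$uAxis]] <- u0:u1
    idx[[fi$vAxis]] <- v0:v1
    G[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  }
  G <- G & B

  # capsule boreholes
  Mb <- array(FALSE, d)
  for (b in spec@boreholes) {
    fi <- .faceInfo(b$face, rng)
    uR <- .axisRange(rng, fi$uAxis)
    vR <- .axisRange(rng, fi$vAxis)
    p0 <- numeric(3)
    p0[fi$outAxis] <- fi$surf
    p0[fi$uAxis] <- .fracToIndex(uR, b$entry[1])
    p0[fi$vAxis] <- .fracToIndex(vR, b$entry[2])
    dir <- if (is.null(b$direction)) {
      v <- numeric(3); v[fi$outAxis] <- -fi$outSign; v
    } else b$direction / sqrt(sum(b$direction^2))
    rVox <- b$radiusUm / spec@prePitchUm
    lVox <- b$lengthUm / spec@prePitchUm
    p1 <- p0 + dir * lVox
    .checkInGrid(pmin(p0, p1) - rVox, pmax(p0, p1) + rVox, d, "borehole")
    lo <- pmax(1L, as.integer(floor(pmin(p0, p1) - rVox - 1)))
    hi <- pmin(d, as.integer(ceiling(pmax(p0, p1) + rVox + 1)))
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    rel <- sweep(pts, 2, p0)
    t <- pmin(pmax(rel %*% dir, 0), lVox)
    dist2 <- rowSums((rel - t %*% t(dir))^2)
    inside <- dist2 <= rVox^2
    Mb[pts[inside, , drop = FALSE]] <- TRUE
  }
  Mb <- Mb & B & !G

  # accretion patches (outside the original block, on exposed faces)
  Adens <- array(0, d)
  for (p in spec@accretionPatches) {
    fi <- .faceInfo(p$face, rng)
    uR <- .axisRange(rng, fi$uAxis)
    vR <- .axisRange(rng, fi$vAxis)
    uc <- .fracToIndex(uR, p$center[1])
    vc <- .fracToIndex(vR, p$center[2])
    u0 <- uc - (p$size[1] %/% 2L); u1 <- u0 + p$size[1] - 1L
    v0 <- vc - (p$size[2] %/% 2L); v1 <- v0 + p$size[2] - 1L
    aIdx <- fi$surf + fi$outSign * seq_len(as.integer(p$thickness))
    lo <- hi <- integer(3)
    lo[fi$outAxis] <- min(aIdx); hi[fi$outAxis] <- max(aIdx)
    lo[fi$uAxis] <- u0; hi[fi$uAxis] <- u1
    lo[fi$vAxis] <- v0; hi[fi$vAxis] <- v1
    .checkInGrid(lo, hi, d, "accretion patch")
    idx <- list(NULL, NULL, NULL)
    idx[[fi$outAxis]] <- aIdx
    idx[[fi$uAxis]] <- u0:u1
    idx[[fi$vAxis]] <- v0:v1
    Adens[idx[[1]], idx[[2]], idx[[3]]] <- p$density
  }
  Adens[B] <- 0
  Acc <- Adens > 0

  Rm <- B & !G & !Mb
  toAtten <- function(dens)
    (dens - spec@calibrationIntercept) / spec@calibrationSlope
  bg <- spec@backgroundAttenuation
  preVals <- array(bg, d)
  preVals[B] <- toAtten(spec@baseDensityGcc)
  modVals <- array(bg, d)
  modVals[Rm] <- toAtten(spec@baseDensityGcc *
                           (1 - spec@microboringDensityDropFrac))
  modVals[Acc] <- toAtten(Adens[Acc])

  voxVol <- (spec@prePitchUm * 1e-4)^3
  saInitial <- surfaceArea(B, spec@prePitchUm, excludeBasePlane = rng$z[1])
  ctr <- (d - 1) / 2 * spec@prePitchUm
  truthTransform <- rigidTransform(
    translation = spec@rigidOffset$translation,
    rotation = spec@rigidOffset$rotation,
    centerUm = ctr, pitchUm = spec@prePitchUm)
  counts <- c(accretion = sum(Acc), macroboring = sum(Mb), grazed = sum(G),
              remaining = sum(Rm), block = sum(B))
  truth <- new("GroundTruth",
               accretionVolumeCm3 = counts[["accretion"]] * voxVol,
               macroboringVolumeCm3 = counts[["macroboring"]] * voxVol,
               grazingVolumeCm3 = counts[["grazed"]] * voxVol,
               microboringMassLossG = spec@microboringDensityDropFrac *
                 spec@baseDensityGcc * counts[["remaining"]] * voxVol,
               initialSurfaceAreaCm2 = saInitial,
               voxelCounts = as.integer(counts) |>
                 stats::setNames(names(counts)),
               transform = truthTransform)

  preClean <- CTVolume(preVals, pitchUm = spec@prePitchUm,
                       metadata = list(scan = "pre", clean = TRUE))
  modified <- CTVolume(modVals, pitchUm = spec@prePitchUm,
                       metadata = list(scan = "post-modified", clean = TRUE))
  # the post scan must frame the block in its new pose: pad the field of
  # view by the maximum displacement the rigid offset can produce (an
  # unmoved block needs no padding, keeping the grids comparable)
  extraUm <- max(abs(spec@rigidOffset$translation)) * spec@prePitchUm +
    sin(max(abs(spec@rigidOffset$rotation)) * pi / 180) *
      max(d) / 2 * spec@prePitchUm
  if (extraUm > 0) extraUm <- extraUm + 2 * spec@postPitchUm
  dPost <- as.integer(ceiling((d * spec@prePitchUm + 2 * extraUm) /
                                spec@postPitchUm))
  postTemplate <- CTVolume(array(0, dPost), pitchUm = spec@postPitchUm,
                           origin = rep(-extraUm, 3))
  postClean <- resampleTo(modified, invertRigid(truthTransform),
                          postTemplate, background = bg)
  set.seed(spec@seed)
  preNoisy <- preVals + array(rnorm(prod(d), sd = spec@noiseSd), d)
  postNoisy <- postClean@values +
    array(rnorm(prod(dPost), sd = spec@noiseSd), dPost)
  list(pre = CTVolume(preNoisy, pitchUm = spec@prePitchUm,
                      metadata = list(scan = "pre")),
       post = CTVolume(postNoisy, pitchUm = spec@postPitchUm,
                       origin = postClean@origin,
                       metadata = list(scan = "post")),
       truth = truth, preClean = preClean, modified = modified)
}

#' Generate a set of density phantom scans
#'
#' Emulates the routine scanning of coral aragonite density standards: each
#' phantom of known density is imaged as a small uniform volume whose mean
#' attenuation satisfies `density = slope * attenuation + intercept`, plus
#' Gaussian scanner noise.
#'
#' @param densitiesGcc known phantom densities, g cm^-3 (at least 2
#'   distinct values, otherwise the calibration would be underdetermined).
#' @param slope,intercept the attenuation-to-density line realized by the
#'   simulated scan session.
#' @param noiseSd attenuation noise s.d.
#' @param seed RNG seed.
#' @param dim phantom volume dimensions, voxels.
#' @param pitchUm voxel pitch of the phantom scans.
#' @return A list with one element per phantom: `list(volume = CTVolume,
#'   density = <g cm^-3>)`, suitable for [fitDensitometry].
#' @examples
#' ph <- makePhantomSet(c(1.5, 2.5), slope = 0.01, intercept = 0.5,
#'                      noiseSd = 0)
#' mean(voxelData(ph[[1]]$volume))  # (1.5 - 0.5) / 0.01 = 100
#' @export
makePhantomSet <- function(densitiesGcc, slope, intercept, noiseSd = 0,
                           seed = 1L, dim = c(16L, 16L, 16L),
                           pitchUm = 59.51) {
  if (any(densitiesGcc <= 0)) stop("phantom densities must be positive")
  if (length(unique(densitiesGcc)) < 2L)
    stop("calibration is underdetermined: at least 2 distinct phantom densities are required")
  if (slope <= 0) stop("slope must be positive")
  set.seed(seed)
  lapply(densitiesGcc, function(dd) {
    atten <- (dd - intercept) / slope
    vals <- array(atten + rnorm(prod(dim), sd = noiseSd), dim)
    list(volume = CTVolume(vals, pitchUm = pitchUm,
                           metadata = list(phantom_density = dd)),
         density = dd)
  })
}
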