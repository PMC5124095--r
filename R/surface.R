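#' Surface area of a binary mask
#'
#' Area of the isosurface following the exterior of the block. The mask is
#' zero-padded, smoothed with a small Gaussian (an antialiasing step that
#' removes the voxel staircase), and triangulated by marching tetrahedra
#' (6-tetrahedron cube decomposition) at iso-level 0.5; the triangle areas
#' are summed. When `excludeBasePlane` is given, facets whose centroids lie
#' on or below that z-plane are dropped, the digital equivalent of removing
#' the covered bottom surface and epoxy of a mounted block.
#'
#' @param mask logical 3-D array (TRUE = solid).
#' @param pitchUm voxel pitch, micrometres.
#' @param excludeBasePlane optional z-index (1-based voxel slab) of the base:
#'   facets with centroid z at or below that slab's lower face are excluded.
#' @param smoothSigmaVox Gaussian smoothing of the indicator before
#'   triangulation, voxels (default 0.8; 0 gives the raw staircase surface,
#'   which overestimates curved areas).
#' @return Surface area, cm^2.
#' @examples
#' # 1 x 1 x 1 cm cube at 500 um pitch: 6 cm^2
#' m <- array(TRUE, c(20, 20, 20))
#' round(surfaceArea(m, 500), 1)
#' @export
surfaceArea <- function(mask, pitchUm, excludeBasePlane = NULL,
                        smoothSigmaVox = 0.8) {
  stopifnot(length(dim(mask)) == 3L, pitchUm > 0)
  if (!any(mask)) stop("empty mask has no surface")
  pad <- as.integer(ceiling(3 * smoothSigmaVox) + 2L)
  d <- dim(mask)
  dp <- d + 2L * pad
  field <- array(0, dp)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  field <- cpp_gaussian_blur(field, dp, smoothSigmaVox)
  zExclude <- NA_real_
  if (!is.null(excludeBasePlane)) {
    # lower face of the base slab sits half a voxel below its centre;
    # allow a 0.75-voxel tolerance for smoothing-induced rounding
    zExclude <- (excludeBasePlane - 1) + pad - 0.5 + 0.75
  }
  areaVox2 <- cpp_mt_area(field, dp, 0.5, zExclude)
  areaVox2 * (pitchUm * 1e-4)^2
}
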