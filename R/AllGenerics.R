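#' Accessors for volume and label objects
#'
#' `voxelData` returns the raw 3-D array, `pitchUm` the voxel pitch in
#' micrometres, `voxelOrigin` the physical origin, `voxelVolumeCm3` the
#' volume of a single voxel in cm^3 and `labelCounts` the per-class voxel
#' counts of a [LabelVolume-class].
#'
#' @param object a [CTVolume-class] or [LabelVolume-class].
#' @return See the individual descriptions.
#' @examples
#' v <- CTVolume(array(1, c(5, 5, 5)), pitchUm = 100)
#' voxelVolumeCm3(v)   # (100e-4)^3 = 1e-6 cm^3
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname volume-accessors
#' @export
setGeneric("pitchUm", function(object) standardGeneric("pitchUm"))

#' @rdname volume-accessors
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))

#' @rdname volume-accessors
#' @export
setGeneric("voxelVolumeCm3", function(object) standardGeneric("voxelVolumeCm3"))

#' @rdname volume-accessors
#' @export
setGeneric("labelCounts", function(object) standardGeneric("labelCounts"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "CTVolume", function(object) object@values)

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "LabelVolume", function(object) object@labels)

#' @rdname volume-accessors
#' @export
setMethod("pitchUm", "CTVolume", function(object) object@pitchUm)

#' @rdname volume-accessors
#' @export
setMethod("pitchUm", "LabelVolume", function(object) object@pitchUm)

#' @rdname volume-accessors
#' @export
setMethod("voxelOrigin", "CTVolume", function(object) object@origin)

#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeCm3", "CTVolume",
          function(object) (object@pitchUm * 1e-4)^3)

#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeCm3", "LabelVolume",
          function(object) (object@pitchUm * 1e-4)^3)

#' @rdname volume-accessors
#' @export
setMethod("labelCounts", "LabelVolume", function(object) {
  lv <- tabulate(object@labels + 1L, nbins = 5L)
  stats::setNames(lv, names(.LABEL_LEGEND))
})
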