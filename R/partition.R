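#' Partition registered voxels into functional-group labels
#'
#' Set algebra over the four binary masks, all on the registered pre-scan
#' grid:
#' \itemize{
#'   \item accretion = postMask \\ preHull (new carbonate outside the
#'     original block),
#'   \item grazed = preHull \\ postHull (external volume lost),
#'   \item macroboring_void = (postHull \\ postMask) intersect preHull
#'     (internal void space within the remaining block),
#'   \item original_remaining = postMask intersect preHull,
#'   \item background = everything else.
#' }
#' The labels are disjoint and exhaustive, and
#' `|preHull| = |original_remaining| + |macroboring_void| + |grazed|`
#' exactly, by construction; both facts are asserted on every run.
#'
#' @param preMask,postMask carbonate masks of the pre and registered post
#'   scans (logical 3-D arrays).
#' @param preHull,postHull solid hulls from [solidHull].
#' @param pitchUm pre-scan voxel pitch, micrometres.
#' @return A [LabelVolume-class].
#' @export
partitionVoxels <- function(preMask, postMask, preHull, postHull, pitchUm) {
  d <- dim(preMask)
  stopifnot(identical(d, dim(postMask)), identical(d, dim(preHull)),
            identical(d, dim(postHull)))
  if (!any(preMask)) stop("empty pre-scan mask: nothing to partition")
  labels <- array(.LABEL_LEGEND[["background"]], d)
  labels[postMask & !preHull] <- .LABEL_LEGEND[["accretion"]]
  labels[postMask & preHull] <- .LABEL_LEGEND[["original_remaining"]]
  labels[postHull & !postMask & preHull] <- .LABEL_LEGEND[["macroboring_void"]]
  labels[preHull & !postHull] <- .LABEL_LEGEND[["grazed"]]
  lv <- new("LabelVolume", labels = labels, pitchUm = pitchUm)
  cnt <- labelCounts(lv)
  stopifnot(sum(cnt) == prod(d))
  conserved <- cnt[["original_remaining"]] + cnt[["macroboring_void"]] +
    cnt[["grazed"]]
  if (conserved != sum(preHull))
    stop("internal error: pre-hull voxel conservation violated")
  lv
}

#' Serialize a label volume
#'
#' Writes the uint8 label codes as a raw NRRD plus a JSON legend sidecar
#' (`<path>.legend.json`).
#'
#' @param labels a [LabelVolume-class].
#' @param path output NRRD path.
#' @return `readLabelVolume` returns the [LabelVolume-class].
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  vol <- CTVolume(labels@labels + 0, pitchUm = labels@pitchUm)
  writeVolume(vol, path, format = "nrrd")
  jsonlite::write_json(as.list(.LABEL_LEGEND), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  vol <- readVolume(path, format = "nrrd")
  new("LabelVolume", labels = array(as.integer(round(vol@values)),
                                    dim(vol@values)),
      pitchUm = vol@pitchUm)
}
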