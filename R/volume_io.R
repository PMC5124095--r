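.nrrdTypeMap <- list(
  "double" = list(what = "double", size = 8L),
  "float" = list(what = "double", size = 4L),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE))

#' Read and write micro-CT volumes
#'
#' Volumes are physical objects: both formats must carry the voxel pitch.
#' NRRD files (`raw` encoding) store it in the `spacings` header field;
#' TIFF stacks store it in a JSON sidecar (`<file>.json`) with fields
#' `pitch_um` and `origin_um`. A file without pitch metadata is an error.
#' Anisotropic spacings are rejected: resample explicitly first.
#'
#' NRRD stores 64-bit doubles and round-trips exactly; TIFF stores 32-bit
#' floats, so round trips are exact only to single precision.
#'
#' @param path file path. For `format = "tiff"` the sidecar is `paste0(path,
#'   ".json")`.
#' @param format "nrrd" or "tiff"; `"auto"` (default for reading) picks by
#'   extension.
#' @param vol a [CTVolume-class].
#' @return `readVolume` returns a [CTVolume-class]; `writeVolume` invisibly
#'   returns `path`.
#' @examples
#' v <- CTVolume(array(runif(8), c(2, 2, 2)), pitchUm = 59.51)
#' p <- file.path(tempdir(), "v.nrrd")
#' writeVolume(v, p)
#' identical(voxelData(readVolume(p)), voxelData(v))
#' @export
readVolume <- function(path, format = c("auto", "nrrd", "tiff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "tiff"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nrrd") .readNrrd(path) else .readTiffStack(path)
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path, format = c("auto", "nrrd", "tiff")) {
  stopifnot(is(vol, "CTVolume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "tiff"
  if (format == "nrrd") .writeNrrd(vol, path) else .writeTiffStack(vol, path)
  invisible(path)
}

.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    hdr[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(hdr[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3-D NRRD volumes are supported")
  if (is.null(hdr[["spacings"]]))
    stop("NRRD header has no 'spacings': pitch metadata is required")
  sp <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  if (diff(range(sp)) > 1e-9 * max(sp))
    stop("anisotropic voxel spacings (", paste(sp, collapse = ", "),
         "); resample to an isotropic grid explicitly first")
  if (!is.null(hdr[["encoding"]]) && hdr[["encoding"]] != "raw")
    stop("only raw-encoded NRRD is supported")
  type <- hdr[["type"]]
  tm <- .nrrdTypeMap[[type]]
  if (is.null(tm)) stop("unsupported NRRD type: ", type)
  endian <- if (!is.null(hdr[["endian"]])) hdr[["endian"]] else "little"
  n <- prod(sizes)
  vals <- if (tm$what == "double")
    readBin(con, "double", n = n, size = tm$size, endian = endian)
  else
    readBin(con, "integer", n = n, size = tm$size, signed = tm$signed,
            endian = endian)
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]),
                                  ",")[[1]])
  CTVolume(array(as.numeric(vals), sizes), pitchUm = sp[1], origin = origin,
           metadata = list(source = path))
}

.writeNrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol@values)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           "encoding: raw",
           "endian: little",
           sprintf("spacings: %.10g %.10g %.10g", vol@pitchUm, vol@pitchUm,
                   vol@pitchUm),
           sprintf("space origin: (%.10g,%.10g,%.10g)", vol@origin[1],
                   vol@origin[2], vol@origin[3]),
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(vol@values), con, size = 8L, endian = "little")
}

.readTiffStack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("TIFF stack has no pitch sidecar (", sidecar,
         "): pitch metadata is required")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pitch_um)) stop("sidecar lacks pitch_um")
  slices <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(slices)) slices <- list(slices)
  nz <- length(slices)
  d <- dim(slices[[1]])
  # slices are stored as y-by-x matrices; undo
  arr <- array(0, c(d[2], d[1], nz))
  for (k in seq_len(nz)) arr[, , k] <- t(slices[[k]])
  if (!is.null(meta$scale) && !is.null(meta$offset))
    arr <- arr * meta$scale + meta$offset
  origin <- if (!is.null(meta$origin_um)) as.numeric(meta$origin_um) else c(0, 0, 0)
  CTVolume(arr, pitchUm = meta$pitch_um, origin = origin,
           metadata = list(source = path))
}

.writeTiffStack <- function(vol, path) {
  rng <- range(vol@values)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  offset <- rng[1]
  d <- dim(vol@values)
  slices <- lapply(seq_len(d[3]), function(k)
    t((vol@values[, , k] - offset) / scale))
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pitch_um = vol@pitchUm, origin_um = vol@origin, scale = scale,
         offset = offset),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Read or write a phantom summary table
#'
#' CSV with columns `phantom_id`, `mean_attenuation`, `density_gcc`, the
#' interchange format for densitometry calibration.
#'
#' @param path CSV path.
#' @param table data.frame with the three columns above.
#' @return `readPhantomTable` returns the data.frame.
#' @export
readPhantomTable <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("phantom_id", "mean_attenuation", "density_gcc")
  if (!all(need %in% names(tab)))
    stop("phantom table must have columns ", paste(need, collapse = ", "))
  tab
}

#' @rdname readPhantomTable
#' @export
writePhantomTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
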