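# Label-map and cohort-table IO.
#
# Label dialects map anatomical structures to integer IDs; the default is
# FreeSurfer aseg numbering (17 = left hippocampus, 53 = right hippocampus),
# onto which all supported segmentation engines can be mapped.

.dialects <- new.env(parent = emptyenv())

.init_dialects <- function() {
  if (!length(ls(.dialects)))
    assign("freesurfer-aseg", c(left = 17L, right = 53L), envir = .dialects)
}

#' Label dialects
#'
#' A label dialect names the integer IDs of the left and right hippocampus
#' in a label map. `"freesurfer-aseg"` (17/53) is registered by default;
#' users can add their own for other segmentation engines.
#'
#' @param name dialect name.
#' @param left,right integer structure IDs.
#' @return `labelDialects()` returns the registered names;
#'   `labelDialect(name)` the named ID vector; `registerLabelDialect()`
#'   (invisibly) the IDs just registered.
#' @examples
#' labelDialect("freesurfer-aseg")
#' registerLabelDialect("first", left = 1, right = 2)
#' @export
labelDialects <- function() {
  .init_dialects()
  ls(.dialects)
}

#' @rdname labelDialects
#' @export
labelDialect <- function(name) {
  .init_dialects()
  if (!exists(name, envir = .dialects, inherits = FALSE))
    stop("unknown label dialect '", name, "'; registered: ",
         paste(labelDialects(), collapse = ", "))
  get(name, envir = .dialects, inherits = FALSE)
}

#' @rdname labelDialects
#' @export
registerLabelDialect <- function(name, left, right) {
  .init_dialects()
  stopifnot(is.character(name), length(name) == 1L)
  left <- as.integer(left); right <- as.integer(right)
  if (is.na(left) || is.na(right) || left < 0 || right < 0 || left == right)
    stop("left/right IDs must be distinct non-negative integers")
  assign(name, c(left = left, right = right), envir = .dialects)
  invisible(c(left = left, right = right))
}

#' Read a NIfTI label map as a canonicalized LabelVolume
#'
#' Reads a NIfTI-1 file with integer-valued data, reorients the voxel
#' array to RAS axis order (using the header xform) and takes the voxel
#' spacing from the header. Left/right anatomy is subsequently identified
#' by label ID, so the stored orientation of the file does not matter.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [LabelVolume-class].
#' @seealso [writeLabelVolume()], [extractStructureMasks()]
#' @export
readLabelVolume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  spacing <- abs(RNifti::pixdim(img)[1:3])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate voxel spacing in NIfTI header of ", path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path)
  if (any(!is.finite(arr)) || any(arr < 0) ||
      max(abs(arr - round(arr))) > 1e-6)
    stop("label volume must contain non-negative integer values: ", path)
  LabelVolume(round(arr), spacing = spacing, orientation = "RAS")
}

#' Write a LabelVolume to NIfTI
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  img <- RNifti::asNifti(vol@labels)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract left/right hippocampus binary masks from a label volume
#'
#' @param vol a [LabelVolume-class].
#' @param dialect label dialect name (see [labelDialects()]).
#' @return A list with [BinaryMask-class] elements `left` and `right`;
#'   spacing is propagated from `vol`.
#' @export
extractStructureMasks <- function(vol, dialect = "freesurfer-aseg") {
  stopifnot(is(vol, "LabelVolume"))
  ids <- labelDialect(dialect)
  out <- list()
  for (side in c("left", "right")) {
    m <- vol@labels == ids[[side]]
    if (!any(m))
      stop("empty structure: no voxels with label ", ids[[side]],
           " (", side, " hippocampus) in volume")
    out[[side]] <- BinaryMask(m, spacing = vol@spacing)
  }
  out
}

.group_levels <- c("HC", "HS-left", "HS-right", "HS-bilateral", "EPI-other")

#' Read a cohort table
#'
#' Reads a CSV of scan records: one row per MRI with columns `subject_id`,
#' `scan_id`, `scan_date` (ISO-8601), `group` (one of HC, HS-left,
#' HS-right, HS-bilateral, EPI-other), `age` (years) and `etiv` (mm^3).
#' Additional measure columns come in `<metric>_lh` / `<metric>_rh` pairs
#' (e.g. `volume_lh`, `volume_rh`).
#'
#' @param path path to a CSV file (UTF-8, header row).
#' @return A data.frame with `scan_date` parsed as `Date` and `group` as a
#'   factor with the five canonical levels; one row per scan record.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "scan_id", "scan_date", "group", "age", "etiv")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$group %in% .group_levels)
  if (length(bad))
    stop("unknown group label '", df$group[bad[1]], "' in row ", bad[1],
         "; expected one of ", paste(.group_levels, collapse = ", "))
  bad <- which(!is.finite(df$age) | df$age <= 0)
  if (length(bad)) stop("non-positive age in row ", bad[1])
  bad <- which(!is.finite(df$etiv) | df$etiv <= 0)
  if (length(bad)) stop("non-positive eTIV in row ", bad[1])
  vol_cols <- grep("^volume_(lh|rh)$", names(df), value = TRUE)
  for (cl in vol_cols) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad)) stop("non-positive ", cl, " in row ", bad[1])
  }
  df$scan_date <- as.Date(df$scan_date)
  if (anyNA(df$scan_date)) stop("unparseable scan_date (expected ISO-8601)")
  df$group <- factor(df$group, levels = .group_levels)
  df
}

#' Write a cohort table
#'
#' @param cohort data.frame as returned by [readCohortTable()] or
#'   [generateMeasurementCohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Measure column pairs of a cohort table
#'
#' @param cohort cohort data.frame.
#' @return Character vector of metric base names that have both `_lh` and
#'   `_rh` columns.
#' @export
cohortMetrics <- function(cohort) {
  lh <- sub("_lh$", "", grep("_lh$", names(cohort), value = TRUE))
  rh <- sub("_rh$", "", grep("_rh$", names(cohort), value = TRUE))
  intersect(lh, rh)
}
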