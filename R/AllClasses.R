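#' LabelVolume: a 3D integer label map with physical voxel spacing
#'
#' Holds the voxel data of a whole-brain segmentation (e.g. FreeSurfer
#' aseg-style numbering) after canonicalization to RAS axis order
#' (indices ascending towards the right / anterior / superior), together
#' with the voxel spacing in mm. Left/right structures are identified by
#' label ID only, never by image side.
#'
#' @slot labels 3D integer array of structure IDs (non-negative).
#' @slot spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm.
#' @slot orientation three-letter axis-to-anatomy code; always "RAS" after
#'   canonicalization on load.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric",
                 orientation = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers (mm)")
    if (any(object@labels < 0) || any(object@labels != round(object@labels)))
      msg <- c(msg, "labels must be non-negative integers")
    if (length(object@orientation) != 1L || nchar(object@orientation) != 3L)
      msg <- c(msg, "orientation must be a three-letter code")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a per-structure binary voxel mask with spacing
#'
#' @slot mask 3D logical array; TRUE marks foreground voxels.
#' @slot spacing numeric length-3 voxel spacing (mm), strictly positive.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
      msg <- c(msg, "mask must be a 3D logical array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive numbers (mm)")
    if (length(msg)) msg else TRUE
  })

#' TriMesh: a closed, consistently oriented triangle mesh in mm
#'
#' Produced by [maskToMesh()]. Validity requires watertightness: every
#' directed edge occurs exactly once and its reverse exactly once.
#'
#' @slot vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @slot faces integer m x 3 matrix of 1-based vertex indices, outward
#'   oriented.
#' @exportClass TriMesh
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    if (nrow(object@faces) > 0) {
      if (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices))
        msg <- c(msg, "face indices out of range")
      else {
        cen <- cpp_edge_census(object@faces, nrow(object@vertices))
        if (!cen$closed_oriented)
          msg <- c(msg, "mesh is not closed and consistently oriented")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' NormativeModel: healthy-control linear model of a volume measure
#'
#' Ordinary least squares of a side-specific volume on z-scored eTIV and
#' age, fitted on healthy controls only; stores the HC z-scoring constants
#' so the correction can be applied to all subjects.
#'
#' @slot metric name of the modelled measure (e.g. "volume_lh").
#' @slot intercept fitted intercept, mm^3.
#' @slot beta_etiv,beta_age slopes in mm^3 per HC standard deviation of the
#'   covariate.
#' @slot covariate_means,covariate_sds named numeric (etiv, age) computed on
#'   the HC rows.
#' @slot residual_sd residual standard deviation, mm^3.
#' @slot n_hc number of HC rows used in the fit.
#' @exportClass NormativeModel
setClass("NormativeModel",
  representation(metric = "character", intercept = "numeric",
                 beta_etiv = "numeric", beta_age = "numeric",
                 covariate_means = "numeric", covariate_sds = "numeric",
                 residual_sd = "numeric", n_hc = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@covariate_sds <= 0))
      msg <- c(msg, "covariate SDs must be positive")
    if (!all(c("etiv", "age") %in% names(object@covariate_means)))
      msg <- c(msg, "covariate_means must be named etiv, age")
    if (length(msg)) msg else TRUE
  })

#' AsymmetryLimits: normative asymmetry-index mean, SD and decision limits
#'
#' Mean and sample SD of the asymmetry index over healthy-control scans,
#' with two-sided limits at mean +/- 2 SD and mean +/- 3 SD. Limits are
#' centred on the HC mean (which is slightly negative for hippocampal
#' volume), not on zero.
#'
#' @slot metric measure the limits refer to ("volume" or
#'   "surface_to_volume_ratio").
#' @slot hc_mean_ai,hc_sd_ai mean and sample SD of HC AI (dimensionless).
#' @slot n_hc number of HC scans used.
#' @slot thresholds list with elements `"2SD"` and `"3SD"`, each c(lo, hi).
#' @exportClass AsymmetryLimits
setClass("AsymmetryLimits",
  representation(metric = "character", hc_mean_ai = "numeric",
                 hc_sd_ai = "numeric", n_hc = "integer",
                 thresholds = "list"),
  validity = function(object) {
    msg <- character()
    if (object@hc_sd_ai <= 0) msg <- c(msg, "hc_sd_ai must be positive")
    if (!all(c("2SD", "3SD") %in% names(object@thresholds)))
      msg <- c(msg, "thresholds must contain 2SD and 3SD")
    for (lv in c("2SD", "3SD")) {
      th <- object@thresholds[[lv]]
      if (length(th) == 2 &&
          !(th[1] < object@hc_mean_ai && object@hc_mean_ai < th[2]))
        msg <- c(msg, sprintf("%s limits must straddle the HC mean", lv))
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  lab <- sort(unique(as.vector(object@labels)))
  cat(sprintf("LabelVolume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], object@orientation))
  cat("  labels:", paste(head(lab, 10), collapse = ", "),
      if (length(lab) > 10) "..." else "", "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask %dx%dx%d, %d foreground voxels, spacing %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], sum(object@mask), object@spacing[1],
              object@spacing[2], object@spacing[3]))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces (closed, oriented)\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "NormativeModel", function(object) {
  cat(sprintf("NormativeModel for %s (n_hc = %d)\n", object@metric, object@n_hc))
  cat(sprintf("  intercept %.1f mm^3, beta_etiv %.1f, beta_age %.1f (per HC SD), residual SD %.1f\n",
              object@intercept, object@beta_etiv, object@beta_age,
              object@residual_sd))
})

setMethod("show", "AsymmetryLimits", function(object) {
  cat(sprintf("AsymmetryLimits for %s: HC mean %.4f, SD %.4f (n = %d)\n",
              object@metric, object@hc_mean_ai, object@hc_sd_ai, object@n_hc))
  for (lv in c("2SD", "3SD")) {
    th <- object@thresholds[[lv]]
    cat(sprintf("  %s: [%.4f, %.4f]\n", lv, th[1], th[2]))
  }
})

# ---- accessors ----

#' @title Accessors for hippasym S4 objects
#' @description `labelArray`, `maskArray`, `voxelSpacing`, `meshVertices`
#'   and `meshFaces` read the corresponding slots without exposing slot
#'   syntax to callers.
#' @param x a [LabelVolume-class], [BinaryMask-class] or [TriMesh-class]
#'   object as appropriate.
#' @return The slot contents (array, numeric spacing vector, or matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
labelArray <- function(x) {
  stopifnot(is(x, "LabelVolume"))
  x@labels
}

#' @rdname accessors
#' @export
maskArray <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@mask
}

#' @rdname accessors
#' @export
meshVertices <- function(x) {
  stopifnot(is(x, "TriMesh"))
  x@vertices
}

#' @rdname accessors
#' @export
meshFaces <- function(x) {
  stopifnot(is(x, "TriMesh"))
  x@faces
}

#' Construct a BinaryMask
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  new("BinaryMask", mask = mask, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param labels 3D array of non-negative integer structure IDs.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param orientation three-letter axis code, default "RAS".
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1), orientation = "RAS") {
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
      orientation = orientation)
}
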