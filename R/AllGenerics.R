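#' Voxel volume of a gridded object
#'
#' @param x an object with a voxel grid.
#' @return Voxel volume in ml (1 ml = 1000 mm^3).
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' Grid accessor
#'
#' @param x a gridded object.
#' @return The [VoxelGrid-class] of the object.
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' Total activity of an activity image
#'
#' @param x an [ActivityImage-class].
#' @return Total activity in MBq (sum of concentration times voxel volume).
#' @export
setGeneric("totalActivityMBq", function(x) standardGeneric("totalActivityMBq"))

#' Effective half-life of a fitted decay model
#'
#' The terminal component is the positive-amplitude component with the
#' smallest rate constant; the effective half-life is ln(2) divided by that
#' rate.
#'
#' @param x a [DecayModel-class].
#' @return Effective half-life in hours.
#' @export
setGeneric("effectiveHalfLifeH",
           function(x) standardGeneric("effectiveHalfLifeH"))

#' Terminal rate constant of a fitted decay model
#'
#' @param x a [DecayModel-class].
#' @return Terminal rate constant in 1/h.
#' @export
setGeneric("terminalRatePerH",
           function(x) standardGeneric("terminalRatePerH"))

#' Evaluate a fitted decay model
#'
#' @param x a [DecayModel-class].
#' @param times times (hours) at which to evaluate the model.
#' @return Modelled activities (MBq) at \code{times}.
#' @export
setGeneric("predictActivity",
           function(x, times) standardGeneric("predictActivity"))

# -- accessors shared across the image-like classes ---------------------------

#' @describeIn voxelVolumeMl voxel volume of a grid
#' @export
setMethod("voxelVolumeMl", "VoxelGrid",
          function(x) prod(x@spacing) / 1000)

#' @describeIn voxelVolumeMl voxel volume of a mask's grid
#' @export
setMethod("voxelVolumeMl", "VoiMask", function(x) voxelVolumeMl(x@grid))

#' @describeIn voxelVolumeMl voxel volume of an activity image's grid
#' @export
setMethod("voxelVolumeMl", "ActivityImage", function(x) voxelVolumeMl(x@grid))

#' @describeIn voxelVolumeMl voxel volume of a TIA map's grid
#' @export
setMethod("voxelVolumeMl", "TIAMap", function(x) voxelVolumeMl(x@grid))

#' @describeIn voxelVolumeMl voxel volume of a dose map's grid
#' @export
setMethod("voxelVolumeMl", "DoseMap", function(x) voxelVolumeMl(x@grid))

#' @describeIn voxelGrid grid of a mask
#' @export
setMethod("voxelGrid", "VoiMask", function(x) x@grid)

#' @describeIn voxelGrid grid of an activity image
#' @export
setMethod("voxelGrid", "ActivityImage", function(x) x@grid)

#' @describeIn voxelGrid grid of a TIA map
#' @export
setMethod("voxelGrid", "TIAMap", function(x) x@grid)

#' @describeIn voxelGrid grid of a dose map
#' @export
setMethod("voxelGrid", "DoseMap", function(x) x@grid)

#' @describeIn totalActivityMBq total activity of an image
#' @export
setMethod("totalActivityMBq", "ActivityImage",
          function(x) sum(x@concentration) * voxelVolumeMl(x))

#' @describeIn terminalRatePerH terminal rate of a fitted model
#' @export
setMethod("terminalRatePerH", "DecayModel", function(x) {
  pos <- x@amplitudes > 0
  if (!any(pos)) stop("model has no positive-amplitude component")
  min(x@rates[pos])
})

#' @describeIn effectiveHalfLifeH effective half-life of a fitted model
#' @export
setMethod("effectiveHalfLifeH", "DecayModel",
          function(x) log(2) / terminalRatePerH(x))

#' @describeIn predictActivity evaluate the exponential-sum model
#' @export
setMethod("predictActivity", "DecayModel", function(x, times) {
  drop(exp(-outer(times, x@rates)) %*% x@amplitudes)
})

# -- show methods -------------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "), "voxels,",
      paste(signif(object@spacing, 4), collapse = " x "), "mm spacing\n")
})

setMethod("show", "VoiMask", function(object) {
  cat("VoiMask on", paste(object@grid@dims, collapse = " x "), "grid\n")
  if (length(object@labelNames)) {
    v <- voxelVolumeMl(object)
    for (nm in names(object@labelNames)) {
      n <- sum(object@labels == object@labelNames[[nm]])
      cat(sprintf("  %s (label %d): %d voxels, %.2f ml\n",
                  nm, object@labelNames[[nm]], n, n * v))
    }
  }
})

setMethod("show", "ActivityImage", function(object) {
  cat(sprintf(
    "ActivityImage [%s]: %s voxels, %.4g MBq total, t = %.3g h p.i.\n",
    object@nuclide, paste(object@grid@dims, collapse = " x "),
    totalActivityMBq(object), object@timePostInjection))
})

setMethod("show", "DoseKernel", function(object) {
  cat(sprintf(
    "DoseKernel [%s]: %s support, %.4g Gy/(MBq s) central, %.4g J/decay retained\n",
    object@nuclide, paste(dim(object@values), collapse = " x "),
    max(object@values), object@energyRetained))
})

setMethod("show", "TIAMap", function(object) {
  cat(sprintf("TIAMap: %s voxels, total %.4g MBq s\n",
              paste(object@grid@dims, collapse = " x "), sum(object@tia)))
})

setMethod("show", "DoseMap", function(object) {
  cat(sprintf("DoseMap: %s voxels, max %.4g Gy\n",
              paste(object@grid@dims, collapse = " x "), max(object@dose)))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s' [%s]: %d samples over %.3g-%.3g h\n",
              object@regionId, object@nuclide, length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "DecayModel", function(object) {
  cat(sprintf("DecayModel (%s): A = %s; rates (1/h) = %s; T_eff = %.4g h%s\n",
              object@kind,
              paste(signif(object@amplitudes, 4), collapse = ", "),
              paste(signif(object@rates, 4), collapse = ", "),
              tryCatch(effectiveHalfLifeH(object), error = function(e) NA),
              if (object@converged) "" else " [flagged]"))
})
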