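#' @import methods
NULL

#' VoxelGrid: geometry of a 3D voxel lattice
#'
#' Describes a regular 3D voxel lattice: array dimensions, voxel spacing and
#' the world coordinate of the grid origin. World coordinates are voxel-centre
#' based: the centre of voxel (i, j, k) (1-based indices) lies at
#' \code{origin + (index - 0.5) * spacing} on each axis.
#'
#' @slot dims integer(3), number of voxels per axis (all >= 1).
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), world coordinate (mm) of the grid corner.
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric"),
  prototype(dims = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive lengths (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite coordinates (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param dims integer(3) voxel counts.
#' @param spacing numeric voxel spacing in mm; a scalar is recycled to 3.
#' @param origin numeric(3) world coordinate of the grid corner (mm). The
#'   default centres the grid on the world origin.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(c(50, 50, 50), spacing = 2)
#' voxelVolumeMl(g)
#' @export
VoxelGrid <- function(dims, spacing = 1, origin = NULL) {
  dims <- as.integer(dims)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(origin)) origin <- -dims * spacing / 2
  new("VoxelGrid", dims = dims, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' VoiMask: integer label volume on a voxel grid
#'
#' Volume-of-interest masks. Label 0 is background; positive labels are
#' named regions, mutually exclusive per voxel.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot labels 3D integer array of region labels.
#' @slot labelNames named integer vector mapping region name -> label value.
#' @export
setClass("VoiMask",
  representation(grid = "VoxelGrid", labels = "array", labelNames = "integer")
)

setValidity("VoiMask", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), as.integer(object@grid@dims)))
    msg <- c(msg, "labels array dimensions must match grid dims")
  if (any(object@labels < 0L, na.rm = TRUE))
    msg <- c(msg, "labels must be >= 0 (0 = background)")
  if (length(object@labelNames)) {
    if (is.null(names(object@labelNames)) || any(names(object@labelNames) == ""))
      msg <- c(msg, "labelNames must be a named integer vector")
    present <- unique(as.vector(object@labels))
    absent <- setdiff(object@labelNames, present)
    if (length(absent))
      msg <- c(msg, paste("named labels absent from array:",
                          paste(absent, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ActivityImage: activity-concentration volume
#'
#' A 3D image of activity concentration (MBq/ml) with its grid geometry,
#' acquisition time post injection and nuclide tag. The functional (SPECT)
#' image stand-in for dosimetry.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot concentration 3D numeric array, MBq/ml, all >= 0.
#' @slot timePostInjection acquisition time, hours post injection.
#' @slot nuclide nuclide key, e.g. "lu177".
#' @export
setClass("ActivityImage",
  representation(grid = "VoxelGrid", concentration = "array",
                 timePostInjection = "numeric", nuclide = "character")
)

setValidity("ActivityImage", function(object) {
  msg <- character()
  if (!identical(dim(object@concentration), as.integer(object@grid@dims)))
    msg <- c(msg, "concentration array dimensions must match grid dims")
  if (any(!is.finite(object@concentration)))
    msg <- c(msg, "concentration must be finite everywhere")
  else if (any(object@concentration < 0))
    msg <- c(msg, "concentration must be >= 0 everywhere")
  if (length(msg)) msg else TRUE
})

#' DoseKernel: voxel S-value kernel
#'
#' Centred 3D array of voxel S values: absorbed dose (Gy) to a voxel at each
#' offset per unit time-integrated activity (MBq s) in the source voxel.
#' Dimensions are odd so the zero offset is the central element.
#'
#' @slot values 3D numeric array, Gy per (MBq s), odd dimensions.
#' @slot spacing numeric(3) voxel spacing (mm) the kernel was built on.
#' @slot nuclide nuclide key.
#' @slot energyRetained energy (J) deposited per decay within the kernel
#'   support; the remainder escaped truncation.
#' @export
setClass("DoseKernel",
  representation(values = "array", spacing = "numeric", nuclide = "character",
                 energyRetained = "numeric")
)

setValidity("DoseKernel", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || any(d %% 2L == 0L))
    msg <- c(msg, "kernel array must be 3D with odd dimensions")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "kernel values must be finite and >= 0")
  else {
    ctr <- (d + 1L) %/% 2L
    if (object@values[ctr[1], ctr[2], ctr[3]] < max(object@values))
      msg <- c(msg, "central kernel element must be the maximum")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive lengths (mm)")
  if (length(object@energyRetained) != 1L || object@energyRetained < 0)
    msg <- c(msg, "energyRetained must be a single non-negative energy (J)")
  if (length(msg)) msg else TRUE
})

#' TIAMap: per-voxel time-integrated activity
#'
#' @slot grid a [VoxelGrid-class].
#' @slot tia 3D numeric array of time-integrated activity (MBq s), >= 0.
#' @slot provenance list of the integration settings that produced the map
#'   (mode, tail_mode, head_mode).
#' @export
setClass("TIAMap",
  representation(grid = "VoxelGrid", tia = "array", provenance = "list")
)

setValidity("TIAMap", function(object) {
  msg <- character()
  if (!identical(dim(object@tia), as.integer(object@grid@dims)))
    msg <- c(msg, "tia array dimensions must match grid dims")
  if (any(!is.finite(object@tia)) || any(object@tia < 0))
    msg <- c(msg, "tia must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' DoseMap: per-voxel absorbed dose
#'
#' @slot grid a [VoxelGrid-class].
#' @slot dose 3D numeric array of absorbed dose (Gy), >= 0.
#' @export
setClass("DoseMap",
  representation(grid = "VoxelGrid", dose = "array")
)

setValidity("DoseMap", function(object) {
  msg <- character()
  if (!identical(dim(object@dose), as.integer(object@grid@dims)))
    msg <- c(msg, "dose array dimensions must match grid dims")
  if (any(!is.finite(object@dose)) || any(object@dose < 0))
    msg <- c(msg, "dose must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' TimeActivityCurve: sampled organ or region activity over time
#'
#' @slot regionId region name.
#' @slot times sample times, hours post injection, strictly increasing, > 0.
#' @slot activities activities at the sample times, MBq, >= 0.
#' @slot nuclide nuclide key.
#' @export
setClass("TimeActivityCurve",
  representation(regionId = "character", times = "numeric",
                 activities = "numeric", nuclide = "character")
)

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@times) < 1L)
    msg <- c(msg, "at least one sample is required")
  if (length(object@times) != length(object@activities))
    msg <- c(msg, "times and activities must have equal length")
  if (any(object@times <= 0) || any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing and > 0")
  if (any(object@activities < 0))
    msg <- c(msg, "activities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeActivityCurve
#'
#' @param regionId region name.
#' @param times sample times (hours post injection).
#' @param activities activities (MBq).
#' @param nuclide nuclide key (default "lu177").
#' @return A [TimeActivityCurve-class] object.
#' @examples
#' tac <- TimeActivityCurve("kidneys", c(1, 4, 24, 44, 72),
#'                          100 * exp(-0.02 * c(1, 4, 24, 44, 72)))
#' @export
TimeActivityCurve <- function(regionId, times, activities, nuclide = "lu177") {
  new("TimeActivityCurve", regionId = as.character(regionId),
      times = as.numeric(times), activities = as.numeric(activities),
      nuclide = nuclide)
}

#' DecayModel: fitted time-activity model
#'
#' Sum-of-exponentials model A(t) = sum_i amplitude_i * exp(-rate_i * t).
#' Negative amplitudes encode an uptake phase. The terminal component is the
#' one with the smallest rate among positive-amplitude components; the
#' effective half-life is ln(2) / terminal rate.
#'
#' @slot kind one of "monoexp", "biexp", "linear_uptake_monoexp".
#' @slot amplitudes component amplitudes, MBq.
#' @slot rates component rate constants, 1/h, all > 0.
#' @slot converged logical, FALSE if the fit was flagged (e.g. non-decaying
#'   data or a bi-exponential fit that fell back to mono-exponential).
#' @slot notes character, diagnostic notes on fallbacks/flags.
#' @export
setClass("DecayModel",
  representation(kind = "character", amplitudes = "numeric", rates = "numeric",
                 converged = "logical", notes = "character")
)

setValidity("DecayModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("monoexp", "biexp", "linear_uptake_monoexp"))
    msg <- c(msg, "kind must be monoexp, biexp or linear_uptake_monoexp")
  if (length(object@amplitudes) != length(object@rates))
    msg <- c(msg, "amplitudes and rates must have equal length")
  if (any(object@rates <= 0))
    msg <- c(msg, "rate constants must be > 0")
  if (object@kind == "biexp" && length(object@rates) == 2L &&
      abs(diff(object@rates)) < 1e-12)
    msg <- c(msg, "biexp requires two distinct rates")
  if (length(msg)) msg else TRUE
})
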