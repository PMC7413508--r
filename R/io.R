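# NIfTI IO for activity images, masks and dose maps. Voxel spacing goes in
# pixdim; the world origin is carried in the sform translation.

niftiFromArray <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid@spacing
  img
}

gridFromNifti <- function(img) {
  VoxelGrid(dim(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Write an activity image as NIfTI
#'
#' Concentration is stored as floating MBq/ml.
#'
#' @param image an [ActivityImage-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeActivityNifti <- function(image, path) {
  stopifnot(is(image, "ActivityImage"))
  RNifti::writeNifti(niftiFromArray(image@concentration, image@grid), path)
  invisible(path)
}

#' Read an activity image from NIfTI
#'
#' @param path NIfTI file path.
#' @param timePostInjection acquisition time, hours post injection.
#' @param nuclide nuclide key.
#' @return An [ActivityImage-class].
#' @export
readActivityNifti <- function(path, timePostInjection = 0,
                              nuclide = "lu177") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  new("ActivityImage", grid = gridFromNifti(img), concentration = arr,
      timePostInjection = timePostInjection, nuclide = nuclide)
}

#' Write a VOI mask as NIfTI
#'
#' Labels are stored as integers; the label-name mapping goes to a sidecar
#' CSV (same path with extension .labels.csv).
#'
#' @param mask a [VoiMask-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMaskNifti <- function(mask, path) {
  stopifnot(is(mask, "VoiMask"))
  RNifti::writeNifti(niftiFromArray(mask@labels, mask@grid), path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.csv")
  write.csv(data.frame(label = unname(mask@labelNames),
                       name = names(mask@labelNames)),
            sidecar, row.names = FALSE)
  invisible(path)
}

#' Read a VOI mask from NIfTI
#'
#' @param path NIfTI file path; the sidecar .labels.csv written by
#'   [writeMaskNifti()] is picked up when present.
#' @return A [VoiMask-class].
#' @export
readMaskNifti <- function(path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim(img))
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.csv")
  nm <- integer(0)
  if (file.exists(sidecar)) {
    df <- read.csv(sidecar, stringsAsFactors = FALSE)
    nm <- df$label; names(nm) <- df$name
    nm <- as.integer(nm); names(nm) <- df$name
  }
  new("VoiMask", grid = gridFromNifti(img), labels = labels, labelNames = nm)
}

#' Write a dose map as NIfTI
#'
#' @param doseMap a [DoseMap-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDoseNifti <- function(doseMap, path) {
  stopifnot(is(doseMap, "DoseMap"))
  RNifti::writeNifti(niftiFromArray(doseMap@dose, doseMap@grid), path)
  invisible(path)
}
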