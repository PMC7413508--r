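# Nuclide constants are read from a YAML config so users can edit or extend
# them without touching code. All energies are mean energy per decay.

.nuclide_cache <- new.env(parent = emptyenv())

#' Nuclide physical constants
#'
#' Reads the packaged nuclide-data config (or a user-supplied one) and
#' returns the constants for one nuclide: physical half-life, mean electron
#' (non-penetrating) energy per decay and mean photon energy per decay.
#'
#' @param nuclide nuclide key, e.g. \code{"lu177"}.
#' @param file optional path to a YAML nuclide config; defaults to the
#'   packaged file.
#' @return A list with elements \code{half_life_days}, \code{half_life_h},
#'   \code{lambda_per_h}, \code{lambda_per_s}, \code{electron_energy_MeV},
#'   \code{electron_energy_J}, \code{photon_energy_MeV},
#'   \code{photon_energy_J}.
#' @examples
#' nuclideData("lu177")$half_life_days
#' @export
nuclideData <- function(nuclide = "lu177", file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "nuclides.yaml", package = "voxdose")
  key <- paste(file, nuclide, sep = "::")
  if (!is.null(.nuclide_cache[[key]])) return(.nuclide_cache[[key]])
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg[[nuclide]]))
    stop("nuclide '", nuclide, "' not found in ", file)
  nd <- cfg[[nuclide]]
  mev_to_j <- 1.602176634e-13
  out <- list(
    half_life_days = nd$half_life_days,
    half_life_h = nd$half_life_days * 24,
    lambda_per_h = log(2) / (nd$half_life_days * 24),
    lambda_per_s = log(2) / (nd$half_life_days * 86400),
    electron_energy_MeV = nd$electron_energy_MeV,
    electron_energy_J = nd$electron_energy_MeV * mev_to_j,
    photon_energy_MeV = nd$photon_energy_MeV,
    photon_energy_J = nd$photon_energy_MeV * mev_to_j
  )
  .nuclide_cache[[key]] <- out
  out
}
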