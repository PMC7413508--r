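# Synthetic voxel phantoms: analytic shapes rasterized onto a VoxelGrid,
# activity painting, and SPECT-like degradation (PSF blur + Poisson noise).
#
# Shape parameter conventions (only total volume is constrained by the
# published phantom descriptions; aspect ratios are fixed package defaults,
# overridable through `params`):
#   sphere    : radius solved from V = 4/3 pi r^3
#   cylinder  : height = diameter unless both given; V = 2 pi r^3
#   ellipsoid : semi-axis ratios a:b:c = 1.6:1.2:1 (solved to volume)
#   torus     : major:minor radius R:r = 3:1; V = 2 pi^2 R r^2
#   pear      : piriform = union of two fused spheres, radius ratio 1.6:1,
#               centre separation equal to the large radius; scaled to volume
#   tube      : finite cylinder, length:diameter = 4:1; V = 8 pi r^3

#' Specify an analytic phantom shape
#'
#' @param kind one of "sphere", "cylinder", "ellipsoid", "torus", "pear",
#'   "tube".
#' @param targetVolumeMl target analytic volume in ml (> 0).
#' @param center world coordinate of the shape centre (mm).
#' @param name region name; defaults to the kind.
#' @param params optional shape-specific overrides: \code{aspect} (ellipsoid
#'   semi-axis ratios), \code{radius_ratio} (torus R:r), \code{height_mm}
#'   (cylinder), \code{length_to_diameter} (tube).
#' @return A list of class "ShapeSpec".
#' @examples
#' sp <- shapeSpec("torus", targetVolumeMl = 9.7)
#' equivalentDiameterMm(sp)
#' @export
shapeSpec <- function(kind, targetVolumeMl, center = c(0, 0, 0),
                      name = kind, params = list()) {
  kind <- match.arg(kind,
    c("sphere", "cylinder", "ellipsoid", "torus", "pear", "tube"))
  stopifnot(is.numeric(targetVolumeMl), length(targetVolumeMl) == 1L,
            targetVolumeMl > 0, length(center) == 3L)
  structure(list(kind = kind, target_volume_ml = targetVolumeMl,
                 center = as.numeric(center), name = name, params = params),
            class = "ShapeSpec")
}

#' Equivalent sphere diameter of a shape or volume
#'
#' The diameter of the sphere with the same volume, d = (6 V / pi)^(1/3);
#' the convention used to name geometric phantom inserts.
#'
#' @param x a "ShapeSpec" or a volume in ml.
#' @return Equivalent diameter in mm.
#' @export
equivalentDiameterMm <- function(x) {
  v_ml <- if (inherits(x, "ShapeSpec")) x$target_volume_ml else x
  (6 * v_ml * 1000 / pi)^(1 / 3)
}

# Solve shape parameters so the analytic volume matches the target.
# Returns inside(dx,dy,dz) on centred mm coordinates, the half extent (mm)
# and the solved parameters.
solveShape <- function(spec) {
  v_mm3 <- spec$target_volume_ml * 1000
  p <- spec$params
  switch(spec$kind,
    sphere = {
      r <- (3 * v_mm3 / (4 * pi))^(1 / 3)
      list(inside = function(x, y, z) x^2 + y^2 + z^2 <= r^2,
           halfExtent = rep(r, 3), params = list(radius_mm = r))
    },
    cylinder = {
      if (!is.null(p$height_mm)) {
        h <- p$height_mm
        r <- sqrt(v_mm3 / (pi * h))
      } else {
        r <- (v_mm3 / (2 * pi))^(1 / 3)  # height = diameter
        h <- 2 * r
      }
      list(inside = function(x, y, z) x^2 + y^2 <= r^2 & abs(z) <= h / 2,
           halfExtent = c(r, r, h / 2),
           params = list(radius_mm = r, height_mm = h))
    },
    ellipsoid = {
      aspect <- if (!is.null(p$aspect)) p$aspect else c(1.6, 1.2, 1.0)
      s <- (3 * v_mm3 / (4 * pi * prod(aspect)))^(1 / 3)
      ax <- s * aspect
      list(inside = function(x, y, z)
             (x / ax[1])^2 + (y / ax[2])^2 + (z / ax[3])^2 <= 1,
           halfExtent = ax, params = list(semi_axes_mm = ax))
    },
    torus = {
      ratio <- if (!is.null(p$radius_ratio)) p$radius_ratio else 3
      r <- (v_mm3 / (2 * pi^2 * ratio))^(1 / 3)
      R <- ratio * r
      list(inside = function(x, y, z)
             (sqrt(x^2 + y^2) - R)^2 + z^2 <= r^2,
           halfExtent = c(R + r, R + r, r),
           params = list(major_radius_mm = R, minor_radius_mm = r))
    },
    pear = {
      # unit configuration: body sphere r1 = 1 at z1, neck sphere r2 = 1/1.6
      # at z1 + 1; union volume from the sphere-sphere lens formula, then
      # the whole solid is scaled uniformly to the target volume
      r1 <- 1; r2 <- 1 / 1.6; d <- 1
      lens <- pi * (r1 + r2 - d)^2 *
        (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
        (12 * d)
      v_unit <- 4 / 3 * pi * (r1^3 + r2^3) - lens
      s <- (v_mm3 / v_unit)^(1 / 3)
      zc <- (d + r2 - r1) / 2            # centre the z extent
      z1 <- -zc * s; z2 <- (d - zc) * s
      list(inside = function(x, y, z)
             (x^2 + y^2 + (z - z1)^2 <= (r1 * s)^2) |
             (x^2 + y^2 + (z - z2)^2 <= (r2 * s)^2),
           halfExtent = c(r1 * s, r1 * s, (r1 + d + r2) / 2 * s),
           params = list(body_radius_mm = r1 * s, neck_radius_mm = r2 * s,
                         separation_mm = d * s))
    },
    tube = {
      ld <- if (!is.null(p$length_to_diameter)) p$length_to_diameter else 4
      r <- (v_mm3 / (2 * ld * pi))^(1 / 3)
      L <- 2 * ld * r
      list(inside = function(x, y, z) x^2 + y^2 <= r^2 & abs(z) <= L / 2,
           halfExtent = c(r, r, L / 2),
           params = list(radius_mm = r, length_mm = L))
    }
  )
}

#' Rasterize an analytic shape onto a voxel grid
#'
#' A voxel is included when at least half of its supersample points (the
#' voxel centre when \code{supersample = 1}) lie inside the analytic surface.
#' Shape parameters are solved so the analytic volume equals the target
#' volume at the fixed aspect ratios; the rasterized volume converges to it
#' as voxel size shrinks.
#'
#' @param spec a [shapeSpec()].
#' @param grid a [VoxelGrid-class].
#' @param supersample integer >= 1, points per voxel edge.
#' @return A [VoiMask-class] with the shape as label 1.
#' @examples
#' g <- VoxelGrid(c(48, 48, 48), spacing = 1)
#' m <- rasterizeShape(shapeSpec("sphere", 28.73), g)
#' sum(m@labels == 1L) * voxelVolumeMl(g)  # ~ 28.73 ml
#' @export
rasterizeShape <- function(spec, grid, supersample = 1L) {
  stopifnot(inherits(spec, "ShapeSpec"), is(grid, "VoxelGrid"),
            supersample >= 1L)
  supersample <- as.integer(supersample)
  sol <- solveShape(spec)
  lo <- grid@origin
  hi <- grid@origin + grid@dims * grid@spacing
  if (any(spec$center - sol$halfExtent < lo) ||
      any(spec$center + sol$halfExtent > hi))
    stop("shape '", spec$name, "' exceeds grid bounds")

  # index window covering the shape
  i0 <- pmax(1L, floor((spec$center - sol$halfExtent - lo) / grid@spacing))
  i1 <- pmin(grid@dims,
             ceiling((spec$center + sol$halfExtent - lo) / grid@spacing) + 1L)
  idx <- lapply(1:3, function(a) seq.int(i0[a], i1[a]))
  ctr <- lapply(1:3, function(a)
    lo[a] + (idx[[a]] - 0.5) * grid@spacing[a] - spec$center[a])
  nx <- length(ctr[[1]]); ny <- length(ctr[[2]]); nz <- length(ctr[[3]])

  sub <- ((seq_len(supersample) - 0.5) / supersample) - 0.5
  counts <- array(0L, c(nx, ny, nz))
  X <- array(ctr[[1]], c(nx, ny, nz))
  Y <- aperm(array(ctr[[2]], c(ny, nx, nz)), c(2, 1, 3))
  Z <- aperm(array(ctr[[3]], c(nz, nx, ny)), c(2, 3, 1))
  for (ox in sub) for (oy in sub) for (oz in sub) {
    counts <- counts + sol$inside(X + ox * grid@spacing[1],
                                  Y + oy * grid@spacing[2],
                                  Z + oz * grid@spacing[3])
  }
  labels <- array(0L, grid@dims)
  labels[idx[[1]], idx[[2]], idx[[3]]] <-
    as.integer(2L * counts >= supersample^3)
  nm <- c(1L); names(nm) <- spec$name
  if (!any(labels == 1L))
    stop("shape '", spec$name, "' rasterized to zero voxels; grid too coarse")
  new("VoiMask", grid = grid, labels = labels, labelNames = nm)
}

#' Rasterize a multi-insert phantom recipe
#'
#' @param recipe a phantom recipe list (see [loadPhantomRecipe()]).
#' @param grid a [VoxelGrid-class].
#' @param supersample points per voxel edge for [rasterizeShape()].
#' @return A [VoiMask-class] with one label per insert (in recipe order).
#' @export
rasterizePhantom <- function(recipe, grid, supersample = 1L) {
  labels <- array(0L, grid@dims)
  nms <- integer(0)
  for (i in seq_along(recipe$inserts)) {
    ins <- recipe$inserts[[i]]
    ctr <- if (!is.null(ins$center_mm)) unlist(ins$center_mm) else c(0, 0, 0)
    spec <- shapeSpec(ins$kind, ins$volume_ml, center = ctr, name = ins$name)
    m <- rasterizeShape(spec, grid, supersample)
    hit <- m@labels == 1L
    if (any(labels[hit] != 0L))
      stop("insert '", ins$name, "' overlaps a previously placed insert")
    labels[hit] <- i
    nms[ins$name] <- i
  }
  new("VoiMask", grid = grid, labels = labels, labelNames = nms)
}

#' Load a phantom recipe
#'
#' Recipes are YAML files listing inserts (name, kind, volume in ml,
#' activity concentration in MBq/ml, optional centre in mm) and a background
#' concentration. Recipes emulating the three published physical phantoms
#' (cylindrical, geometrical, anthropomorphic) are shipped with the package.
#'
#' @param x a packaged recipe name ("cylindrical", "geometrical",
#'   "anthropomorphic") or a path to a YAML recipe file.
#' @return The recipe as a named list.
#' @examples
#' rec <- loadPhantomRecipe("geometrical")
#' sapply(rec$inserts, `[[`, "name")
#' @export
loadPhantomRecipe <- function(x) {
  path <- if (file.exists(x)) x else
    system.file("extdata", "recipes", paste0(x, ".yaml"), package = "voxdose")
  if (path == "" || !file.exists(path))
    stop("no recipe file or packaged recipe named '", x, "'")
  yaml::read_yaml(path)
}

#' Paint activity concentrations onto a label mask
#'
#' @param mask a [VoiMask-class].
#' @param concentrations named numeric vector, MBq/ml per region name.
#' @param background background concentration (MBq/ml) for label 0.
#' @param timePostInjection acquisition time tag, hours post injection.
#' @param nuclide nuclide key.
#' @return An [ActivityImage-class].
#' @examples
#' g <- VoxelGrid(c(40, 40, 40), spacing = 2)
#' m <- rasterizeShape(shapeSpec("sphere", 28.5, name = "E38"), g)
#' img <- paintActivity(m, c(E38 = 1.53), background = 0)
#' totalActivityMBq(img)
#' @export
paintActivity <- function(mask, concentrations, background = 0,
                          timePostInjection = 0, nuclide = "lu177") {
  stopifnot(is(mask, "VoiMask"), background >= 0)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(concentrations), names(mask@labelNames))
  if (length(unknown))
    stop("unknown labels in concentration mapping: ",
         paste(unknown, collapse = ", "))
  conc <- array(background, dim(mask@labels))
  for (nm in names(concentrations))
    conc[mask@labels == mask@labelNames[[nm]]] <- concentrations[[nm]]
  new("ActivityImage", grid = mask@grid, concentration = conc,
      timePostInjection = as.numeric(timePostInjection), nuclide = nuclide)
}

#' Paint a full phantom recipe
#'
#' Convenience wrapper: rasterizes a recipe and paints its concentrations.
#'
#' @inheritParams rasterizePhantom
#' @param timePostInjection acquisition time tag, hours post injection.
#' @return A list with elements \code{mask} ([VoiMask-class]) and
#'   \code{image} ([ActivityImage-class]).
#' @export
buildPhantom <- function(recipe, grid, supersample = 1L,
                         timePostInjection = 0) {
  mask <- rasterizePhantom(recipe, grid, supersample)
  conc <- vapply(recipe$inserts, `[[`, numeric(1), "concentration_MBq_per_ml")
  names(conc) <- vapply(recipe$inserts, `[[`, character(1), "name")
  bg <- if (!is.null(recipe$background_MBq_per_ml))
    recipe$background_MBq_per_ml else 0
  list(mask = mask,
       image = paintActivity(mask, conc, background = bg,
                             timePostInjection = timePostInjection))
}

# Separable Gaussian blur kernel with voxel-integrated (erf) weights; each
# 1D factor sums to 1 over infinite support, truncated at 4 sigma and
# renormalized so the discrete kernel has exactly unit sum.
gaussianKernel3d <- function(fwhm_mm, spacing) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  k1 <- lapply(1:3, function(a) {
    if (sigma <= 0) return(1)
    h <- max(1L, ceiling(4 * sigma / spacing[a]))
    x <- (-h:h) * spacing[a]
    w <- pnorm(x + spacing[a] / 2, sd = sigma) -
         pnorm(x - spacing[a] / 2, sd = sigma)
    w / sum(w)
  })
  k <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  array(k, c(length(k1[[1]]), length(k1[[2]]), length(k1[[3]])))
}

#' Apply SPECT-like degradation to an activity image
#'
#' Emulates the resolution loss and counting noise of a reconstructed SPECT
#' image: an isotropic Gaussian point-spread function of the stated FWHM,
#' optionally followed by Poisson resampling of the counts in each voxel at
#' a stated calibration (counts per MBq). The blur kernel has unit sum, so
#' total activity is preserved up to truncation at the grid boundary. The
#' real reconstruction chain (projection, attenuation, scatter, iterative
#' reconstruction) is deliberately not modelled.
#'
#' @param image an [ActivityImage-class].
#' @param psfFwhmMm Gaussian PSF full width at half maximum, mm (>= 0;
#'   0 returns the input unchanged).
#' @param noiseSeed integer seed for Poisson resampling, or NULL for no
#'   noise.
#' @param countsPerMBq calibration factor for the Poisson branch.
#' @return A degraded [ActivityImage-class].
#' @export
simulateSpect <- function(image, psfFwhmMm, noiseSeed = NULL,
                          countsPerMBq = 1000) {
  stopifnot(is(image, "ActivityImage"))
  if (psfFwhmMm < 0) stop("psfFwhmMm must be >= 0")
  conc <- image@concentration
  if (psfFwhmMm > 0) {
    k <- gaussianKernel3d(psfFwhmMm, image@grid@spacing)
    conc <- fftConvolve3d(conc, k)
    conc[conc < 0] <- 0
  }
  if (!is.null(noiseSeed)) {
    v <- voxelVolumeMl(image)
    counts <- conc * v * countsPerMBq
    set.seed(as.integer(noiseSeed))
    conc <- array(rpois(length(counts), counts), dim(counts)) /
      (v * countsPerMBq)
  }
  new("ActivityImage", grid = image@grid, concentration = conc,
      timePostInjection = image@timePostInjection, nuclide = image@nuclide)
}

#' Count exposed voxel faces of a mask label
#'
#' Surface area proxy used to compare shape compactness on rasterized masks:
#' the number of voxel faces whose neighbour lies outside the region,
#' multiplied by the face area.
#'
#' @param mask a [VoiMask-class].
#' @param label label value (default 1).
#' @return Surface area estimate in mm^2.
#' @export
maskSurfaceAreaMm2 <- function(mask, label = 1L) {
  b <- mask@labels == label
  d <- dim(b)
  sp <- mask@grid@spacing
  shift_diff <- function(axis) {
    pad <- d; pad[axis] <- 1L
    padded <- array(FALSE, d + c(axis == 1, axis == 2, axis == 3) * 2L)
    ix <- lapply(1:3, function(a) seq_len(d[a]) + (a == axis))
    padded[ix[[1]], ix[[2]], ix[[3]]] <- b
    up <- lapply(1:3, function(a) seq_len(d[a]) + 2L * (a == axis))
    dn <- lapply(1:3, function(a) seq_len(d[a]))
    sum(b & !padded[up[[1]], up[[2]], up[[3]]]) +
      sum(b & !padded[dn[[1]], dn[[2]], dn[[3]]])
  }
  areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  sum(vapply(1:3, shift_diff, numeric(1)) * areas)
}
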