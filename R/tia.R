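# Time-integrated activity (TIA): curve fitting and the trapezoid +
# analytic-tail integration rule. All TIA values are in MBq s; sample times
# are hours (converted internally).

#' Fit a mono-exponential decay model
#'
#' Least-squares fit of \eqn{A(t) = A_0 e^{-\lambda t}} on the linear scale,
#' seeded deterministically by log-linear regression. If the fitted rate is
#' not positive (non-decaying data) the model is returned flagged
#' (\code{converged = FALSE}) with the rate clamped to the physical decay
#' constant; the caller decides how to proceed.
#'
#' @param curve a [TimeActivityCurve-class] with >= 2 positive samples.
#' @return A [DecayModel-class] of kind "monoexp".
#' @examples
#' t <- c(1, 4, 24, 44, 72)
#' m <- fitMonoexp(TimeActivityCurve("k", t, 100 * exp(-log(2) / 40 * t)))
#' effectiveHalfLifeH(m)  # 40 h
#' @export
fitMonoexp <- function(curve) {
  stopifnot(is(curve, "TimeActivityCurve"))
  keep <- curve@activities > 0
  if (sum(keep) < 2L)
    stop("mono-exponential fit needs >= 2 samples with positive activity")
  t <- curve@times[keep]; a <- curve@activities[keep]
  ll <- lm(log(a) ~ t)
  lam0 <- -coef(ll)[[2]]; A0 <- exp(coef(ll)[[1]])
  if (lam0 <= 0) {
    lam_phys <- nuclideData(curve@nuclide)$lambda_per_h
    return(new("DecayModel", kind = "monoexp", amplitudes = A0,
               rates = lam_phys, converged = FALSE,
               notes = "non-decaying data: rate clamped to physical decay"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A * exp(-l * t), start = list(A = A0, l = lam0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || coef(fit)[["l"]] <= 0)
    return(new("DecayModel", kind = "monoexp", amplitudes = A0, rates = lam0,
               converged = FALSE, notes = "refinement failed; log-linear fit"))
  cf <- coef(fit)
  new("DecayModel", kind = "monoexp", amplitudes = cf[["A"]],
      rates = cf[["l"]], converged = TRUE, notes = character(0))
}

#' Fit a bi-exponential model
#'
#' Least-squares fit of \eqn{A(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}}
#' with unconstrained amplitude signs, so uptake-shaped curves (negative fast
#' amplitude) are representable. Rate seeds come from a deterministic
#' curve-peeling of the terminal samples; no random starts. On failure the
#' fit falls back to [fitMonoexp()] and the result is flagged.
#'
#' @param curve a [TimeActivityCurve-class] with >= 4 samples.
#' @return A [DecayModel-class] of kind "biexp" (or the flagged
#'   mono-exponential fallback).
#' @export
fitBiexp <- function(curve) {
  stopifnot(is(curve, "TimeActivityCurve"))
  if (length(curve@times) < 4L) stop("bi-exponential fit needs >= 4 samples")
  t <- curve@times; a <- curve@activities
  # terminal seed: log-linear on the last half of positive samples
  tail_n <- max(2L, ceiling(length(t) / 2))
  it <- seq.int(length(t) - tail_n + 1L, length(t))
  pos <- it[a[it] > 0]
  if (length(pos) < 2L) pos <- which(a > 0)
  ll <- lm(log(a[pos]) ~ t[pos])
  l2 <- max(-coef(ll)[[2]], 1e-4); A2 <- exp(coef(ll)[[1]])
  resid1 <- a[1] - A2 * exp(-l2 * t[1])
  A1 <- resid1           # positive -> fast-clearing extra; negative -> uptake
  l1 <- l2 * 8
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                      start = list(A1 = A1, l1 = l1, A2 = A2, l2 = l2),
                      lower = c(-Inf, 1e-6, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  ok <- !is.null(fit)
  if (ok) {
    cf <- coef(fit)
    ok <- all(is.finite(cf)) && cf[["l1"]] > 0 && cf[["l2"]] > 0 &&
      (cf[["A1"]] > 0 || cf[["A2"]] > 0) &&
      abs(cf[["l1"]] - cf[["l2"]]) > 1e-10
  }
  if (!ok) {
    mono <- fitMonoexp(curve)
    return(new("DecayModel", kind = "monoexp", amplitudes = mono@amplitudes,
               rates = mono@rates, converged = FALSE,
               notes = "bi-exponential fit failed; mono-exponential fallback"))
  }
  cf <- coef(fit)
  # order components fast -> slow
  o <- order(c(cf[["l1"]], cf[["l2"]]), decreasing = TRUE)
  new("DecayModel", kind = "biexp",
      amplitudes = c(cf[["A1"]], cf[["A2"]])[o],
      rates = c(cf[["l1"]], cf[["l2"]])[o],
      converged = TRUE, notes = character(0))
}

#' Integrate a time-activity curve to time-integrated activity
#'
#' The published integration rule: trapezoid between the first and the last
#' sample, analytic extrapolation outside. The tail beyond the last sample is
#' \eqn{A(t_N)/\lambda} with the effective rate (from a fitted model's
#' terminal component) or the physical decay constant. The head before the
#' first sample is selectable: a triangle from (0, 0) to the first sample
#' (default; organ activity is zero at injection), a constant at the first
#' sample's activity, or nothing.
#'
#' @param curve a [TimeActivityCurve-class].
#' @param tailMode "effective" (needs \code{model}) or "physical".
#' @param headMode "triangle", "none" or "constant".
#' @param model a fitted [DecayModel-class]; required when
#'   \code{tailMode = "effective"}.
#' @return A data.frame (one row) with columns \code{region_id},
#'   \code{tia_MBqs}, \code{head_MBqs}, \code{trapezoid_MBqs},
#'   \code{tail_MBqs}, \code{tail_mode}. Parts satisfy
#'   tia = head + trapezoid + tail.
#' @examples
#' # single scan, physical tail: TIA = A / lambda_phys
#' tac <- TimeActivityCurve("insert", 24, 10)
#' integrateTia(tac, tailMode = "physical", headMode = "none")
#' @export
integrateTia <- function(curve, tailMode = c("effective", "physical"),
                         headMode = c("triangle", "none", "constant"),
                         model = NULL) {
  stopifnot(is(curve, "TimeActivityCurve"))
  tailMode <- match.arg(tailMode)
  headMode <- match.arg(headMode)
  t <- curve@times; a <- curve@activities
  n <- length(t)
  if (n == 1L && !(headMode == "none" && tailMode == "physical"))
    stop("a single-sample curve requires headMode = 'none' and ",
         "tailMode = 'physical'")
  lam_h <- if (tailMode == "physical") {
    nuclideData(curve@nuclide)$lambda_per_h
  } else {
    if (is.null(model)) stop("tailMode = 'effective' requires a fitted model")
    terminalRatePerH(model)
  }
  if (lam_h <= 0) stop("tail rate constant must be > 0")
  head_h <- switch(headMode,
                   triangle = 0.5 * t[1] * a[1],
                   constant = t[1] * a[1],
                   none = 0)
  trap_h <- if (n > 1L) pracma::trapz(t, a) else 0
  tail_h <- a[n] / lam_h
  data.frame(region_id = curve@regionId,
             tia_MBqs = (head_h + trap_h + tail_h) * 3600,
             head_MBqs = head_h * 3600,
             trapezoid_MBqs = trap_h * 3600,
             tail_MBqs = tail_h * 3600,
             tail_mode = tailMode,
             stringsAsFactors = FALSE)
}

# organ terminal rate for tail extrapolation: bi-exponential when there are
# enough samples, mono-exponential otherwise
organTailRate <- function(curve, tailMode) {
  if (tailMode == "physical")
    return(nuclideData(curve@nuclide)$lambda_per_h)
  model <- if (length(curve@times) >= 4L) fitBiexp(curve)
           else fitMonoexp(curve)
  terminalRatePerH(model)
}

#' Build a per-voxel time-integrated activity map from an image series
#'
#' Voxelwise mode integrates each voxel's own time-activity samples
#' (trapezoid over the scan interval, triangle/constant/none head) and
#' extrapolates every voxel's tail with its organ's terminal rate - per-voxel
#' tail fits would be noise-dominated, so the organ rate is shared, mirroring
#' whole-organ tail fitting practice. Organwise mode integrates the organ
#' total TAC and redistributes the organ TIA over voxels proportionally to
#' the time-averaged voxel activity, conserving the organ total by
#' construction.
#'
#' Voxels outside every named region (label 0, background) use the physical
#' decay constant for the tail.
#'
#' @param imageSeries list of [ActivityImage-class] objects on one grid,
#'   in any order (sorted by acquisition time internally).
#' @param mask a [VoiMask-class] on the same grid.
#' @param mode "voxelwise" or "organwise".
#' @param tailMode "effective" or "physical".
#' @param headMode "triangle", "none" or "constant".
#' @return A [TIAMap-class]; provenance records the modes used.
#' @export
voxelTiaMap <- function(imageSeries, mask,
                        mode = c("voxelwise", "organwise"),
                        tailMode = c("effective", "physical"),
                        headMode = c("triangle", "none", "constant")) {
  mode <- match.arg(mode)
  tailMode <- match.arg(tailMode)
  headMode <- match.arg(headMode)
  stopifnot(length(imageSeries) >= 1L, is(mask, "VoiMask"))
  for (im in imageSeries) {
    stopifnot(is(im, "ActivityImage"))
    if (!isTRUE(all.equal(im@grid@dims, mask@grid@dims)) ||
        !isTRUE(all.equal(im@grid@spacing, mask@grid@spacing)))
      stop("all images and the mask must share one grid")
  }
  ord <- order(vapply(imageSeries, function(im) im@timePostInjection,
                      numeric(1)))
  imageSeries <- imageSeries[ord]
  times <- vapply(imageSeries, function(im) im@timePostInjection, numeric(1))
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("acquisition times must be strictly increasing and > 0")
  nuclide <- imageSeries[[1]]@nuclide
  v_ml <- voxelVolumeMl(mask)
  n_t <- length(times)
  nvox <- prod(mask@grid@dims)
  A <- matrix(0, nvox, n_t)     # per-voxel activity (MBq) per time point
  for (j in seq_len(n_t))
    A[, j] <- as.vector(imageSeries[[j]]@concentration) * v_ml

  labels <- as.vector(mask@labels)
  all_labels <- sort(unique(labels))
  # organ TACs (label 0 = background included)
  organ_curves <- lapply(all_labels, function(lb) {
    tot <- colSums(A[labels == lb, , drop = FALSE])
    TimeActivityCurve(as.character(lb), times, tot, nuclide = nuclide)
  })
  names(organ_curves) <- as.character(all_labels)

  tia <- numeric(nvox)
  if (mode == "voxelwise") {
    # trapezoid weights over time
    w <- numeric(n_t)
    if (n_t > 1L) {
      dt <- diff(times)
      w[1] <- dt[1] / 2; w[n_t] <- dt[n_t - 1] / 2
      if (n_t > 2L)
        w[2:(n_t - 1)] <- (dt[-length(dt)] + dt[-1]) / 2
    }
    # a single scan carries no information before it: head and trapezoid
    # are zero and the tail runs from the scan time (physical decay)
    if (n_t == 1L && tailMode != "physical")
      stop("a single time point requires tailMode = 'physical'")
    head_w <- if (n_t == 1L) 0 else
      switch(headMode, triangle = 0.5 * times[1],
             constant = times[1], none = 0)
    trap <- as.vector(A %*% w)
    head_part <- A[, 1] * head_w
    tail_part <- numeric(nvox)
    for (lb in all_labels) {
      sel <- labels == lb
      curve <- organ_curves[[as.character(lb)]]
      lam <- if (lb == 0L || all(curve@activities == 0))
        nuclideData(nuclide)$lambda_per_h
      else organTailRate(curve, tailMode)
      tail_part[sel] <- A[sel, n_t] / lam
    }
    tia <- (head_part + trap + tail_part) * 3600
  } else {
    time_avg <- rowMeans(A)
    for (lb in all_labels) {
      sel <- labels == lb
      curve <- organ_curves[[as.character(lb)]]
      if (all(curve@activities == 0)) next   # empty region: TIA stays 0
      model <- if (tailMode == "effective") {
        if (n_t >= 4L) fitBiexp(curve) else fitMonoexp(curve)
      } else NULL
      organ_tia <- integrateTia(curve, tailMode = tailMode,
                        headMode = if (n_t == 1L) "none" else headMode,
                        model = model)$tia_MBqs
      wsum <- sum(time_avg[sel])
      if (wsum > 0) tia[sel] <- organ_tia * time_avg[sel] / wsum
    }
  }
  tia[tia < 0] <- 0
  new("TIAMap", grid = mask@grid, tia = array(tia, mask@grid@dims),
      provenance = list(mode = mode, tail_mode = tailMode,
                        head_mode = headMode, times_h = times))
}
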