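# Renal biologically effective dose: linear-quadratic model with
# exponentially decaying dose-rate delivery, as used for kidney dose limits
# in 177Lu/90Y peptide receptor therapy.

#' BED model parameters
#'
#' @param alphaBeta tissue alpha/beta ratio, Gy (> 0). Default 2.6 Gy
#'   (literature value for kidney).
#' @param tRepairH sublethal-damage repair half-time, hours (> 0). Default
#'   2.8 h (literature value).
#' @param tEffectiveH effective half-life of the dose-rate decay in the
#'   kidney, hours (> 0).
#' @return A list of class "BEDParams".
#' @export
bedParams <- function(alphaBeta = 2.6, tRepairH = 2.8, tEffectiveH = 70) {
  if (alphaBeta <= 0) stop("alpha/beta must be > 0")
  if (tRepairH <= 0 || tEffectiveH <= 0)
    stop("repair and effective half-times must be > 0")
  structure(list(alpha_beta_gy = alphaBeta, t_repair_h = tRepairH,
                 t_effective_h = tEffectiveH), class = "BEDParams")
}

#' Renal biologically effective dose over treatment cycles
#'
#' Per-cycle BED under the linear-quadratic model with mono-exponential
#' dose-rate decay:
#' \deqn{BED_i = D_i \left[1 + \frac{T_{rep}}{T_{rep} + T_{eff}}
#'   \frac{D_i}{\alpha/\beta}\right]}
#' where \eqn{T_{rep}} is the repair half-time and \eqn{T_{eff}} the
#' effective half-life of the renal dose rate. Cycle BEDs add.
#'
#' @param dosesPerCycle absorbed kidney dose per cycle, Gy (>= 0).
#' @param params a [bedParams()] object, or a list of one per cycle when
#'   cycle-specific effective half-lives are available.
#' @return A list with \code{per_cycle_bed_gy}, \code{cumulative_bed_gy}.
#' @examples
#' p <- bedParams(alphaBeta = 2.6, tRepairH = 2.8, tEffectiveH = 2.8)
#' renalBed(10, p)$cumulative_bed_gy  # 10 * (1 + 0.5 * 10 / 2.6)
#' @export
renalBed <- function(dosesPerCycle, params) {
  if (any(dosesPerCycle < 0)) stop("doses must be >= 0")
  if (inherits(params, "BEDParams"))
    params <- rep(list(params), length(dosesPerCycle))
  if (length(params) != length(dosesPerCycle))
    stop("provide one BEDParams, or one per cycle")
  per <- mapply(function(d, p) {
    stopifnot(inherits(p, "BEDParams"))
    g <- p$t_repair_h / (p$t_repair_h + p$t_effective_h)
    d * (1 + g * d / p$alpha_beta_gy)
  }, dosesPerCycle, params)
  list(per_cycle_bed_gy = as.numeric(per),
       cumulative_bed_gy = sum(per))
}

#' Check the cumulative kidney BED against the trial dose limit
#'
#' Cumulative kidney limits used for activity prescription: 46 Gy BED for
#' patients without risk factors, 28 Gy with risk factors (hypertension,
#' diabetes, renal failure).
#'
#' @param cumulativeBedGy cumulative kidney BED, Gy (>= 0).
#' @param hasRiskFactors logical.
#' @return A list with \code{limit_gy}, \code{remaining_gy} (never
#'   negative) and \code{within} (TRUE when cumulative <= limit).
#' @examples
#' checkKidneyLimit(40, hasRiskFactors = FALSE)
#' @export
checkKidneyLimit <- function(cumulativeBedGy, hasRiskFactors = FALSE) {
  if (cumulativeBedGy < 0) stop("cumulative BED must be >= 0")
  limit <- if (hasRiskFactors) 28 else 46
  list(limit_gy = limit,
       remaining_gy = max(0, limit - cumulativeBedGy),
       within = cumulativeBedGy <= limit)
}
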