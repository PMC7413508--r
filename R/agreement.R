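# Method-agreement statistics for paired dose tables: Lin's concordance
# correlation coefficient, Bland-Altman limits of agreement and the signed
# relative-difference convention used to compare dosimetry software.

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2}}
#' with population (1/n) moments, Lin's original estimator. Measures
#' agreement with the identity line: +1 is perfect concordance, -1 perfect
#' discordance, 0 no correlation. Pairs where either value is missing are
#' deleted.
#'
#' @param x,y numeric vectors of equal length (>= 2 complete pairs).
#' @return The concordance correlation coefficient in [-1, 1].
#' @examples
#' linCcc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
linCcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need >= 2 complete pairs")
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  denom <- sx2 + sy2 + (mean(x) - mean(y))^2
  if (denom == 0) stop("zero denominator: both vectors constant and equal")
  2 * sxy / denom
}

#' Confidence interval for Lin's CCC via the Fisher z-transform
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @param level confidence level (default 0.95).
#' @return A list with \code{ccc}, \code{lower}, \code{upper}, \code{n}.
#' @export
linCccConfint <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop("need >= 3 complete pairs for a confidence interval")
  rc <- linCcc(x, y)
  z <- atanh(rc)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  list(ccc = rc, lower = tanh(z - q * se), upper = tanh(z + q * se), n = n)
}

#' Signed relative difference in percent
#'
#' \code{100 * (a - b) / b}: the percentage by which \code{a} differs from
#' the reference \code{b}. Used with the voxel-engine dose as \code{a} and
#' the comparator method as \code{b}.
#'
#' @param a numeric, dose(s) of the method under comparison.
#' @param b numeric, reference dose(s); must be nonzero.
#' @return Signed percentage difference(s).
#' @examples
#' relativeDifference(3.0, 4.0)  # -25
#' @export
relativeDifference <- function(a, b) {
  if (any(b == 0, na.rm = TRUE)) stop("zero reference dose")
  100 * (a - b) / b
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences with mean and limits of agreement
#' (mean +/- 1.96 SD). Difference modes: percentage of the reference
#' (\code{100 (x - y)/y}), percentage of the pair mean
#' (\code{100 (x - y)/((x + y)/2)}), or absolute (\code{x - y}).
#'
#' @param x,y numeric vectors of equal length; \code{y} is the reference.
#' @param mode "percent_of_reference", "percent_of_mean" or "absolute".
#' @return A data.frame (one row) of class "AgreementSummary":
#'   \code{n_pairs}, \code{mean_diff}, \code{mean_abs_diff}, \code{sd_diff},
#'   \code{loa_low}, \code{loa_high} (percent or Gy per \code{mode}).
#' @examples
#' blandAltman(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
blandAltman <- function(x, y, mode = c("percent_of_reference",
                                       "percent_of_mean", "absolute")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ref <- switch(mode, percent_of_reference = y,
                percent_of_mean = (x + y) / 2, absolute = NULL)
  if (!is.null(ref) && any(ref == 0)) {
    warning(sum(ref == 0), " pair(s) with zero reference dropped")
    keep <- ref != 0
    x <- x[keep]; y <- y[keep]; ref <- ref[keep]
  }
  if (length(x) < 2L) stop("need >= 2 complete pairs")
  d <- switch(mode,
              percent_of_reference = 100 * (x - y) / y,
              percent_of_mean = 100 * (x - y) / ((x + y) / 2),
              absolute = x - y)
  m <- mean(d); s <- sd(d)
  structure(data.frame(n_pairs = length(d), mean_diff = m,
                       mean_abs_diff = mean(abs(d)), sd_diff = s,
                       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s),
            class = c("AgreementSummary", "data.frame"), mode = mode)
}

#' Build a paired dose table from a printed-table CSV
#'
#' Reads a wide per-case dose table whose columns are named
#' \code{<organ>_<method>} (e.g. \code{kidneys_voxelmed},
#' \code{spleen_voxelmed_lrd}) plus a \code{case} column, and reshapes it to
#' the long paired format. Missing entries stay NA - they are never
#' zero-filled; agreement statistics delete incomplete pairs pairwise.
#'
#' @param path CSV file path.
#' @return A data.frame of class "PairedDoseTable" with columns
#'   \code{case}, \code{organ}, \code{method}, \code{dose}.
#' @export
readPairedDoseTable <- function(path) {
  wide <- read.csv(path, stringsAsFactors = FALSE)
  if (!"case" %in% names(wide)) stop("expected a 'case' column")
  value_cols <- setdiff(names(wide), "case")
  parts <- regmatches(value_cols, regexpr("_", value_cols), invert = TRUE)
  long <- do.call(rbind, lapply(seq_along(value_cols), function(i) {
    data.frame(case = wide$case, organ = parts[[i]][1],
               method = parts[[i]][2], dose = wide[[value_cols[i]]],
               stringsAsFactors = FALSE)
  }))
  pairedDoseTable(long)
}

#' Construct/validate a paired dose table
#'
#' @param df data.frame with columns \code{case}, \code{organ},
#'   \code{method}, \code{dose} (NA for missing values).
#' @return The data.frame classed "PairedDoseTable".
#' @export
pairedDoseTable <- function(df) {
  req <- c("case", "organ", "method", "dose")
  if (!all(req %in% names(df)))
    stop("paired dose table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df[c("case", "organ", "method")]))
    stop("one dose per (case, organ, method) is required")
  structure(df[req], class = c("PairedDoseTable", "data.frame"))
}

#' Compare two dosimetry methods over a paired dose table
#'
#' For every group (per organ, or pooled over organs), rows where either
#' method's dose is missing are deleted pairwise, then Lin's CCC and the
#' Bland-Altman percentage-difference summary are computed with
#' \code{methodB} as the reference (differences are
#' \code{100 (A - B)/B}).
#'
#' @param table a [pairedDoseTable()].
#' @param methodA,methodB method names present in the table; \code{methodB}
#'   is the reference.
#' @param grouping "per_organ" or "pooled".
#' @return A data.frame with one row per group: \code{group},
#'   \code{n_pairs}, \code{ccc}, \code{ccc_lower}, \code{ccc_upper},
#'   \code{mean_pct_diff}, \code{mean_abs_pct_diff}, \code{loa_low},
#'   \code{loa_high}. Groups with fewer than 2 complete pairs are skipped
#'   with a warning.
#' @examples
#' path <- system.file("extdata", "sample_b_doses.csv", package = "voxdose")
#' tab <- readPairedDoseTable(path)
#' compareMethods(tab, "voxelmed", "raydose")
#' @export
compareMethods <- function(table, methodA, methodB,
                           grouping = c("per_organ", "pooled")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(table, "PairedDoseTable"))
  for (m in c(methodA, methodB))
    if (!m %in% table$method) stop("method '", m, "' not in table")
  a <- table[table$method == methodA, ]
  b <- table[table$method == methodB, ]
  merged <- merge(a, b, by = c("case", "organ"), suffixes = c("_a", "_b"))
  groups <- if (grouping == "per_organ") split(merged, merged$organ)
            else list(pooled = merged)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    ok <- is.finite(d$dose_a) & is.finite(d$dose_b)
    if (sum(ok) < 2L) {
      warning("group '", g, "' has < 2 complete pairs; skipped")
      return(NULL)
    }
    ci <- linCccConfint(d$dose_a[ok], d$dose_b[ok])
    ba <- blandAltman(d$dose_a[ok], d$dose_b[ok])
    data.frame(group = g, n_pairs = ci$n, ccc = ci$ccc,
               ccc_lower = ci$lower, ccc_upper = ci$upper,
               mean_pct_diff = ba$mean_diff,
               mean_abs_pct_diff = ba$mean_abs_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
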