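#' Per-vertex measurement error SD from paired repeat scans
#'
#' If measurement error is zero-mean and independent between two scans of
#' the same subject, the difference of the pair has twice the error
#' variance, so the error variance is estimated as one half the variance of
#' the paired differences (n - 1 denominator across subjects). A constant
#' offset between scans contributes nothing — the estimator is blind to
#' fixed bias by construction.
#'
#' @param scan1,scan2 matrices (vertices x subjects) of paired fields on
#'   the canonical mesh, or a list with elements \code{scan1}/\code{scan2}
#'   as returned by [simulateRepeatScans()]
#' @return numeric per-vertex error SD (units of the variable)
#' @export
pairedErrorSd <- function(scan1, scan2 = NULL) {
  if (is.list(scan1) && is.null(scan2)) {
    scan2 <- scan1$scan2; scan1 <- scan1$scan1
  }
  stopifnot(identical(dim(scan1), dim(scan2)))
  if (ncol(scan1) < 2L)
    stop("insufficient data: at least 2 scan pairs required")
  d <- scan1 - scan2
  sqrt(apply(d, 1, stats::var) / 2)
}

#' Precision report in absolute, %-of-mean and %-of-cohort-SD terms
#'
#' Summarises measurement repeatability for one CBM variable the way
#' precision studies report it: the per-vertex error SD (averaged over the
#' surface), the coefficient of variation (SD as a percentage of the cohort
#' mean), and the SD as a percentage of the between-subject SD in the
#' cohort — the latter being the most relevant for prediction, since about
#' twice this value is the minimum detectable difference for a single
#' subject at 95\% confidence (1.96 sqrt(2) SD). Patch-level rows aggregate
#' each scan over the patch first and then apply the half-variance
#' estimator to the patch means (aggregate-then-difference).
#'
#' @param pairs list with \code{scan1}/\code{scan2} matrices for one
#'   variable (see [simulateRepeatScans()])
#' @param cohortField matrix (vertices x subjects) of the variable in the
#'   full cohort, for the mean and between-subject SD references
#' @param patches optional named list of [PatchDefinition-class] for
#'   patch-level rows
#' @return list of class \code{PrecisionReport}: \code{sdMap} (per-vertex),
#'   \code{table} (data.frame: quantity, absolute, pct_of_mean,
#'   pct_of_cohort_sd, min_detectable_difference)
#' @export
precisionReport <- function(pairs, cohortField, patches = NULL) {
  sdMap <- pairedErrorSd(pairs)
  vmean <- rowMeans(cohortField)
  vsd <- apply(cohortField, 1, stats::sd)

  row <- function(label, sdv, mu, cohortSd) {
    data.frame(quantity = label, absolute = sdv,
               pct_of_mean = if (mu > 0) 100 * sdv / mu else NA_real_,
               pct_of_cohort_sd = if (cohortSd > 0) 100 * sdv / cohortSd
                                  else NA_real_,
               min_detectable_difference = 1.96 * sqrt(2) * sdv)
  }
  # point-wise row: mean error SD over the surface vs pooled cohort spread
  tab <- row("point", mean(sdMap), mean(vmean), sqrt(mean(vsd^2)))
  for (nm in names(patches)) {
    p <- patches[[nm]]
    m1 <- colMeans(pairs$scan1[p@vertices, , drop = FALSE])
    m2 <- colMeans(pairs$scan2[p@vertices, , drop = FALSE])
    sdp <- sqrt(stats::var(m1 - m2) / 2)
    cm <- colMeans(cohortField[p@vertices, , drop = FALSE])
    tab <- rbind(tab, row(paste0(nm, "_patch"), sdp, mean(cm), stats::sd(cm)))
  }
  structure(list(sdMap = sdMap, table = tab), class = "PrecisionReport")
}

#' @export
print.PrecisionReport <- function(x, ...) {
  cat("PrecisionReport (half-variance paired-difference estimator)\n")
  print(x$table, digits = 3)
  invisible(x)
}
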