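#' Fill Barlow pseudo-likelihood weights on a case-cohort sample
#'
#' Under the Barlow weighting scheme for case-cohort Cox regression, cases
#' carry weight 1 at (and just before) their own event; subcohort members
#' carry weight 1/alpha while at risk as controls. The \code{weight} slot
#' stores each subject's at-risk control weight (1/alpha if in the
#' subcohort, else 1 — non-subcohort cases never appear as controls); the
#' event-time weight of 1 for every case is applied when the counting-
#' process data are built (see [buildBarlowData()]).
#'
#' @param sample a [CaseCohortSample-class]
#' @return the sample with weights filled
#' @examples
#' # a non-case subcohort control at alpha = 308/3515 carries weight ~11.41
#' 1 / (308 / 3515)
#' @export
barlowWeights <- function(sample) {
  stopifnot(is(sample, "CaseCohortSample"))
  if (sample@alpha <= 0) stop("alpha must be positive")
  sample@weight <- ifelse(sample@inSubcohort, 1 / sample@alpha, 1)
  sample
}

#' Counting-process data for Barlow-weighted case-cohort Cox regression
#'
#' Expands the analysis sample into (start, stop] rows implementing the
#' Barlow scheme with Breslow-equivalent risk sets:
#' \itemize{
#'   \item non-case subcohort member: one row (0, T] censored, weight 1/alpha;
#'   \item case outside the subcohort: one row (T - eps, T] with the event,
#'     weight 1 (enters the risk set only just before its own event);
#'   \item case inside the subcohort: (0, T - eps] censored at weight
#'     1/alpha, plus (T - eps, T] with the event at weight 1.
#' }
#'
#' @param subjects data.frame with columns \code{id}, \code{event_time},
#'   \code{fracture_type} and any covariates
#' @param sample a [CaseCohortSample-class] with weights filled
#' @param outcome \code{"any"}, \code{"trochanteric"} or \code{"neck"};
#'   competing fracture types are treated as censored at their event time
#' @param eps half-open interval offset; default 1e-5 times the largest
#'   event time
#' @return data.frame with columns \code{tstart}, \code{tstop},
#'   \code{status}, \code{ccweight} appended to the subject covariates
#' @export
buildBarlowData <- function(subjects, sample,
                            outcome = c("any", "trochanteric", "neck"),
                            eps = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(is(sample, "CaseCohortSample"))
  idx <- match(sample@ids, subjects$id)
  if (anyNA(idx)) stop("sample ids missing from subjects table")
  d <- subjects[idx, , drop = FALSE]
  isCase <- sample@isCase
  isOut <- isCase & (outcome == "any" |
                     as.character(d$fracture_type) == outcome)
  if (is.null(eps)) eps <- 1e-5 * max(d$event_time)
  w <- sample@weight

  rows <- list()
  ctrl <- sample@inSubcohort        # at-risk as control over (0, T-eps]
  # never let the offset cross zero for very early events
  ctrlStop <- ifelse(isCase, pmax(d$event_time - eps, d$event_time / 2),
                     d$event_time)
  keepCtrl <- ctrl & ctrlStop > 0
  if (any(keepCtrl)) {
    r <- d[keepCtrl, , drop = FALSE]
    r$tstart <- 0; r$tstop <- ctrlStop[keepCtrl]; r$status <- 0L
    r$ccweight <- w[keepCtrl]
    rows[[length(rows) + 1L]] <- r
  }
  if (any(isCase)) {                # event row, weight 1
    r <- d[isCase, , drop = FALSE]
    r$tstart <- pmax(r$event_time - eps, r$event_time / 2)
    r$tstop <- r$event_time
    r$status <- as.integer(isOut[isCase])
    r$ccweight <- 1
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Barlow-weighted case-cohort Cox fit with robust variance
#'
#' Fits a weighted Cox proportional-hazards model (Breslow ties) on the
#' case-cohort counting-process data, with a sandwich (robust) variance
#' clustered on subject. The exposure is standardized by its SD in the
#' subcohort (the population-representative sample); hazard ratios are
#' reported per 1 SD decrease (sign-flipped standardization), per 1 SD
#' increase, or per 5-year increase for age. Following the convention for
#' reporting demographic covariates, \code{age} and \code{height} fits with
#' \code{adjusted = FALSE} use an unadjusted (single-covariate) model.
#'
#' @param subjects data.frame with \code{id}, \code{event_time},
#'   \code{fracture_type}, the exposure column and adjustment covariates
#'   \code{age}, \code{height}, \code{site}
#' @param sample a [CaseCohortSample-class]
#' @param exposure name of the exposure column
#' @param outcome \code{"any"}, \code{"trochanteric"} or \code{"neck"}
#' @param direction \code{"per_sd_decrease"} (default, the convention for
#'   imaging variables), \code{"per_sd_increase"}, or \code{"per_5yr"}
#' @param adjusted add age + height + site adjustment (default TRUE)
#' @param minEvents minimum events of the requested outcome (default 10)
#' @return list of class \code{SurvivalFit}: \code{variable},
#'   \code{outcome}, \code{hr}, \code{ci} (95\%), \code{coef} (log-hazard
#'   per standardized unit), \code{robustSe}, \code{p}, \code{nEvents},
#'   \code{converged}
#' @export
fitWeightedCox <- function(subjects, sample, exposure,
                           outcome = c("any", "trochanteric", "neck"),
                           direction = c("per_sd_decrease",
                                         "per_sd_increase", "per_5yr"),
                           adjusted = TRUE, minEvents = 10L) {
  outcome <- match.arg(outcome)
  direction <- match.arg(direction)
  d <- buildBarlowData(subjects, sample, outcome)
  nEvents <- sum(d$status)
  if (nEvents < minEvents)
    stop("insufficient events: ", nEvents, " < ", minEvents)

  subIdx <- subjects$id %in% sample@ids[sample@inSubcohort]
  xRaw <- subjects[[exposure]][subIdx]
  scaleBy <- switch(direction,
                    per_sd_decrease = -stats::sd(xRaw),
                    per_sd_increase = stats::sd(xRaw),
                    per_5yr = 5)
  d$.expo <- (d[[exposure]] - mean(xRaw, na.rm = TRUE)) / scaleBy

  fml <- if (adjusted)
    survival::Surv(tstart, tstop, status) ~ .expo + age + height + site
  else survival::Surv(tstart, tstop, status) ~ .expo
  fit <- survival::coxph(fml, data = d, weights = d$ccweight,
                         cluster = id, ties = "breslow")
  co <- fit$coefficients[[".expo"]]
  se <- sqrt(diag(fit$var))[[1]]     # robust (clustered) variance
  structure(list(variable = exposure, outcome = outcome,
                 direction = direction,
                 coef = co, robustSe = se, hr = exp(co),
                 ci = exp(co + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(co / se)),
                 nEvents = nEvents,
                 converged = !is.na(co) && is.finite(se)),
            class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("%s (%s, %s): HR %.2f (95%% CI %.2f-%.2f), p = %.3g [%d events]\n",
              x$variable, x$outcome, x$direction, x$hr, x$ci[1], x$ci[2],
              x$p, x$nEvents))
  invisible(x)
}

#' Hazard-ratio table across variables and outcomes
#'
#' Convenience wrapper producing the standard layout: one row per variable
#' and outcome with the per-SD (or per-5-year) hazard ratio, 95\% CI and p
#' value, using unadjusted fits for age and height and age + height + site
#' adjustment for all imaging variables.
#'
#' @param subjects subject table (see [fitWeightedCox()])
#' @param sample a [CaseCohortSample-class]
#' @param variables named character; names are output labels, values are
#'   column names in \code{subjects}
#' @param outcomes outcomes to fit (default all three)
#' @return data.frame: variable, outcome, hr, lo, hi, p, n_events
#' @export
hazardRatioTable <- function(subjects, sample, variables,
                             outcomes = c("any", "trochanteric", "neck")) {
  rows <- list()
  for (vlab in names(variables)) {
    vcol <- variables[[vlab]]
    dir <- if (vcol == "age") "per_5yr"
           else if (vcol == "height") "per_sd_increase" else "per_sd_decrease"
    adj <- !vcol %in% c("age", "height")
    for (oc in outcomes) {
      f <- tryCatch(fitWeightedCox(subjects, sample, vcol, oc, dir, adj),
                    error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vlab, outcome = oc,
        hr = if (is.null(f)) NA_real_ else f$hr,
        lo = if (is.null(f)) NA_real_ else f$ci[1],
        hi = if (is.null(f)) NA_real_ else f$ci[2],
        p = if (is.null(f)) NA_real_ else f$p,
        n_events = if (is.null(f)) NA_integer_ else f$nEvents)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
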