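#' Predictive model specification
#'
#' Names a logistic fracture-incidence model: the base covariates age,
#' height and clinical site (model "m") plus an optional set of imaging
#' variables. Imaging entries are column names in the analysis table; the
#' shorthand groups \code{"DXA"}, \code{"QCT"} and \code{"CBM"} expand to
#' the DXA-like surrogate, the QCT-like surrogate, and the four CBM patch
#' means (CM and ECTD, trochanteric and neck) respectively.
#'
#' @param name model label (e.g. \code{"m+CBM"})
#' @param imaging character vector of imaging variables / group shorthands
#' @param outcome \code{"binary_any"} or \code{"trichotomous"}
#' @return object of class \code{ModelSpec}
#' @export
modelSpec <- function(name, imaging = character(),
                      outcome = c("binary_any", "trichotomous")) {
  outcome <- match.arg(outcome)
  expand <- list(DXA = "bmd_dxa_like", QCT = "bmd_qct_like",
                 CBM = c("cm_troch_patch", "cm_neck_patch",
                         "ectd_troch_patch", "ectd_neck_patch"))
  vars <- unlist(lapply(imaging, function(v)
    if (v %in% names(expand)) expand[[v]] else v), use.names = FALSE)
  structure(list(name = name, base = c("age", "height", "site"),
                 imaging = unique(vars), outcome = outcome),
            class = "ModelSpec")
}

#' Is one model nested in another?
#'
#' @param small,large [modelSpec()] objects
#' @return TRUE when both share the base covariates and outcome and the
#'   small model's imaging set is contained in the large one's
#' @export
isNested <- function(small, large) {
  identical(small$base, large$base) &&
    identical(small$outcome, large$outcome) &&
    all(small$imaging %in% large$imaging)
}

.patchVarInfo <- function(v) {
  m <- regmatches(v, regexec("^(cth|cm|cbmd|ectd)_(troch|neck)_patch$", v))[[1]]
  if (!length(m)) return(NULL)
  list(variable = toupper(m[2]),
       contrast = if (m[3] == "troch") "trochanteric" else "neck")
}

.checkPatchVars <- function(imaging, allowNonPreferred) {
  for (v in imaging) {
    info <- .patchVarInfo(v)
    if (!is.null(info) && info$variable %in% c("CTH", "CBMD") &&
        !allowNonPreferred)
      stop("CTh/CBMD patches are reported for completeness only; ",
           "set allowNonPreferredPatches = TRUE to model them")
  }
}

# 10-year incidence outcome: fracture type for events inside the horizon,
# "none" otherwise (late fractures count as non-fractured)
.outcome10 <- function(data, horizon = 10) {
  ft <- as.character(data$fracture_type)
  ft[data$event_time > horizon] <- "none"
  factor(ft, levels = c("none", "trochanteric", "neck"))
}

#' Fit a binomial or trichotomous multinomial fracture model
#'
#' Binary models ("any fracture within the horizon") use maximum-likelihood
#' logistic regression; trichotomous models (none / trochanteric / neck,
#' reference "none") use multinomial logistic regression. Imaging variables
#' are standardized by their subcohort SD (or whole-sample SD when no
#' sample is given) and sign-flipped so odds ratios read per 1 SD decrease;
#' age is scaled per 5 years and height per SD increase. Deviance is
#' -2 log-likelihood. Complete quasi-separation is flagged, not silently
#' accepted.
#'
#' @param data analysis table with base covariates, imaging columns,
#'   \code{fracture_type} and \code{event_time}
#' @param spec a [modelSpec()]
#' @param horizon incidence horizon in years (default 10)
#' @param sdRef optional data.frame of reference rows (e.g. the subcohort)
#'   used for standardization SDs
#' @param weights optional per-row weights (a weighted variant for the
#'   case-cohort over-sampling; default unweighted)
#' @param allowNonPreferredPatches permit CTh/CBMD patch variables
#' @return list of class \code{FractureModelFit}: \code{fit}, \code{spec},
#'   \code{deviance}, \code{npar}, \code{or} (odds-ratio table),
#'   \code{separation}, \code{probs} (in-sample predicted probabilities)
#' @export
fitFractureModel <- function(data, spec, horizon = 10, sdRef = NULL,
                             weights = NULL,
                             allowNonPreferredPatches = FALSE) {
  stopifnot(inherits(spec, "ModelSpec"))
  .checkPatchVars(spec$imaging, allowNonPreferredPatches)
  d <- as.data.frame(data)
  d$.y3 <- .outcome10(d, horizon)
  d$.y2 <- as.integer(d$.y3 != "none")
  ref <- if (is.null(sdRef)) d else as.data.frame(sdRef)

  covs <- setdiff(c(spec$base, spec$imaging), "site")
  refStats <- lapply(stats::setNames(covs, covs), function(v) {
    if (v == "age") return(c(center = 74, scale = 5))   # per 5-year increase
    m <- mean(ref[[v]], na.rm = TRUE)
    s <- stats::sd(ref[[v]], na.rm = TRUE)
    if (v == "height") c(center = m, scale = s)         # per SD increase
    else c(center = m, scale = -s)                      # per SD decrease
  })
  for (v in covs)
    d[[v]] <- (d[[v]] - refStats[[v]]["center"]) / refStats[[v]]["scale"]

  rhs <- c("age", "height", "site", spec$imaging)
  if (is.null(weights)) weights <- rep(1, nrow(d))
  d$.w <- weights

  if (spec$outcome == "binary_any") {
    fml <- stats::reformulate(rhs, response = ".y2")
    fit <- suppressWarnings(
      stats::glm(fml, family = stats::binomial(), data = d, weights = .w))
    dev <- -2 * as.numeric(stats::logLik(fit))
    probs <- stats::fitted(fit)
    cf <- summary(fit)$coefficients
    sep <- any(probs > 1 - 1e-8 | probs < 1e-8) ||
      any(abs(cf[, 1]) > 15)
    np <- length(stats::coef(fit))
    orTab <- data.frame(term = rownames(cf)[-1], or = exp(cf[-1, 1]),
                        lo = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
                        hi = exp(cf[-1, 1] + 1.96 * cf[-1, 2]),
                        p = cf[-1, 4], row.names = NULL)
  } else {
    fml <- stats::reformulate(rhs, response = ".y3")
    fit <- nnet::multinom(fml, data = d, weights = .w, trace = FALSE,
                          maxit = 300)
    dev <- fit$deviance
    probs <- stats::fitted(fit)
    if (is.null(dim(probs)))
      probs <- cbind(none = 1 - probs, trochanteric = probs, neck = 0)
    sep <- any(probs > 1 - 1e-8) || max(abs(stats::coef(fit))) > 15
    np <- length(stats::coef(fit))
    co <- stats::coef(fit)
    # Hessian SEs are NaN under (near-)separation; the flag above reports it
    se <- suppressWarnings(summary(fit)$standard.errors)
    orTab <- data.frame(
      outcome = rep(rownames(co), ncol(co)),
      term = rep(colnames(co), each = nrow(co)),
      or = exp(as.numeric(co)),
      lo = exp(as.numeric(co) - 1.96 * as.numeric(se)),
      hi = exp(as.numeric(co) + 1.96 * as.numeric(se)), row.names = NULL)
    orTab <- orTab[orTab$term != "(Intercept)", ]
  }
  structure(list(fit = fit, spec = spec, deviance = dev, npar = np,
                 or = orTab, separation = sep, probs = probs,
                 outcomes = d$.y3, model = fml, horizon = horizon,
                 refStats = refStats),
            class = "FractureModelFit")
}

#' @export
print.FractureModelFit <- function(x, ...) {
  cat(sprintf("FractureModelFit %s (%s): deviance %.1f, %d parameters%s\n",
              x$spec$name, x$spec$outcome, x$deviance, x$npar,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Cross-validated fracture prediction with in-fold patch re-derivation
#'
#' Leave-one-out (default) or k-fold cross-validation of a fracture model.
#' When the model contains CBM patch variables and
#' \code{rederivePatches = TRUE}, the surface GLM and patch extraction are
#' re-run on each fold's training subjects, patch means are recomputed for
#' everyone from the fold's patches, the model is fitted without the
#' held-out subjects, and their probabilities are predicted — so patch
#' discovery never sees the held-out subject. Fold provenance (including
#' any empty-patch fallback) is recorded.
#'
#' @param x a [CbmExperiment-class] with outcomes (and shape scores if used)
#' @param spec a [modelSpec()]
#' @param folds number of folds; defaults to n (leave-one-out)
#' @param rederivePatches re-derive SPM patches inside each fold
#' @param spmMethod,nPerm,clusterP,spmAlpha,spmSeed settings forwarded to
#'   [extractSignificantPatches()]; the permutation seed is fixed across
#'   folds so one run's folds share a null
#' @param horizon incidence horizon (years)
#' @param allowNonPreferredPatches permit CTh/CBMD patch variables
#' @param seed seed for the fold split (ignored for leave-one-out)
#' @return list of class \code{PredictionResult}: \code{probs} (n x 3 or
#'   length-n vector), \code{outcomes}, \code{spec}, \code{foldProvenance},
#'   \code{nSpmRuns}
#' @export
looPredict <- function(x, spec, folds = NULL, rederivePatches = TRUE,
                       spmMethod = "permutation_fwer", nPerm = 1000L,
                       clusterP = 0.001, spmAlpha = 0.05, spmSeed = 1L,
                       horizon = 10, allowNonPreferredPatches = FALSE,
                       seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  n <- ncol(x)
  if (n < 30L) stop("need at least 30 subjects for cross-validation")
  if (is.null(folds)) folds <- n
  folds <- min(folds, n)
  .checkPatchVars(spec$imaging, allowNonPreferredPatches)

  patchInfo <- Filter(Negate(is.null), lapply(spec$imaging, .patchVarInfo))
  needSpm <- length(patchInfo) > 0 && rederivePatches

  foldId <- if (folds == n) seq_len(n) else
    .withSeed(seed, sample(rep_len(seq_len(folds), n)))

  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd$id <- colnames(x)
  nSpm <- 0L
  prov <- character(folds)
  probs <- matrix(NA_real_, n, 3,
                  dimnames = list(colnames(x),
                                  c("none", "trochanteric", "neck")))

  for (k in seq_len(folds)) {
    test <- which(foldId == k)
    train <- setdiff(seq_len(n), test)
    d <- cd
    if (length(patchInfo)) {
      if (needSpm) {
        xs <- x[, train]
        patches <- lapply(patchInfo, function(pi) {
          res <- fitVertexGlm(xs, pi$variable, pi$contrast)
          extractSignificantPatches(xs, res, method = spmMethod,
                                    alpha = spmAlpha, clusterP = clusterP,
                                    nPerm = nPerm, seed = spmSeed,
                                    provenance = paste0("loo_fold_", k))
        })
        nSpm <- nSpm + length(patches)
        prov[k] <- paste(vapply(patches, function(p) p@fallback,
                                character(1)), collapse = ",")
        pm <- patchMeans(x, patches)
      } else {
        pm <- patchMeans(x, S4Vectors::metadata(x)$patches)
        prov[k] <- "full_sample_patches"
      }
      d <- cbind(d, pm[match(d$id, rownames(pm)), , drop = FALSE])
    }
    fitk <- fitFractureModel(d[train, , drop = FALSE], spec,
                             horizon = horizon,
                             allowNonPreferredPatches = allowNonPreferredPatches)
    dk <- .standardizeLike(fitk, d[test, , drop = FALSE])
    pk <- stats::predict(fitk$fit, newdata = dk, type =
                           if (spec$outcome == "binary_any") "response"
                           else "probs")
    if (spec$outcome == "binary_any") {
      probs[test, "none"] <- 1 - pk
      probs[test, "trochanteric"] <- pk    # combined fracture probability
      probs[test, "neck"] <- pk
    } else {
      if (is.null(dim(pk))) pk <- matrix(pk, nrow = length(test),
                                         dimnames = list(NULL, colnames(fitk$probs)))
      probs[test, colnames(pk)] <- pk
    }
  }

  out <- list(probs = probs,
              pFracture = if (spec$outcome == "binary_any")
                probs[, "trochanteric"] else 1 - probs[, "none"],
              outcomes = .outcome10(cd, horizon), spec = spec,
              foldProvenance = prov, nSpmRuns = nSpm, folds = folds)
  class(out) <- "PredictionResult"
  out
}

# apply the training standardization to new rows (same centering/scaling
# rules as fitFractureModel, using the training data as reference)
.standardizeLike <- function(fitk, newdata) {
  ref <- fitk$refStats
  d <- as.data.frame(newdata)
  for (v in names(ref)) {
    r <- ref[[v]]
    d[[v]] <- (d[[v]] - r["center"]) / r["scale"]
  }
  d
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("PredictionResult %s: %d subjects, %d folds, %d SPM runs\n",
              x$spec$name, length(x$outcomes), x$folds, x$nSpmRuns))
  invisible(x)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC is the probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counting one half (the Mann-Whitney
#' formulation); the ROC curve is traced over all score thresholds and the
#' trapezoidal area equals the pair-counting value. The confidence interval
#' is a subject-level percentile bootstrap, stratified by outcome so no
#' resample loses a class.
#'
#' @param scores numeric risk scores (higher = more at risk)
#' @param outcomes factor/character outcomes
#' @param positive the positive class label
#' @param nBoot bootstrap resamples (default 2000; 0 skips the CI)
#' @param seed integer seed for the bootstrap
#' @return list: \code{auc}, \code{ci}, \code{roc} (data.frame fpr/tpr),
#'   \code{nPos}, \code{nNeg}
#' @export
rocAuc <- function(scores, outcomes, positive, nBoot = 2000L, seed = 1L) {
  pos <- scores[outcomes == positive]
  neg <- scores[outcomes != positive]
  if (!length(pos) || !length(neg))
    stop("undefined AUC: both classes must be present")
  aucOf <- function(p, ng) {
    r <- rank(c(p, ng))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(ng))
  }
  auc <- aucOf(pos, neg)
  th <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(th, function(t) mean(neg >= t), numeric(1)), 1),
    tpr = c(0, vapply(th, function(t) mean(pos >= t), numeric(1)), 1))
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    bs <- .withSeed(seed, {
      vapply(seq_len(nBoot), function(b)
        aucOf(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
        numeric(1))
    })
    ci <- unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  list(auc = auc, ci = ci, roc = roc, nPos = length(pos), nNeg = length(neg))
}

#' Nested-model deviance chi-squared comparison
#'
#' Tests whether the larger model improves fit: statistic =
#' DEV(small) - DEV(large), df = parameter-count difference, p from the
#' upper chi-squared tail. Only valid for nested models; non-nested inputs
#' raise an error.
#'
#' @param fitSmall,fitLarge [fitFractureModel()] results
#' @return list: \code{statistic}, \code{df}, \code{p},
#'   \code{significant} (at the conservative 0.005 convention)
#' @export
compareDeviance <- function(fitSmall, fitLarge) {
  stopifnot(inherits(fitSmall, "FractureModelFit"),
            inherits(fitLarge, "FractureModelFit"))
  if (!isNested(fitSmall$spec, fitLarge$spec))
    stop("not nested: a direct deviance test is not possible")
  stat <- fitSmall$deviance - fitLarge$deviance
  df <- fitLarge$npar - fitSmall$npar
  p <- if (df > 0) stats::pchisq(max(stat, 0), df, lower.tail = FALSE) else 1
  if (df == 0) stat <- 0
  list(statistic = stat, df = df, p = p, significant = p < 0.005)
}
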