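#' Planted-effect specification for the synthetic cohort
#'
#' Describes the generative model for per-vertex CBM fields: baseline levels,
#' covariate slopes, spatial noise, between-subject variation, and the
#' fracture-type-specific deficit geometry. Deficits are *not* assigned from
#' fracture labels: each subject carries two latent standard-normal risk
#' scores (trochanteric and neck); the score scales a relative deficit inside
#' the corresponding anatomical region, and fracture outcomes are later
#' generated from a proportional-hazards model driven by the resulting patch
#' means, so patch discovery faces a realistic inverse problem.
#'
#' \code{effectFraction} is calibrated so that the group-mean field inside
#' the region differs by that relative amount between the top and bottom
#' deciles of the latent risk score (the mean gap between deciles of a
#' standard normal is 3.51 SD, hence the internal scaling by 1/3.51).
#'
#' Baseline levels follow cohort-typical values for older men: CTh 1.6 mm,
#' CBMD 1095 mg/cm^3 (CM follows as 0.1 * CTh * CBMD ~ 175 mg/cm^2) and
#' ECTD 170 mg/cm^3.
#'
#' @param baseline named numeric: mean CTh (mm), CBMD (mg/cm^3),
#'   ECTD (mg/cm^3); all > 0. CM is always derived via the identity.
#' @param effectFraction named numeric in (-1, 1): relative deficit per
#'   variable attached to the latent risk scores (negative = deficit).
#' @param patchRegion named list mapping fracture type to the mesh region
#'   carrying its deficit.
#' @param spatialNoiseSd named numeric: SD of the smooth spatial noise as a
#'   fraction of baseline.
#' @param subjectSd named numeric: SD of the global per-subject level as a
#'   fraction of baseline.
#' @param lrNoiseSd left/right independent noise as a fraction of baseline
#'   (left and right share the same underlying truth).
#' @param ageSlope,weightSlope relative field change per year of age above
#'   74 / per kg of weight above 84.
#' @param siteSd SD of per-site relative calibration offsets.
#' @param smoothK k-ring smoothing passes for the spatial noise.
#' @return object of class \code{TrueEffectSpec} (a validated list)
#' @export
trueEffectSpec <- function(
    baseline = c(CTh = 1.6, CBMD = 1095, ECTD = 170),
    effectFraction = c(CTh = -0.10, CBMD = -0.02, ECTD = -0.15),
    patchRegion = list(trochanteric = "trochanter_superolateral",
                       neck = "neck_superior"),
    spatialNoiseSd = c(CTh = 0.10, CBMD = 0.03, ECTD = 0.10),
    subjectSd = c(CTh = 0.10, CBMD = 0.03, ECTD = 0.12),
    lrNoiseSd = 0.03,
    ageSlope = -0.004, weightSlope = 0.001, siteSd = 0.01,
    smoothK = 2L) {
  vars <- c("CTh", "CBMD", "ECTD")
  stopifnot(all(vars %in% names(baseline)), all(baseline[vars] > 0),
            all(vars %in% names(effectFraction)),
            all(abs(effectFraction[vars]) < 1),
            all(vars %in% names(spatialNoiseSd)),
            all(spatialNoiseSd[vars] >= 0),
            all(unlist(patchRegion) %in% .regionLevels))
  structure(list(baseline = baseline[vars],
                 effectFraction = effectFraction[vars],
                 patchRegion = patchRegion,
                 spatialNoiseSd = spatialNoiseSd[vars],
                 subjectSd = subjectSd[vars], lrNoiseSd = lrNoiseSd,
                 ageSlope = ageSlope, weightSlope = weightSlope,
                 siteSd = siteSd, smoothK = as.integer(smoothK)),
            class = "TrueEffectSpec")
}

# smooth unit-SD spatial noise, one column per draw
.spatialNoise <- function(mesh, nDraw, k) {
  z <- matrix(stats::rnorm(nVertices(mesh) * nDraw), nVertices(mesh), nDraw)
  z <- kRingSmooth(mesh, z, k)
  n <- nrow(z)
  sdz <- sqrt((colSums(z^2) - colSums(z)^2 / n) / (n - 1))
  sweep(z, 2, pmax(sdz, 1e-12), "/")
}

#' Simulate a cohort of subjects with per-vertex CBM fields
#'
#' Draws covariates (age ~ Normal(74, 6) truncated at 65, weight ~
#' Normal(84, 14) kg, height ~ Normal(174, 7) cm, site uniform over six
#' levels), latent fracture-type risk scores, and per-vertex CTh/CBMD/ECTD
#' fields following \code{spec}; CM is computed by the exact identity
#' CM = 0.1 * CTh * CBMD at every vertex. Left and right hips share a common
#' truth plus independent noise. Global DXA-like and QCT-like BMD surrogates
#' are noisy monotone functions of the whole-surface mean CM and mean ECTD.
#' Fracture type and time are filled later by [simulateFractureOutcomes()].
#'
#' @param mesh canonical [FemurMesh-class]
#' @param n number of subjects (0 allowed)
#' @param spec a [trueEffectSpec()]
#' @param seed integer seed
#' @param sides \code{"both"} stores per-side and combined assays;
#'   \code{"combined"} stores only the left/right-averaged assays (halves the
#'   memory for large simulations)
#' @param shapes if TRUE, per-subject surface coordinates (mean shape plus
#'   five smooth displacement modes, a random size factor and translation)
#'   are stored in \code{metadata()$shape_coords} for [computeShapeModes()]
#' @return a [CbmExperiment-class]; latent risk scores are kept in
#'   \code{colData} columns \code{u_troch}/\code{u_neck} (generator
#'   internals, never used by the analysis stages)
#' @export
simulatePopulation <- function(mesh, n, spec = trueEffectSpec(), seed = 1L,
                               sides = c("both", "combined"), shapes = TRUE) {
  sides <- match.arg(sides)
  stopifnot(inherits(spec, "TrueEffectSpec"), n >= 0)
  V <- nVertices(mesh)
  vars <- c("CTh", "CBMD", "ECTD")
  reg <- as.character(regionLabels(mesh))
  inreg <- cbind(trochanteric = reg == spec$patchRegion$trochanteric,
                 neck = reg == spec$patchRegion$neck)

  out <- .withSeed(seed, {
    age <- 65 + abs(stats::rnorm(n, 74, 6) - 65)      # truncated below 65
    weight <- stats::rnorm(n, 84, 14)
    height <- stats::rnorm(n, 174, 7)
    site <- factor(sample(paste0("site", 1:6), n, replace = TRUE),
                   levels = paste0("site", 1:6))
    siteOff <- stats::rnorm(6, 0, spec$siteSd)
    u <- cbind(u_troch = stats::rnorm(n), u_neck = stats::rnorm(n))
    covTerm <- spec$ageSlope * (age - 74) + spec$weightSlope * (weight - 84) +
      siteOff[as.integer(site)]

    assays <- list()
    for (v in vars) {
      subj <- stats::rnorm(n, 0, spec$subjectSd[[v]])
      c_v <- spec$effectFraction[[v]] / 3.51
      if (n > 0) {
        relTruth <- matrix(rep(covTerm + subj, each = V), V, n) +
          inreg[, "trochanteric"] %o% (c_v * u[, "u_troch"]) +
          inreg[, "neck"] %o% (c_v * u[, "u_neck"]) +
          spec$spatialNoiseSd[[v]] * .spatialNoise(mesh, n, spec$smoothK)
      } else relTruth <- matrix(0, V, 0)
      truth <- spec$baseline[[v]] * (1 + relTruth)
      truth <- pmax(truth, 0.01 * spec$baseline[[v]])
      lrsd <- spec$lrNoiseSd * spec$baseline[[v]]
      if (sides == "both") {
        left <- truth + matrix(stats::rnorm(length(truth), 0, lrsd), V, ncol(truth))
        right <- truth + matrix(stats::rnorm(length(truth), 0, lrsd), V, ncol(truth))
        assays[[paste0(v, "_left")]] <- left
        assays[[paste0(v, "_right")]] <- right
        assays[[v]] <- (left + right) / 2
      } else {
        # (left+right)/2 has noise SD lrsd/sqrt(2); draw it directly
        assays[[v]] <- truth +
          matrix(stats::rnorm(length(truth), 0, lrsd / sqrt(2)), V, ncol(truth))
      }
    }
    cmFrom <- function(cth, cbmd) 0.1 * cth * cbmd
    if (sides == "both") {
      assays$CM_left <- cmFrom(assays$CTh_left, assays$CBMD_left)
      assays$CM_right <- cmFrom(assays$CTh_right, assays$CBMD_right)
    }
    assays$CM <- cmFrom(assays$CTh, assays$CBMD)

    meanCM <- colMeans(assays$CM)
    meanECTD <- colMeans(assays$ECTD)
    cmRef <- 0.1 * spec$baseline[["CTh"]] * spec$baseline[["CBMD"]]
    bmdDxa <- 0.95 * (meanCM / cmRef) + stats::rnorm(n, 0, 0.06)
    bmdQct <- 0.28 * (0.6 * meanCM / cmRef +
                      0.4 * meanECTD / spec$baseline[["ECTD"]]) +
      stats::rnorm(n, 0, 0.02)

    shapeCoords <- NULL
    if (shapes && n > 0) {
      basis <- matrix(stats::rnorm(3 * V * 5), 3 * V, 5)
      basis <- apply(basis, 2, function(b)
        as.numeric(kRingSmooth(mesh, matrix(b, V, 3), 3)))
      basis <- qr.Q(qr(basis))
      modeSd <- c(3, 2, 1.5, 1, 0.7)
      scores <- matrix(stats::rnorm(n * 5), n, 5) %*% diag(modeSd)
      size <- stats::rnorm(n, 1, 0.05)
      shapeCoords <- array(0, c(V, 3, n))
      base <- as.numeric(meshVertices(mesh))
      for (i in seq_len(n)) {
        ci <- size[i] * (base + basis %*% scores[i, ]) +
          rep(stats::rnorm(3, 0, 5), each = V)
        shapeCoords[, , i] <- matrix(ci, V, 3)
      }
    }

    cd <- S4Vectors::DataFrame(
      id = sprintf("S%04d", seq_len(n)), age = age, weight = weight,
      height = height, site = site,
      fracture_type = factor(rep("none", n),
                             levels = c("none", "trochanteric", "neck")),
      event_time = rep(NA_real_, n), censored = rep(TRUE, n),
      bmd_dxa_like = bmdDxa, bmd_qct_like = bmdQct,
      u_troch = u[, "u_troch"], u_neck = u[, "u_neck"])
    list(assays = assays, cd = cd, shapeCoords = shapeCoords)
  })

  rd <- S4Vectors::DataFrame(region = regionLabels(mesh))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = out$assays, colData = out$cd, rowData = rd)
  colnames(se) <- out$cd$id
  md <- list(spec = spec, seed = seed)
  if (!is.null(out$shapeCoords)) md$shape_coords <- out$shapeCoords
  S4Vectors::metadata(se) <- md
  new("CbmExperiment", se, mesh = mesh)
}

#' Hazard specification for competing fracture-type outcomes
#'
#' Baseline yearly rates and log-hazard coefficients (per SD *increase*, so
#' protective bone variables carry negative signs) for two competing
#' exponential event processes. Defaults give a cohort-realistic ~3% 10-year
#' hip-fracture incidence split roughly 45/55 between trochanteric and neck,
#' with hazard driven by the patch-mean CM (trochanteric), patch-mean ECTD
#' (neck) and age.
#'
#' @param lambdaTroch,lambdaNeck baseline yearly rates (>= 0)
#' @param coefTroch,coefNeck named numeric log-hazard coefficients on the
#'   standardized drivers \code{cm} (patch-mean CM in the type's region),
#'   \code{ectd} (patch-mean ECTD in the type's region) and \code{age}
#' @return object of class \code{HazardSpec}
#' @export
hazardSpec <- function(lambdaTroch = 0.0012, lambdaNeck = 0.0014,
                       coefTroch = c(cm = -0.8, ectd = -0.4, age = 0.35),
                       coefNeck = c(cm = -0.3, ectd = -0.8, age = 0.45)) {
  if (lambdaTroch < 0 || lambdaNeck < 0)
    stop("baseline rates must be non-negative")
  structure(list(lambdaTroch = lambdaTroch, lambdaNeck = lambdaNeck,
                 coefTroch = coefTroch, coefNeck = coefNeck),
            class = "HazardSpec")
}

#' Simulate competing fracture outcomes from planted fields
#'
#' Each subject's trochanteric and neck hazards are constant over time:
#' \code{lambda_type * exp(b_cm z_cm + b_ectd z_ectd + b_age z_age)}, with
#' z the population-standardized patch-mean CM / patch-mean ECTD (over the
#' type's anatomical region) and standardized age. The earlier of the two
#' exponential event times, if it falls before \code{horizon}, sets
#' \code{fracture_type} and \code{event_time}; otherwise the subject is
#' censored at the horizon.
#'
#' @param x a [CbmExperiment-class] from [simulatePopulation()]
#' @param hazard a [hazardSpec()]
#' @param horizon follow-up in years (default 10)
#' @param seed integer seed
#' @return \code{x} with \code{fracture_type}, \code{event_time},
#'   \code{censored} filled in
#' @export
simulateFractureOutcomes <- function(x, hazard = hazardSpec(), horizon = 10,
                                     seed = 1L) {
  stopifnot(inherits(hazard, "HazardSpec"))
  n <- ncol(x)
  if (n == 0) return(x)
  reg <- as.character(regionLabels(femurMesh(x)))
  spec <- S4Vectors::metadata(x)$spec
  regs <- list(trochanteric = spec$patchRegion$trochanteric,
               neck = spec$patchRegion$neck)
  zs <- function(v) as.numeric(scale(v))
  drivers <- function(type) {
    sel <- reg == regs[[type]]
    cbind(cm = zs(colMeans(SummarizedExperiment::assay(x, "CM")[sel, , drop = FALSE])),
          ectd = zs(colMeans(SummarizedExperiment::assay(x, "ECTD")[sel, , drop = FALSE])),
          age = zs(x$age))
  }
  lpT <- drop(drivers("trochanteric") %*% hazard$coefTroch[c("cm", "ectd", "age")])
  lpN <- drop(drivers("neck") %*% hazard$coefNeck[c("cm", "ectd", "age")])
  res <- .withSeed(seed, {
    rT <- hazard$lambdaTroch * exp(lpT)
    rN <- hazard$lambdaNeck * exp(lpN)
    tT <- ifelse(rT > 0, stats::rexp(n, pmax(rT, 1e-300)), Inf)
    tN <- ifelse(rN > 0, stats::rexp(n, pmax(rN, 1e-300)), Inf)
    tMin <- pmin(tT, tN)
    type <- ifelse(tMin > horizon, "none",
                   ifelse(tT <= tN, "trochanteric", "neck"))
    list(type = type, time = pmin(tMin, horizon))
  })
  x$fracture_type <- factor(res$type,
                            levels = c("none", "trochanteric", "neck"))
  x$event_time <- res$time
  x$censored <- res$type == "none"
  x
}

#' Draw a case-cohort sample
#'
#' All fractured subjects are cases; the subcohort is a simple random sample
#' of \code{round(alpha * N)} subjects from the *whole* population (cases are
#' not excluded, so overlap is possible). Barlow weights are filled with
#' [barlowWeights()].
#'
#' @param x a [CbmExperiment-class] with fracture outcomes filled, or a
#'   data.frame with columns \code{id} and \code{fracture_type}
#' @param alpha subcohort sampling fraction in (0, 1]
#' @param seed integer seed
#' @return a [CaseCohortSample-class]
#' @export
drawCaseCohort <- function(x, alpha, seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (is.data.frame(x)) {
    n <- nrow(x); ids <- as.character(x$id)
  } else {
    n <- ncol(x); ids <- colnames(x)
  }
  isCase <- as.character(x$fracture_type) != "none"
  sub <- .withSeed(seed, sample.int(n, round(alpha * n)))
  inSub <- seq_len(n) %in% sub
  keep <- isCase | inSub
  s <- new("CaseCohortSample", ids = ids[keep], isCase = isCase[keep],
           inSubcohort = inSub[keep], alpha = alpha,
           weight = rep(1, sum(keep)))
  barlowWeights(s)
}

#' Simulate paired repeat scans for precision analysis
#'
#' For each selected subject and each CBM variable, two scans are generated
#' as the subject's true (combined) field plus two independent zero-mean
#' Gaussian noise draws with the given per-vertex SD. The default subset
#' size of 19 mirrors a typical short-interval repeat-scan precision study.
#'
#' @param x a [CbmExperiment-class]
#' @param errorSd named list/vector of per-variable error SDs, each either a
#'   scalar or a per-vertex vector (units of the variable); non-negative
#' @param subjects subject ids or indices (default: the first 19)
#' @param seed integer seed
#' @return named list per variable, each with matrices \code{scan1},
#'   \code{scan2} (vertices x subjects)
#' @export
simulateRepeatScans <- function(x, errorSd, subjects = NULL, seed = 1L) {
  if (is.null(subjects)) subjects <- seq_len(min(19L, ncol(x)))
  vars <- intersect(names(errorSd), SummarizedExperiment::assayNames(x))
  if (!length(vars)) stop("errorSd must name assay variables")
  V <- nrow(x)
  .withSeed(seed, {
    out <- list()
    for (v in vars) {
      sdv <- rep_len(errorSd[[v]], V)
      if (any(sdv < 0)) stop("error SD must be non-negative")
      truth <- SummarizedExperiment::assay(x, v)[, subjects, drop = FALSE]
      noise <- function() truth + sdv *
        matrix(stats::rnorm(length(truth)), V)
      out[[v]] <- list(scan1 = noise(), scan2 = noise())
    }
    out
  })
}

#' Render noisy blurred density profiles for a set of vertices
#'
#' Produces per-vertex 1-D density profiles by evaluating the blurred
#' three-density model ([modelProfile()]) at each vertex's true (CTh, CBMD,
#' ECTD) with a common soft-tissue level, then adding i.i.d. Gaussian noise
#' — the fixture generator that lets the measurement engine be exercised
#' end-to-end against known truth.
#'
#' @param cth,cbmd,ectd numeric per-vertex truths (recycled to the longest)
#' @param sigmaBlur imaging blur SD in mm (> 0)
#' @param noiseSd intensity noise SD (mg/cm^3)
#' @param grid strictly increasing positions (mm); must span
#'   \code{[-3 sigmaBlur, max(cth) + 3 sigmaBlur]}
#' @param y0 soft-tissue density level (default 80 mg/cm^3)
#' @param seed integer seed
#' @return long data.frame: vertex_id, position_mm, intensity, with the blur
#'   and grid recorded in attributes \code{sigma_blur} and \code{grid}
#' @export
renderProfiles <- function(cth, cbmd, ectd, sigmaBlur = 1.5, noiseSd = 0,
                           grid = seq(-6, 12, by = 0.5), y0 = 80, seed = 1L) {
  if (sigmaBlur <= 0) stop("sigmaBlur must be positive")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  nv <- max(length(cth), length(cbmd), length(ectd))
  cth <- rep_len(cth, nv); cbmd <- rep_len(cbmd, nv); ectd <- rep_len(ectd, nv)
  if (min(grid) > -3 * sigmaBlur || max(grid) < max(cth) + 3 * sigmaBlur)
    stop("grid must cover [x0 - 3 sigma, x1 + 3 sigma]")
  .withSeed(seed, {
    rows <- lapply(seq_len(nv), function(i) {
      y <- modelProfile(list(y0 = y0, y1 = cbmd[i], y2 = ectd[i], x0 = 0,
                             x1 = cth[i], sigma = sigmaBlur), grid)
      if (noiseSd > 0) y <- y + stats::rnorm(length(grid), 0, noiseSd)
      data.frame(vertex_id = i, position_mm = grid, intensity = y)
    })
    out <- do.call(rbind, rows)
    attr(out, "sigma_blur") <- sigmaBlur
    attr(out, "grid") <- grid
    out
  })
}

#' Planted-patch demonstration scenario
#'
#' A fixed generator configuration used throughout the package's validation
#' studies: fracture-type deficits strong enough that incident cases show a
#' roughly 10\% patch-mean CM (and larger ECTD) deficit against the cohort,
#' with ~10\% spatial field noise, a small global subject effect, and
#' elevated baseline rates so that a desk-scale cohort yields enough cases
#' for surface statistics. Returns the effect spec and the matching hazard
#' spec.
#'
#' @param rate baseline yearly rate per fracture type (default 0.02)
#' @return list with elements \code{spec} ([trueEffectSpec()]) and
#'   \code{hazard} ([hazardSpec()])
#' @export
plantedPatchScenario <- function(rate = 0.02) {
  list(spec = trueEffectSpec(
         effectFraction = c(CTh = -0.14, CBMD = -0.02, ECTD = -0.21),
         spatialNoiseSd = c(CTh = 0.10, CBMD = 0.03, ECTD = 0.10),
         subjectSd = c(CTh = 0.03, CBMD = 0.02, ECTD = 0.04)),
       hazard = hazardSpec(rate, rate,
                           coefTroch = c(cm = -2, ectd = -0.3, age = 0.3),
                           coefNeck = c(cm = -0.2, ectd = -2, age = 0.4)))
}
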