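#' @importFrom stats model.matrix pt qt
NULL

# Design matrix for the surface GLM: intercept, trochanteric/neck fracture
# indicators (against "none"), and the nuisance covariates. Returns the
# matrix plus the indicator column indices.
.spmDesign <- function(x, covariates) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  fr <- factor(as.character(cd$fracture_type),
               levels = c("none", "trochanteric", "neck"))
  df <- data.frame(.troch = as.numeric(fr == "trochanteric"),
                   .neck = as.numeric(fr == "neck"))
  for (cv in covariates) {
    if (!cv %in% names(cd)) stop("covariate not found: ", cv)
    df[[cv]] <- if (is.factor(cd[[cv]])) droplevels(cd[[cv]]) else cd[[cv]]
  }
  X <- model.matrix(~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("invalid design: collinear columns ", paste(bad, collapse = ", "))
  }
  list(X = X, qrX = qrX,
       contrastCol = c(trochanteric = which(colnames(X) == ".troch"),
                       neck = which(colnames(X) == ".neck")))
}

# OLS t-statistics for one design column across all vertices.
# Y: vertices x n; returns list(beta, t, df)
.vertexGlmT <- function(Y, qrX, j) {
  n <- nrow(qrX$qr); p <- qrX$rank
  Qty <- qr.qty(qrX, t(Y))                     # n x V
  beta <- backsolve(qr.R(qrX), Qty[seq_len(p), , drop = FALSE])
  yss <- rowSums(Y^2)
  rss <- yss - colSums(Qty[seq_len(p), , drop = FALSE]^2)
  df <- n - p
  Rinv <- backsolve(qr.R(qrX), diag(p))
  cjj <- sum(Rinv[j, ]^2)
  s2 <- pmax(rss, 0) / df
  tval <- beta[j, ] / sqrt(pmax(s2 * cjj, 1e-300))
  # an exactly-fitted vertex (zero residual to float precision) carries no
  # evidence about the contrast: report t = 0, not an exploding ratio
  tval[rss < 1e-10 * (yss + 1e-300)] <- 0
  list(beta = beta[j, ], t = tval, df = df)
}

#' Vertex-wise general linear model over the surface
#'
#' Fits, at every canonical vertex, an ordinary least-squares model of the
#' chosen CBM variable on the fracture factor (two indicators against
#' "none") plus nuisance covariates — by default age, weight, clinical site
#' and the five shape-mode scores, mirroring the confounders used in
#' surface statistical parametric mapping. Returns the t map for the
#' requested fracture-type indicator, with the effect size expressed as a
#' percentage of the vertex-wise mean value.
#'
#' @param x a [CbmExperiment-class] with outcomes and (if requested) shape
#'   scores in \code{colData}
#' @param variable assay to analyse (CTh, CM, CBMD or ECTD; combined fields)
#' @param contrast \code{"trochanteric"} or \code{"neck"}
#' @param covariates nuisance covariate names; defaults to age, weight,
#'   site and any \code{shape*} columns present
#' @return an [SpmResult-class] (mask all-FALSE until
#'   [extractSignificantPatches()] is run)
#' @export
fitVertexGlm <- function(x, variable = "CM",
                         contrast = c("trochanteric", "neck"),
                         covariates = NULL) {
  contrast <- match.arg(contrast)
  if (is.null(covariates)) {
    cd <- names(SummarizedExperiment::colData(x))
    covariates <- c("age", "weight", "site", grep("^shape[0-9]+$", cd, value = TRUE))
  }
  Y <- SummarizedExperiment::assay(x, variable)
  des <- .spmDesign(x, covariates)
  n <- ncol(x)
  if (n <= des$qrX$rank + 10L)
    stop("too few subjects for the design (need n > rank + 10)")
  j <- des$contrastCol[[contrast]]
  g <- .vertexGlmT(Y, des$qrX, j)
  vmean <- rowMeans(Y)
  eff <- ifelse(vmean > 0, 100 * g$beta / vmean, NA_real_)
  praw <- 2 * pt(-abs(g$t), g$df)
  new("SpmResult", contrast = contrast, variable = variable,
      effectPct = eff, tStat = g$t, pRaw = praw,
      mask = rep(FALSE, nrow(x)), df = g$df, method = "none",
      threshold = NA_real_)
}

# connected components of a vertex subset on the mesh edge graph
# (two vertices adjacent iff they share a mesh edge); edges may be
# precomputed with meshEdges() for repeated calls
.surfaceClusters <- function(mesh, vertexSet, edges = NULL) {
  if (!length(vertexSet)) return(list())
  if (is.null(edges)) edges <- meshEdges(mesh)
  inset <- logical(max(edges, vertexSet))
  inset[vertexSet] <- TRUE
  keep <- inset[edges[, 1]] & inset[edges[, 2]]
  ed <- edges[keep, , drop = FALSE]
  # union-find over the subset
  parent <- seq_len(length(inset))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(ed))) {
    a <- find(ed[r, 1]); b <- find(ed[r, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(vertexSet, find, integer(1))
  unname(split(vertexSet, roots))
}

# Freedman-Lane style permutation t map: Y and the fracture indicators are
# residualized against the fixed nuisance covariates once; each permutation
# shuffles subjects' fracture labels jointly and refits only the 2-column
# indicator block. Returns max cluster mass for the contrast.
.permNullMass <- function(Yr, Fr0, Zqr, perms, j, df, tCrit, mesh, edges) {
  yss <- colSums(Yr^2)
  vapply(seq_len(ncol(perms)), function(k) {
    Fp <- Fr0[perms[, k], , drop = FALSE]
    Fp <- Fp - qr.fitted(Zqr, Fp)
    XtX <- crossprod(Fp)
    Xty <- crossprod(Fp, Yr)                  # 2 x V
    beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
    if (is.null(beta)) return(0)
    rss <- yss - colSums(Xty * beta)
    s2 <- pmax(rss, 0) / df
    cjj <- tryCatch(solve(XtX)[j, j], error = function(e) NA_real_)
    if (!is.finite(cjj)) return(0)
    tv <- beta[j, ] / sqrt(pmax(s2 * cjj, 1e-300))
    sup <- which(abs(tv) > tCrit)
    if (!length(sup)) return(0)
    cl <- .surfaceClusters(mesh, sup, edges)
    max(vapply(cl, function(ix) sum(abs(tv[ix])), numeric(1)))
  }, numeric(1))
}

#' Multiplicity-corrected patch extraction from a surface t map
#'
#' Permutation method: vertices with raw p below the cluster-forming
#' threshold (default 0.001) are grouped into connected clusters on the mesh
#' edge graph; each cluster's mass (sum of |t|) is compared against the null
#' distribution of the maximum cluster mass obtained by permuting subjects'
#' fracture labels (Freedman-Lane residualization against the nuisance
#' covariates); clusters with family-wise-error-corrected p < alpha are
#' retained and their union is the patch. Bonferroni method: vertices with
#' raw p < alpha / V.
#'
#' If no vertex survives, the patch falls back first to the uncorrected
#' cluster-forming mask, then to the top 1\% most significant vertices, and
#' the fallback is flagged in the result's provenance — cross-validation
#' folds always need a usable patch.
#'
#' @param x the [CbmExperiment-class] the result was fitted on
#' @param result an [SpmResult-class] from [fitVertexGlm()]
#' @param method \code{"permutation_fwer"} (default) or \code{"bonferroni"}
#' @param alpha family-wise error level (default 0.05)
#' @param clusterP cluster-forming raw p threshold (default 0.001)
#' @param nPerm number of permutations (>= 500)
#' @param seed integer seed for the permutation draw
#' @param covariates nuisance covariates (must match the fit; default as in
#'   [fitVertexGlm()])
#' @param provenance provenance label recorded on the patch
#' @return a [PatchDefinition-class]; the updated mask is in
#'   \code{attr(, "result")}
#' @export
extractSignificantPatches <- function(x, result,
                                      method = c("permutation_fwer",
                                                 "bonferroni"),
                                      alpha = 0.05, clusterP = 0.001,
                                      nPerm = 1000L, seed = 1L,
                                      covariates = NULL,
                                      provenance = "full_sample") {
  method <- match.arg(method)
  mesh <- femurMesh(x)
  V <- nrow(x)
  tv <- result@tStat
  fallback <- "none"

  if (method == "bonferroni") {
    mask <- result@pRaw < alpha / V
    patchV <- which(mask)
  } else {
    if (nPerm < 500L) stop("nPerm must be at least 500")
    tCrit <- qt(1 - clusterP / 2, result@df)
    edges <- meshEdges(mesh)
    sup <- which(abs(tv) > tCrit)
    cl <- .surfaceClusters(mesh, sup, edges)
    patchV <- integer(0)
    if (length(cl)) {
      if (is.null(covariates)) {
        cd <- names(SummarizedExperiment::colData(x))
        covariates <- c("age", "weight", "site",
                        grep("^shape[0-9]+$", cd, value = TRUE))
      }
      des <- .spmDesign(x, covariates)
      X <- des$X
      frCols <- des$contrastCol
      Z <- X[, -frCols, drop = FALSE]
      Zqr <- qr(Z)
      Fr0 <- X[, frCols, drop = FALSE]
      Y <- SummarizedExperiment::assay(x, result@variable)
      Yr <- qr.resid(Zqr, t(Y))               # n x V
      jj <- match(result@contrast, names(frCols))
      df <- result@df
      perms <- .withSeed(seed, {
        n <- ncol(x)
        vapply(seq_len(nPerm), function(i) sample.int(n), integer(ncol(x)))
      })
      nullMass <- .permNullMass(Yr, Fr0, Zqr, perms, jj, df, tCrit, mesh,
                                edges)
      obsMass <- vapply(cl, function(ix) sum(abs(tv[ix])), numeric(1))
      pFwer <- vapply(obsMass, function(m)
        (1 + sum(nullMass >= m)) / (nPerm + 1), numeric(1))
      patchV <- sort(unlist(cl[pFwer < alpha], use.names = FALSE))
    }
    mask <- rep(FALSE, V); mask[patchV] <- TRUE
  }

  if (!length(patchV)) {                      # empty-patch fallback chain
    unc <- which(result@pRaw < clusterP)
    if (length(unc)) {
      patchV <- unc; fallback <- "uncorrected"
    } else {
      k <- max(1L, ceiling(0.01 * V))
      patchV <- order(result@pRaw)[seq_len(k)]
      fallback <- "top_fraction"
    }
    mask <- rep(FALSE, V)
  }

  result@mask <- mask
  result@method <- method
  result@threshold <- if (method == "bonferroni") alpha / V else clusterP
  patch <- new("PatchDefinition", variable = result@variable,
               contrast = result@contrast, vertices = as.integer(sort(patchV)),
               provenance = provenance, fallback = fallback)
  attr(patch, "result") <- result
  patch
}

#' Mean of a per-vertex field over a patch
#'
#' @param field numeric per-vertex values (canonical order)
#' @param patch a [PatchDefinition-class]
#' @return unweighted mean over the patch vertices
#' @export
patchAverage <- function(field, patch) {
  stopifnot(is(patch, "PatchDefinition"))
  if (!length(patch@vertices)) stop("empty patch")
  v <- field[patch@vertices]
  if (anyNA(v)) stop("field incomplete on patch vertices")
  mean(v)
}

#' Patch-mean matrix for all subjects
#'
#' Applies [patchAverage()] columnwise: one value per subject for each
#' (variable, contrast) patch. Only CM and ECTD patches are carried into
#' hazard/odds modelling by the pipeline; CTh and CBMD patches are reported
#' for completeness.
#'
#' @param x a [CbmExperiment-class]
#' @param patches list of [PatchDefinition-class]
#' @return data.frame, one column per patch named
#'   \code{<variable>_<contrast>_patch}, rows = subjects
#' @export
patchMeans <- function(x, patches) {
  out <- data.frame(row.names = colnames(x))
  for (p in patches) {
    Y <- SummarizedExperiment::assay(x, p@variable)
    out[[paste0(tolower(p@variable), "_", substr(p@contrast, 1, 5), "_patch")]] <-
      colMeans(Y[p@vertices, , drop = FALSE])
  }
  out
}
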