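#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Canonical proximal-femur surface mesh
#'
#' A closed, orientable triangulated surface standing in for the canonical
#' femur onto which all subjects' cortical bone mapping (CBM) measurements
#' are mapped. Every vertex carries exactly one anatomical region label.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot regions factor of length \code{nrow(vertices)} with levels
#'   \code{head}, \code{neck_superior}, \code{neck_inferior},
#'   \code{trochanter_superolateral}, \code{trochanter_other}, \code{shaft}.
#'
#' @seealso [makeCanonicalMesh()], [writePly()], [readPly()]
#' @export
setClass("FemurMesh",
  slots = c(vertices = "matrix", faces = "matrix", regions = "factor"))

.regionLevels <- c("head", "neck_superior", "neck_inferior",
                   "trochanter_superolateral", "trochanter_other", "shaft")

setValidity("FemurMesh", function(object) {
  v <- object@vertices; f <- object@faces; r <- object@regions
  msg <- character()
  if (ncol(v) != 3L) msg <- c(msg, "vertices must have 3 columns")
  if (ncol(f) != 3L) msg <- c(msg, "faces must have 3 columns")
  if (length(r) != nrow(v)) msg <- c(msg, "one region label per vertex required")
  if (anyNA(r)) msg <- c(msg, "region labels must not be NA")
  if (!all(levels(r) %in% .regionLevels))
    msg <- c(msg, "unknown region level")
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > nrow(v))
      msg <- c(msg, "face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      msg <- c(msg, "degenerate face (repeated vertex)")
    ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ne <- nrow(unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))))
    if (nrow(v) - ne + nrow(f) != 2L)
      msg <- c(msg, "mesh is not closed with sphere topology (V - E + F != 2)")
  }
  if (length(msg)) msg else TRUE
})

#' Number of vertices / faces of a mesh
#' @param mesh a [FemurMesh-class]
#' @return integer count
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @rdname nVertices
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @rdname nVertices
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname nVertices
#' @export
meshFaces <- function(mesh) mesh@faces

#' Per-vertex anatomical region labels
#' @param mesh a [FemurMesh-class]
#' @return factor of region labels, one per vertex
#' @export
regionLabels <- function(mesh) mesh@regions

setMethod("show", "FemurMesh", function(object) {
  cat("FemurMesh with", nVertices(object), "vertices and",
      nFaces(object), "faces\n")
  print(table(object@regions))
})

#' Case-cohort sampling bookkeeping
#'
#' All incident fracture cases plus a simple random subcohort drawn from the
#' full population at sampling fraction \code{alpha}. A subject may be both a
#' case and a subcohort member. \code{weight} holds the Barlow pseudo-
#' likelihood weight used in the weighted Cox fit (cases 1 at their event,
#' subcohort controls 1/alpha while at risk).
#'
#' @slot ids character subject ids covered by the sample.
#' @slot isCase logical, fracture case flag.
#' @slot inSubcohort logical, random subcohort membership.
#' @slot alpha numeric sampling fraction in (0, 1].
#' @slot weight numeric per-subject Barlow weight summary (the weight a
#'   subject carries as an at-risk control; cases contribute weight 1 at
#'   their own event regardless).
#' @seealso [drawCaseCohort()], [barlowWeights()]
#' @export
setClass("CaseCohortSample",
  slots = c(ids = "character", isCase = "logical", inSubcohort = "logical",
            alpha = "numeric", weight = "numeric"))

setValidity("CaseCohortSample", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (length(object@isCase) != n || length(object@inSubcohort) != n)
    msg <- c(msg, "flag vectors must match ids")
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicated subject id")
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in (0, 1]")
  if (length(object@weight) && any(object@weight <= 0, na.rm = TRUE))
    msg <- c(msg, "weights must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CaseCohortSample", function(object) {
  cat("CaseCohortSample:", sum(object@isCase), "cases,",
      sum(object@inSubcohort), "subcohort members (alpha =",
      format(object@alpha, digits = 3), "),",
      sum(object@isCase & object@inSubcohort), "overlap\n")
})

#' CBM study container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} whose assays are
#' per-vertex CBM variable matrices (rows = canonical vertices, columns =
#' subjects) and whose \code{colData} carries the subject table (age, weight,
#' height, site, fracture type, event/censoring time, global BMD surrogates,
#' shape-mode scores). The canonical surface lives in the \code{mesh} slot;
#' \code{rowData} carries the vertex region labels.
#'
#' Assay names follow \code{<variable>} for left/right-averaged fields and
#' \code{<variable>_left} / \code{<variable>_right} for per-side fields,
#' with variables in \code{CTh} (mm), \code{CM} (mg/cm^2), \code{CBMD}
#' (mg/cm^3) and \code{ECTD} (mg/cm^3).
#'
#' @slot mesh the canonical [FemurMesh-class].
#' @seealso [simulatePopulation()], [averageLeftRight()], [fitVertexGlm()]
#' @export
setClass("CbmExperiment",
  contains = "SummarizedExperiment",
  slots = c(mesh = "FemurMesh"))

setValidity("CbmExperiment", function(object) {
  if (nrow(object) != nVertices(object@mesh))
    "assay rows must match mesh vertex count" else TRUE
})

#' @rdname CbmExperiment-class
#' @param x a \code{CbmExperiment}
#' @return \code{femurMesh} returns the canonical [FemurMesh-class].
#' @export
femurMesh <- function(x) x@mesh

setMethod("show", "CbmExperiment", function(object) {
  callNextMethod()
  cat("mesh:", nVertices(object@mesh), "vertices;",
      sum(!is.na(object$fracture_type) & object$fracture_type != "none"),
      "fracture cases\n")
})

#' Fracture-type-specific surface patch
#'
#' A set of canonical-surface vertex indices tied to one CBM variable and one
#' fracture-type contrast, as produced by the surface statistical parametric
#' mapping (SPM) stage. \code{provenance} records whether the patch came from
#' the full sample or from a cross-validation fold, and whether an
#' empty-patch fallback was used.
#'
#' @slot variable one of CTh, CM, CBMD, ECTD.
#' @slot contrast \code{"trochanteric"} or \code{"neck"}.
#' @slot vertices integer vertex indices (1-based, unique).
#' @slot provenance character, e.g. \code{"full_sample"} or \code{"loo_fold_7"}.
#' @slot fallback character: \code{"none"}, \code{"uncorrected"} or
#'   \code{"top_fraction"} when the corrected map was empty.
#' @export
setClass("PatchDefinition",
  slots = c(variable = "character", contrast = "character",
            vertices = "integer", provenance = "character",
            fallback = "character"))

setValidity("PatchDefinition", function(object) {
  msg <- character()
  if (anyDuplicated(object@vertices)) msg <- c(msg, "duplicated vertex index")
  if (length(object@vertices) && min(object@vertices) < 1L)
    msg <- c(msg, "vertex indices must be >= 1")
  if (!object@contrast %in% c("trochanteric", "neck"))
    msg <- c(msg, "contrast must be trochanteric or neck")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatchDefinition", function(object) {
  cat(sprintf("PatchDefinition: %s / %s, %d vertices (%s%s)\n",
              object@variable, object@contrast, length(object@vertices),
              object@provenance,
              if (object@fallback != "none")
                paste0(", fallback=", object@fallback) else ""))
})

#' Vertex-wise GLM result over the surface
#'
#' Per-vertex effect sizes (as a percentage of the vertex mean), t statistics
#' and raw p values for one fracture-type contrast, plus the significance
#' mask after multiplicity correction.
#'
#' @slot contrast \code{"trochanteric"} or \code{"neck"}.
#' @slot variable response CBM variable name.
#' @slot effectPct numeric per-vertex effect as % of vertex mean (NA where the
#'   vertex mean is not positive).
#' @slot tStat numeric per-vertex t statistic for the fracture indicator.
#' @slot pRaw numeric per-vertex raw two-sided p value.
#' @slot mask logical significance mask after correction (set by
#'   [extractSignificantPatches()]; all-FALSE until then).
#' @slot df residual degrees of freedom of the vertex GLM.
#' @slot method correction method recorded on the mask.
#' @slot threshold cluster-forming / correction threshold recorded on the mask.
#' @export
setClass("SpmResult",
  slots = c(contrast = "character", variable = "character",
            effectPct = "numeric", tStat = "numeric", pRaw = "numeric",
            mask = "logical", df = "numeric", method = "character",
            threshold = "numeric"))

setMethod("show", "SpmResult", function(object) {
  cat(sprintf("SpmResult: %s ~ %s contrast, %d vertices, %d significant (%s)\n",
              object@variable, object@contrast, length(object@tStat),
              sum(object@mask), object@method))
})
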