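#' Map a subject's per-vertex values onto the canonical surface
#'
#' Applies a vertex correspondence (a permutation of, or nearest-vertex map
#' onto, canonical indices) so that entry i of the output is the subject's
#' value at the subject-mesh vertex corresponding to canonical vertex i.
#' Canonical vertices with no correspondent are returned as NA (missing,
#' never silently zero).
#'
#' @param values numeric per-vertex values on the subject mesh
#' @param correspondence integer vector, one entry per canonical vertex,
#'   giving the subject-mesh vertex index mapped to it (NA = missing)
#' @param canonical the canonical [FemurMesh-class]
#' @return numeric vector of length \code{nVertices(canonical)}
#' @export
mapToCanonical <- function(values, correspondence, canonical) {
  V <- nVertices(canonical)
  if (length(correspondence) != V)
    stop("correspondence length must equal canonical vertex count")
  ok <- !is.na(correspondence)
  if (any(correspondence[ok] < 1L | correspondence[ok] > length(values)))
    stop("correspondence index out of range")
  out <- rep(NA_real_, V)
  out[ok] <- values[correspondence[ok]]
  out
}

#' Size-excluded principal shape modes of a surface population
#'
#' Each subject's vertex coordinates are translated to zero centroid and
#' scaled to unit centroid size (the root-summed squared distance of the
#' vertices from their centroid — the standard geometric-morphometrics size
#' measure) *before* the principal decomposition, so overall size never
#' enters the model. The leading \code{nModes} principal components of the
#' flattened coordinate matrix are returned with per-subject scores, for use
#' as registration-confounder covariates in the surface GLM.
#'
#' @param coords array (vertices x 3 x subjects) or list of V x 3 matrices,
#'   all sharing the canonical topology
#' @param nModes number of modes to retain (default 5)
#' @return list of class \code{ShapeModel}: \code{meanShape} (V x 3),
#'   \code{modes} (3V x nModes, orthonormal columns), \code{scores}
#'   (subjects x nModes, zero column means), \code{varianceExplained}
#'   (fraction per mode)
#' @export
computeShapeModes <- function(coords, nModes = 5L) {
  if (is.list(coords)) coords <- simplify2array(coords)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[3]
  if (n < nModes + 2L)
    stop("insufficient data: need at least nModes + 2 subjects")
  flat <- vapply(seq_len(n), function(i) {
    x <- coords[, , i]
    x <- sweep(x, 2, colMeans(x))
    cs <- sqrt(sum(x^2))
    as.numeric(x / max(cs, 1e-12))
  }, numeric(dim(coords)[1] * 3L))       # 3V x n
  mu <- rowMeans(flat)
  X <- t(flat - mu)                      # n x 3V, centered
  sv <- svd(X, nu = nModes, nv = nModes)
  totVar <- sum(sv$d^2)
  keep <- seq_len(min(nModes, length(sv$d)))
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  list(meanShape = matrix(mu, ncol = 3L),
       modes = sv$v[, keep, drop = FALSE],
       scores = scores,
       varianceExplained = if (totVar > 0) sv$d[keep]^2 / totVar
                           else rep(0, length(keep)))
}

#' Average left and right hip fields on the canonical surface
#'
#' Vertex-wise mean of the two sides when both are present; pass-through of
#' the available side otherwise (flagged single-side). The right-hip field is
#' assumed already mirrored onto the canonical (left-handed) orientation.
#'
#' @param left,right numeric per-vertex fields (either may be NULL)
#' @return numeric field with attribute \code{sides} one of
#'   \code{"both"}, \code{"left_only"}, \code{"right_only"}
#' @export
averageLeftRight <- function(left = NULL, right = NULL) {
  if (is.null(left) && is.null(right))
    stop("missing data: at least one side is required")
  if (!is.null(left) && !is.null(right)) {
    stopifnot(length(left) == length(right))
    out <- (left + right) / 2
    attr(out, "sides") <- "both"
  } else if (is.null(right)) {
    out <- left; attr(out, "sides") <- "left_only"
  } else {
    out <- right; attr(out, "sides") <- "right_only"
  }
  out
}

#' Mirror a right-hip field onto the canonical orientation
#'
#' The canonical surface is left-handed; right hips are reflected through
#' the x = 0 plane and re-indexed by nearest-vertex matching before use.
#' For meshes sharing the canonical topology (as all synthetic subjects do)
#' the reflection leaves vertex order intact, so this reduces to a
#' correspondence lookup.
#'
#' @param values per-vertex field on the reflected right mesh
#' @param correspondence canonical-vertex correspondence after reflection
#'   (defaults to identity)
#' @param canonical the canonical [FemurMesh-class]
#' @return per-vertex field on the canonical surface
#' @export
mirrorRightField <- function(values, correspondence = NULL, canonical) {
  if (is.null(correspondence)) correspondence <- seq_len(nVertices(canonical))
  mapToCanonical(values, correspondence, canonical)
}

#' Attach shape-mode scores to a study container
#'
#' Runs [computeShapeModes()] on the per-subject surface coordinates stored
#' by the generator and appends columns \code{shape1..shapeK} to
#' \code{colData}.
#'
#' @param x a [CbmExperiment-class] with \code{metadata()$shape_coords}
#' @param nModes number of modes (default 5)
#' @return \code{x} with score columns appended and the model stored in
#'   \code{metadata()$shape_model}
#' @export
addShapeScores <- function(x, nModes = 5L) {
  sc <- S4Vectors::metadata(x)$shape_coords
  if (is.null(sc)) stop("no shape coordinates stored; rerun the generator with shapes = TRUE")
  sm <- computeShapeModes(sc, nModes)
  for (k in seq_len(ncol(sm$scores)))
    SummarizedExperiment::colData(x)[[paste0("shape", k)]] <- sm$scores[, k]
  md <- S4Vectors::metadata(x)
  md$shape_model <- sm
  S4Vectors::metadata(x) <- md
  x
}
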