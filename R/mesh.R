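#' Build the canonical proximal-femur-like surface
#'
#' Constructs a closed triangulated surface of sphere topology shaped as a
#' femoral head sphere, a narrower neck, a flared trochanter and a short
#' shaft stub, aligned along the z axis (shaft at the bottom, head at the
#' top). Vertices are laid out on a latitude/longitude grid with two polar
#' vertices, so V - E + F = 2 by construction. Anatomical region labels are
#' assigned from the parametric position along the axis and the
#' circumferential angle (the lateral/superior sector of the trochanter and
#' the superior half of the neck get their own labels). A small smooth,
#' seed-dependent radial perturbation (~1% of the radius) makes distinct
#' seeds produce distinct — but equally valid — canonical surfaces.
#'
#' @param nVerticesTarget requested vertex count (>= 100); the realised count
#'   is within about 10\% of this.
#' @param seed integer seed; the mesh is a deterministic function of it.
#' @return a [FemurMesh-class]
#' @examples
#' mesh <- makeCanonicalMesh(500, seed = 1)
#' table(regionLabels(mesh))
#' @export
makeCanonicalMesh <- function(nVerticesTarget = 2000L, seed = 1L) {
  if (!is.numeric(nVerticesTarget) || nVerticesTarget < 100)
    stop("nVerticesTarget must be at least 100")
  nLon <- max(8L, as.integer(round(sqrt(nVerticesTarget / 2))))
  nLat <- max(6L, as.integer(round((nVerticesTarget - 2) / nLon)))

  # parametric axis t in (0,1): 0 = shaft base pole, 1 = head apex pole
  t <- seq_len(nLat) / (nLat + 1)
  phi <- 2 * pi * (seq_len(nLon) - 1) / nLon
  length_mm <- 110                      # shaft base to head apex

  radius <- function(t) {
    shaft <- 14 * exp(-((t - 0.05) / 0.22)^2)
    troch <- 24 * exp(-((t - 0.32) / 0.16)^2)
    neck  <- 11.5 * exp(-((t - 0.60) / 0.18)^2)
    head  <- 23 * exp(-((t - 0.86) / 0.115)^2)
    base <- sqrt(shaft^2 + troch^2 + neck^2 + head^2)
    base * sqrt(pmax(sin(pi * t), 0))   # close smoothly at the poles
  }

  rng <- .withSeed(seed, {
    list(a = stats::runif(3, -0.015, 0.015), ph = stats::runif(3, 0, 2 * pi))
  })

  grid <- expand.grid(phi = phi, t = t)  # phi fastest, matching face indexing
  r0 <- radius(grid$t)
  pert <- 1 + rng$a[1] * sin(2 * pi * grid$t + rng$ph[1]) +
    rng$a[2] * cos(grid$phi + rng$ph[2]) +
    rng$a[3] * sin(2 * grid$phi + 4 * pi * grid$t + rng$ph[3])
  r <- r0 * pert
  verts <- cbind(x = r * cos(grid$phi), y = r * sin(grid$phi),
                 z = length_mm * grid$t)
  south <- c(0, 0, 0); north <- c(0, 0, length_mm)
  vertices <- rbind(verts, south, north)
  rownames(vertices) <- NULL
  iSouth <- nrow(verts) + 1L; iNorth <- nrow(verts) + 2L

  idx <- function(i, j) (i - 1L) * nLon + ((j - 1L) %% nLon) + 1L  # ring i, lon j
  faces <- vector("list", 2L * nLon * nLat)
  k <- 0L
  for (j in seq_len(nLon)) {            # south cap fan
    k <- k + 1L; faces[[k]] <- c(iSouth, idx(1L, j + 1L), idx(1L, j))
  }
  for (i in seq_len(nLat - 1L)) for (j in seq_len(nLon)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    k <- k + 1L; faces[[k]] <- c(a, b, d)
    k <- k + 1L; faces[[k]] <- c(a, d, cc)
  }
  for (j in seq_len(nLon)) {            # north cap fan
    k <- k + 1L; faces[[k]] <- c(iNorth, idx(nLat, j), idx(nLat, j + 1L))
  }
  faces <- do.call(rbind, faces[seq_len(k)])
  storage.mode(faces) <- "integer"

  tAll <- c(grid$t, 0, 1)
  phiAll <- c(grid$phi, 0, 0)
  regions <- .labelRegions(tAll, phiAll)

  new("FemurMesh", vertices = vertices, faces = faces, regions = regions)
}

# Region labels from axial position t and circumferential angle phi.
# Superior/lateral = positive-y half (phi in (0, pi)).
.labelRegions <- function(t, phi) {
  superior <- sin(phi) > 0
  lab <- character(length(t))
  lab[t < 0.18] <- "shaft"
  troch <- t >= 0.18 & t < 0.47
  lab[troch & superior] <- "trochanter_superolateral"
  lab[troch & !superior] <- "trochanter_other"
  neck <- t >= 0.47 & t < 0.74
  lab[neck & superior] <- "neck_superior"
  lab[neck & !superior] <- "neck_inferior"
  lab[t >= 0.74] <- "head"
  factor(lab, levels = .regionLevels)
}

#' Undirected edge list of the mesh triangulation
#'
#' @param mesh a [FemurMesh-class]
#' @return 2-column integer matrix of unique undirected edges
#' @export
meshEdges <- function(mesh) {
  f <- mesh@faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}

#' Smooth per-vertex white noise by k-ring neighbourhood averaging
#'
#' Each smoothing pass replaces a vertex value by the mean of itself and its
#' 1-ring neighbours; \code{k} passes give roughly a k-ring kernel. Used by
#' the synthetic-data generator for spatially correlated field noise.
#'
#' @param mesh a [FemurMesh-class]
#' @param values numeric vector (length = vertices) or matrix
#'   (vertices x draws)
#' @param k number of averaging passes (default 2)
#' @return smoothed values, same shape as the input
#' @export
kRingSmooth <- function(mesh, values, k = 2L) {
  v <- as.matrix(values)
  if (nrow(v) != nVertices(mesh)) stop("values length must match vertex count")
  if (k < 1L) return(values)
  ed <- meshEdges(mesh)
  n <- nVertices(mesh)
  A <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2], seq_len(n)),
                            j = c(ed[, 2], ed[, 1], seq_len(n)),
                            x = 1, dims = c(n, n))
  W <- A / Matrix::rowSums(A)
  for (pass in seq_len(k)) v <- as.matrix(W %*% v)
  if (is.matrix(values)) v else drop(v)
}

# evaluate expr with a local RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
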