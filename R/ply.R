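#' Write a mesh (with optional per-vertex scalars) as ASCII PLY
#'
#' Vertex coordinates, 0-based triangular faces, the integer region label
#' (property \code{region}) and any extra per-vertex scalar properties are
#' written in the standard ASCII PLY layout readable by external surface
#' viewers.
#'
#' @param mesh a [FemurMesh-class]
#' @param path output file
#' @param scalars optional named list of per-vertex numeric vectors written
#'   as additional float properties (NA written as NaN)
#' @return invisibly, the path
#' @export
writePly <- function(mesh, path, scalars = NULL) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  for (nm in names(scalars))
    stopifnot(length(scalars[[nm]]) == nrow(v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               "property int region",
               if (length(scalars))
                 paste("property float", names(scalars)),
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  cols <- cbind(v, as.integer(mesh@regions))
  for (nm in names(scalars)) cols <- cbind(cols, scalars[[nm]])
  utils::write.table(format(cols, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [writePly()]
#'
#' @param path PLY file path
#' @return list: \code{mesh} (a [FemurMesh-class]) and \code{scalars}
#'   (named list of extra per-vertex properties, possibly empty)
#' @export
readPly <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdrEnd <- match("end_header", lines)
  hdr <- lines[seq_len(hdrEnd)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  props <- sub("^property (float|int|double) ", "",
               grep("^property (float|int|double) ", hdr, value = TRUE))
  vdat <- utils::read.table(text = lines[hdrEnd + seq_len(nv)],
                            col.names = props)
  fdat <- utils::read.table(text = lines[hdrEnd + nv + seq_len(nf)])
  if (any(fdat[, 1] != 3)) stop("non-triangular face found")
  faces <- as.matrix(fdat[, 2:4]) + 1L
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  regions <- factor(.regionLevels[vdat$region], levels = .regionLevels)
  mesh <- new("FemurMesh",
              vertices = as.matrix(vdat[, c("x", "y", "z")]),
              faces = faces, regions = regions)
  extra <- setdiff(props, c("x", "y", "z", "region"))
  list(mesh = mesh, scalars = lapply(stats::setNames(extra, extra),
                                     function(p) vdat[[p]]))
}
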