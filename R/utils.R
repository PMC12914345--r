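#' @importFrom stats optim quantile runif setNames
#' @importFrom utils write.csv head tail
#' @importFrom methods as
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_letplan <- function(..., class) {
  stop(structure(
    class = c(class, "letplan_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Coordinate arrays of voxel centers
#'
#' World coordinates follow the fixed package convention: axes are ordered
#' left-right, anterior-posterior, superior-inferior, and the center of voxel
#' `(i, j, k)` (1-based) sits at `origin + (index - 0.5) * voxel_size`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param origin numeric length 3, mm.
#' @param voxel_size numeric scalar or length 3, mm.
#' @return list with 3-d arrays `x`, `y`, `z` of world coordinates (mm).
#' @keywords internal
voxel_coordinates <- function(shape, origin, voxel_size) {
  vs <- rep(voxel_size, length.out = 3)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * vs[a])
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(
    x = array(rep(ax[[1]], times = ny * nz), dim = shape),
    y = array(rep(rep(ax[[2]], each = nx), times = nz), dim = shape),
    z = array(rep(ax[[3]], each = nx * ny), dim = shape)
  )
}

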