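#' Mirror a volume about the mid-sagittal plane
#'
#' The left-right axis is the first array dimension, which must have even
#' length L. The mid-sagittal plane lies between voxel columns L/2 and
#' L/2 + 1; mirroring maps column i to column L + 1 - i. Columns 1..L/2 are
#' the left hemisphere, columns L/2 + 1..L the right. Every flip and mirror
#' operation in the package uses this one convention.
#'
#' @param x 3-D array (any storage mode) with an even first dimension.
#' @return The array reversed along its first dimension; attributes kept.
#' @export
mirror_lr <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3-D array")
  if (d[1] %% 2L != 0L)
    stop("left-right axis has odd length ", d[1],
         "; an even first dimension is required for a mid-sagittal plane")
  out <- x[d[1]:1L, , , drop = FALSE]
  attributes(out) <- attributes(x)
  out
}

#' Hemisphere membership of every voxel
#'
#' @param dims length-3 integer dimensions with an even first entry.
#' @return logical array, TRUE for left-hemisphere voxels (columns 1..L/2).
#' @export
left_hemisphere <- function(dims) {
  if (dims[1] %% 2L != 0L)
    stop("left-right axis has odd length ", dims[1])
  array(rep(seq_len(dims[1]) <= dims[1] / 2L, times = prod(dims[2:3])), dim = dims)
}

# voxel-centre coordinates along one axis
axis_coords <- function(n) seq_len(n)
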