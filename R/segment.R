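#' Label 3-D connected components
#'
#' Components of a foreground mask under 6- (faces), 18- (faces+edges) or
#' 26- (faces+edges+corners) connectivity, numbered from 1 in order of
#' first encounter in column-major order.
#'
#' @param fg logical 3-D array.
#' @param connectivity one of 6, 18, 26.
#' @return integer array of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components <- function(fg, connectivity = 26L) {
  d <- dim(fg)
  if (is.null(d) || length(d) != 3L) stop("expected a 3-D array")
  lab <- label_components_cpp(as.logical(fg), as.integer(d),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = d)
  attr(lab, "n_components") <- n
  lab
}

#' Segment a binary lesion from a probability volume
#'
#' Thresholds the lesion-probability map at `threshold` (strict: a voxel at
#' exactly the threshold is excluded) and keeps only contiguous clusters of
#' at least `min_cluster` voxels. The defaults — probability > 0.3 and
#' clusters of 100 or more voxels — are the standard operating point for
#' probability maps of this kind. An empty mask is a valid result.
#'
#' @param prob `lesion_prob` volume (or plain 3-D array in \[0, 1\]).
#' @param threshold probability threshold in \[0, 1); strictly exceeded.
#' @param min_cluster minimum cluster size in voxels (>= 1).
#' @param connectivity cluster contiguity definition: 6, 18 or 26.
#' @return logical 3-D array of class `lesion_mask` with attributes
#'   `subject_id` and `n_voxels`.
#' @export
segment_lesion <- function(prob, threshold = 0.3, min_cluster = 100L,
                           connectivity = 26L) {
  stopifnot(threshold >= 0, threshold < 1, min_cluster >= 1)
  d <- dim(prob)
  if (is.null(d) || length(d) != 3L) stop("expected a 3-D probability volume")
  fg <- unclass(prob) > threshold
  mask <- array(FALSE, d)
  if (any(fg)) {
    lab <- label_components(fg, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_cluster)
    if (length(keep)) mask <- array(lab %in% keep, d)
  }
  structure(mask, subject_id = attr(prob, "subject_id"),
            n_voxels = sum(mask), class = "lesion_mask")
}

#' Flip a subject to put the lesion in the right hemisphere
#'
#' If the segmented lesion has strictly more voxels in the left hemisphere
#' than in the right, both the probability volume and the binary mask are
#' mirrored about the mid-sagittal plane; otherwise (including an exact
#' tie) they are returned unchanged. Applying the operation twice is the
#' identity. The decision uses the binary mask, since "injury" is what the
#' segmentation defines.
#'
#' @param prob `lesion_prob` volume.
#' @param mask matching `lesion_mask`.
#' @return list with elements `prob`, `mask`, `flipped`.
#' @export
flip_to_right <- function(prob, mask) {
  d <- dim(prob)
  if (!identical(d, dim(mask))) stop("probability and mask grids differ")
  lh <- left_hemisphere(d)
  n_left <- sum(mask & lh)
  n_right <- sum(mask & !lh)
  if (n_left > n_right) {
    list(prob = mirror_lr(prob), mask = mirror_lr(mask), flipped = TRUE)
  } else {
    list(prob = prob, mask = mask, flipped = FALSE)
  }
}

#' Union of binary lesion masks
#'
#' Voxels that are part of a lesion in at least one subject of the list.
#'
#' @param masks non-empty list of `lesion_mask` arrays on a shared grid.
#' @return logical 3-D array.
#' @export
lesion_union_mask <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  d <- dim(masks[[1]])
  out <- array(FALSE, d)
  for (m in masks) {
    if (!identical(dim(m), d)) stop("masks are not on a shared grid")
    out <- out | m
  }
  array(out, d)
}
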