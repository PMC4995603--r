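#' Round a continuous composite score to the five-point scale
#'
#' Rounds to the closest integer (ties at x.5 rounded half away from zero)
#' and clamps to the range -2..2, the discrete range used for the
#' lesion-symptom-mapping ROIs.
#'
#' @param x numeric scores.
#' @return integer vector in -2..2.
#' @export
round_score_bin <- function(x) {
  r <- sign(x) * floor(abs(x) + 0.5)
  as.integer(pmin(pmax(r, -2), 2))
}

# half-integer medians are shrunk toward the neutral (0) category:
# round half toward zero. Medians of integers are integral or half-integral.
median_to_bin <- function(m) {
  as.integer(ifelse(m == floor(m), m, sign(m) * floor(abs(m))))
}

#' Build lesion-symptom-mapping ROIs from training subjects
#'
#' Each training subject's composite motor score is rounded to the discrete
#' range -2..2; for every voxel lesioned in at least one training subject,
#' the median of the rounded scores of the subjects lesioned there is taken
#' and the voxel is assigned to that median's ROI. Half-integer medians
#' (even subject counts) are rounded toward zero. This yields five
#' problem-specific ROIs partitioning the lesion-union volume; voxels never
#' lesioned stay unlabelled. Only training data may enter: the ROI set is
#' rebuilt inside every cross-validation fold.
#'
#' @param train_masks list of `lesion_mask` arrays (training subjects).
#' @param train_fpc numeric composite (first-principal-component) scores,
#'   aligned with `train_masks`.
#' @return object of class `vlsm_rois`: list with `roi_labels` (integer 3-D
#'   array, 1..5 mapping to scores -2..2, 0 elsewhere), `n_voxels_per_roi`
#'   (named length-5 integer), `score_of_label` (map label -> score).
#' @export
build_vlsm_rois <- function(train_masks, train_fpc) {
  if (length(train_masks) != length(train_fpc))
    stop("masks and scores are not aligned: ", length(train_masks), " vs ",
         length(train_fpc))
  if (!length(train_masks)) stop("need at least one training subject")
  d <- dim(train_masks[[1]])
  rounded <- round_score_bin(train_fpc)

  # per-voxel counts of lesioned subjects at each rounded score -2..2
  counts <- matrix(0L, nrow = prod(d), ncol = 5L)
  for (i in seq_along(train_masks)) {
    col <- rounded[i] + 3L
    counts[, col] <- counts[, col] + as.integer(train_masks[[i]])
  }
  n <- rowSums(counts)
  lesioned <- n > 0L

  roi <- integer(prod(d))
  if (any(lesioned)) {
    cc <- counts[lesioned, , drop = FALSE]
    nn <- n[lesioned]
    cum <- cc
    for (j in 2:5) cum[, j] <- cum[, j - 1L] + cc[, j]
    k1 <- floor((nn + 1) / 2)          # lower middle order statistic
    k2 <- ceiling((nn + 1) / 2)        # upper middle order statistic
    vals <- c(-2L, -1L, 0L, 1L, 2L)
    v1 <- vals[rowSums(cum < k1) + 1L]
    v2 <- vals[rowSums(cum < k2) + 1L]
    med <- (v1 + v2) / 2
    roi[lesioned] <- median_to_bin(med) + 3L
  }
  roi <- array(roi, d)
  nv <- vapply(1:5, function(l) sum(roi == l), integer(1))
  names(nv) <- as.character(-2:2)
  structure(list(roi_labels = roi, n_voxels_per_roi = nv,
                 score_of_label = setNames(-2:2, 1:5)),
            class = "vlsm_rois")
}

#' Union mask of the five lesion-symptom-mapping ROIs
#'
#' All labelled voxels — by construction, exactly the voxels lesioned in at
#' least one training subject. Used to restrict voxel-pattern features.
#'
#' @param rois a `vlsm_rois` object.
#' @return `roi_mask` (logical 3-D array).
#' @export
vlsm_mask <- function(rois) {
  stopifnot(inherits(rois, "vlsm_rois"))
  new_roi_mask(array(rois$roi_labels > 0L, dim = dim(rois$roi_labels)),
               name = "vlsm", provenance = "vlsm")
}
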