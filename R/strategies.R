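# The eight region-delimitation strategies, mirroring the model grid:
# all atlas ROIs, CST only, atlas+CST, motor ROIs, motor+CST, functional
# mask, lesion-symptom-mapping ROIs, lesion union — plus whole brain,
# which in the lesion-load family is the single "proportion of damage in
# the brain" feature. Data-driven strategies (vlsm, lesion_union) consume
# training subjects only and are rebuilt inside every CV fold.

#' Names of the ROI strategies
#' @return character vector of the eight grid strategies (whole_brain is
#'   additionally accepted by the builders).
#' @export
roi_strategies <- function() {
  c("atlas_all", "cst", "atlas_plus_cst", "atlas_motor", "motor_plus_cst",
    "functional", "vlsm", "lesion_union")
}

#' Synthetic functional motor mask
#'
#' Stand-in for a task-fMRI motor activation map from healthy controls
#' using their dominant hand: the motor-category atlas regions of a single
#' hemisphere. Like a real functional mask it is unilateral on arrival and
#' is mirrored by the consumer. Synthetic: no GLM is involved.
#'
#' @param atlas `lesion_atlas`.
#' @param hemisphere which hemisphere the "activation" lies in.
#' @return unilateral `roi_mask` with provenance `functional`.
#' @export
simulate_functional_mask <- function(atlas, hemisphere = "left") {
  rt <- atlas$region_table
  labs <- rt$label[rt$category == "motor" & rt$hemisphere == hemisphere]
  m <- roi_subset(atlas, labs, name = "functional")
  new_roi_mask(unclass(m), name = "functional", provenance = "functional")
}

#' Build the voxel mask for one ROI strategy
#'
#' @param strategy one of [roi_strategies()] or `"whole_brain"`.
#' @param atlas `lesion_atlas`.
#' @param train_masks training subjects' `lesion_mask` list (required for
#'   `vlsm` and `lesion_union`).
#' @param train_fpc training subjects' composite scores (required for
#'   `vlsm`).
#' @param functional_mask unilateral functional `roi_mask` (required for
#'   `functional`; it is mirrored here).
#' @return `roi_mask` with provenance set to the strategy name.
#' @export
build_strategy_mask <- function(strategy, atlas, train_masks = NULL,
                                train_fpc = NULL, functional_mask = NULL) {
  m <- switch(strategy,
    atlas_all      = roi_subset(atlas, c("motor", "nonmotor")),
    cst            = roi_subset(atlas, "cst"),
    atlas_plus_cst = roi_subset(atlas, "all"),
    atlas_motor    = roi_subset(atlas, "motor"),
    motor_plus_cst = roi_subset(atlas, c("motor", "cst")),
    functional = {
      if (is.null(functional_mask)) stop("strategy 'functional' needs a mask")
      mirror_mask(functional_mask)
    },
    vlsm = {
      if (is.null(train_masks) || is.null(train_fpc))
        stop("strategy 'vlsm' needs training masks and scores")
      vlsm_mask(build_vlsm_rois(train_masks, train_fpc))
    },
    lesion_union = {
      if (is.null(train_masks)) stop("strategy 'lesion_union' needs training masks")
      new_roi_mask(lesion_union_mask(train_masks), "lesion_union", "lesion_union")
    },
    whole_brain = new_roi_mask(atlas$brain_mask, "whole_brain", "whole_brain"),
    stop("unknown ROI strategy: ", strategy)
  )
  attr(m, "provenance") <- strategy
  m
}

#' Region list for lesion-load extraction under one strategy
#'
#' Multi-region strategies give one region (column) per atlas label;
#' single-mask strategies (cst, functional, lesion_union, whole_brain)
#' give exactly one region, and the vlsm strategy gives one region per
#' non-empty score ROI (up to five).
#'
#' @inheritParams build_strategy_mask
#' @return named list of logical arrays.
#' @export
strategy_regions <- function(strategy, atlas, train_masks = NULL,
                             train_fpc = NULL, functional_mask = NULL) {
  rt <- atlas$region_table
  label_regions <- function(labs, nms) {
    out <- lapply(labs, function(l) array(atlas$labels == l,
                                          dim = dim(atlas$labels)))
    names(out) <- nms
    out
  }
  cst_union <- function() {
    list(cst = unclass(roi_subset(atlas, "cst")))
  }
  switch(strategy,
    atlas_all = {
      sel <- rt$category %in% c("motor", "nonmotor")
      label_regions(rt$label[sel], rt$name[sel])
    },
    cst = cst_union(),
    atlas_plus_cst = {
      sel <- rt$category %in% c("motor", "nonmotor")
      c(label_regions(rt$label[sel], rt$name[sel]), cst_union())
    },
    atlas_motor = {
      sel <- rt$category == "motor"
      label_regions(rt$label[sel], rt$name[sel])
    },
    motor_plus_cst = {
      sel <- rt$category == "motor"
      c(label_regions(rt$label[sel], rt$name[sel]), cst_union())
    },
    functional = {
      m <- build_strategy_mask("functional", atlas,
                               functional_mask = functional_mask)
      list(functional = unclass(m))
    },
    vlsm = {
      if (is.null(train_masks) || is.null(train_fpc))
        stop("strategy 'vlsm' needs training masks and scores")
      rois <- build_vlsm_rois(train_masks, train_fpc)
      out <- lapply(1:5, function(l)
        array(rois$roi_labels == l, dim = dim(rois$roi_labels)))
      names(out) <- sprintf("vlsm_roi_%d", -2:2)
      out[vapply(out, any, logical(1))]   # empty score bins carry no region
    },
    lesion_union = {
      if (is.null(train_masks)) stop("strategy 'lesion_union' needs training masks")
      list(lesion_union = lesion_union_mask(train_masks))
    },
    whole_brain = list(whole_brain = atlas$brain_mask),
    stop("unknown ROI strategy: ", strategy)
  )
}
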