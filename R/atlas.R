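#' Build a synthetic mirrored brain atlas
#'
#' Constructs a desk-scale stand-in for a labelled anatomical atlas plus a
#' corticospinal-tract (CST) mask: `n_region_pairs` ellipsoidal regions are
#' placed at random in the left hemisphere and mirrored about the
#' mid-sagittal plane, and one tube-shaped CST running inferior-superior
#' (along the third axis) is placed in each hemisphere. A fixed fraction of
#' the region pairs is flagged as motor-related; the rest are non-motor.
#' All regions are pairwise disjoint and lie inside an ellipsoidal brain
#' mask inscribed in the grid.
#'
#' Label numbering: pair j gets labels 2j-1 (left) and 2j (right); the CST
#' pair gets the last two labels.
#'
#' @param grid_shape length-3 positive integers; the first (left-right)
#'   dimension must be even so a mid-sagittal plane exists between columns.
#' @param n_region_pairs number of mirrored region pairs (excluding CST).
#' @param motor_fraction fraction of pairs flagged `motor` (first pairs).
#' @param cst_radius in-plane radius of the CST tube, in voxels.
#' @param region_axis_range range of ellipsoid semi-axes for regions, voxels.
#' @param seed integer seed; output is deterministic given all arguments.
#' @param max_tries placement attempts per region before giving up.
#' @return object of class `lesion_atlas`: list with `labels` (3-D integer
#'   array, 0 = background), `region_table` (data.frame with columns
#'   `label`, `name`, `hemisphere`, `category`), `brain_mask` (logical
#'   array), `voxel_size` (mm, informational).
#' @export
make_atlas <- function(grid_shape = c(32L, 32L, 32L), n_region_pairs = 10L,
                       motor_fraction = 0.4, cst_radius = 1.6,
                       region_axis_range = NULL, seed = 1L,
                       max_tries = 2000L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            n_region_pairs >= 1L, cst_radius > 0)
  if (grid_shape[1] %% 2L != 0L)
    stop("first (left-right) dimension must be even, got ", grid_shape[1])
  if (is.null(region_axis_range))   # scale region size to the grid
    region_axis_range <- c(min(2, min(grid_shape) / 8),
                           max(2.5, min(min(grid_shape) / 8, 4.5)))
  # a region must fit between the margins of the left hemisphere
  lim <- c(grid_shape[1] / 2, grid_shape[2], grid_shape[3])
  feasible <- (lim - 1) / 2 > region_axis_range[1]
  if (!all(feasible))
    stop("grid too small to place regions: limiting dimension is ",
         which(!feasible)[1], " (length ", grid_shape[which(!feasible)[1]],
         ")")

  set.seed(as.integer(seed))
  d <- grid_shape
  half <- d[1] / 2L

  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  xs <- slice.index(array(0, d), 1)
  ys <- slice.index(array(0, d), 2)
  zs <- slice.index(array(0, d), 3)
  brain <- ((xs - cx) / (d[1] / 2 - 0.5))^2 +
           ((ys - cy) / (d[2] / 2 - 0.5))^2 +
           ((zs - cz) / (d[3] / 2 - 0.5))^2 <= 1

  labels <- array(0L, d)
  lh <- left_hemisphere(d)

  # CST first: a vertical tube per hemisphere, mirrored
  cst_x <- round(d[1] * 0.30)
  cst_y <- round(d[2] * 0.45)
  zspan <- seq(max(2L, round(d[3] * 0.15)), min(d[3] - 1L, round(d[3] * 0.85)))
  tube <- (xs - cst_x)^2 + (ys - cst_y)^2 <= cst_radius^2
  tube <- tube & array(rep(seq_len(d[3]) %in% zspan, each = d[1] * d[2]), d)
  tube <- tube & brain & lh
  if (!any(tube))
    stop("grid too small to place the CST tube: limiting dimension is 3 (length ",
         d[3], ")")
  cst_left_lab <- 2L * n_region_pairs + 1L
  cst_right_lab <- 2L * n_region_pairs + 2L
  labels[tube] <- cst_left_lab
  labels[mirror_lr(tube)] <- cst_right_lab

  place_one <- function(labels, lab_left, lab_right) {
    for (try in seq_len(max_tries)) {
      ax <- runif(3, region_axis_range[1], region_axis_range[2])
      lo <- ax + 1
      hi <- c(half, d[2], d[3]) - ax
      if (any(hi <= lo)) next  # sampled axes cannot fit this grid
      ctr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
               runif(1, lo[3], hi[3]))
      vox <- ((xs - ctr[1]) / ax[1])^2 + ((ys - ctr[2]) / ax[2])^2 +
             ((zs - ctr[3]) / ax[3])^2 <= 1
      vox <- vox & brain & lh
      if (!any(vox)) next
      mir <- mirror_lr(vox)
      if (any(labels[vox] != 0L) || any(labels[mir] != 0L)) next
      labels[vox] <- lab_left
      labels[mir] <- lab_right
      return(labels)
    }
    stop("could not place region after ", max_tries,
         " attempts: limiting dimension is ", which.min(d),
         " (length ", min(d), ")")
  }

  for (j in seq_len(n_region_pairs))
    labels <- place_one(labels, 2L * j - 1L, 2L * j)

  n_motor <- max(1L, round(motor_fraction * n_region_pairs))
  cat_of_pair <- c(rep("motor", n_motor),
                   rep("nonmotor", n_region_pairs - n_motor))
  region_table <- data.frame(
    label = c(rbind(2L * seq_len(n_region_pairs) - 1L,
                    2L * seq_len(n_region_pairs)),
              cst_left_lab, cst_right_lab),
    name = c(rbind(sprintf("region_%02d_left", seq_len(n_region_pairs)),
                   sprintf("region_%02d_right", seq_len(n_region_pairs))),
             "cst_left", "cst_right"),
    hemisphere = c(rep(c("left", "right"), n_region_pairs), "left", "right"),
    category = c(rep(cat_of_pair, each = 2L), "cst", "cst"),
    stringsAsFactors = FALSE
  )

  structure(list(labels = labels, region_table = region_table,
                 brain_mask = brain, voxel_size = c(1, 1, 1)),
            class = "lesion_atlas")
}

#' @export
print.lesion_atlas <- function(x, ...) {
  cat("lesion_atlas:", paste(dim(x$labels), collapse = "x"), "grid,",
      nrow(x$region_table), "regions (",
      sum(x$region_table$category == "motor"), "motor,",
      sum(x$region_table$category == "nonmotor"), "non-motor,",
      sum(x$region_table$category == "cst"), "CST )\n")
  invisible(x)
}

#' Boolean ROI mask from atlas labels
#'
#' Unions the voxel sets of the selected labels. `selector` is either one of
#' `"all"`, `"motor"`, `"nonmotor"`, `"cst"` (resolved through the region
#' table's `category` column; `"all"` means every labelled voxel) or an
#' explicit integer vector of labels.
#'
#' @param atlas a `lesion_atlas`.
#' @param selector category keyword or integer label vector.
#' @param name optional mask name; defaults to the selector.
#' @return logical 3-D array of class `roi_mask` with attributes `name` and
#'   `provenance`.
#' @export
roi_subset <- function(atlas, selector = "all", name = NULL) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  rt <- atlas$region_table
  if (is.character(selector) && length(selector) >= 1 &&
      all(selector %in% c("all", "motor", "nonmotor", "cst"))) {
    labs <- if ("all" %in% selector) rt$label
            else rt$label[rt$category %in% selector]
    if (is.null(name)) name <- paste(selector, collapse = "+")
  } else {
    labs <- as.integer(selector)
    unknown <- setdiff(labs, rt$label)
    if (length(unknown))
      stop("unknown atlas label(s): ", paste(unknown, collapse = ", "))
    if (is.null(name)) name <- paste0("labels_", paste(labs, collapse = "_"))
  }
  if (length(labs) == 0L) stop("selector resolves to no labels")
  m <- array(atlas$labels %in% labs, dim = dim(atlas$labels))
  new_roi_mask(m, name = name, provenance = "atlas_subset")
}

new_roi_mask <- function(mask, name, provenance) {
  structure(mask, name = name, provenance = provenance, class = "roi_mask")
}

#' Mirror an ROI mask across the mid-sagittal plane
#'
#' Returns the union of the mask and its left-right reflection, so both
#' hemispheres are covered. A mask that is already mirror-symmetric is a
#' fixed point.
#'
#' @param mask logical 3-D array (class `roi_mask` or plain).
#' @return `roi_mask` of the symmetric union.
#' @export
mirror_mask <- function(mask) {
  m <- mask | mirror_lr(mask)
  new_roi_mask(array(m, dim = dim(mask)),
               name = paste0(attr(mask, "name") %||% "mask", "_mirrored"),
               provenance = attr(mask, "provenance") %||% "mirrored")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
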