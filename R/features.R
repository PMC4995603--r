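#' Extract voxel-pattern features
#'
#' One feature per voxel inside the mask: the raw lesion probability of
#' that voxel. Columns are ordered by ascending linear (column-major,
#' x-fastest) voxel index; the mapping is stored on the result so kernels
#' are reproducible bit-for-bit.
#'
#' @param probs list of `lesion_prob` volumes on a shared grid.
#' @param mask non-empty `roi_mask` (or logical array) on the same grid.
#' @return numeric matrix, subjects x voxels, of class `feature_matrix`
#'   with attributes `feature_kind = "voxel_pattern"`, `mask_provenance`,
#'   `voxel_index` (linear indices of the columns).
#' @export
extract_voxel_patterns <- function(probs, mask) {
  if (!length(probs)) stop("no subjects supplied")
  d <- dim(probs[[1]])
  if (!identical(dim(mask), d)) stop("mask grid differs from volume grid")
  idx <- which(mask)
  if (!length(idx)) stop("cannot extract voxel patterns from an empty mask")
  X <- t(vapply(probs, function(p) unclass(p)[idx], numeric(length(idx))))
  if (length(idx) == 1L) X <- matrix(as.numeric(X), ncol = 1L)
  rownames(X) <- vapply(probs, function(p)
    attr(p, "subject_id") %||% "", character(1))
  structure(X, feature_kind = "voxel_pattern",
            mask_provenance = attr(mask, "provenance") %||% "mask",
            voxel_index = idx, class = c("feature_matrix", "matrix"))
}

#' Extract lesion-load features
#'
#' For each region r, the lesion load of subject i is
#' |lesion_i intersect region_r| / |region_r|: the proportion of the
#' region's voxels that fall inside the subject's binary lesion. Regions
#' are either all labelled regions of an atlas (one column per label) or an
#' explicit list of boolean masks (one column each; a single mask gives a
#' one-column matrix).
#'
#' @param lesions list of `lesion_mask` arrays.
#' @param regions a `lesion_atlas` or a (possibly named) list of logical
#'   arrays on the same grid.
#' @return `feature_matrix`, subjects x regions, values in \[0, 1\], with
#'   attributes `feature_kind = "lesion_load"` and `roi_labels`.
#' @export
extract_lesion_load <- function(lesions, regions) {
  if (!length(lesions)) stop("no subjects supplied")
  d <- dim(lesions[[1]])
  if (inherits(regions, "lesion_atlas")) {
    rt <- regions$region_table
    region_list <- lapply(rt$label, function(l)
      array(regions$labels == l, d))
    names(region_list) <- rt$name
  } else {
    region_list <- regions
    if (is.null(names(region_list)))
      names(region_list) <- sprintf("region%02d", seq_along(region_list))
  }
  if (!length(region_list)) stop("no regions supplied")
  sizes <- vapply(region_list, sum, numeric(1))
  if (any(sizes == 0))
    stop("region(s) with zero voxels: ",
         paste(names(region_list)[sizes == 0], collapse = ", "))
  idxs <- lapply(region_list, which)
  X <- t(vapply(lesions, function(m)
    vapply(seq_along(idxs), function(r) sum(m[idxs[[r]]]) / sizes[r],
           numeric(1)),
    numeric(length(idxs))))
  if (length(idxs) == 1L) X <- matrix(X, ncol = 1L)  # vapply drops shape
  colnames(X) <- names(region_list)
  rownames(X) <- vapply(lesions, function(m)
    attr(m, "subject_id") %||% "", character(1))
  structure(X, feature_kind = "lesion_load",
            roi_labels = names(region_list),
            class = c("feature_matrix", "matrix"))
}

#' Standardize feature matrices (train-fitted, test-applied)
#'
#' Two steps: (1) each row (subject) is normalized by its Euclidean norm —
#' all-zero rows pass through unchanged; (2) each column (feature) is
#' scaled to zero mean and unit variance using means and standard
#' deviations computed on the training rows only, which are then applied
#' unchanged to the test rows. Constant training columns are centred but
#' not scaled (divisor 1).
#'
#' @param train training feature matrix (>= 2 rows).
#' @param test optional test feature matrix with matching columns.
#' @return list with `train`, `test` (NULL if not supplied) and `params`
#'   (list of per-column `mean` and `sd` after row normalization).
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("variance undefined with a single training row")
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) stop("test columns do not match training")
  }
  row_normalize <- function(X) {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X / nrm
  }
  tr <- row_normalize(train)
  mu <- colMeans(tr)
  sdev <- apply(tr, 2, sd)
  sdev[sdev < 1e-12] <- 1
  ztr <- sweep(sweep(tr, 2, mu, "-"), 2, sdev, "/")
  zte <- NULL
  if (!is.null(test)) {
    te <- row_normalize(test)
    zte <- sweep(sweep(te, 2, mu, "-"), 2, sdev, "/")
  }
  list(train = ztr, test = zte, params = list(mean = mu, sd = sdev))
}

#' Linear covariance (kernel) matrix
#'
#' C = A B^T: entry (i, j) is the dot product of subject i's features in A
#' with subject j's in B. With A = B this is the linear self-covariance
#' used as the Gaussian-process kernel; it is symmetric positive
#' semi-definite.
#'
#' @param A,B numeric feature matrices with equal column counts (and, when
#'   present, identical column mappings). `B` defaults to `A`.
#' @return numeric covariance matrix, rows of A x rows of B.
#' @export
linear_kernel <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stop("feature dimensions differ")
  map_a <- attr(A, "voxel_index"); map_b <- attr(B, "voxel_index")
  if (!is.null(map_a) && !is.null(map_b) && !identical(map_a, map_b))
    stop("column (voxel) mappings differ between A and B")
  tcrossprod(as.matrix(A), as.matrix(B))
}

#' First principal component of the four motor scales
#'
#' Column means are computed on the training subjects and subtracted; the
#' covariance matrix of the centred training scores is eigen-decomposed and
#' subjects are projected onto the leading eigenvector, giving a single
#' composite score that captures the greatest possible variance of the four
#' correlated scales. Test subjects are centred with the training means and
#' projected with the training eigenvector — no test information enters the
#' loadings. The eigenvector sign is oriented so that the sum of its
#' loadings is positive (falling back to a positive first nonzero loading
#' when the sum is zero).
#'
#' @param train_scores data.frame or matrix of training subjects' four
#'   scale values (non-numeric columns such as subject ids are dropped).
#' @param test_scores optional test subjects' scores, same columns.
#' @param tol relative eigenvalue-gap tolerance below which the leading
#'   component is flagged as degenerate (a warning; the first eigenvector
#'   is still used).
#' @return list with `train` (numeric FPC values), `test` (or NULL),
#'   `loadings`, `center`, `eigenvalues`.
#' @export
fpc_scores <- function(train_scores, test_scores = NULL, tol = 1e-10) {
  to_mat <- function(s) {
    if (is.data.frame(s)) s <- s[vapply(s, is.numeric, logical(1))]
    as.matrix(s)
  }
  Y <- to_mat(train_scores)
  if (nrow(Y) < 2) stop("need at least 2 training subjects")
  if (ncol(Y) != 4) stop("expected 4 score columns, got ", ncol(Y))
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu, "-")
  S <- crossprod(Yc) / (nrow(Yc) - 1)
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[1] > 0 &&
      (eg$values[1] - eg$values[2]) < tol * eg$values[1])
    warning("leading eigenvalues nearly tied; first component used")
  v <- eg$vectors[, 1]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[which(v != 0)[1]] < 0)) v <- -v
  out_test <- NULL
  if (!is.null(test_scores)) {
    Yt <- to_mat(test_scores)
    out_test <- as.numeric(sweep(Yt, 2, mu, "-") %*% v)
  }
  list(train = as.numeric(Yc %*% v), test = out_test, loadings = v,
       center = mu, eigenvalues = eg$values)
}
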