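#' Random k-fold assignment
#'
#' A random permutation of subjects dealt into k folds whose sizes differ
#' by at most one; every subject is used exactly once for validation.
#'
#' @param n number of subjects.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed; assignment is deterministic per seed.
#' @return object of class `fold_plan`: list with `n`, `k`, `assignment`
#'   (per-subject fold index), `seed`.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (k > n) stop("k = ", k, " exceeds the number of subjects (", n, ")")
  if (k < 2) stop("need at least 2 folds")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Root mean squared error
#' @param pred,actual numeric vectors of equal nonzero length.
#' @return sqrt of the mean squared difference.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual) || !length(pred))
    stop("prediction and target lengths differ or are empty")
  sqrt(mean((pred - actual)^2))
}

#' Pearson correlation between predictions and targets
#'
#' Returns NA when either vector is constant (or shorter than 2), the
#' undefined-correlation case; cross-validation folds with NA correlation
#' are excluded from the fold-mean and counted in the result metadata.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return sample Pearson correlation, or NA when undefined.
#' @export
pearson_r <- function(pred, actual) {
  if (length(pred) != length(actual))
    stop("prediction and target lengths differ")
  if (length(pred) < 2) return(NA_real_)
  if (sd(pred) == 0 || sd(actual) == 0) return(NA_real_)
  cor(pred, actual)
}

# scale columns of the cohort score table (everything numeric)
score_columns <- function(scores) {
  scores[vapply(scores, is.numeric, logical(1))]
}

#' Leakage-controlled k-fold cross-validated decoding
#'
#' For every fold: (1) the composite target — first principal component of
#' the four motor scales — and its z-scaling are fitted on training
#' subjects only and applied to test subjects; (2) data-dependent masks
#' (lesion-symptom-mapping ROIs, lesion union) are rebuilt from training
#' subjects only; (3) feature standardization is fitted on training rows;
#' (4) a GP (or multiple-kernel GP) is fitted on the training kernel;
#' (5) test predictions are scored by Pearson correlation and RMSE. The
#' final R and RMSE are plain averages of the per-fold values; a pooled-
#' prediction correlation over all held-out subjects is reported as an
#' additional diagnostic.
#'
#' @param cohort `lesion_cohort` (or a list with `probs`, `scores`,
#'   `atlas`, optional `functional_mask`).
#' @param feature_spec list with `kind` (`"voxel_pattern"` or
#'   `"lesion_load"`) and `mask_strategy` (see [roi_strategies()]).
#' @param model_spec list with `kind` (`"gpr"` or `"mkl"`); for `"mkl"`,
#'   features must be voxel patterns and sources are the atlas labels
#'   intersecting the strategy mask.
#' @param fold_plan a `fold_plan`; defaults to 10 folds seeded from `seed`.
#' @param segmentation list of `threshold`, `min_cluster`, `connectivity`
#'   for [segment_lesion()].
#' @param flip flip subjects with left-dominant lesions to the right
#'   hemisphere before analysis.
#' @param seed seed for the default fold plan and model restarts.
#' @return object of class `cv_result`: `folds` data.frame (per-fold `r`,
#'   `rmse`, `n_test`, `n_features`), `predictions` (per-subject held-out
#'   prediction and target), `mean_r`, `mean_rmse`, `pooled_r`,
#'   `n_folds_used`, provenance (`feature_spec`, `model_spec`,
#'   `fold_plan`, `segmentation`).
#' @export
run_cv <- function(cohort, feature_spec, model_spec = list(kind = "gpr"),
                   fold_plan = NULL,
                   segmentation = list(threshold = 0.3, min_cluster = 100L,
                                       connectivity = 26L),
                   flip = TRUE, seed = 1L) {
  stopifnot(feature_spec$kind %in% c("voxel_pattern", "lesion_load"),
            model_spec$kind %in% c("gpr", "mkl"))
  if (model_spec$kind == "mkl" && feature_spec$kind != "voxel_pattern")
    stop("MKL sources are defined over voxel patterns")
  n <- length(cohort$probs)
  if (is.null(fold_plan)) fold_plan <- kfold_split(n, 10L, seed)
  stopifnot(inherits(fold_plan, "fold_plan"), fold_plan$n == n)
  atlas <- cohort$atlas
  strategy <- feature_spec$mask_strategy

  # per-subject preprocessing (no cross-subject information)
  seg <- lapply(cohort$probs, segment_lesion,
                threshold = segmentation$threshold,
                min_cluster = segmentation$min_cluster,
                connectivity = segmentation$connectivity)
  probs <- cohort$probs
  if (flip) {
    for (i in seq_len(n)) {
      fl <- flip_to_right(probs[[i]], seg[[i]])
      probs[[i]] <- fl$prob
      seg[[i]] <- fl$mask
    }
  }
  scores <- score_columns(cohort$scores)

  folds <- data.frame(fold = seq_len(fold_plan$k), n_test = NA_integer_,
                      n_features = NA_integer_, r = NA_real_,
                      rmse = NA_real_)
  pooled_pred <- numeric(n)
  pooled_act <- numeric(n)

  for (f in seq_len(fold_plan$k)) {
    te <- which(fold_plan$assignment == f)
    tr <- which(fold_plan$assignment != f)
    stage <- "fpc"
    res <- tryCatch({
      fpc <- fpc_scores(scores[tr, , drop = FALSE],
                        scores[te, , drop = FALSE])
      mu_y <- mean(fpc$train); sd_y <- sd(fpc$train)
      if (sd_y == 0) sd_y <- 1
      y_tr <- (fpc$train - mu_y) / sd_y
      y_te <- (fpc$test - mu_y) / sd_y

      stage <- "mask"
      if (feature_spec$kind == "voxel_pattern") {
        mask <- build_strategy_mask(strategy, atlas,
                                    train_masks = seg[tr],
                                    train_fpc = fpc$train,
                                    functional_mask = cohort$functional_mask)
        stage <- "features"
        X <- extract_voxel_patterns(probs, mask)
      } else {
        regions <- strategy_regions(strategy, atlas,
                                    train_masks = seg[tr],
                                    train_fpc = fpc$train,
                                    functional_mask = cohort$functional_mask)
        stage <- "features"
        X <- extract_lesion_load(seg, regions)
      }
      nf <- ncol(X)

      stage <- "standardize"
      std <- standardize_features(X[tr, , drop = FALSE],
                                  X[te, , drop = FALSE])

      stage <- "model"
      if (model_spec$kind == "gpr") {
        K <- linear_kernel(std$train)
        model <- gpr_fit(K, y_tr, seed = derive_seed(seed, 100L + f))
        Kc <- linear_kernel(std$test, std$train)
        pred <- gpr_predict(model, Kc)$mean
      } else {
        lab_of_col <- atlas$labels[attr(X, "voxel_index")]
        keep <- lab_of_col > 0L
        groups <- split(which(keep), lab_of_col[keep])
        rt <- atlas$region_table
        names(groups) <- rt$name[match(as.integer(names(groups)), rt$label)]
        sources <- lapply(groups, function(cols)
          tcrossprod(std$train[, cols, drop = FALSE]))
        model <- mkl_fit(sources, y_tr,
                         seed = derive_seed(seed, 100L + f))
        cross <- lapply(groups, function(cols)
          tcrossprod(std$test[, cols, drop = FALSE],
                     std$train[, cols, drop = FALSE]))
        pred <- gpr_predict(model, cross)$mean
      }

      stage <- "score"
      list(pred = pred, y_te = y_te, nf = nf)
    }, error = function(e)
      stop("fold ", f, ", stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))

    folds$n_test[f] <- length(te)
    folds$n_features[f] <- res$nf
    folds$r[f] <- pearson_r(res$pred, res$y_te)
    folds$rmse[f] <- rmse(res$pred, res$y_te)
    pooled_pred[te] <- res$pred
    pooled_act[te] <- res$y_te
  }

  structure(list(
    folds = folds,
    predictions = data.frame(subject = seq_len(n),
                             fold = fold_plan$assignment,
                             predicted = pooled_pred, actual = pooled_act),
    mean_r = mean(folds$r, na.rm = TRUE),
    mean_rmse = mean(folds$rmse),
    pooled_r = pearson_r(pooled_pred, pooled_act),
    n_folds_used = sum(!is.na(folds$r)),
    feature_spec = feature_spec, model_spec = model_spec,
    fold_plan = fold_plan, segmentation = segmentation, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$feature_spec$kind, "/", x$feature_spec$mask_strategy,
      "/", x$model_spec$kind, "\n")
  cat("  mean R =", signif(x$mean_r, 3), "over", x$n_folds_used,
      "folds; mean RMSE =", signif(x$mean_rmse, 3),
      "; pooled R =", signif(x$pooled_r, 3), "\n")
  invisible(x)
}

#' Compare two models' per-fold errors by Wilcoxon rank-sum test
#'
#' Two-sided rank-sum (Mann-Whitney) test on the two sets of fold RMSEs:
#' exact null distribution when the combined sample is small (<= 20) and
#' untied, normal approximation with tie correction otherwise. If every
#' value in both samples is identical the test is degenerate and p = 1.
#'
#' @param rmse_a,rmse_b per-fold error vectors (need not be paired).
#' @return list with `statistic` (rank-sum W of the first sample, in
#'   Mann-Whitney U form), `p_value`, `method`.
#' @export
compare_models_wilcoxon <- function(rmse_a, rmse_b) {
  if (!length(rmse_a) || !length(rmse_b)) stop("both samples must be nonempty")
  pooled <- c(rmse_a, rmse_b)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = length(rmse_a) * length(rmse_b) / 2,
                p_value = 1, method = "degenerate (all values identical)"))
  ties <- any(duplicated(pooled))
  exact <- !ties && length(pooled) <= 20L
  wt <- suppressWarnings(
    wilcox.test(rmse_a, rmse_b, alternative = "two.sided",
                exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact rank-sum" else
         "normal approximation with tie correction")
}
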