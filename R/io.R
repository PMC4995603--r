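#' Write a volume as NIfTI-1
#'
#' @param vol 3-D array (probabilities, labels or 0/1 mask).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size physical voxel dimensions in mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1)) {
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file.
#' @return 3-D numeric array.
#' @export
read_volume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI per subject under `dir/volumes/`, the atlas labels, brain
#' mask and functional mask as NIfTI, the region table and motor scores as
#' tab-separated text, and the generator ground truth (latent scores,
#' noise, scale transforms, seed) as a JSON sidecar. The voxelwise beta
#' map is written as NIfTI rather than JSON.
#'
#' @param cohort `lesion_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$atlas$voxel_size
  for (p in cohort$probs)
    write_volume(p, file.path(dir, "volumes",
                              paste0(attr(p, "subject_id"), ".nii.gz")), vs)
  write_volume(cohort$atlas$labels, file.path(dir, "atlas.nii.gz"), vs)
  write_volume(cohort$atlas$brain_mask, file.path(dir, "brain_mask.nii.gz"), vs)
  if (!is.null(cohort$functional_mask))
    write_volume(cohort$functional_mask,
                 file.path(dir, "functional_mask.nii.gz"), vs)
  utils::write.table(cohort$atlas$region_table,
                     file.path(dir, "region_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$scores, file.path(dir, "motor_scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    write_volume(cohort$truth$beta_map, file.path(dir, "beta_map.nii.gz"), vs)
    sidecar <- cohort$truth[setdiff(names(cohort$truth), "beta_map")]
    jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return `lesion_cohort` (without the beta map's generator metadata
#'   unless the truth sidecar is present).
#' @export
read_cohort <- function(dir) {
  labels <- read_volume(file.path(dir, "atlas.nii.gz"))
  region_table <- utils::read.delim(file.path(dir, "region_table.tsv"),
                                    stringsAsFactors = FALSE)
  brain <- read_volume(file.path(dir, "brain_mask.nii.gz")) > 0.5
  atlas <- structure(list(labels = array(as.integer(round(labels)),
                                         dim = dim(labels)),
                          region_table = region_table,
                          brain_mask = array(brain, dim = dim(labels)),
                          voxel_size = c(1, 1, 1)),
                     class = "lesion_atlas")
  scores <- utils::read.delim(file.path(dir, "motor_scores.tsv"),
                              stringsAsFactors = FALSE)
  files <- file.path(dir, "volumes", paste0(scores$subject_id, ".nii.gz"))
  probs <- lapply(seq_along(files), function(i)
    structure(read_volume(files[i]), subject_id = scores$subject_id[i],
              class = "lesion_prob"))
  fm_path <- file.path(dir, "functional_mask.nii.gz")
  functional <- if (file.exists(fm_path))
    new_roi_mask(array(read_volume(fm_path) > 0.5, dim = dim(labels)),
                 "functional", "functional")
  truth <- NULL
  tr_path <- file.path(dir, "truth.json")
  if (file.exists(tr_path)) {
    truth <- jsonlite::read_json(tr_path, simplifyVector = TRUE)
    bm <- file.path(dir, "beta_map.nii.gz")
    if (file.exists(bm)) truth$beta_map <- read_volume(bm)
  }
  structure(list(probs = probs, scores = scores, truth = truth,
                 atlas = atlas, functional_mask = functional),
            class = "lesion_cohort")
}

#' Write a cross-validation result as tab-separated text
#'
#' Per-fold table plus a trailing summary row (`fold = "mean"`).
#'
#' @param cv `cv_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  tab <- cv$folds
  tab$fold <- as.character(tab$fold)
  tab <- rbind(tab, data.frame(fold = "mean", n_test = sum(tab$n_test),
                               n_features = NA, r = cv$mean_r,
                               rmse = cv$mean_rmse))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
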