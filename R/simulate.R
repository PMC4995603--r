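#' Default definitions of the four motor scales
#'
#' Slopes and intercepts map the latent damage score g (0 = intact, more
#' negative = more damage) to each clinical scale; floors and ceilings are
#' the instruments' score bounds, and clipping to them after noise emulates
#' the floor/ceiling effects of the individual measures. The pegboard test
#' (NHPT) is a timed score, so it carries a negative slope: more impairment
#' means a longer time.
#'
#' @return data.frame with columns `name`, `slope`, `intercept`, `floor`,
#'   `ceiling`.
#' @export
default_motor_scales <- function() {
  data.frame(
    name      = c("ARAT", "GS", "MI", "NHPT"),
    slope     = c(25, 20, 35, -80),
    intercept = c(55, 45, 85, 40),
    floor     = c(0, 0, 0, 0),
    ceiling   = c(57, 60, 100, 300),
    stringsAsFactors = FALSE
  )
}

#' Simulate one soft-edged ellipsoidal lesion-probability volume
#'
#' Draws a random ellipsoid centred at an in-brain voxel. Core probabilities
#' are near 1 and decay to 0 across roughly `edge_softness` voxels through a
#' sigmoid of the (approximate) signed distance to the ellipsoid surface,
#' giving the soft boundary characteristic of lesion-probability maps. With
#' probability `unilateral_prob` the blob is clipped to the hemisphere its
#' centre lies in.
#'
#' @param atlas `lesion_atlas` providing grid and brain mask.
#' @param size_range numeric (min, max) target lesion core volume in voxels.
#' @param edge_softness positive real; length scale of the probability
#'   falloff in voxels. Values near 0 give an effectively binary blob.
#' @param unilateral_prob probability that the lesion is confined to one
#'   hemisphere.
#' @param subject_id identifier stored on the output.
#' @param seed integer seed; identical seeds give identical volumes.
#' @return 3-D array of class `lesion_prob`, values in \[0, 1\], with
#'   attribute `subject_id`.
#' @export
simulate_lesion <- function(atlas, size_range = c(40, 800), edge_softness = 1,
                            unilateral_prob = 0.95, subject_id = "subj",
                            seed = 1L) {
  stopifnot(inherits(atlas, "lesion_atlas"), edge_softness > 0,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  d <- dim(atlas$labels)
  n_brain <- sum(atlas$brain_mask)
  if (size_range[2] > n_brain)
    stop("requested lesion volume ", size_range[2],
         " exceeds brain volume ", n_brain)
  set.seed(as.integer(seed))

  lh <- left_hemisphere(d)
  go_left <- runif(1) < 0.5
  hemi <- if (go_left) (atlas$brain_mask & lh) else (atlas$brain_mask & !lh)
  centre_idx <- sample(which(hemi), 1L)
  ctr <- arrayInd(centre_idx, d)[1, ]

  vol <- runif(1, size_range[1], size_range[2])
  a0 <- (3 * vol / (4 * pi))^(1 / 3)
  skew <- exp(runif(3, -0.35, 0.35))
  ax <- a0 * skew / prod(skew)^(1 / 3)   # preserves volume

  xs <- slice.index(array(0, d), 1)
  ys <- slice.index(array(0, d), 2)
  zs <- slice.index(array(0, d), 3)
  r <- sqrt(((xs - ctr[1]) / ax[1])^2 + ((ys - ctr[2]) / ax[2])^2 +
            ((zs - ctr[3]) / ax[3])^2)
  dist <- (r - 1) * mean(ax)             # ~signed distance to surface, voxels
  p <- stats::plogis(-dist / (edge_softness / 4))
  p[!atlas$brain_mask] <- 0
  if (runif(1) < unilateral_prob) {
    p[if (go_left) !lh else lh] <- 0
  }
  # sub-percent likelihoods are indistinguishable from background noise in
  # probability maps; treating them as 0 also keeps far-tail voxels from
  # becoming spuriously informative near-constant features
  p[p < 0.01] <- 0
  structure(array(pmin(pmax(p, 0), 1), dim = d),
            subject_id = subject_id, class = "lesion_prob")
}

# deterministic per-stage substream derivation from the top-level seed
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% .Machine$integer.max)
}

#' Simulate a synthetic stroke cohort
#'
#' Generates `n_subjects` lesion-probability volumes, a latent damage score
#' per subject, and four correlated clinical motor scales. The latent score
#' is g_i = -effect_scale * sum_v beta(v) * p_i(v), where beta is a
#' positive, voxelwise-heterogeneous effect map supported only on
#' `signal_regions`; more damage inside signal regions lowers the score.
#' Each scale k is slope_k * g_i + intercept_k plus Gaussian noise with sd
#' `noise_sd * |slope_k|`, then clipped to the scale's \[floor, ceiling\].
#'
#' @param atlas `lesion_atlas`.
#' @param n_subjects cohort size (>= 2).
#' @param signal_regions integer atlas labels carrying the behavioural
#'   effect; must be non-empty and a subset of the atlas labels.
#' @param effect_scale positive scaling of damage into the latent score.
#' @param noise_sd per-scale noise, expressed on the latent scale (each
#'   scale's additive sd is `noise_sd * |slope|`).
#' @param beta_sd log-sd of the voxelwise effect heterogeneity inside
#'   signal regions (0 = homogeneous beta of 1).
#' @param scales scale definition table, see [default_motor_scales()].
#' @param size_range,edge_softness,unilateral_prob passed to
#'   [simulate_lesion()].
#' @param seed top-level integer seed; all per-subject streams derive from it.
#' @return list of class `lesion_cohort`: `probs` (list of `lesion_prob`),
#'   `scores` (data.frame, one row per subject, columns `subject_id` + four
#'   scales), `truth` (beta map, latent scores, noise sd, scale transforms,
#'   seed), `atlas`.
#' @export
simulate_cohort <- function(atlas, n_subjects = 50L, signal_regions,
                            effect_scale = 0.02, noise_sd = 0.1,
                            beta_sd = 0.5, scales = default_motor_scales(),
                            size_range = c(40, 800), edge_softness = 1,
                            unilateral_prob = 0.95, seed = 1L) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  if (n_subjects < 2) stop("cohort must have at least 2 subjects")
  if (missing(signal_regions) || length(signal_regions) == 0L)
    stop("signal_regions must name at least one atlas label")
  unknown <- setdiff(signal_regions, atlas$region_table$label)
  if (length(unknown))
    stop("signal_regions not in atlas: ", paste(unknown, collapse = ", "))

  d <- dim(atlas$labels)
  set.seed(derive_seed(seed, 0L))
  beta <- array(0, d)
  in_sig <- atlas$labels %in% signal_regions
  nb <- sum(in_sig)
  beta[in_sig] <- if (beta_sd > 0)
    exp(rnorm(nb, 0, beta_sd) - beta_sd^2 / 2) else 1

  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  probs <- lapply(seq_len(n_subjects), function(i)
    simulate_lesion(atlas, size_range = size_range,
                    edge_softness = edge_softness,
                    unilateral_prob = unilateral_prob,
                    subject_id = ids[i], seed = derive_seed(seed, i)))

  latent <- -effect_scale *
    vapply(probs, function(p) sum(beta * unclass(p)), numeric(1))

  set.seed(derive_seed(seed, n_subjects + 1L))
  score_mat <- sapply(seq_len(nrow(scales)), function(k) {
    raw <- scales$slope[k] * latent + scales$intercept[k] +
      rnorm(n_subjects, 0, noise_sd * abs(scales$slope[k]))
    pmin(pmax(raw, scales$floor[k]), scales$ceiling[k])
  })
  colnames(score_mat) <- scales$name
  scores <- data.frame(subject_id = ids, score_mat, stringsAsFactors = FALSE)

  truth <- list(beta_map = beta, latent_scores = setNames(latent, ids),
                noise_sd = noise_sd, scale_transforms = scales, seed = seed)
  structure(list(probs = probs, scores = scores, truth = truth, atlas = atlas),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("lesion_cohort:", length(x$probs), "subjects on a",
      paste(dim(x$atlas$labels), collapse = "x"), "grid\n")
  invisible(x)
}
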