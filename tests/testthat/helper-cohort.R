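# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

tiny_atlas <- function() memo("tiny_atlas",
  make_atlas(c(16L, 16L, 16L), n_region_pairs = 4L, seed = 11L))

tiny_cohort <- function() memo("tiny_cohort", {
  at <- tiny_atlas()
  sig <- at$region_table$label[at$region_table$category %in% c("motor", "cst")]
  co <- simulate_cohort(at, n_subjects = 20L, signal_regions = sig,
                        size_range = c(20, 200), noise_sd = 0.05, seed = 7L)
  co$functional_mask <- simulate_functional_mask(at)
  co
})

tiny_segmentation <- function() list(threshold = 0.3, min_cluster = 20L,
                                     connectivity = 26L)

# random probability volume with a few blobs, for oracle comparisons
random_prob_volume <- function(dims, seed, density = 0.35) {
  set.seed(seed)
  fg <- array(runif(prod(dims)) < density, dims)
  p <- array(0, dims)
  p[fg] <- runif(sum(fg), 0.31, 1)
  p
}

# strip class and attributes, keep dims
as_plain <- function(x) array(as.vector(unclass(x)), dim(x))
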