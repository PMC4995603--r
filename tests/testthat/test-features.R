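lesion_prob_of <- function(arr, id = "s") {
  structure(arr, subject_id = id, class = "lesion_prob")
}

test_that("voxel patterns read probabilities off in declared column order", {
  d <- c(2L, 2L, 1L)
  v1 <- lesion_prob_of(array(c(0.1, 0.2, 0.3, 0.4), d), "a")
  v2 <- lesion_prob_of(array(0, d), "b")
  mask <- array(c(TRUE, FALSE, TRUE, FALSE), d)  # linear indices 1 and 3
  X <- extract_voxel_patterns(list(v1, v2), mask)
  expect_equal(dim(X), c(2L, 2L))
  expect_equal(unname(X[1, ]), c(0.1, 0.3))  # ascending linear index
  expect_equal(unname(X[2, ]), c(0, 0))      # zero volume -> all-zero row
  expect_identical(attr(X, "voxel_index"), c(1L, 3L))
  # shape contract: 3 subjects x 5-voxel mask
  m5 <- array(FALSE, c(3L, 3L, 2L)); m5[c(1, 4, 7, 10, 13)] <- TRUE
  probs <- lapply(1:3, function(i)
    lesion_prob_of(array(runif(18), c(3L, 3L, 2L)), paste0("s", i)))
  expect_equal(dim(extract_voxel_patterns(probs, m5)), c(3L, 5L))
  expect_error(extract_voxel_patterns(probs, array(FALSE, c(3L, 3L, 2L))),
               "empty mask")
})

test_that("lesion load is the lesioned fraction of each region", {
  d <- c(4L, 4L, 2L)
  region <- array(FALSE, d); region[1:2, 1:2, 1] <- TRUE  # 4 voxels
  big <- array(FALSE, d); big[1:2, 1:4, 1] <- TRUE        # 8 voxels
  lesion_full <- structure(region, class = "lesion_mask")
  lesion_off <- structure(array(FALSE, d), class = "lesion_mask")
  lesion_two <- structure(array(FALSE, d), class = "lesion_mask")
  lesion_two[1, 1:2, 1] <- TRUE                            # 2 of big's 8
  X <- extract_lesion_load(list(lesion_full, lesion_off, lesion_two),
                           list(roi = region, big = big))
  expect_equal(unname(X[, "roi"]), c(1, 0, 0.5))
  expect_equal(unname(X[, "big"]), c(0.5, 0, 0.25))
  expect_error(extract_lesion_load(list(lesion_full),
                                   list(empty = array(FALSE, d))),
               "zero voxels")
  # single region gives a one-column matrix
  X1 <- extract_lesion_load(list(lesion_full, lesion_off), list(r = region))
  expect_equal(dim(X1), c(2L, 1L))
})

test_that("lesion load of the whole brain equals volume fraction", {
  co <- tiny_cohort()
  seg <- lapply(co$probs, segment_lesion, threshold = 0.3, min_cluster = 20L,
                connectivity = 26L)
  X <- extract_lesion_load(seg, list(brain = co$atlas$brain_mask))
  manual <- vapply(seg, function(m) sum(m & co$atlas$brain_mask), numeric(1)) /
    sum(co$atlas$brain_mask)
  expect_equal(unname(X[, 1]), manual)
})

test_that("standardization is row-normalized then train-fitted z-scoring", {
  set.seed(5)
  train <- matrix(runif(60, 0, 2), 10, 6)
  test <- rbind(train[3, ], runif(6))
  std <- standardize_features(train, test)
  expect_equal(unname(colMeans(std$train)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(std$train, 2, sd)), rep(1, 6), tolerance = 1e-10)
  # a test row equal to a training row maps to the same standardized row
  expect_equal(unname(std$test[1, ]), unname(std$train[3, ]), tolerance = 1e-12)
  # row normalization: (3,4) -> (0.6, 0.8)
  s2 <- standardize_features(matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE))
  # recover step 1 from params: mean of rows (0.6,0.8) and (0,0)
  expect_equal(unname(s2$params$mean), c(0.3, 0.4))
  # constant columns are centred but unscaled (divisor 1, no NaN)
  s3 <- standardize_features(cbind(c(2, 2, 2), c(0, 0, 0)))
  expect_true(all(is.finite(s3$train)))
  expect_equal(unname(s3$train), matrix(0, 3, 2))
  expect_error(standardize_features(matrix(1, 1, 3)), "single training row")
})

test_that("row rescaling of raw features does not change the kernel", {
  set.seed(8)
  X <- matrix(runif(40), 8, 5)
  scal <- runif(8, 0.1, 10)
  k1 <- linear_kernel(standardize_features(X)$train)
  k2 <- linear_kernel(standardize_features(X * scal)$train)
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("linear kernel is the dot-product covariance and is PSD", {
  A <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(linear_kernel(A), matrix(c(1, 1, 1, 2), 2, 2))
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(linear_kernel(Q), diag(4), tolerance = 1e-12)
  set.seed(3)
  X <- matrix(rnorm(30), 6, 5)
  K <- linear_kernel(X)
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-8 * sum(diag(K)))
  expect_error(linear_kernel(X, matrix(0, 2, 4)), "dimensions differ")
})

test_that("voxel patterns and lesion load agree for binary single-voxel regions", {
  d <- c(3L, 4L, 2L)
  set.seed(12)
  bin <- lapply(1:4, function(i)
    array(runif(prod(d)) < 0.5, d))
  probs <- lapply(seq_along(bin), function(i)
    lesion_prob_of(array(as.numeric(bin[[i]]), d), paste0("s", i)))
  masks <- lapply(seq_along(bin), function(i)
    structure(bin[[i]], class = "lesion_mask"))
  vox <- c(2L, 7L, 13L)
  mask <- array(FALSE, d); mask[vox] <- TRUE
  regions <- lapply(vox, function(v) { r <- array(FALSE, d); r[v] <- TRUE; r })
  Xp <- extract_voxel_patterns(probs, mask)
  Xl <- extract_lesion_load(masks, regions)
  expect_equal(dim(Xp), dim(Xl))
  expect_equal(as.vector(unclass(Xp)), as.vector(unclass(Xl)))
})

test_that("the first principal component matches an SVD oracle and dominates", {
  set.seed(23)
  for (rep in 1:10) {
    Y <- matrix(rnorm(20, sd = rep(c(3, 2, 1, 0.5), each = 5)), 5, 4)
    f <- fpc_scores(Y)
    o <- oracle_fpc(Y)
    expect_equal(abs(f$train), abs(o$scores), tolerance = 1e-8)
    expect_equal(abs(f$loadings), abs(o$loadings), tolerance = 1e-8)
    # leading-direction optimality over random unit vectors
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    for (k in 1:20) {
      u <- rnorm(4); u <- u / sqrt(sum(u^2))
      expect_gte(var(f$train) + 1e-12, var(Yc %*% u))
    }
  }
})

test_that("identical score columns give symmetric loadings and centred FPC", {
  x <- c(1, 5, 2, 9, 3)
  Y <- cbind(x, x, x, x)
  f <- suppressWarnings(fpc_scores(Y))
  expect_equal(f$loadings, rep(0.5, 4), tolerance = 1e-10)
  expect_equal(f$train, 2 * (x - mean(x)), tolerance = 1e-10)
})

test_that("test subjects are projected with training loadings only", {
  set.seed(2)
  Y <- matrix(rnorm(40), 10, 4)
  f_all <- fpc_scores(Y[1:8, ], Y[9:10, ])
  manual <- sweep(Y[9:10, ], 2, f_all$center, "-") %*% f_all$loadings
  expect_equal(f_all$test, as.numeric(manual), tolerance = 1e-12)
})
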