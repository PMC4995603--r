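test_that("log marginal likelihood matches scaled-identity closed forms", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    y <- rnorm(n)
    q <- sum(y^2)
    expect_equal(log_marginal_likelihood(diag(1, n), y),
                 -q / 2 - n / 2 * log(2 * pi), tolerance = 1e-12)
    cc <- runif(1, 0.2, 5)
    expect_equal(log_marginal_likelihood(diag(cc, n), y),
                 -n / 2 * log(cc) - q / (2 * cc) - n / 2 * log(2 * pi),
                 tolerance = 1e-12)
  }
  # shrinking y toward zero raises L toward the data-free bound
  y <- rnorm(6); K <- crossprod(matrix(rnorm(36), 6)) + diag(0.5, 6)
  Ls <- vapply(c(1, 0.5, 0.1, 0.01), function(s)
    log_marginal_likelihood(K, s * y), numeric(1))
  expect_true(all(diff(Ls) > 0))
  R <- chol(K)
  bound <- -sum(log(diag(R))) - 3 * log(2 * pi)
  expect_true(all(Ls < bound + 1e-9))
})

test_that("GP fit recovers a near-noiseless linear signal", {
  set.seed(14)
  X <- matrix(rnorm(80), 16, 5)
  C <- tcrossprod(X)
  a <- rnorm(16)
  y <- as.numeric(C %*% a)
  y <- y / sd(y)
  m <- gpr_fit(C, y)
  expect_lt(m$noise_variance, 1e-3)
  pred <- gpr_predict(m, C)$mean
  expect_lt(max(abs(pred - y)), 1e-2)
  # reported L equals the likelihood recomputed at the fitted parameters
  L_re <- log_marginal_likelihood(
    m$signal_scale * C + diag(m$noise_variance, 16), y)
  expect_equal(m$log_marginal, L_re, tolerance = 1e-8)
})

test_that("the optimizer never returns a worse likelihood than its start", {
  set.seed(25)
  for (rep in 1:5) {
    n <- 10
    C <- tcrossprod(matrix(rnorm(n * 4), n, 4))
    y <- rnorm(n)
    init <- c(runif(1, 0.2, 3), runif(1, 0.05, 1))
    m <- gpr_fit(C, y, init = init)
    L0 <- log_marginal_likelihood(init[1] * C + diag(init[2], n), y)
    expect_gte(m$log_marginal, L0 - 1e-8)
  }
})

test_that("subject permutation leaves fitted hyperparameters unchanged", {
  set.seed(33)
  n <- 12
  C <- tcrossprod(matrix(rnorm(n * 6), n, 6))
  y <- rnorm(n)
  m1 <- gpr_fit(C, y)
  perm <- sample(n)
  m2 <- gpr_fit(C[perm, perm], y[perm])
  expect_equal(m1$signal_scale, m2$signal_scale, tolerance = 1e-4)
  expect_equal(m1$noise_variance, m2$noise_variance, tolerance = 1e-4)
  expect_equal(m1$log_marginal, m2$log_marginal, tolerance = 1e-6)
})

test_that("linear-kernel GP mean equals the primal ridge oracle", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(4:20, 1); d <- sample(2:30, 1); nt <- sample(1:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    Xs <- matrix(rnorm(nt * d), nt, d)
    y <- rnorm(n)
    s2 <- runif(1, 0.05, 2)
    model <- structure(list(train_kernel = tcrossprod(X), signal_scale = 1,
                            noise_variance = s2, source_weights = NULL,
                            alpha = solve(tcrossprod(X) + diag(s2, n), y)),
                       class = "gp_model")
    dual <- gpr_predict(model, Xs %*% t(X))$mean
    primal <- Xs %*% solve(crossprod(X) + diag(s2, d), crossprod(X, y))
    expect_equal(dual, as.numeric(primal), tolerance = 1e-8)
  }
})

test_that("prediction interpolates training points as noise vanishes", {
  set.seed(55)
  X <- matrix(rnorm(24), 6, 4)
  C <- tcrossprod(X) + diag(1e-6, 6)  # well conditioned
  y <- rnorm(6)
  model <- structure(list(train_kernel = C, signal_scale = 1,
                          noise_variance = 1e-10, source_weights = NULL,
                          alpha = solve(C + diag(1e-10, 6), y)),
                     class = "gp_model")
  pred <- gpr_predict(model, C, test_diag = diag(C))
  expect_equal(pred$mean, y, tolerance = 1e-4)
  expect_true(all(pred$variance >= -1e-8))
})

test_that("single-source MKL reduces to the single-kernel fit", {
  set.seed(66)
  n <- 12
  C <- tcrossprod(matrix(rnorm(n * 5), n, 5))
  y <- rnorm(n)
  g <- gpr_fit(C, y)
  m <- mkl_fit(list(C), y)
  expect_equal(m$log_marginal, g$log_marginal, tolerance = 1e-6)
  expect_equal(m$source_weights[1] , g$signal_scale, tolerance = 1e-3)
})

test_that("analytic MKL gradient matches central finite differences", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 8; M <- 4
    sources <- lapply(seq_len(M), function(i)
      tcrossprod(matrix(rnorm(n * 3), n, 3)))
    y <- rnorm(n)
    w <- runif(M, 0.2, 2)
    v <- runif(1, 0.3, 1.5)
    lg <- mkl_loglik_grad(sources, w, v, y)
    h <- 1e-5
    for (i in seq_len(M)) {
      wp <- w; wp[i] <- w[i] + h
      wm <- w; wm[i] <- w[i] - h
      fd <- (log_marginal_likelihood(
               Reduce(`+`, Map(`*`, wp, sources)) + diag(v, n), y) -
             log_marginal_likelihood(
               Reduce(`+`, Map(`*`, wm, sources)) + diag(v, n), y)) / (2 * h)
      expect_equal(lg$grad_weights[i], fd, tolerance = 1e-5)
    }
    fdv <- (log_marginal_likelihood(
              Reduce(`+`, Map(`*`, w, sources)) + diag(v + h, n), y) -
            log_marginal_likelihood(
              Reduce(`+`, Map(`*`, w, sources)) + diag(v - h, n), y)) / (2 * h)
    expect_equal(lg$grad_noise, fdv, tolerance = 1e-5)
  }
})

test_that("MKL assigns the top weight to the informative source", {
  hits <- 0L
  for (s in 1:6) {
    set.seed(300 + s)
    n <- 30; dper <- 6; M <- 4
    Xs <- lapply(seq_len(M), function(i) matrix(rnorm(n * dper), n, dper))
    y <- as.numeric(Xs[[1]] %*% rnorm(dper)) + rnorm(n, sd = 0.2)
    y <- (y - mean(y)) / sd(y)
    kernels <- lapply(Xs, tcrossprod)
    m <- mkl_fit(kernels, y, seed = s)
    if (which.max(m$source_weights) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("equal sources split the same total kernel as a single fit", {
  set.seed(88)
  n <- 10
  C <- tcrossprod(matrix(rnorm(n * 4), n, 4))
  y <- rnorm(n)
  g <- gpr_fit(C, y)
  m <- mkl_fit(list(C, C, C), y)
  K_mkl <- Reduce(`+`, Map(`*`, m$source_weights, list(C, C, C)))
  expect_equal(K_mkl, g$signal_scale * C, tolerance = 1e-2)
  expect_equal(m$log_marginal, g$log_marginal, tolerance = 1e-5)
})

test_that("adding a pure-noise source cannot hurt the fitted likelihood", {
  set.seed(99)
  n <- 12
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.numeric(X %*% rnorm(4)) + rnorm(n, sd = 0.3)
  y <- (y - mean(y)) / sd(y)
  base <- mkl_fit(list(tcrossprod(X)), y)
  noiseK <- tcrossprod(matrix(rnorm(n * 4), n, 4))
  bigger <- mkl_fit(list(tcrossprod(X), noiseK), y)
  # slack at the optimizer's own convergence scale
  expect_gte(bigger$log_marginal, base$log_marginal - 1e-3)
})
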