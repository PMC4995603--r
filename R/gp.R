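# Cholesky with one jitter retry; returns upper-triangular factor.
chol_pd <- function(K) {
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-8 * mean(diag(K))
    R <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (is.null(R))
      stop("covariance matrix is not positive definite (even after jitter)")
  }
  R
}

#' Log marginal likelihood of a Gaussian process
#'
#' L = -1/2 log|K_y| - 1/2 y' K_y^{-1} y - (n/2) log 2*pi, the standard
#' multivariate Gaussian log-likelihood of the observations under the GP
#' prior plus noise.
#'
#' @param K_y symmetric positive-definite covariance of the observations
#'   (signal kernel plus noise variance on the diagonal).
#' @param y numeric observation vector.
#' @return scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(K_y, y) {
  n <- length(y)
  stopifnot(nrow(K_y) == n, ncol(K_y) == n)
  R <- chol_pd(K_y)
  z <- backsolve(R, y, transpose = TRUE)
  -sum(log(diag(R))) - 0.5 * sum(z^2) - 0.5 * n * log(2 * pi)
}

#' Marginal likelihood and analytic gradient of the multi-kernel GP
#'
#' For K_y = sum_i w_i C_i + sigma_n^2 I, returns L together with the
#' analytic derivatives dL/dw_i = 1/2 tr((alpha alpha' - K_y^{-1}) C_i)
#' (alpha = K_y^{-1} y) and dL/dsigma_n^2. This is the quantity the MKL
#' optimizer ascends; it is exported so the gradient can be checked
#' against finite differences.
#'
#' @param sources list of source covariance matrices C_i.
#' @param weights nonnegative source weights w_i.
#' @param noise_variance sigma_n^2 > 0.
#' @param y observation vector.
#' @return list with `L`, `grad_weights`, `grad_noise`.
#' @export
mkl_loglik_grad <- function(sources, weights, noise_variance, y) {
  n <- length(y)
  Ky <- Reduce(`+`, Map(`*`, weights, sources)) + diag(noise_variance, n)
  R <- chol_pd(Ky)
  Kinv <- chol2inv(R)
  alpha <- as.numeric(Kinv %*% y)
  A <- alpha %o% alpha - Kinv
  list(L = -sum(log(diag(R))) - 0.5 * sum(y * alpha) - 0.5 * n * log(2 * pi),
       grad_weights = vapply(sources, function(Ci) 0.5 * sum(A * Ci),
                             numeric(1)),
       grad_noise = 0.5 * sum(diag(A)))
}

#' Fit a single-kernel Gaussian process regressor
#'
#' Maximizes the log marginal likelihood over a signal scale s and noise
#' variance sigma_n^2, both log-parameterized (hence positive), for the
#' model K_y = s*C + sigma_n^2*I. Optimization is quasi-Newton (L-BFGS-B)
#' with analytic gradients and multiple restarts; the best run is kept and
#' is never worse than the likelihood at the supplied initialization.
#'
#' @param C precomputed linear self-covariance of the training subjects.
#' @param y standardized training targets.
#' @param init length-2 numeric, starting (s, sigma_n^2).
#' @param n_restarts extra random restarts beyond `init` and a
#'   data-scaled start.
#' @param seed seed for the random restarts.
#' @return object of class `gp_model`: kernel, `signal_scale`,
#'   `noise_variance`, `alpha` (= K_y^{-1} y), `log_marginal`,
#'   `convergence` info.
#' @export
gpr_fit <- function(C, y, init = c(1, 0.1), n_restarts = 2, seed = 1L) {
  C <- as.matrix(C)
  n <- length(y)
  stopifnot(nrow(C) == n, ncol(C) == n, all(init > 0))
  I <- diag(1, n)

  # failed factorizations yield a large finite penalty so the line search
  # can back off instead of aborting the whole run
  negL <- function(theta) {
    s <- exp(theta[1]); v <- exp(theta[2])
    tryCatch(-log_marginal_likelihood(s * C + v * I, y),
             error = function(e) 1e10)
  }
  negG <- function(theta) {
    s <- exp(theta[1]); v <- exp(theta[2])
    Ky <- s * C + v * I
    R <- tryCatch(chol_pd(Ky), error = function(e) NULL)
    if (is.null(R)) return(c(0, 0))
    Kinv <- chol2inv(R)
    alpha <- as.numeric(Kinv %*% y)
    A <- alpha %o% alpha - Kinv
    # chain rule through the log-parameterization
    -c(0.5 * sum(A * C) * s, 0.5 * sum(diag(A)) * v)
  }

  mean_diag <- mean(diag(C))
  starts <- list(log(init),
                 log(c(1 / max(mean_diag, 1e-12), 0.1)))
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts))
    starts[[length(starts) + 1L]] <- rnorm(2, 0, 1.5)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, negL, negG, method = "L-BFGS-B",
            lower = rep(-15, 2), upper = rep(15, 2),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed from every start (non-PD covariance?)")
  L_init <- -negL(log(init))
  L_fit <- -best$value
  if (L_fit < L_init - 1e-8) {  # ascent contract: never worse than init
    best <- list(par = log(init), value = -L_init, convergence = 0L)
    L_fit <- L_init
  }
  s <- exp(best$par[1]); v <- exp(best$par[2])
  Ky <- s * C + v * I
  R <- chol_pd(Ky)
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  structure(list(train_kernel = C, signal_scale = s, noise_variance = v,
                 source_weights = NULL, alpha = as.numeric(alpha),
                 log_marginal = L_fit, y = y,
                 convergence = best$convergence),
            class = "gp_model")
}

#' Predict from a fitted Gaussian process
#'
#' Predictive mean k*' K_y^{-1} y (= cross kernel times the precomputed
#' alpha coefficients) and, when prior self-covariances of the test points
#' are supplied, the predictive variance of the latent function. Cross
#' kernels are passed raw (plain dot products); the model's fitted scale or
#' source weights are applied internally so train and test use identical
#' scaling.
#'
#' @param model a `gp_model` from [gpr_fit()] or [mkl_fit()].
#' @param cross test x train covariance: a matrix (single kernel) or a
#'   list of per-source matrices (MKL model).
#' @param test_diag optional raw prior self-covariance diagonal of the test
#'   points (vector, or list of vectors for MKL); enables variances.
#' @return list with `mean` and (if requested) `variance`, both per test
#'   subject.
#' @export
gpr_predict <- function(model, cross, test_diag = NULL) {
  stopifnot(inherits(model, "gp_model"))
  if (is.null(model$source_weights)) {
    Kstar <- model$signal_scale * as.matrix(cross)
    Ktrain <- model$signal_scale * model$train_kernel
    prior_diag <- if (!is.null(test_diag)) model$signal_scale * test_diag
  } else {
    w <- model$source_weights
    stopifnot(is.list(cross), length(cross) == length(w))
    Kstar <- Reduce(`+`, Map(function(wi, Ci) wi * as.matrix(Ci), w, cross))
    Ktrain <- Reduce(`+`, Map(`*`, w, model$train_kernels))
    prior_diag <- if (!is.null(test_diag))
      Reduce(`+`, Map(`*`, w, test_diag))
  }
  if (ncol(Kstar) != length(model$alpha))
    stop("cross kernel columns do not match training subjects")
  mu <- as.numeric(Kstar %*% model$alpha)
  out <- list(mean = mu)
  if (!is.null(prior_diag)) {
    Ky <- Ktrain + diag(model$noise_variance, length(model$alpha))
    R <- chol_pd(Ky)
    V <- backsolve(R, t(Kstar), transpose = TRUE)
    out$variance <- pmax(prior_diag - colSums(V^2), -1e-8)
  }
  out
}

#' Fit a multiple-kernel Gaussian process by marginal-likelihood ascent
#'
#' The GP covariance is the weighted sum K = sum_i w_i C_i over M source
#' kernels (plus a noise term sigma_n^2 I), and the nonnegative weights —
#' interpretable as the relevance of each source when all sources are
#' scaled identically — are learned by maximizing the multivariate Gaussian
#' log marginal likelihood. Positivity is enforced by optimizing log
#' weights; gradients are analytic, dL/dw_i = 1/2 tr((alpha alpha' -
#' K_y^{-1}) C_i). Quasi-Newton ascent with restarts from a uniform-weight
#' start and random log-weight starts.
#'
#' @param sources list of M training self-covariance matrices sharing
#'   dimensions and subject order (built from identically standardized
#'   features).
#' @param y standardized training targets.
#' @param noise `"optimize"` (default) to learn sigma_n^2 jointly, or a
#'   fixed positive value.
#' @param n_restarts random restarts beyond the uniform start.
#' @param max_iter,tol optimizer iteration cap and convergence tolerance
#'   on the likelihood.
#' @param seed seed for random restarts.
#' @return `gp_model` with `source_weights` (raw), `source_weights_norm`
#'   (sum-normalized), `noise_variance`, `alpha`, `log_marginal`,
#'   `source_names`.
#' @export
mkl_fit <- function(sources, y, noise = "optimize", n_restarts = 2,
                    max_iter = 500, tol = 1e-8, seed = 1L) {
  stopifnot(is.list(sources), length(sources) >= 1)
  M <- length(sources)
  n <- length(y)
  sources <- lapply(sources, as.matrix)
  for (Ci in sources)
    if (!all(dim(Ci) == c(n, n))) stop("source kernel dimensions differ")
  opt_noise <- identical(noise, "optimize")
  if (!opt_noise) stopifnot(is.numeric(noise), noise > 0)
  I <- diag(1, n)

  assemble <- function(theta) {
    w <- exp(theta[seq_len(M)])
    v <- if (opt_noise) exp(theta[M + 1L]) else noise
    Ky <- Reduce(`+`, Map(`*`, w, sources)) + v * I
    list(w = w, v = v, Ky = Ky)
  }
  negL <- function(theta) {
    a <- assemble(theta)
    tryCatch(-log_marginal_likelihood(a$Ky, y), error = function(e) 1e10)
  }
  negG <- function(theta) {
    a <- assemble(theta)
    lg <- tryCatch(mkl_loglik_grad(sources, a$w, a$v, y),
                   error = function(e) NULL)
    if (is.null(lg)) return(rep(0, length(theta)))
    gw <- lg$grad_weights * a$w          # chain rule: theta = log w
    g <- if (opt_noise) c(gw, lg$grad_noise * a$v) else gw
    -g
  }

  p <- M + if (opt_noise) 1L else 0L
  mean_diag <- mean(vapply(sources, function(C) mean(diag(C)), numeric(1)))
  uniform <- c(rep(log(1 / (M * max(mean_diag, 1e-12))), M),
               if (opt_noise) log(0.1))
  starts <- list(uniform)
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts))
    starts[[length(starts) + 1L]] <- rnorm(p, uniform[1], 1.5)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, negL, negG, method = "L-BFGS-B",
            lower = rep(-15, p), upper = rep(15, p),
            control = list(maxit = max_iter, factr = tol / 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("MKL optimizer failed from every start")
  if (best$convergence != 0L)
    warning("MKL optimizer did not fully converge; best-so-far returned")
  a <- assemble(best$par)
  R <- chol_pd(a$Ky)
  alpha <- backsolve(R, backsolve(R, y, transpose = TRUE))
  structure(list(train_kernels = sources,
                 train_kernel = Reduce(`+`, Map(`*`, a$w, sources)),
                 source_weights = a$w,
                 source_weights_norm = a$w / sum(a$w),
                 source_names = names(sources),
                 noise_variance = a$v, alpha = as.numeric(alpha),
                 log_marginal = -best$value, y = y,
                 convergence = best$convergence),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  if (is.null(x$source_weights)) {
    cat("gp_model (single kernel): s =", signif(x$signal_scale, 4),
        " sigma_n^2 =", signif(x$noise_variance, 4),
        " L =", signif(x$log_marginal, 6), "\n")
  } else {
    cat("gp_model (MKL,", length(x$source_weights), "sources): sigma_n^2 =",
        signif(x$noise_variance, 4), " L =", signif(x$log_marginal, 6), "\n")
    w <- sort(x$source_weights, decreasing = TRUE)
    print(utils::head(signif(w, 4), 10))
  }
  invisible(x)
}

#' Source-weight table sorted by relevance
#'
#' @param model an MKL `gp_model`.
#' @return data.frame of sources sorted by descending raw weight, with the
#'   sum-normalized weights and each source's kernel scale (mean diagonal
#'   of its covariance) alongside. The kernel scale matters for
#'   interpretation: a source that carries no variation (for instance a
#'   region never lesioned in the cohort) has a near-zero kernel, so its
#'   weight is unidentifiable and should be discounted.
#' @export
weight_table <- function(model) {
  stopifnot(inherits(model, "gp_model"), !is.null(model$source_weights))
  nm <- model$source_names %||% sprintf("source%02d",
                                        seq_along(model$source_weights))
  ks <- vapply(model$train_kernels, function(K) mean(diag(K)), numeric(1))
  o <- order(model$source_weights, decreasing = TRUE)
  data.frame(source = nm[o], weight = model$source_weights[o],
             weight_normalized = model$source_weights_norm[o],
             kernel_scale = ks[o],
             row.names = NULL, stringsAsFactors = FALSE)
}
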