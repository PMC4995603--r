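# Independent brute-force oracles, deliberately written with different
# algorithms and data layouts than the package implementation.

# flood-fill connected components: explicit stack over array indices
flood_fill_components <- function(fg, connectivity) {
  d <- dim(fg)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nnz <- rowSums(offs != 0)
  offs <- switch(as.character(connectivity),
                 "6" = offs[nnz == 1, , drop = FALSE],
                 "18" = offs[nnz >= 1 & nnz <= 2, , drop = FALSE],
                 "26" = offs[nnz >= 1, , drop = FALSE])
  lab <- array(0L, d)
  nxt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!fg[i, j, k] || lab[i, j, k] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j, k))
    lab[i, j, k] <- nxt
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        if (fg[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- nxt
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  lab
}

# oracle segmentation built on the oracle component labeller
oracle_segment <- function(prob, threshold, min_cluster, connectivity) {
  fg <- prob > threshold
  lab <- flood_fill_components(fg, connectivity)
  keep <- array(FALSE, dim(prob))
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      vox <- lab == l
      if (sum(vox) >= min_cluster) keep <- keep | vox
    }
  }
  keep
}

# first-principal-component oracle through the SVD (package uses eigen on
# the covariance matrix)
oracle_fpc <- function(Y) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  v <- sv$v[, 1]
  if (sum(v) < 0) v <- -v
  list(scores = as.numeric(Yc %*% v), loadings = v)
}

# exact two-sided rank-sum p-value by enumeration of all rank assignments
oracle_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n)])
  combs <- utils::combn(n + m, n)
  sums <- colSums(matrix(seq_len(n + m)[combs], nrow = n))
  mu <- n * (n + m + 1) / 2
  p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
  p
}
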