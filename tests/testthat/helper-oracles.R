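# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain double loops, exhaustive enumeration and
# from-scratch formulas.

# O(n^2) double-loop silhouette oracle
brute_silhouette <- function(M, labels, squared = TRUE) {
  n <- nrow(M)
  d <- function(i, j) {
    v <- sum((M[i, ] - M[j, ])^2)
    if (squared) v else sqrt(v)
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == g)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Exhaustive minimum k-means SSE over all partitions into k non-empty
# clusters, vectorized over assignment vectors (first point pinned to
# cluster 1 to break label symmetry). Feasible for k = 2, n <= 13 and
# k = 3, n <= 11.
brute_best_sse <- function(X, k) {
  n <- nrow(X)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n - 1L)))
  A <- cbind(1L, A)
  keep <- rep(TRUE, nrow(A))
  for (c in seq_len(k)) keep <- keep & (rowSums(A == c) > 0L)
  A <- A[keep, , drop = FALSE]
  sq <- sum(X^2)
  sse <- rep(sq, nrow(A))
  for (c in seq_len(k)) {
    Z <- (A == c) * 1
    S <- Z %*% X                       # cluster sums
    m <- rowSums(Z)
    sse <- sse - rowSums(S^2) / m
  }
  min(sse)
}

# direct SSE of a labelled clustering (independent summation)
label_sse <- function(X, labels) {
  s <- 0
  for (c in unique(labels)) {
    pts <- X[labels == c, , drop = FALSE]
    ctr <- colMeans(pts)
    s <- s + sum(sweep(pts, 2, ctr)^2)
  }
  s
}

# smooth unit-variance Gaussian field generator (independent of the
# package's smooth_noise): FFT-free direct convolution with generous padding
smooth_field <- function(n_curves, len = 101, fwhm = 15) {
  sigma <- fwhm / sqrt(8 * log(2))
  half <- ceiling(4 * sigma)
  kern <- exp(-0.5 * (seq(-half, half) / sigma)^2)
  kern <- kern / sqrt(sum(kern^2))
  t(vapply(seq_len(n_curves), function(i) {
    z <- rnorm(len + 2 * half)
    as.numeric(stats::filter(z, kern, sides = 2))[(half + 1):(half + len)]
  }, numeric(len)))
}

# independent root-solve of the 1D t-field expected-Euler-characteristic
# equation (two-tailed, alpha split across tails)
ec_threshold_oracle <- function(alpha, df, fwhm, field_length = 100) {
  resels <- field_length / fwhm
  g <- function(u) {
    ec <- (1 - pt(u, df)) +
      resels * (4 * log(2))^0.5 / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
    ec - alpha / 2
  }
  uniroot(g, c(0.01, 50), tol = 1e-12)$root
}

# all permutations of 1..k, written independently (recursive prepend)
perm_list <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perm_list(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# small deterministic cohort for fast end-to-end tests
tiny_cohort <- function(seed = 1, sizes = c(3L, 4L, 4L, 3L), n_steps = 2L) {
  generate_cohort(sizes = sizes, seed = seed, n_steps = n_steps)
}
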