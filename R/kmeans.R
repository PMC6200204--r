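#' @title Multi-restart k-means and silhouette cluster quality
#'
#' @description
#' Clustering uses Lloyd's algorithm with Forgy initialization (k distinct
#' seed rows drawn from the data), run `n_restarts` times per k; the restart
#' with the smallest sum of squared errors (SSE, squared Euclidean distance
#' of every row to its cluster centroid) is kept as the solution for that k.
#' Cluster quality is measured by the silhouette value
#' \deqn{s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}}}
#' where `a(i)` is the mean distance of row i to the other members of its own
#' cluster and `b(i)` the smallest mean distance to any other cluster;
#' distances here are squared Euclidean, and members of singleton clusters
#' get s(i) = 0. The whole procedure is repeated R times with independent
#' random streams to measure how repeatable the allocations are.
#'
#' @name clustering
NULL

# squared Euclidean distances from rows of M to rows of C (n x k)
dist_sq_to <- function(M, C) {
  d2 <- outer(rowSums(M^2), rep(1, nrow(C))) - 2 * M %*% t(C) +
    outer(rep(1, nrow(M)), rowSums(C^2))
  d2[d2 < 0] <- 0   # guard tiny negative rounding
  d2
}

#' One Lloyd k-means run from random data-row seeds
#'
#' Iterates assignment and centroid update until assignments are stable or
#' the maximum centroid shift falls below `tol` (default 1e-8), up to
#' `max_iter` iterations. An emptied cluster is re-seeded with the point
#' farthest from its current centroid, keeping k fixed. Within a run the SSE
#' is non-increasing across iterations.
#'
#' @param M numeric matrix (rows = participants).
#' @param k number of clusters, `2 <= k <= nrow(M)` (k = 1 allowed for the
#'   degenerate grand-mean solution).
#' @param tol centroid-shift convergence tolerance.
#' @param max_iter iteration cap.
#' @return a `kmeans_result`: `list(k, labels, centroids, sse, n_iter)`.
#'   Uses the current RNG stream.
#' @export
kmeans_single <- function(M, k, tol = 1e-8, max_iter = 300L) {
  M <- unclass(M)
  n <- nrow(M)
  if (k > n)
    stop("k_exceeds_n: k = ", k, " but only ", n, " rows", call. = FALSE)
  if (!all(is.finite(M)))
    stop("nonfinite_data: M must be finite", call. = FALSE)
  C <- M[sample.int(n, k), , drop = FALSE]
  labels <- rep(0L, n)
  n_iter <- 0L
  sse_trace <- numeric(0)
  repeat {
    n_iter <- n_iter + 1L
    d2 <- dist_sq_to(M, C)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(new_labels))
    while (length(empty) > 0) {
      own_d2 <- d2[cbind(seq_len(n), new_labels)]
      far <- which.max(own_d2)
      new_labels[far] <- empty[1L]
      C[empty[1L], ] <- M[far, ]
      empty <- setdiff(seq_len(k), unique(new_labels))
    }
    C_new <- t(vapply(seq_len(k), function(j)
      colMeans(M[new_labels == j, , drop = FALSE]), numeric(ncol(M))))
    shift <- max(abs(C_new - C))
    stable <- all(new_labels == labels)
    labels <- new_labels
    C <- C_new
    sse_trace <- c(sse_trace,
                   sum(dist_sq_to(M, C)[cbind(seq_len(n), labels)]))
    if (stable || shift < tol || n_iter >= max_iter) break
  }
  sse <- sse_trace[length(sse_trace)]
  structure(list(k = as.integer(k), labels = labels, centroids = C,
                 sse = sse, n_iter = n_iter, sse_trace = sse_trace),
            class = "kmeans_result")
}

#' Best-of-n-restarts k-means
#'
#' Runs [kmeans_single()] `n_restarts` times and returns the solution with
#' the minimal SSE; ties keep the earliest restart.
#'
#' @inheritParams kmeans_single
#' @param n_restarts number of random restarts (default 50).
#' @return the winning `kmeans_result`, with `restart_index` and
#'   `restart_sse` (all restart SSEs) attached.
#' @export
kmeans_restarts <- function(M, k, n_restarts = 50L, tol = 1e-8,
                            max_iter = 300L) {
  stopifnot(n_restarts >= 1)
  best <- NULL
  all_sse <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- kmeans_single(M, k, tol = tol, max_iter = max_iter)
    all_sse[r] <- fit$sse
    if (is.null(best) || fit$sse < best$sse) {
      best <- fit
      best$restart_index <- r
    }
  }
  best$restart_sse <- all_sse
  best
}

#' Silhouette values with squared Euclidean distances
#'
#' Computes a(i), b(i) and s(i) for every row given cluster labels. The
#' distance entering a(i) and b(i) is the squared Euclidean distance by
#' default (`distance = "euclidean"` is available for cross-checks against
#' conventional silhouette implementations). Members of singleton clusters
#' receive s(i) = 0.
#'
#' @param M data matrix.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @param distance `"squared_euclidean"` (default) or `"euclidean"`.
#' @return a `silhouette_result`: `list(s_values, a_values, b_values,
#'   mean_s)`.
#' @export
silhouette_values <- function(M, labels,
                              distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  M <- unclass(M)
  n <- nrow(M)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2L)
    stop("single_cluster: silhouette requires at least 2 clusters",
         call. = FALSE)
  # direct pairwise distances (no quadratic expansion, which loses precision)
  D <- as.matrix(stats::dist(M))
  if (distance == "squared_euclidean") D <- D^2
  a <- b <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1L) { a[i] <- NA_real_; b[i] <- NA_real_; next }
    a[i] <- sum(D[i, own]) / (n_own - 1L)   # excludes self (D[i,i] = 0)
    b[i] <- min(vapply(setdiff(ks, labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1L)))
  }
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0   # a == b == 0: duplicated points across clusters
  structure(list(s_values = s, a_values = a, b_values = b,
                 mean_s = mean(s)),
            class = "silhouette_result")
}

#' Run the full clustering ensemble
#'
#' For every k in `k_range` and every repetition `1..R`, runs
#' `n_restarts`-restart k-means and computes silhouettes on the winning
#' restart. Each repetition has its own RNG seed derived from `master_seed`,
#' recorded for replay.
#'
#' @param M feature matrix.
#' @param k_range integer vector of cluster counts (default 2:5).
#' @param n_restarts restarts per k per repetition (default 50).
#' @param R number of repetitions (default 10).
#' @param master_seed integer seed driving all randomness.
#' @return a `cluster_ensemble`: `list(k_range, R, rep_seeds, runs)` where
#'   `runs[[as.character(k)]][[r]]` holds `kmeans` and `silhouette` results.
#' @export
run_ensemble <- function(M, k_range = 2:5, n_restarts = 50L, R = 10L,
                         master_seed = 1L) {
  n <- nrow(M)
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("bad_k_range: k_range must lie within [2, n-1]", call. = FALSE)
  rep_seeds <- with_seed(master_seed,
                         sample.int(.Machine$integer.max, R))
  runs <- lapply(k_range, function(k) vector("list", R))
  names(runs) <- as.character(k_range)
  for (r in seq_len(R)) {
    with_seed(rep_seeds[r], {
      for (k in k_range) {
        km <- kmeans_restarts(M, k, n_restarts = n_restarts)
        sil <- silhouette_values(M, km$labels)
        runs[[as.character(k)]][[r]] <- list(kmeans = km, silhouette = sil)
      }
    })
  }
  structure(list(k_range = as.integer(k_range), R = as.integer(R),
                 rep_seeds = rep_seeds, runs = runs,
                 participant_ids = rownames(M)),
            class = "cluster_ensemble")
}

#' Serialize / restore a cluster ensemble as JSON
#'
#' Stores, per k and repetition, the seed, labels, SSE and silhouette
#' values; numeric values round-trip exactly.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param path JSON path.
#' @export
write_ensemble_json <- function(ensemble, path) {
  out <- list(k_range = ensemble$k_range, R = ensemble$R,
              rep_seeds = ensemble$rep_seeds,
              participant_ids = ensemble$participant_ids,
              runs = lapply(ensemble$runs, function(per_k)
                lapply(per_k, function(run)
                  list(labels = run$kmeans$labels, sse = run$kmeans$sse,
                       s_values = run$silhouette$s_values))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  runs <- lapply(raw$runs, function(per_k)
    lapply(per_k, function(run)
      list(kmeans = list(labels = vapply(run$labels, as.integer, integer(1)),
                         sse = as.numeric(run$sse)),
           silhouette = list(
             s_values = vapply(run$s_values, as.numeric, numeric(1)),
             mean_s = mean(vapply(run$s_values, as.numeric, numeric(1)))))))
  structure(list(k_range = vapply(raw$k_range, as.integer, integer(1)),
                 R = as.integer(raw$R),
                 rep_seeds = vapply(raw$rep_seeds, as.numeric, numeric(1)),
                 participant_ids = vapply(raw$participant_ids, as.character, ""),
                 runs = runs),
            class = "cluster_ensemble")
}
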