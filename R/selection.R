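#' @title Allocation repeatability and choice of the number of clusters
#'
#' @description
#' K-means labels are arbitrary per run, so before allocations can be
#' compared across the R repetitions each repetition's labels are relabelled
#' by the bijection on `{1..k}` that maximizes agreement with repetition 1
#' (exact optimal assignment on the k x k contingency table; for k <= 5 all
#' k! permutations are enumerated). Repeatability is then the percentage of
#' participant-by-repetition allocation records that agree with that
#' participant's modal aligned label. The final k is the largest k whose
#' repeatability meets a threshold (default 95%), operationalizing "the
#' largest number of groupings while retaining high cluster quality and
#' repeatability"; consolidated labels are each participant's modal aligned
#' label, with silhouette-based tie-breaking.
#'
#' @name selection
NULL

# all permutations of 1..k as a matrix (k! rows), by insertion
perms <- function(k) {
  k <- as.integer(k)
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  out <- NULL
  for (i in seq_len(nrow(sub))) {
    row <- sub[i, ]
    for (pos in seq_len(k)) {
      out <- rbind(out, append(row, k, after = pos - 1L))
    }
  }
  out
}

# best permutation (new label for old label j = perm[j]) aligning `labels`
# to `ref`, maximizing agreement
best_permutation <- function(ref, labels, k) {
  tab <- matrix(0L, k, k)
  for (i in seq_along(ref)) tab[labels[i], ref[i]] <- tab[labels[i], ref[i]] + 1L
  P <- perms(k)
  scores <- vapply(seq_len(nrow(P)), function(p)
    sum(tab[cbind(seq_len(k), P[p, ])]), numeric(1L))
  P[which.max(scores), ]
}

#' Align ensemble labels across repetitions
#'
#' @param ensemble a `cluster_ensemble` (or an R x n label matrix).
#' @param k which cluster count to align (ignored when a matrix is given).
#' @return an `aligned_ensemble`: `list(k, labels, s_values, mappings)` with
#'   `labels` an R x n matrix of aligned labels (repetition 1 is the
#'   reference) and `s_values` the matching R x n silhouette matrix (NULL
#'   when a bare matrix was supplied).
#' @export
align_labels <- function(ensemble, k = NULL) {
  if (is.matrix(ensemble)) {
    lab <- ensemble
    sil <- NULL
    if (is.null(k)) k <- max(lab)
  } else {
    stopifnot(inherits(ensemble, "cluster_ensemble"), !is.null(k))
    per_k <- ensemble$runs[[as.character(k)]]
    lab <- do.call(rbind, lapply(per_k, function(run) run$kmeans$labels))
    sil <- do.call(rbind, lapply(per_k, function(run) run$silhouette$s_values))
  }
  k <- as.integer(k)
  R <- nrow(lab)
  if (R < 2L)
    stop("too_few_repetitions: alignment needs >= 2 repetitions",
         call. = FALSE)
  storage.mode(lab) <- "integer"
  aligned <- lab
  mappings <- vector("list", R)
  mappings[[1L]] <- seq_len(k)
  for (r in 2:R) {
    p <- best_permutation(lab[1L, ], lab[r, ], k)
    aligned[r, ] <- p[lab[r, ]]
    mappings[[r]] <- p
  }
  structure(list(k = as.integer(k), labels = aligned, s_values = sil,
                 mappings = mappings),
            class = "aligned_ensemble")
}

# modal label per participant (column); ties -> silhouette tie-break when
# available, else smallest label
modal_labels <- function(aligned) {
  lab <- aligned$labels
  vapply(seq_len(ncol(lab)), function(i) {
    tab <- table(lab[, i])
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    if (!is.null(aligned$s_values)) {
      cand <- which(lab[, i] %in% top)
      return(as.integer(lab[cand[which.max(aligned$s_values[cand, i])], i]))
    }
    min(top)
  }, integer(1L))
}

#' Allocation repeatability of an aligned ensemble
#'
#' An allocation record is one participant in one repetition (n x R records
#' in total); a record counts as switched when its aligned label differs
#' from that participant's modal aligned label.
#'
#' @param aligned an `aligned_ensemble`.
#' @return list with `repeatability_pct`, `n_records`, `n_switch_events`
#'   (switched records), `n_switching_participants`, and per-participant
#'   `switches_per_participant`.
#' @export
repeatability <- function(aligned) {
  lab <- aligned$labels
  modal <- modal_labels(aligned)
  sw <- sweep(lab, 2L, modal, `!=`)
  per_participant <- colSums(sw)
  n_records <- length(lab)
  n_switch <- sum(per_participant)
  list(repeatability_pct = 100 * (1 - n_switch / n_records),
       n_records = n_records,
       n_switch_events = as.integer(n_switch),
       n_switching_participants = as.integer(sum(per_participant > 0)),
       switches_per_participant = as.integer(per_participant))
}

#' Consolidated ("median") cluster allocation
#'
#' Per participant, the most frequent aligned label across repetitions; a
#' tie between labels is resolved by the label of the repetition in which
#' that participant attained the highest silhouette value (among the tied
#' labels).
#'
#' @param aligned an `aligned_ensemble`.
#' @return integer vector of final labels, one per participant.
#' @export
median_allocation <- function(aligned) {
  modal_labels(aligned)
}

#' Choose the number of clusters
#'
#' The chosen k is the largest k whose allocation repeatability meets
#' `repeatability_threshold`; if no k qualifies, the choice falls back to
#' the smallest k in range with `fallback = TRUE` flagged. A quality warning
#' is attached when the chosen k's mean silhouette is below that of every
#' smaller candidate k.
#'
#' @param metrics data frame with columns `k`, `mean_s`, `sd_s`,
#'   `repeatability_pct` (one row per k).
#' @param repeatability_threshold percentage threshold (default 95).
#' @return list with `chosen_k`, `fallback`, `quality_warning`.
#' @export
select_k <- function(metrics, repeatability_threshold = 95) {
  ok <- metrics$k[metrics$repeatability_pct >= repeatability_threshold]
  if (length(ok) == 0L) {
    return(list(chosen_k = min(metrics$k), fallback = TRUE,
                quality_warning = FALSE))
  }
  chosen <- max(ok)
  smaller <- metrics$mean_s[metrics$k < chosen]
  warn <- length(smaller) > 0 &&
    all(metrics$mean_s[metrics$k == chosen] < smaller)
  list(chosen_k = as.integer(chosen), fallback = FALSE,
       quality_warning = warn)
}

#' Per-participant boundary analysis
#'
#' Pairs each participant's mean silhouette value (across repetitions) with
#' the number of repetitions in which its allocation deviated from its modal
#' cluster, quantifying the boundary effect: allocations switch more as s
#' approaches zero.
#'
#' @param aligned an `aligned_ensemble` carrying silhouette values.
#' @return data frame `participant, mean_s, n_switches`.
#' @export
boundary_analysis <- function(aligned) {
  if (is.null(aligned$s_values))
    stop("missing_silhouettes: aligned ensemble carries no s values",
         call. = FALSE)
  rep_stats <- repeatability(aligned)
  data.frame(participant = seq_len(ncol(aligned$labels)),
             mean_s = colMeans(aligned$s_values),
             n_switches = rep_stats$switches_per_participant)
}

#' Build the full selection report for an ensemble
#'
#' Aligns every k, computes per-k silhouette summaries (mean and SD over all
#' participant-by-repetition s values) and repeatability, applies the
#' selection rule, and consolidates final labels at the chosen k.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param repeatability_threshold see [select_k()].
#' @return a `selection_report`: `list(metrics, chosen_k, fallback,
#'   quality_warning, final_labels, boundary, aligned)`.
#' @export
selection_report <- function(ensemble, repeatability_threshold = 95) {
  aligned_all <- lapply(ensemble$k_range, function(k) align_labels(ensemble, k))
  names(aligned_all) <- as.character(ensemble$k_range)
  metrics <- do.call(rbind, lapply(seq_along(ensemble$k_range), function(j) {
    k <- ensemble$k_range[j]
    s_mat <- aligned_all[[j]]$s_values
    rep_stats <- repeatability(aligned_all[[j]])
    data.frame(k = k, mean_s = mean(s_mat), sd_s = stats::sd(as.vector(s_mat)),
               repeatability_pct = rep_stats$repeatability_pct,
               n_switch_events = rep_stats$n_switch_events,
               n_switching_participants = rep_stats$n_switching_participants)
  }))
  choice <- select_k(metrics, repeatability_threshold)
  aligned_chosen <- aligned_all[[as.character(choice$chosen_k)]]
  final <- median_allocation(aligned_chosen)
  boundary <- boundary_analysis(aligned_chosen)
  structure(list(metrics = metrics, chosen_k = choice$chosen_k,
                 fallback = choice$fallback,
                 quality_warning = choice$quality_warning,
                 final_labels = final, boundary = boundary,
                 aligned = aligned_all,
                 repeatability_threshold = repeatability_threshold,
                 participant_ids = ensemble$participant_ids),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Cluster selection report\n")
  cat(format_selection_table(x), sep = "\n")
  cat("\nChosen k:", x$chosen_k,
      if (x$fallback) "(fallback: no k met the repeatability threshold)",
      if (x$quality_warning) "(warning: lower mean silhouette than all smaller k)",
      "\n")
  invisible(x)
}

#' Render the per-k metric table as markdown
#'
#' @param report a `selection_report`.
#' @return character vector of markdown lines.
#' @export
format_selection_table <- function(report) {
  m <- report$metrics
  c("| k | mean s | SD s | repeatability % | switching participants |",
    "|---|--------|------|-----------------|------------------------|",
    sprintf("| %d | %.3f | %.3f | %.1f | %d |", m$k, m$mean_s, m$sd_s,
            m$repeatability_pct, m$n_switching_participants))
}

#' Serialize a selection report to JSON
#'
#' @param report a `selection_report`.
#' @param path JSON path.
#' @export
write_selection_json <- function(report, path) {
  jsonlite::write_json(
    list(metrics = report$metrics, chosen_k = report$chosen_k,
         fallback = report$fallback, quality_warning = report$quality_warning,
         final_labels = report$final_labels,
         repeatability_threshold = report$repeatability_threshold,
         participant_ids = report$participant_ids),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
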