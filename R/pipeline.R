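#' @title End-to-end pipeline orchestration
#'
#' @description
#' `run_gait_pipeline()` chains the stages: preprocessing into the
#' participant-by-505 feature matrix, the multi-restart k-means ensemble
#' over k = 2-5, silhouette/repeatability-based selection of the final k,
#' and the SPM comparison of each final cluster against the augmented ND
#' reference. All randomness derives from one master seed, so a run is
#' fully reproducible from its configuration.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Defaults mirror the study settings: k = 2-5, 50 restarts per k, 10
#' ensemble repetitions, 95% repeatability threshold, alpha 0.05, and a
#' 5/12/12/8 synthetic cohort at amplitude scale 1.
#'
#' @param ... overrides for any field.
#' @return a named list configuration.
#' @export
pipeline_config <- function(...) {
  cfg <- list(k_range = 2:5, n_restarts = 50L, n_repetitions = 10L,
              repeatability_threshold = 95, alpha = 0.05, master_seed = 1L,
              sizes = c(5L, 12L, 12L, 8L), amplitude_scale = 1,
              noise_params = default_noise_params(), n_steps = 5L,
              interpolation = "linear")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown_config_field: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unknown fields are rejected; missing fields keep their defaults.
#'
#' @param path YAML file.
#' @return a validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("package 'yaml' is required to read YAML configurations",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' @param participants list of `participant_waveforms` or a
#'   `synthetic_cohort` (whose bundled ND reference is then used by
#'   default).
#' @param nd_ref an `nd_reference` for the SPM comparison; defaults to the
#'   cohort's own when a `synthetic_cohort` is given.
#' @param config a [pipeline_config()] list.
#' @return a `gait_pipeline_result`: `list(feature_matrix, ensemble,
#'   selection, deviation_report, config)`.
#' @export
run_gait_pipeline <- function(participants, nd_ref = NULL,
                              config = pipeline_config()) {
  if (inherits(participants, "synthetic_cohort")) {
    if (is.null(nd_ref)) nd_ref <- participants$nd_ref
    participants <- participants$participants
  }
  if (is.null(nd_ref))
    stop("missing_nd_reference: supply nd_ref for the SPM comparison",
         call. = FALSE)
  M <- cohort_matrix(participants, method = config$interpolation)
  ensemble <- run_ensemble(M, k_range = config$k_range,
                           n_restarts = config$n_restarts,
                           R = config$n_repetitions,
                           master_seed = config$master_seed)
  selection <- selection_report(ensemble, config$repeatability_threshold)
  patterns <- cluster_mean_patterns(participants, selection$final_labels)
  nd_set <- augment_nd(nd_ref)
  report <- compare_clusters_to_nd(patterns, nd_set, alpha = config$alpha)
  structure(list(feature_matrix = M, ensemble = ensemble,
                 selection = selection, deviation_report = report,
                 config = config),
            class = "gait_pipeline_result")
}

#' Simulate a cohort and write its files
#'
#' Writes the long-format cohort CSV, the ND reference CSV and a JSON truth
#' sidecar (seed, parameters, true labels) into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @return invisibly, the generated `synthetic_cohort`.
#' @export
simulate_cohort_files <- function(out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(sizes = config$sizes,
                            amplitude_scale = config$amplitude_scale,
                            noise_params = config$noise_params,
                            seed = config$master_seed,
                            n_steps = config$n_steps)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"),
                   file.path(out_dir, "cohort_truth.json"))
  write_nd_reference_csv(cohort$nd_ref, file.path(out_dir, "nd_reference.csv"))
  invisible(cohort)
}

#' Run the pipeline from files on disk
#'
#' @param cohort_csv long-format cohort CSV.
#' @param nd_csv ND reference CSV.
#' @param out_dir directory for artifacts (selection JSON, deviation CSV,
#'   markdown table, ensemble JSON, run log).
#' @param config a [pipeline_config()].
#' @return the `gait_pipeline_result`, invisibly.
#' @export
run_pipeline_files <- function(cohort_csv, nd_csv, out_dir,
                               config = pipeline_config()) {
  participants <- read_cohort_csv(cohort_csv)
  nd_ref <- read_nd_reference_csv(nd_csv)
  res <- run_gait_pipeline(participants, nd_ref, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_selection_json(res$selection, file.path(out_dir, "selection.json"))
  write_ensemble_json(res$ensemble, file.path(out_dir, "ensemble.json"))
  write_deviation_report(res$deviation_report,
                         file.path(out_dir, "deviations.csv"),
                         file.path(out_dir, "deviations.md"),
                         file.path(out_dir, "spm_audit.json"))
  writeLines(c(paste("gaitclust", as.character(utils::packageVersion("gaitclust"))),
               paste("master_seed:", config$master_seed),
               paste("k_range:", paste(config$k_range, collapse = ",")),
               paste("n_restarts:", config$n_restarts),
               paste("n_repetitions:", config$n_repetitions),
               paste("alpha:", config$alpha)),
             file.path(out_dir, "run_log.txt"))
  invisible(res)
}

# logical support (101 samples) of an archetype's injected deviations on one
# channel
archetype_support <- function(spec, channel) {
  out <- rep(FALSE, N_STANCE)
  rows <- spec$deviations[spec$deviations$channel == channel, , drop = FALSE]
  for (j in seq_len(nrow(rows)))
    out[(rows$start_pct[j]:rows$end_pct[j]) + 1L] <- TRUE
  out
}

#' Evaluate recovery of ground truth on a synthetic cohort
#'
#' Quantifies (a) agreement between final cluster labels and the true
#' archetype labels via the adjusted Rand index, and (b) overlap between
#' detected SPM deviation intervals and the injected deviation supports via
#' the Jaccard index, computed per archetype-channel cell that carries an
#' injected deviation (clusters are matched to archetypes by the
#' agreement-maximizing bijection; interval recovery is only defined when
#' the chosen k equals the number of archetypes).
#'
#' @param result a `gait_pipeline_result`.
#' @param cohort the `synthetic_cohort` the result was computed from.
#' @return list with `chosen_k`, `ari`, `mean_jaccard`, and a per-cell
#'   `jaccard_table`.
#' @export
evaluate_recovery <- function(result, cohort) {
  truth <- cohort$true_labels
  final <- result$selection$final_labels
  ari <- mclust::adjustedRandIndex(final, truth)
  chosen_k <- result$selection$chosen_k
  n_arch <- length(unique(truth))
  if (chosen_k != n_arch) {
    return(list(chosen_k = chosen_k, ari = ari, mean_jaccard = NA_real_,
                jaccard_table = NULL))
  }
  map <- best_permutation(truth, final, n_arch)  # archetype = map[cluster]
  tab <- result$deviation_report$table
  cells <- list()
  for (ci in seq_len(n_arch)) {
    arch <- cohort$archetypes[[map[ci]]]
    for (ch in gait_channels()) {
      injected <- archetype_support(arch, ch)
      if (!any(injected)) next
      detected <- rep(FALSE, N_STANCE)
      rows <- tab[tab$cluster == ci & tab$channel == ch, , drop = FALSE]
      for (j in seq_len(nrow(rows)))
        detected[(rows$start_pct[j]:rows$end_pct[j]) + 1L] <- TRUE
      cells[[length(cells) + 1L]] <- data.frame(
        archetype = map[ci], cluster = ci, channel = ch,
        jaccard = sum(injected & detected) / sum(injected | detected))
    }
  }
  jt <- do.call(rbind, cells)
  list(chosen_k = chosen_k, ari = ari, mean_jaccard = mean(jt$jaccard),
       jaccard_table = jt)
}
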