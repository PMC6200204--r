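#' @title Diagnostic and kinematics figures
#'
#' @description
#' Three figure families mirror the pipeline's outputs: per-k silhouette
#' panels, the boundary-effect scatter (allocation switches against mean
#' silhouette), and per-channel cluster kinematics with the ND reference
#' band and shaded significant intervals. All plotting requires ggplot2
#' (Suggests) and operates on computed pipeline artifacts only.
#'
#' @name plots
NULL

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package 'ggplot2' is required for plotting", call. = FALSE)
}

#' Silhouette panel across k
#'
#' Per k, sorted silhouette values of the consolidated allocation (first
#' repetition), faceted in the style of classical silhouette plots.
#'
#' @param result a `gait_pipeline_result`.
#' @return a ggplot object.
#' @export
plot_silhouette_panels <- function(result) {
  need_ggplot()
  sel <- result$selection
  df <- do.call(rbind, lapply(as.character(sel$metrics$k), function(kc) {
    al <- sel$aligned[[kc]]
    s <- al$s_values[1L, ]
    lab <- al$labels[1L, ]
    ord <- order(lab, -s)
    data.frame(k = paste0("k = ", kc), idx = seq_along(s),
               s = s[ord], cluster = factor(lab[ord]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = idx, y = s,
                                   fill = cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~k) +
    ggplot2::labs(x = "participants (sorted within cluster)",
                  y = "silhouette s(i)") +
    ggplot2::theme_minimal()
}

#' Boundary-effect scatter
#'
#' Allocation switch count against mean silhouette per participant at the
#' chosen k; switches concentrate where s approaches zero.
#'
#' @param result a `gait_pipeline_result`.
#' @return a ggplot object.
#' @export
plot_boundary_effect <- function(result) {
  need_ggplot()
  df <- result$selection$boundary
  ggplot2::ggplot(df, ggplot2::aes(x = mean_s, y = n_switches)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean silhouette s(i)",
                  y = "allocation switches (out of R repetitions)") +
    ggplot2::theme_minimal()
}

#' Cluster kinematics for one channel
#'
#' Mean curve per cluster with the ND reference mean, shading the
#' significant deviation intervals from the SPM comparison.
#'
#' @param result a `gait_pipeline_result`.
#' @param participants the participant list (or `synthetic_cohort`) used in
#'   the run.
#' @param nd_ref the ND reference used in the run.
#' @param channel one of [gait_channels()].
#' @return a ggplot object.
#' @export
plot_cluster_kinematics <- function(result, participants, nd_ref, channel) {
  need_ggplot()
  assert_channel(channel)
  if (inherits(participants, "synthetic_cohort")) {
    if (is.null(nd_ref)) nd_ref <- participants$nd_ref
    participants <- participants$participants
  }
  labels <- result$selection$final_labels
  patterns <- cluster_mean_patterns(participants, labels)
  pct <- 0:(N_STANCE - 1L)
  df <- do.call(rbind, lapply(seq_along(patterns), function(ci)
    data.frame(cluster = paste("cluster", ci), pct = pct,
               deg = colMeans(patterns[[ci]][[channel]]))))
  nd_mean <- rowMeans(vapply(nd_ref[[channel]], `[[`, numeric(N_STANCE),
                             "mean"))
  nd_df <- data.frame(pct = pct, deg = nd_mean)
  tab <- result$deviation_report$table
  shade <- tab[tab$channel == channel, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = pct, y = deg))
  if (nrow(shade) > 0) {
    shade$cluster <- paste("cluster", shade$cluster)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = start_pct, xmax = end_pct),
      ymin = -Inf, ymax = Inf, fill = "grey80", alpha = 0.6,
      inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(data = nd_df, colour = "darkgreen", linewidth = 0.8) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "% stance", y = paste(channel, "(deg)")) +
    ggplot2::theme_minimal()
}

#' Write the full figure set for a run
#'
#' One silhouette panel figure, one boundary-effect figure and five
#' kinematics figures (one per channel), as PDFs.
#'
#' @param result a `gait_pipeline_result`.
#' @param participants,nd_ref inputs of the run.
#' @param out_dir output directory.
#' @return character vector of the 7 file paths.
#' @export
save_pipeline_figures <- function(result, participants, nd_ref, out_dir) {
  need_ggplot()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  f <- file.path(out_dir, "silhouettes.pdf")
  ggplot2::ggsave(f, plot_silhouette_panels(result), width = 8, height = 6)
  paths <- c(paths, f)
  f <- file.path(out_dir, "boundary_effect.pdf")
  ggplot2::ggsave(f, plot_boundary_effect(result), width = 6, height = 5)
  paths <- c(paths, f)
  for (ch in gait_channels()) {
    f <- file.path(out_dir, paste0("kinematics_", ch, ".pdf"))
    ggplot2::ggsave(f, plot_cluster_kinematics(result, participants, nd_ref,
                                               ch), width = 8, height = 6)
    paths <- c(paths, f)
  }
  paths
}
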