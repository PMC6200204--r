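#' @title One-dimensional Statistical Parametric Mapping of gait deviations
#'
#' @description
#' Each cluster's member mean patterns (in degrees) are compared against an
#' augmented normally-developing (ND) comparison set channel by channel with
#' a pointwise two-sample t statistic, forming a 101-point t field SPM{t}.
#' Family-wise inference across the field uses random field theory (RFT):
#' the smoothness (FWHM) of the residual fields is estimated from normalized
#' residual gradients, and the critical threshold is the value t* at which
#' the expected Euler characteristic of the excursion set of a smooth t
#' field of `field_length / FWHM` resels equals the per-tail alpha. Maximal
#' runs of |t| above the threshold become the reported deviation intervals,
#' signed by the direction of the mean difference and labelled with clinical
#' direction terms (flexion, abduction, ...).
#'
#' @name spm
NULL

#' Augment an ND reference into the 20-waveform comparison set
#'
#' For each channel, every one of the four mean templates spawns five
#' waveforms at offsets of -1, -0.5, 0, +0.5 and +1 times its pointwise SD,
#' giving 20 waveforms per channel that carry the reference variance into
#' the two-sample comparison.
#'
#' @param nd_ref an `nd_reference` whose templates carry pointwise SDs.
#' @return an `nd_comparison_set`: named list (per channel) of 20 x 101
#'   matrices.
#' @export
augment_nd <- function(nd_ref) {
  offsets <- c(-1, -0.5, 0, 0.5, 1)
  out <- lapply(gait_channels(), function(ch) {
    tpls <- nd_ref[[ch]]
    rows <- lapply(tpls, function(tpl) {
      if (is.null(tpl$sd))
        stop("missing_sd: ND template for channel '", ch,
             "' has no pointwise SD", call. = FALSE)
      t(vapply(offsets, function(o) tpl$mean + o * tpl$sd,
               numeric(N_STANCE)))
    })
    do.call(rbind, rows)
  })
  names(out) <- gait_channels()
  structure(out, class = "nd_comparison_set")
}

#' Pointwise two-sample t field
#'
#' Computes, at each of the 101 stance samples, the pooled-variance
#' two-sample t statistic for group A minus group B, along with the
#' residual curves (deviations from the group means) used for smoothness
#' estimation.
#'
#' @param A,B waveform matrices (rows = curves, 101 columns); each group
#'   needs >= 2 curves.
#' @return list with `t` (101 values), `df` (`nA + nB - 2`), `diff` (mean
#'   A - mean B), and `residuals` (`(nA + nB) x 101`).
#' @export
spm_t_two_sample <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("group_too_small: both groups need >= 2 waveforms", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("length_mismatch: groups must share the sample grid", call. = FALSE)
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2L, stats::var)
  vB <- apply(B, 2L, stats::var)
  df <- nA + nB - 2L
  vp <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
  se <- sqrt(vp * (1 / nA + 1 / nB))
  tt <- (mA - mB) / se
  res <- rbind(sweep(A, 2L, mA), sweep(B, 2L, mB))
  list(t = tt, df = df, diff = mA - mB, residuals = res)
}

#' Estimate residual-field smoothness (FWHM)
#'
#' Standard 1D random-field smoothness estimator: residual curves are
#' normalized pointwise by the root sum of squares across curves, the
#' gradient variance of the normalized residuals is averaged along the
#' field, and FWHM = sqrt(4 log 2 / mean gradient variance), in sample
#' units (= % stance on the 101-point grid). Scale-invariant by
#' construction.
#'
#' @param residuals matrix of residual curves (>= 2 rows).
#' @return estimated FWHM (> 0), in % stance.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2L)
    stop("too_few_residuals: need >= 2 residual curves", call. = FALSE)
  ssq <- colSums(R^2)
  if (all(ssq == 0))
    stop("zero_residuals: smoothness is undefined for all-zero residuals",
         call. = FALSE)
  dR <- R[, -1L, drop = FALSE] - R[, -ncol(R), drop = FALSE]
  ssq_mid <- (ssq[-1L] + ssq[-length(ssq)]) / 2
  ok <- ssq_mid > 0
  v <- colSums(dR^2)[ok] / ssq_mid[ok]
  fwhm <- sqrt(4 * log(2) / mean(v))
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("zero_residuals: smoothness is undefined", call. = FALSE)
  fwhm
}

# expected Euler characteristic of the excursion set of a smooth 1D t field
# above u: EC(u) = P(T > u) + resels * rho1(u), with the standard EC density
# rho1(u) = sqrt(4 log 2) / (2 pi) * (1 + u^2/df)^(-(df-1)/2)
ec_expected <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t field
#'
#' Solves for the threshold t* at which the expected-Euler-characteristic
#' approximation of the excursion probability of a smooth t field equals
#' alpha. With `two_tailed = TRUE` (default) alpha is split across tails,
#' i.e. t* satisfies EC(t*) = alpha / 2. As FWHM grows without bound the
#' threshold decays to the pointwise critical t; for any finite FWHM it
#' exceeds it.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param df degrees of freedom (>= 1).
#' @param fwhm residual smoothness in % stance (> 0).
#' @param field_length field extent in % stance (default 100).
#' @param two_tailed split alpha across tails (default TRUE).
#' @return the critical threshold t* > 0.
#' @export
rft_threshold <- function(alpha = 0.05, df, fwhm, field_length = 100,
                          two_tailed = TRUE) {
  if (!is.finite(alpha) || !is.finite(df) || !is.finite(fwhm) ||
      alpha <= 0 || alpha >= 1 || df < 1 || fwhm <= 0)
    stop("bad_rft_inputs: alpha in (0,1), df >= 1 and fwhm > 0 required",
         call. = FALSE)
  resels <- field_length / fwhm
  target <- if (two_tailed) alpha / 2 else alpha
  f <- function(u) ec_expected(u, df, resels) - target
  lo <- 1e-6
  hi <- 10
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Extract suprathreshold intervals from a t field
#'
#' Maximal runs of consecutive samples with |t| > t_crit, reported as
#' inclusive % stance bounds on the 0-100 grid together with the sign of t
#' on the run.
#'
#' @param t_field numeric t statistics on the 0-100% grid.
#' @param t_crit positive critical threshold.
#' @return data frame `start_pct, end_pct, sign` (possibly 0 rows).
#' @export
suprathreshold_intervals <- function(t_field, t_crit) {
  above <- abs(t_field) > t_crit
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L)
    return(data.frame(start_pct = integer(0), end_pct = integer(0),
                      sign = integer(0)))
  out <- do.call(rbind, lapply(keep, function(j) {
    idx <- starts[j]:ends[j]
    peak <- idx[which.max(abs(t_field[idx]))]
    data.frame(start_pct = starts[j] - 1L, end_pct = ends[j] - 1L,
               sign = as.integer(sign(t_field[peak])))
  }))
  rownames(out) <- NULL
  out
}

#' Compare final clusters against the ND comparison set
#'
#' For every cluster and channel, runs the two-sample SPM{t} of the cluster
#' members' degree-scale mean patterns against the channel's 20 ND
#' waveforms, thresholds it by RFT at `alpha`, extracts signed
#' suprathreshold intervals and attaches clinical direction labels. Clusters
#' with fewer than 2 members are skipped with a warning.
#'
#' @param cluster_patterns list (per cluster) of named lists (per channel) of
#'   member-by-101 matrices of mean patterns in degrees; see
#'   [cluster_mean_patterns()].
#' @param nd_set an [augment_nd()] comparison set.
#' @param alpha family-wise error rate (default 0.05).
#' @return a `deviation_report`: `list(table, audit)` where `table` is a
#'   data frame `cluster, channel, direction, start_pct, end_pct` and
#'   `audit` holds per-comparison t fields, thresholds, df and FWHM.
#' @export
compare_clusters_to_nd <- function(cluster_patterns, nd_set, alpha = 0.05) {
  rows <- list()
  audit <- list()
  for (ci in seq_along(cluster_patterns)) {
    for (ch in gait_channels()) {
      A <- cluster_patterns[[ci]][[ch]]
      if (is.null(A) || nrow(A) < 2L) {
        warning("cluster ", ci, " has < 2 members; channel '", ch,
                "' skipped")
        next
      }
      fit <- spm_t_two_sample(A, nd_set[[ch]])
      fwhm <- estimate_fwhm(fit$residuals)
      t_crit <- rft_threshold(alpha, fit$df, fwhm)
      ints <- suprathreshold_intervals(fit$t, t_crit)
      audit[[paste0("cluster", ci, ".", ch)]] <-
        list(cluster = ci, channel = ch, t_field = fit$t, t_crit = t_crit,
             df = fit$df, fwhm_est = fwhm)
      if (nrow(ints) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = ci, channel = ch,
          direction = vapply(ints$sign, function(s) direction_label(ch, s), ""),
          start_pct = ints$start_pct, end_pct = ints$end_pct,
          stringsAsFactors = FALSE)
      }
    }
  }
  table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster = integer(0), channel = character(0),
               direction = character(0), start_pct = integer(0),
               end_pct = integer(0))
  structure(list(table = table, audit = audit, alpha = alpha),
            class = "deviation_report")
}

#' Collect per-cluster member mean patterns in degrees
#'
#' @param participants list of `participant_waveforms` (or a
#'   `synthetic_cohort`).
#' @param labels final cluster labels, one per participant.
#' @return list (per cluster 1..max(labels)) of named lists (per channel) of
#'   member-by-101 matrices.
#' @export
cluster_mean_patterns <- function(participants, labels) {
  if (inherits(participants, "synthetic_cohort"))
    participants <- participants$participants
  stopifnot(length(participants) == length(labels))
  patt <- lapply(participants, participant_mean_patterns)
  lapply(seq_len(max(labels)), function(ci) {
    members <- which(labels == ci)
    per_ch <- lapply(gait_channels(), function(ch)
      do.call(rbind, lapply(patt[members], `[[`, ch)))
    names(per_ch) <- gait_channels()
    per_ch
  })
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("Cluster vs ND deviation report (alpha", x$alpha, ")\n")
  if (nrow(x$table) == 0) cat("  no significant deviations\n")
  else print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a deviation report as CSV and markdown
#'
#' @param report a `deviation_report`.
#' @param csv_path CSV output (`cluster, channel, direction, start_pct,
#'   end_pct`).
#' @param md_path optional markdown table path.
#' @param json_path optional per-comparison audit JSON (t fields,
#'   thresholds, df, FWHM).
#' @export
write_deviation_report <- function(report, csv_path, md_path = NULL,
                                   json_path = NULL) {
  utils::write.csv(report$table, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(md_path)) {
    tab <- report$table
    lines <- c("| cluster | channel | direction | % stance |",
               "|---------|---------|-----------|----------|",
               if (nrow(tab) > 0)
                 sprintf("| %d | %s | %s | %d-%d |", tab$cluster, tab$channel,
                         tab$direction, tab$start_pct, tab$end_pct))
    writeLines(lines, md_path)
  }
  if (!is.null(json_path))
    jsonlite::write_json(report$audit, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(csv_path)
}
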