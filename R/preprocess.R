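#' @title From raw stance-phase series to the cohort feature matrix
#'
#' @description
#' Each participant contributes up to five raw joint-angle series (one per
#' successful gait repetition) for each of the five channels. The pipeline
#' time-normalizes each series to 101 points spanning heel strike to toe-off,
#' averages the repetitions pointwise, z-standardizes each channel's mean
#' pattern (subtract the mean, divide by the population SD), and concatenates
#' the five standardized 101-point blocks in a fixed channel order into a
#' 505-feature participant vector. Vectors are stacked row-wise into the
#' cohort feature matrix used for clustering.
#'
#' @name preprocessing
NULL

#' Time-normalize a stance-phase series to a uniform grid
#'
#' Resamples a raw series onto `n_points` uniformly spaced points from the
#' first to the last sample (heel strike to toe-off). Endpoints are preserved
#' exactly; interior values are interpolated (linear by default, cubic
#' natural spline optionally).
#'
#' @param series numeric vector, length >= 2, no missing values.
#' @param n_points output length (default 101).
#' @param method `"linear"` (default) or `"cubic"`.
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(series, n_points = N_STANCE,
                           method = c("linear", "cubic")) {
  method <- match.arg(method)
  if (length(series) < 2L)
    stop("series_too_short: need at least 2 samples, got ", length(series),
         call. = FALSE)
  if (anyNA(series))
    stop("missing_values: series contains NA", call. = FALSE)
  stopifnot(n_points >= 2)
  x_in <- seq(0, 1, length.out = length(series))
  x_out <- seq(0, 1, length.out = n_points)
  out <- if (method == "linear") {
    stats::approx(x_in, series, xout = x_out)$y
  } else {
    stats::spline(x_in, series, xout = x_out, method = "natural")$y
  }
  out[1L] <- series[1L]
  out[n_points] <- series[length(series)]
  out
}

#' Pointwise mean pattern across gait repetitions
#'
#' @param steps a matrix (steps x 101) or list of 101-sample series, all
#'   already time-normalized.
#' @return the pointwise arithmetic mean, length 101.
#' @export
mean_pattern <- function(steps) {
  if (is.list(steps)) steps <- do.call(rbind, steps)
  if (is.null(steps) || NROW(steps) == 0L)
    stop("no_steps: at least one gait repetition is required", call. = FALSE)
  if (is.vector(steps)) steps <- matrix(steps, nrow = 1L)
  colMeans(steps)
}

#' Z-standardize a channel mean pattern
#'
#' Subtracts the mean and divides by the population SD (divide by N, not
#' N - 1); the convention is fixed so standardized vectors are comparable
#' across implementations.
#'
#' @param series 101-sample mean pattern.
#' @param participant_id,channel used only to name the error for degenerate
#'   (constant) input.
#' @return standardized series with mean 0 and population SD 1.
#' @export
standardize_channel <- function(series, participant_id = NULL, channel = NULL) {
  m <- mean(series)
  s <- sqrt(mean((series - m)^2))
  if (!is.finite(s) || s <= 0)
    stop("constant_channel: zero variance",
         if (!is.null(participant_id)) paste0(" for participant '",
                                              participant_id, "'"),
         if (!is.null(channel)) paste0(", channel '", channel, "'"),
         call. = FALSE)
  (series - m) / s
}

#' Build a 505-feature participant vector
#'
#' Concatenates the five standardized channel blocks in the fixed order
#' `hip_sagittal, hip_coronal, hip_transverse, knee_sagittal,
#' ankle_sagittal`, regardless of the input list's ordering.
#'
#' @param channels named list of 5 standardized 101-sample series.
#' @param participant_id id string attached to the vector.
#' @return a `participant_vector`: `list(participant_id, values,
#'   channel_order)` with 505 values.
#' @export
build_vector <- function(channels, participant_id = "P1") {
  missing_ch <- setdiff(gait_channels(), names(channels))
  if (length(missing_ch) > 0)
    stop("missing_channel: ", paste(missing_ch, collapse = ", "),
         " absent for participant '", participant_id, "'", call. = FALSE)
  vals <- unlist(lapply(gait_channels(), function(ch) {
    v <- channels[[ch]]
    if (length(v) != N_STANCE)
      stop("bad_channel_length: channel '", ch, "' has ", length(v),
           " samples, expected ", N_STANCE, call. = FALSE)
    v
  }), use.names = FALSE)
  structure(list(participant_id = participant_id, values = vals,
                 channel_order = gait_channels()),
            class = "participant_vector")
}

#' Stack participant vectors into the cohort feature matrix
#'
#' @param vectors list of `participant_vector`s with unique ids.
#' @return a `feature_matrix`: numeric matrix (participants x 505) with
#'   participant ids as row names and `f000`-`f504` column names.
#' @export
build_matrix <- function(vectors) {
  ids <- vapply(vectors, `[[`, "", "participant_id")
  if (anyDuplicated(ids))
    stop("duplicate_participant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  M <- do.call(rbind, lapply(vectors, `[[`, "values"))
  rownames(M) <- ids
  colnames(M) <- sprintf("f%03d", 0:(ncol(M) - 1L))
  structure(M, class = c("feature_matrix", "matrix", "array"))
}

#' Preprocess one participant's raw waveforms into a vector
#'
#' Runs time normalization, repetition averaging and standardization, then
#' assembles the 505-feature vector.
#'
#' @param pw a `participant_waveforms`.
#' @param method interpolation method for [time_normalize()].
#' @return a `participant_vector`.
#' @export
preprocess_participant <- function(pw, method = "linear") {
  channels <- lapply(gait_channels(), function(ch) {
    steps <- pw$steps[[ch]]
    if (is.null(steps))
      stop("missing_channel: ", ch, " absent for participant '",
           pw$participant_id, "'", call. = FALSE)
    if (is.vector(steps)) steps <- matrix(steps, nrow = 1L)
    norm <- t(apply(steps, 1L, time_normalize, method = method))
    standardize_channel(mean_pattern(norm), pw$participant_id, ch)
  })
  names(channels) <- gait_channels()
  build_vector(channels, pw$participant_id)
}

#' Build the feature matrix for a whole cohort
#'
#' @param participants list of `participant_waveforms` (or a
#'   `synthetic_cohort`).
#' @param method interpolation method.
#' @return a `feature_matrix` with rows in input order.
#' @export
cohort_matrix <- function(participants, method = "linear") {
  if (inherits(participants, "synthetic_cohort"))
    participants <- participants$participants
  build_matrix(lapply(participants, preprocess_participant, method = method))
}

#' Per-participant mean patterns in degrees
#'
#' The degree-scale (unstandardized) mean patterns are what the SPM stage
#' compares against the ND reference: standardization is appropriate for
#' clustering but would distort the amplitude of clinical deviations.
#'
#' @param pw a `participant_waveforms`.
#' @param method interpolation method.
#' @return named list of 101-sample mean patterns (degrees) per channel.
#' @export
participant_mean_patterns <- function(pw, method = "linear") {
  out <- lapply(gait_channels(), function(ch) {
    steps <- pw$steps[[ch]]
    if (is.vector(steps)) steps <- matrix(steps, nrow = 1L)
    mean_pattern(t(apply(steps, 1L, time_normalize, method = method)))
  })
  names(out) <- gait_channels()
  out
}

#' Write / read a feature matrix as CSV
#'
#' @param M a `feature_matrix`.
#' @param path CSV path; round-trips exactly (values written in full
#'   precision).
#' @export
write_feature_matrix_csv <- function(M, path) {
  df <- data.frame(participant_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix_csv
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df$participant_id
  storage.mode(M) <- "double"
  structure(M, class = c("feature_matrix", "matrix", "array"))
}
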