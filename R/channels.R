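#' Joint-angle channels and sign conventions
#'
#' The pipeline operates on five stance-phase joint-angle channels recorded
#' for the left leg: hip angles in the sagittal, coronal and transverse
#' planes, plus sagittal knee and ankle angles. All angles are in degrees and
#' follow one fixed sign convention: flexion, adduction, internal rotation
#' and dorsiflexion are positive; extension, abduction, external rotation and
#' plantarflexion are negative.
#'
#' @format `gait_channels()` returns a character vector of the five channel
#'   names in their fixed concatenation order.
#' @export
gait_channels <- function() {
  c("hip_sagittal", "hip_coronal", "hip_transverse",
    "knee_sagittal", "ankle_sagittal")
}

# Number of samples per time-normalized stance-phase waveform (0-100% stance).
N_STANCE <- 101L

#' Clinical direction label for a signed deviation on a channel
#'
#' Maps the sign of a mean angular difference (cluster minus reference) to the
#' clinical label used in deviation reports, under the package's sign
#' convention (flexion / adduction / internal rotation / dorsiflexion
#' positive).
#'
#' @param channel one of [gait_channels()].
#' @param sign +1 or -1.
#' @return a label such as `"flexion"` or `"abduction"`.
#' @export
direction_label <- function(channel, sign) {
  stopifnot(channel %in% gait_channels(), sign %in% c(-1, 1))
  pos <- c(hip_sagittal = "flexion", hip_coronal = "adduction",
           hip_transverse = "internal_rotation", knee_sagittal = "flexion",
           ankle_sagittal = "dorsiflexion")
  neg <- c(hip_sagittal = "extension", hip_coronal = "abduction",
           hip_transverse = "external_rotation", knee_sagittal = "extension",
           ankle_sagittal = "plantarflexion")
  if (sign > 0) unname(pos[channel]) else unname(neg[channel])
}

# internal: check a channel name, with a named error
assert_channel <- function(channel) {
  if (!channel %in% gait_channels()) {
    stop("unknown_channel: '", channel, "' is not one of ",
         paste(gait_channels(), collapse = ", "), call. = FALSE)
  }
  invisible(channel)
}
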