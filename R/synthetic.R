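#' @title Synthetic gait cohorts with known kinematic archetypes
#'
#' @description
#' The clinical cohort behind this pipeline is not publicly deposited, so the
#' package ships a generator that emulates its statistical structure: a
#' normally-developing (ND) reference of four mean waveforms per channel with
#' pointwise SDs, and a cerebral-palsy cohort partitioned into four kinematic
#' archetypes. Each archetype injects smooth, signed deviations (flexion
#' deficits, abduction patterns, rotation offsets, dorsi-/plantarflexion
#' shifts) on stated stance-phase intervals on top of an ND base curve, plus
#' smooth correlated noise. Ground-truth archetype labels are retained so
#' cluster recovery and deviation-interval recovery are directly testable.
#'
#' @name synthetic-cohorts
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Smooth stationary Gaussian noise over stance
#'
#' White Gaussian noise convolved with a Gaussian kernel and rescaled to a
#' target pointwise SD. The correlation length is expressed as the kernel
#' full-width-at-half-maximum in % stance, matching the smoothness language of
#' random-field theory; smooth residuals are what make the SPM stage's
#' thresholds appropriate for the simulated data.
#'
#' @param n number of samples (default 101).
#' @param sd target pointwise standard deviation in degrees.
#' @param fwhm_pct correlation length as kernel FWHM in % stance.
#' @return numeric vector of length `n`. Uses the current RNG stream.
#' @export
smooth_noise <- function(n = N_STANCE, sd = 1, fwhm_pct = 10) {
  stopifnot(n >= 1, sd >= 0, fwhm_pct > 0)
  if (sd == 0) return(numeric(n))
  sigma <- fwhm_pct / sqrt(8 * log(2))   # samples == % stance on the 101 grid
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  z <- stats::rnorm(n + 2L * half)
  sm <- stats::convolve(z, kern, type = "filter")   # length n, edges padded
  sm * sd / sqrt(sum(kern^2))                       # unit pointwise SD * sd
}

# Canonical physiological base shapes, one per channel, over t in [0, 1]
# (fraction of stance). Magnitudes are typical barefoot-walking values for
# children; these are synthetic stand-ins, not digitized normative data.
nd_base_shape <- function(channel, t) {
  switch(channel,
    hip_sagittal   = 12.5 + 22.5 * cos(pi * t),                 # 35 deg flex -> -10 ext
    hip_coronal    = 2 + 6 * sin(pi * t) - 10 * t,              # early adduction -> late abduction
    hip_transverse = 8 - 12 * t + 2 * sin(2 * pi * t),          # internal -> external rotation
    knee_sagittal  = 5 + 15 * exp(-((t - 0.15) / 0.10)^2) +     # loading-response flexion
                     30 * exp(-((t - 1.05) / 0.18)^2),          # pre-swing flexion
    ankle_sagittal = -5 * exp(-((t - 0.05) / 0.06)^2) +         # initial plantarflexion
                     12 * exp(-((t - 0.75) / 0.25)^2) -         # progressive dorsiflexion
                     18 * exp(-((t - 1.02) / 0.10)^2),          # push-off plantarflexion
    stop("unknown_channel: ", channel, call. = FALSE)
  )
}

#' Generate a normally-developing reference set
#'
#' Builds, for each of the five channels, four mean-waveform variants with
#' strictly positive pointwise SDs. The four variants are small smooth
#' perturbations of one canonical physiological shape, emulating reference
#' waveforms drawn from four comparable normative sources.
#'
#' @param seed integer seed; the same seed always yields the same reference.
#' @param variant_sd SD (degrees) of the smooth between-variant perturbation.
#' @return an object of class `nd_reference`: a named list (by channel) of
#'   lists of 4 templates, each `list(channel, variant, mean, sd)` with
#'   101-sample `mean` and `sd` curves.
#' @export
make_nd_reference <- function(seed = 1L, variant_sd = 0.5) {
  with_seed(seed, {
    t <- seq(0, 1, length.out = N_STANCE)
    ref <- lapply(gait_channels(), function(ch) {
      base <- nd_base_shape(ch, t)
      lapply(seq_len(4L), function(v) {
        m <- base + smooth_noise(sd = variant_sd, fwhm_pct = 25)
        s <- 2.5 + 0.75 * tanh(smooth_noise(sd = 1, fwhm_pct = 25))
        list(channel = ch, variant = v, mean = m, sd = s)
      })
    })
    names(ref) <- gait_channels()
    structure(ref, class = "nd_reference", seed = as.integer(seed))
  })
}

#' Default kinematic archetype specifications
#'
#' Four archetypes of stance-phase deviation patterns seen in spastic
#' diplegic gait, expressed as signed deviations of the joint angle on
#' inclusive % stance intervals. Archetype 1 carries a sustained hip
#' abduction (0-94%) and external rotation (20-100%) pattern; archetype 2
#' moves from hip adduction (5-18%) to abduction (41-60%) with pre-swing
#' plantarflexion (90-100%); archetype 3 deviates in the sagittal plane only
#' (apparent-equinus-like); archetype 4 shows the longest hip and knee
#' extension deficits with a mid-to-late dorsiflexion pattern
#' (crouch-like). Directions refer to the signed angle convention
#' (see [direction_label()]), so "increased abduction" is a `decrease`.
#'
#' @param amplitude_deg peak deviation amplitude in degrees (default 8).
#' @return list of 4 `archetype_spec` objects, each with an `archetype_id`
#'   and a data frame `deviations` (`channel`, `direction`, `start_pct`,
#'   `end_pct`, `amplitude_deg`).
#' @export
default_archetypes <- function(amplitude_deg = 8) {
  dev <- function(channel, direction, start, end)
    data.frame(channel = channel, direction = direction,
               start_pct = start, end_pct = end,
               amplitude_deg = amplitude_deg, stringsAsFactors = FALSE)
  specs <- list(
    rbind(                                        # sustained abduction / ext rotation
      dev("hip_sagittal",   "increase", 98, 100), # flexion (extension deficit)
      dev("hip_coronal",    "decrease",  0,  94), # abduction
      dev("hip_transverse", "decrease", 20, 100), # external rotation
      dev("knee_sagittal",  "increase",  0,  18),
      dev("ankle_sagittal", "increase",  8,  44)  # dorsiflexion
    ),
    rbind(                                        # jump-like
      dev("hip_sagittal",   "increase", 66, 100),
      dev("hip_coronal",    "increase",  5,  18), # adduction
      dev("hip_coronal",    "decrease", 41,  60), # abduction
      dev("hip_transverse", "increase",  0,  11), # internal rotation
      dev("knee_sagittal",  "increase",  0,  20),
      dev("ankle_sagittal", "increase",  8,  31),
      dev("ankle_sagittal", "decrease", 90, 100)  # plantarflexion
    ),
    rbind(                                        # sagittal-only
      dev("hip_sagittal",   "increase",  0,   5),
      dev("hip_sagittal",   "increase", 63, 100),
      dev("knee_sagittal",  "increase",  0,  18),
      dev("knee_sagittal",  "increase", 96, 100),
      dev("ankle_sagittal", "increase", 10,  28)
    ),
    rbind(                                        # crouch-like
      dev("hip_sagittal",   "increase", 41, 100),
      dev("hip_coronal",    "decrease",  0,  15),
      dev("hip_coronal",    "decrease", 18,  40),
      dev("hip_transverse", "decrease",  0,   7),
      dev("knee_sagittal",  "increase",  0,  18),
      dev("knee_sagittal",  "increase", 60, 100),
      dev("ankle_sagittal", "increase", 11,  33),
      dev("ankle_sagittal", "increase", 49,  86)
    )
  )
  lapply(seq_along(specs), function(i) {
    structure(list(archetype_id = i, deviations = specs[[i]]),
              class = "archetype_spec")
  })
}

# internal: graded-membership blend of two archetype deviation profiles.
# Deviation bumps are linear in amplitude, so the blend concatenates the two
# row sets with amplitudes scaled by (1 - w) and w. Small w leaves a nearly
# pure presentation; w toward 0.5 yields a genuinely intermediate one.
mix_archetypes <- function(own, other, w) {
  stopifnot(w >= 0, w <= 1)
  a <- own$deviations
  b <- other$deviations
  a$amplitude_deg <- a$amplitude_deg * (1 - w)
  b$amplitude_deg <- b$amplitude_deg * w
  structure(list(archetype_id = own$archetype_id,
                 deviations = rbind(a, b), mix_weight = w,
                 mixed_with = other$archetype_id),
            class = "archetype_spec")
}

# internal: a near-flat signed bump supported on [start_pct, end_pct]
# (inclusive, 0-100 grid) with raised-cosine tapers at both ends. The
# plateau sits at `amplitude`, so the mean deviation over the support is
# close to the nominal amplitude.
deviation_bump <- function(start_pct, end_pct, amplitude, n = N_STANCE) {
  stopifnot(start_pct >= 0, end_pct <= 100, start_pct <= end_pct)
  idx <- (start_pct:end_pct) + 1L
  len <- length(idx)
  taper <- min(5L, len %/% 4L)
  w <- rep(1, len)
  if (taper > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(taper) / (taper + 1)))
    w[seq_len(taper)] <- ramp
    w[len + 1L - seq_len(taper)] <- rev(ramp)
  }
  out <- numeric(n)
  out[idx] <- amplitude * w
  out
}

#' Render one synthetic participant from an archetype
#'
#' Each channel is a randomly chosen ND base variant plus the archetype's
#' signed deviation bumps plus smooth correlated noise; channels the
#' archetype leaves untouched differ from the ND base only by noise.
#' Optionally renders several "steps" (gait repetitions) that add smaller
#' step-to-step smooth noise around the participant curve.
#'
#' @param nd_ref an [make_nd_reference()] object.
#' @param spec an `archetype_spec`.
#' @param noise_params list with `sd_deg` (participant-level smooth noise SD),
#'   `fwhm_pct` (correlation length, % stance), `step_sd_deg` (step-level
#'   noise SD).
#' @param participant_id id string.
#' @param n_steps number of gait repetitions to render (1-5).
#' @return a `participant_waveforms` object: `list(participant_id, steps)`
#'   with `steps` a named list (per channel) of `n_steps x 101` matrices of
#'   raw angles in degrees. Uses the current RNG stream.
#' @export
render_archetype <- function(nd_ref, spec,
                             noise_params = default_noise_params(),
                             participant_id = "P1", n_steps = 5L) {
  stopifnot(inherits(spec, "archetype_spec"), n_steps >= 1, n_steps <= 5)
  for (ch in spec$deviations$channel) assert_channel(ch)
  steps <- lapply(gait_channels(), function(ch) {
    variant <- sample.int(4L, 1L)
    curve <- nd_ref[[ch]][[variant]]$mean
    rows <- spec$deviations[spec$deviations$channel == ch, , drop = FALSE]
    if (nrow(rows) > 0) {
      for (j in seq_len(nrow(rows))) {
        amp <- rows$amplitude_deg[j] *
          if (rows$direction[j] == "increase") 1 else -1
        curve <- curve + deviation_bump(rows$start_pct[j], rows$end_pct[j], amp)
      }
    }
    curve <- curve + smooth_noise(sd = noise_params$sd_deg,
                                  fwhm_pct = noise_params$fwhm_pct)
    t(vapply(seq_len(n_steps), function(s) {
      curve + smooth_noise(sd = noise_params$step_sd_deg,
                           fwhm_pct = noise_params$fwhm_pct)
    }, numeric(N_STANCE)))
  })
  names(steps) <- gait_channels()
  structure(list(participant_id = participant_id, steps = steps),
            class = "participant_waveforms")
}

#' Default noise parameters for the synthetic cohort
#'
#' `sd_deg` is the SD of the smooth participant-level deviation from the ND
#' base curve, `fwhm_pct` its correlation length in % stance, and
#' `step_sd_deg` the smaller step-to-step variability around the participant
#' curve. `mix_max` and `mix_shape2` control graded archetype membership:
#' each participant blends in a second archetype's deviation profile with
#' weight `w = mix_max * Beta(1, mix_shape2)`, so most participants are
#' nearly pure presentations while a few are genuinely intermediate
#' ("boundary") cases, as in real spastic-diplegia cohorts where recognized
#' gait patterns grade into one another. Defaults are chosen so the default
#' cohort is separable but overlapping, with a four-cluster mean silhouette
#' in the 0.2-0.4 band typical of clinical gait clusters.
#'
#' @export
default_noise_params <- function() {
  list(sd_deg = 2.3, fwhm_pct = 10, step_sd_deg = 1,
       mix_max = 0.5, mix_shape2 = 3)
}

#' Generate a synthetic cohort with ground-truth archetype labels
#'
#' @param sizes integer vector of 4 archetype sizes (default `c(5, 12, 12, 8)`,
#'   a 37-participant cohort).
#' @param amplitude_scale multiplier on the 8-degree default deviation
#'   amplitude.
#' @param noise_params see [default_noise_params()].
#' @param seed integer master seed; cohorts are bit-identical given the same
#'   seed and parameters.
#' @param nd_ref optional pre-built ND reference; by default one is derived
#'   from `seed`.
#' @param n_steps gait repetitions per participant.
#' @return a `synthetic_cohort`: `list(participants, true_labels, seed,
#'   params, nd_ref, archetypes)`.
#' @export
generate_cohort <- function(sizes = c(5L, 12L, 12L, 8L), amplitude_scale = 1,
                            noise_params = default_noise_params(),
                            seed = 1L, nd_ref = NULL, n_steps = 5L) {
  if (length(sizes) != 4L || any(sizes < 0) || any(sizes != round(sizes)))
    stop("invalid_sizes: 'sizes' must be 4 non-negative integers",
         call. = FALSE)
  with_seed(seed, {
    if (is.null(nd_ref))
      nd_ref <- make_nd_reference(seed = sample.int(.Machine$integer.max, 1L))
    archetypes <- default_archetypes(amplitude_deg = 8 * amplitude_scale)
    n <- sum(sizes)
    labels <- rep(seq_len(4L), times = sizes)
    ids <- sprintf("P%02d", seq_len(n))
    mix_max <- if (is.null(noise_params$mix_max)) 0 else noise_params$mix_max
    mix_shape2 <- if (is.null(noise_params$mix_shape2)) 3 else noise_params$mix_shape2
    participants <- lapply(seq_len(n), function(i) {
      spec <- archetypes[[labels[i]]]
      if (mix_max > 0 && length(unique(labels)) > 1L) {
        w <- mix_max * stats::rbeta(1L, 1, mix_shape2)
        other <- sample(setdiff(unique(labels), labels[i]), 1L)
        spec <- mix_archetypes(spec, archetypes[[other]], w)
      }
      render_archetype(nd_ref, spec, noise_params,
                       participant_id = ids[i], n_steps = n_steps)
    })
    structure(list(participants = participants, true_labels = labels,
                   seed = as.integer(seed),
                   params = list(sizes = as.integer(sizes),
                                 amplitude_scale = amplitude_scale,
                                 noise_params = noise_params,
                                 n_steps = as.integer(n_steps)),
                   nd_ref = nd_ref, archetypes = archetypes),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic gait cohort:", length(x$participants), "participants,",
      "archetype sizes", paste(x$params$sizes, collapse = "/"),
      "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

# ---- plain-text serialization ------------------------------------------------

#' Write a cohort as long-format CSV plus a JSON sidecar
#'
#' The CSV has columns `participant_id, channel, step, sample_index,
#' value_deg` with `sample_index` 0-100; the sidecar records seed, parameters
#' and true labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param csv_path,json_path output paths.
#' @export
write_cohort_csv <- function(cohort, csv_path, json_path = NULL) {
  rows <- lapply(cohort$participants, function(p) {
    per_ch <- lapply(gait_channels(), function(ch) {
      m <- p$steps[[ch]]
      data.frame(participant_id = p$participant_id, channel = ch,
                 step = rep(seq_len(nrow(m)), each = ncol(m)),
                 sample_index = rep(0:(ncol(m) - 1L), times = nrow(m)),
                 value_deg = as.vector(t(m)), stringsAsFactors = FALSE)
    })
    do.call(rbind, per_ch)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(seed = cohort$seed, params = cohort$params,
           true_labels = cohort$true_labels,
           participant_ids = vapply(cohort$participants,
                                    `[[`, "", "participant_id")),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Read a long-format cohort CSV
#'
#' Accepts the format written by [write_cohort_csv()]; the `step` column is
#' optional (absent means a single step per participant).
#'
#' @param csv_path path to the CSV.
#' @return a list of `participant_waveforms`, in first-appearance order.
#' @export
read_cohort_csv <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "channel", "sample_index", "value_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("malformed_cohort_csv: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"step" %in% names(df)) df$step <- 1L
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    steps <- lapply(gait_channels(), function(ch) {
      chd <- sub[sub$channel == ch, , drop = FALSE]
      if (nrow(chd) == 0)
        stop("malformed_cohort_csv: participant '", id,
             "' is missing channel '", ch, "'", call. = FALSE)
      sp <- split(chd, chd$step)
      t(vapply(sp, function(s)
        s$value_deg[order(s$sample_index)],
        numeric(nrow(sp[[1]]))))
    })
    names(steps) <- gait_channels()
    structure(list(participant_id = id, steps = steps),
              class = "participant_waveforms")
  })
}

#' Write / read an ND reference as CSV
#'
#' Columns: `channel, variant, sample_index, mean_deg, sd_deg`.
#'
#' @param nd_ref an `nd_reference`.
#' @param path CSV path.
#' @export
write_nd_reference_csv <- function(nd_ref, path) {
  rows <- lapply(gait_channels(), function(ch) {
    do.call(rbind, lapply(nd_ref[[ch]], function(tpl) {
      data.frame(channel = ch, variant = tpl$variant,
                 sample_index = 0:(N_STANCE - 1L),
                 mean_deg = tpl$mean, sd_deg = tpl$sd,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nd_reference_csv
#' @export
read_nd_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "variant", "sample_index", "mean_deg", "sd_deg")
  if (!all(need %in% names(df)))
    stop("malformed_nd_csv: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ref <- lapply(gait_channels(), function(ch) {
    sub <- df[df$channel == ch, , drop = FALSE]
    lapply(sort(unique(sub$variant)), function(v) {
      vd <- sub[sub$variant == v, , drop = FALSE]
      vd <- vd[order(vd$sample_index), , drop = FALSE]
      list(channel = ch, variant = v, mean = vd$mean_deg, sd = vd$sd_deg)
    })
  })
  names(ref) <- gait_channels()
  structure(ref, class = "nd_reference")
}
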