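test_that("ND reference has the right shape, positive SDs and is deterministic", {
  ref <- make_nd_reference(seed = 7)
  expect_setequal(names(ref), gait_channels())
  for (ch in gait_channels()) {
    expect_length(ref[[ch]], 4L)
    for (tpl in ref[[ch]]) {
      expect_length(tpl$mean, 101L)
      expect_length(tpl$sd, 101L)
      expect_true(all(tpl$sd > 0))
      expect_true(all(abs(tpl$mean) < 60))
    }
  }
  expect_identical(ref, make_nd_reference(seed = 7))
  expect_false(identical(unclass(ref), unclass(make_nd_reference(seed = 8))))
})

test_that("zero-amplitude, zero-noise renders collapse onto an ND base curve", {
  ref <- make_nd_reference(seed = 3)
  spec0 <- default_archetypes(amplitude_deg = 0)[[2]]
  np <- list(sd_deg = 0, fwhm_pct = 10, step_sd_deg = 0)
  set.seed(11)
  pw <- render_archetype(ref, spec0, np, n_steps = 1L)
  for (ch in gait_channels()) {
    curve <- pw$steps[[ch]][1L, ]
    dists <- vapply(ref[[ch]], function(tpl) max(abs(curve - tpl$mean)),
                    numeric(1))
    expect_equal(min(dists), 0)
  }
})

test_that("noise-free renders carry the archetype's signed deviations and nothing else", {
  ref <- make_nd_reference(seed = 3, variant_sd = 0)   # known base curves
  np <- list(sd_deg = 0, fwhm_pct = 10, step_sd_deg = 0)
  arch <- default_archetypes(amplitude_deg = 8)
  sgn <- c(increase = 1, decrease = -1)
  for (a in seq_len(4L)) {
    set.seed(100 + a)
    pw <- render_archetype(ref, arch[[a]], np, n_steps = 1L)
    dv <- arch[[a]]$deviations
    for (ch in gait_channels()) {
      curve <- pw$steps[[ch]][1L, ]
      rows <- dv[dv$channel == ch, , drop = FALSE]
      if (nrow(rows) == 0) {
        # untouched channel: exactly an ND base curve (e.g. archetype 3
        # leaves hip coronal and transverse undisturbed)
        expect_equal(curve, ref[[ch]][[1]]$mean)
      } else {
        bump <- curve - ref[[ch]][[1]]$mean
        for (j in seq_len(nrow(rows))) {
          idx <- (rows$start_pct[j]:rows$end_pct[j]) + 1L
          m <- mean(bump[idx])
          expect_gt(m * sgn[[rows$direction[j]]], 0)
        }
        outside <- setdiff(seq_len(101L),
                           unlist(lapply(seq_len(nrow(rows)), function(j)
                             (rows$start_pct[j]:rows$end_pct[j]) + 1L)))
        expect_equal(bump[outside], rep(0, length(outside)))
      }
    }
  }
})

test_that("Monte-Carlo render average recovers the injected bump profile", {
  # identical ND variants so the base curve is known exactly
  ref <- make_nd_reference(seed = 5, variant_sd = 0)
  base <- ref$hip_coronal[[1]]$mean
  spec <- structure(list(
    archetype_id = 1L,
    deviations = data.frame(channel = "hip_coronal", direction = "decrease",
                            start_pct = 0, end_pct = 94,
                            amplitude_deg = 10, stringsAsFactors = FALSE)),
    class = "archetype_spec")
  np0 <- list(sd_deg = 0, fwhm_pct = 10, step_sd_deg = 0)
  set.seed(21)
  exact <- render_archetype(ref, spec, np0, n_steps = 1L)
  bump <- exact$steps$hip_coronal[1L, ] - base
  expect_lt(mean(bump[1:95]), -8.5)   # ~ -10 deg with raised-cosine tapers
  expect_gt(mean(bump[1:95]), -10.5)

  # noisy Monte-Carlo: averaging 100 renders recovers the analytic bump
  np <- list(sd_deg = 3, fwhm_pct = 10, step_sd_deg = 0)
  set.seed(22)
  mc <- rowMeans(vapply(1:100, function(i) {
    render_archetype(ref, spec, np, n_steps = 1L)$steps$hip_coronal[1L, ] - base
  }, numeric(101)))
  expect_lt(max(abs(mc - bump)), 1.2)   # 3 deg noise / sqrt(100) ~ 0.3 SE
})

test_that("render_archetype rejects unknown channels", {
  ref <- make_nd_reference(seed = 1)
  bad <- structure(list(
    archetype_id = 1L,
    deviations = data.frame(channel = "pelvis_sagittal",
                            direction = "increase", start_pct = 0,
                            end_pct = 10, amplitude_deg = 5)),
    class = "archetype_spec")
  expect_error(render_archetype(ref, bad, default_noise_params()),
               "unknown_channel")
})

test_that("generate_cohort honours sizes, labels and determinism", {
  co <- generate_cohort(seed = 42)
  expect_length(co$participants, 37L)
  expect_identical(co$true_labels, rep(1:4, times = c(5L, 12L, 12L, 8L)))
  expect_identical(co, generate_cohort(seed = 42))

  one <- generate_cohort(sizes = c(0L, 0L, 0L, 1L), seed = 9)
  expect_length(one$participants, 1L)
  expect_identical(one$true_labels, 4L)

  expect_error(generate_cohort(sizes = c(-1L, 2L, 2L, 2L)), "invalid_sizes")
  expect_error(generate_cohort(sizes = c(1L, 2L, 3L)), "invalid_sizes")
})

test_that("cohort and ND reference CSV round-trips preserve the data", {
  co <- tiny_cohort(seed = 2, sizes = c(1L, 1L, 1L, 1L))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_cohort_csv(co, csv, js)
  back <- read_cohort_csv(csv)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$participant_id, co$participants[[i]]$participant_id)
    for (ch in gait_channels())
      expect_equal(unname(back[[i]]$steps[[ch]]),
                   unname(co$participants[[i]]$steps[[ch]]),
                   tolerance = 1e-12)
  }
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$true_labels, co$true_labels)

  ndcsv <- tempfile(fileext = ".csv")
  write_nd_reference_csv(co$nd_ref, ndcsv)
  nd2 <- read_nd_reference_csv(ndcsv)
  for (ch in gait_channels())
    expect_equal(nd2[[ch]][[3]]$mean, co$nd_ref[[ch]][[3]]$mean,
                 tolerance = 1e-12)
})
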