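# build a minimal aligned_ensemble by hand
mk_aligned <- function(labels, s_values = NULL, k = max(labels)) {
  structure(list(k = as.integer(k), labels = labels, s_values = s_values,
                 mappings = NULL),
            class = "aligned_ensemble")
}

test_that("align_labels undoes label permutations and matches exhaustive search", {
  set.seed(1)
  base <- sample(1:4, 37, replace = TRUE)
  base[1:4] <- 1:4
  perm <- c(4L, 1L, 2L, 3L)
  lab <- rbind(base, perm[base], c(3L, 1L, 4L, 2L)[base])
  al <- align_labels(lab, k = 4)
  expect_identical(unname(al$labels[2, ]), base)
  expect_identical(unname(al$labels[3, ]), base)

  # a single differing participant leaves exactly one mismatch at k = 2
  a <- rep(1:2, each = 5)
  b <- a; b[1] <- 2L
  al2 <- align_labels(rbind(a, b), k = 2)
  expect_equal(sum(al2$labels[1, ] != al2$labels[2, ]), 1L)

  # optimal alignment agrees with brute force over all 24 permutations
  for (trial in 1:5) {
    set.seed(10 + trial)
    r1 <- sample(1:4, 37, replace = TRUE); r1[1:4] <- 1:4
    r2 <- sample(1:4, 37, replace = TRUE); r2[1:4] <- 1:4
    al3 <- align_labels(rbind(r1, r2), k = 4)
    scores <- vapply(perm_list(4), function(p)
      sum(unlist(p)[r2] == r1), numeric(1))
    expect_equal(sum(al3$labels[2, ] == r1), max(scores))
  }
})

test_that("alignment never alters the partitions themselves", {
  set.seed(2)
  lab <- rbind(sample(1:3, 20, replace = TRUE),
               sample(1:3, 20, replace = TRUE))
  lab[, 1:3] <- rbind(1:3, 1:3)
  al <- align_labels(lab, k = 3)
  for (r in 1:2) {
    before <- unname(split(seq_len(20), lab[r, ]))
    after <- unname(split(seq_len(20), al$labels[r, ]))
    expect_setequal(lapply(before, sort), lapply(after, sort))
  }
})

test_that("repeatability reproduces the 12-of-370 bookkeeping", {
  # 37 participants x 10 repetitions, all agreeing
  lab <- matrix(rep(rep(1:4, times = c(5, 12, 12, 8)), each = 10), nrow = 10)
  al <- mk_aligned(lab, k = 4)
  r <- repeatability(al)
  expect_equal(r$repeatability_pct, 100)
  expect_equal(r$n_switch_events, 0L)

  # plant exactly 12 switched records: one participant switching 4 times,
  # three switching twice, two switching once (the reported pattern);
  # participants 6-17 carry modal label 2, so deviations go to other labels
  lab2 <- lab
  lab2[1:4, 6] <- 3L    # switches 4 of 10 repetitions
  lab2[1:2, 7] <- 3L
  lab2[1:2, 8] <- 4L
  lab2[1:2, 9] <- 1L
  lab2[1, 10] <- 4L
  lab2[1, 11] <- 4L
  al2 <- mk_aligned(lab2, k = 4)
  r2 <- repeatability(al2)
  expect_equal(r2$n_records, 370L)
  expect_equal(r2$n_switch_events, 12L)
  expect_equal(round(100 - r2$repeatability_pct, 1), 3.2)
  expect_equal(round(r2$repeatability_pct, 1), 96.8)
  expect_equal(r2$n_switching_participants, 6L)
  expect_equal(r2$switches_per_participant[6], 4L)
})

test_that("median allocation is the modal label with silhouette tie-breaking", {
  lab <- matrix(rep(2L, 10), ncol = 1)
  expect_equal(median_allocation(mk_aligned(lab, k = 3)), 2L)

  lab2 <- matrix(c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2), ncol = 1)
  expect_equal(median_allocation(mk_aligned(lab2, k = 2)), 1L)

  # 5-5 split: label of the repetition with the highest silhouette wins
  lab3 <- matrix(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), ncol = 1)
  s <- matrix(c(0.2, 0.3, 0.1, 0.2, 0.2, 0.9, 0.1, 0.1, 0.2, 0.1), ncol = 1)
  expect_equal(median_allocation(mk_aligned(lab3, s, k = 2)), 2L)
  s2 <- matrix(c(0.95, 0.3, 0.1, 0.2, 0.2, 0.9, 0.1, 0.1, 0.2, 0.1), ncol = 1)
  expect_equal(median_allocation(mk_aligned(lab3, s2, k = 2)), 1L)
})

test_that("select_k implements the largest-repeatable-k rule", {
  m <- data.frame(k = 2:5, mean_s = c(0.316, 0.268, 0.275, 0.256),
                  sd_s = 0.15, repeatability_pct = c(100, 100, 96.8, 41))
  expect_equal(select_k(m, 95)$chosen_k, 4L)
  expect_equal(select_k(m, 99)$chosen_k, 3L)
  m2 <- m; m2$repeatability_pct <- rep(100, 4)
  expect_equal(select_k(m2, 95)$chosen_k, 5L)
  m3 <- m; m3$repeatability_pct <- c(80, 70, 60, 41)
  out <- select_k(m3, 95)
  expect_equal(out$chosen_k, 2L)
  expect_true(out$fallback)
  # monotone in the threshold
  prev <- Inf
  for (thr in c(40, 60, 90, 95, 97, 99, 100)) {
    ck <- select_k(m, thr)$chosen_k
    expect_lte(ck, prev)
    prev <- ck
  }
})

test_that("boundary analysis ties switching to low silhouette", {
  # no switches anywhere -> all zero
  lab <- matrix(rep(rep(1:2, each = 5), each = 6), nrow = 6)
  s <- matrix(1, nrow = 6, ncol = 10)
  b <- boundary_analysis(mk_aligned(lab, s, k = 2))
  expect_equal(b$n_switches, rep(0L, 10))

  # constructed boundary case: only the low-s participant switches
  lab2 <- lab; lab2[1:3, 1] <- 2L
  s2 <- s; s2[, 1] <- 0.05
  b2 <- boundary_analysis(mk_aligned(lab2, s2, k = 2))
  expect_equal(b2$n_switches[1], 3L)
  expect_equal(sum(b2$n_switches[-1]), 0L)

  # default synthetic cohorts: switch count does not rise with silhouette
  pooled <- do.call(rbind, lapply(1:3, function(seed) {
    co <- generate_cohort(seed = seed)
    M <- cohort_matrix(co)
    ens <- run_ensemble(M, k_range = 4L, n_restarts = 20, R = 6,
                        master_seed = seed)
    boundary_analysis(align_labels(ens, 4))
  }))
  expect_gt(sum(pooled$n_switches), 0)
  rho <- suppressWarnings(
    cor(pooled$mean_s, pooled$n_switches, method = "spearman"))
  expect_lte(rho, 0)
})

test_that("selection_report assembles metrics and final labels coherently", {
  co <- tiny_cohort(seed = 4)
  M <- cohort_matrix(co)
  ens <- run_ensemble(M, k_range = 2:4, n_restarts = 10, R = 4,
                      master_seed = 99)
  rep_ <- selection_report(ens)
  expect_equal(rep_$metrics$k, 2:4)
  expect_true(all(rep_$metrics$repeatability_pct >= 0 &
                    rep_$metrics$repeatability_pct <= 100))
  expect_true(rep_$chosen_k %in% 2:4)
  expect_length(rep_$final_labels, nrow(M))
  expect_true(all(rep_$final_labels %in% seq_len(rep_$chosen_k)))
  f <- tempfile(fileext = ".json")
  write_selection_json(rep_, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$chosen_k, rep_$chosen_k)
  expect_equal(js$final_labels, rep_$final_labels)
  # repeatability 100 iff all rows identical after alignment
  al <- rep_$aligned[[as.character(rep_$chosen_k)]]
  r <- repeatability(al)
  expect_equal(r$repeatability_pct == 100,
               all(apply(al$labels, 2, function(x) length(unique(x)) == 1)))
})
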