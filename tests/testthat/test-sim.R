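test_that("forced class probabilities yield the forced classification", {
  cfg <- sim_config(p_pre_established = 0, p_never_established = 1,
                    duration_s = 120)
  ct <- simulate_contest(cfg, 1, trajectory = FALSE)
  expect_equal(ct$truth$classification, "never_established")
  expect_null(ct$truth$onset_s)
  expect_equal(length(ct$truth$reversal_times_s), 0)

  cfg2 <- sim_config(p_pre_established = 1, p_never_established = 0,
                     duration_s = 120)
  ct2 <- simulate_contest(cfg2, 1, trajectory = FALSE)
  expect_equal(ct2$truth$classification, "pre_established")
  expect_equal(ct2$truth$onset_s, 0)
})

test_that("identical (config, seed) reproduce byte-identical output", {
  cfg <- sim_config(duration_s = 90, onset_median_s = 65, seed = 5)
  a <- simulate_contest(cfg, 123)
  b <- simulate_contest(cfg, 123)
  expect_identical(tibble::as_tibble(a$trajectory),
                   tibble::as_tibble(b$trajectory))
  expect_identical(tibble::as_tibble(a$truth$events),
                   tibble::as_tibble(b$truth$events))
  expect_identical(a$truth$onset_s, b$truth$onset_s)
})

test_that("cohort contests equal standalone simulations with derived seeds", {
  cfg <- sim_config(duration_s = 90, onset_median_s = 65, seed = 7)
  cohort <- simulate_cohort(cfg, 5, trajectory = FALSE)
  expect_length(cohort, 5)
  solo <- simulate_contest(cfg, derive_contest_seed(7, 4),
                           trajectory = FALSE)
  expect_identical(
    tibble::as_tibble(dplyr::select(cohort[[4]]$truth$events, -"contest_id")),
    tibble::as_tibble(dplyr::select(solo$truth$events, -"contest_id")))
  expect_length(simulate_cohort(cfg, 1, trajectory = FALSE), 1)
})

test_that("configured onset latency is recovered by the sample median", {
  cohort <- cached_truth_cohort(100, key = "onset100",
                                p_pre_established = 0,
                                p_never_established = 0, seed = 21)
  onsets <- vapply(cohort, function(ct) ct$truth$onset_s, numeric(1))
  expect_lt(abs(median(onsets) - 300) / 300, 0.2)
})

test_that("reversal frequency matches one-in-five at the default rate", {
  cohort <- cached_truth_cohort(200, key = "rev200",
                                p_pre_established = 0,
                                p_never_established = 0, seed = 31)
  has_rev <- vapply(cohort, function(ct)
    length(ct$truth$reversal_times_s) >= 1, logical(1))
  ci_half <- 1.96 * sqrt(0.2 * 0.8 / 200)
  expect_lt(abs(mean(has_rev) - 0.2), ci_half)
})

test_that("every establishment and reversal is a pursue-to-climb sequence by construction", {
  cohort <- cached_truth_cohort(20, key = "pattern20",
                                p_pre_established = 0,
                                p_never_established = 0,
                                p_reversal = 0.6, seed = 41)
  for (ct in cohort) {
    tr <- ct$truth
    ev <- tr$events
    doms <- tr$dominant_sequence
    marks <- c(tr$onset_s, tr$reversal_times_s)
    for (i in seq_along(marks)) {
      dom <- doms[i]; sub <- setdiff(c("A", "B"), dom)
      climb <- ev[ev$behavior == "climb" & ev$fly == sub &
                    abs(ev$start_s - marks[i]) < 1e-6, ]
      expect_equal(nrow(climb), 1)
      pursuit <- ev[ev$behavior == "pursuit" & ev$fly == dom &
                      ev$end_s <= marks[i] &
                      ev$end_s >= marks[i] - 1, ]  # climb_latency_s = 1
      expect_gte(nrow(pursuit), 1)
    }
    expect_true(all(ev$start_s >= 0 & ev$end_s < 1200))
    if (length(tr$reversal_times_s) > 0) {
      expect_true(all(diff(c(tr$onset_s, tr$reversal_times_s)) > 0))
    }
  }
})

test_that("with lunge_dominant_fraction = 1 every post-onset lunge is by the dominant", {
  cohort <- cached_truth_cohort(12, key = "ldf1",
                                p_pre_established = 0,
                                p_never_established = 0,
                                p_reversal = 0.5,
                                lunge_dominant_fraction = 1, seed = 51)
  for (ct in cohort) {
    tl <- truth_timeline(ct)
    ev <- ct$truth$events
    lunges <- ev[ev$behavior == "lunge" & ev$start_s >= ct$truth$onset_s, ]
    if (nrow(lunges) == 0) next
    status <- dominance_status(tl, lunges$start_s)
    expect_equal(paste0(lunges$fly, "_dominant"), status)
  }
})

test_that("per-phase true event counts sum to the contest totals", {
  ct <- cached_truth_cohort(12, key = "ldf1",
                            p_pre_established = 0, p_never_established = 0,
                            p_reversal = 0.5, lunge_dominant_fraction = 1,
                            seed = 51)[[2]]
  tl <- truth_timeline(ct)
  segs <- phase_partition(tl)
  ev <- ct$truth$events
  for (b in unique(ev$behavior)) {
    eb <- ev[ev$behavior == b, ]
    per_seg <- vapply(seq_len(nrow(segs)), function(i)
      sum(eb$start_s >= segs$start_s[i] & eb$start_s < segs$end_s[i]),
      numeric(1))
    expect_equal(sum(per_seg), nrow(eb))
  }
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(pursuit_gap_mm = 20), "arena diameter",
               class = "flydom_config_error")
  expect_error(sim_config(p_reversal = 1.5), class = "flydom_config_error")
  expect_error(sim_config(p_pre_established = 0.7,
                          p_never_established = 0.5),
               class = "flydom_config_error")
  expect_error(sim_config(fps = 0), class = "flydom_config_error")
})

test_that("winner rematches implement the winner-effect design", {
  cfg <- sim_config(duration_s = 600, onset_median_s = 200, seed = 61,
                    p_pre_established = 0, p_never_established = 0)
  first <- simulate_contest(cfg, 61, trajectory = FALSE)
  expect_equal(first$truth$classification, "established")

  # certain winner: the prior dominant always prevails
  for (s in 1:6) {
    rm <- winner_rematch(cfg, first, seed = s, p_win = 1,
                         trajectory = FALSE)
    expect_equal(rm$truth$dominant_id, first$truth$dominant_id)
    expect_equal(rm$truth$prior_dominant_id, first$truth$dominant_id)
  }

  # zero precocious-lunge probability: no lunges before onset
  for (s in 1:6) {
    rm <- winner_rematch(cfg, first, seed = s, p_precocious = 0,
                         p_naive_precocious = 0, trajectory = FALSE)
    ev <- rm$truth$events
    expect_equal(sum(ev$behavior == "lunge" &
                       ev$start_s < rm$truth$onset_s), 0)
  }

  # a never-established first contest cannot seed a rematch
  nev <- simulate_contest(sim_config(p_never_established = 1,
                                     p_pre_established = 0),
                          5, trajectory = FALSE)
  expect_error(winner_rematch(cfg, nev, seed = 1),
               class = "flydom_sim_error")
})

test_that("prior dominants lunge early more often than naive opponents", {
  cfg <- sim_config(duration_s = 600, onset_median_s = 200, seed = 71,
                    p_pre_established = 0, p_never_established = 0)
  first <- simulate_contest(cfg, 71, trajectory = FALSE)
  prior <- first$truth$dominant_id
  naive <- setdiff(c("A", "B"), prior)
  res <- vapply(1:60, function(s) {
    rm <- winner_rematch(cfg, first, seed = 1000 + s, trajectory = FALSE)
    ev <- rm$truth$events
    pre <- ev[ev$behavior == "lunge" & ev$start_s < rm$truth$onset_s, ]
    c(any(pre$fly == prior), any(pre$fly == naive))
  }, logical(2))
  expect_gt(mean(res[1, ]), mean(res[2, ]))
})
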