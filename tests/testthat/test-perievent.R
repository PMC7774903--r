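events_tbl <- function(...) {
  as_event_table(tibble::tibble(...))
}

test_that("point events land in the right onset-aligned bin", {
  tl <- simple_timeline(300, duration_s = 1200)
  ev <- events_tbl(contest_id = "t1", fly = "A", behavior = "lunge",
                   start_s = 330, end_s = 330)
  m <- align_and_bin(ev, list(tl), "lunge")
  b0 <- which(m$bin_edges_s == 0)
  expect_equal(unname(m$values[1, b0]), 1)
  expect_equal(sum(m$values[1, ], na.rm = TRUE), 1)
  # a contest with no events has an all-zero row over covered bins
  ev2 <- events_tbl(contest_id = "t1", fly = "A", behavior = "wing_flick",
                    start_s = 10, end_s = 10)
  m2 <- align_and_bin(ev2, list(tl), "lunge")
  expect_equal(sum(m2$values[1, ], na.rm = TRUE), 0)
  expect_true(any(!is.na(m2$values[1, ])))
})

test_that("state events contribute fractional bin occupancy", {
  tl <- simple_timeline(300, duration_s = 1200)
  ev <- events_tbl(contest_id = "t1", fly = "both", behavior = "fence",
                   start_s = 210, end_s = 270)  # [-90, -30) relative
  m <- align_and_bin(ev, list(tl), "fence")
  i1 <- which(m$bin_edges_s == -120)
  i2 <- which(m$bin_edges_s == -60)
  expect_equal(unname(m$values[1, i1]), 0.5)
  expect_equal(unname(m$values[1, i2]), 0.5)
  expect_equal(sum(m$values[1, ], na.rm = TRUE), 1)
})

test_that("bins outside a contest's recording are missing, inside are not", {
  tl <- simple_timeline(90, duration_s = 300)
  ev <- events_tbl(contest_id = "t1", fly = "A", behavior = "lunge",
                   start_s = 100, end_s = 100)
  m <- align_and_bin(ev, list(tl), "lunge")
  expect_true(is.na(m$values[1, which(m$bin_edges_s == -120)]))
  # [-90, -30) is not aligned with full coverage: first full bin is [-60, 0)
  expect_false(is.na(m$values[1, which(m$bin_edges_s == -60)]))
  expect_true(is.na(m$values[1, which(m$bin_edges_s == 180)]))
})

test_that("binned counts conserve the raw event count over covered bins", {
  cohort <- cached_truth_cohort(10, key = "peri10",
                                p_pre_established = 0,
                                p_never_established = 0, seed = 91)
  events <- dplyr::bind_rows(lapply(cohort, function(ct) ct$truth$events))
  kept <- lapply(cohort, truth_timeline)
  m <- align_and_bin(events, kept, "wing_flick")
  for (i in seq_along(kept)) {
    tl <- kept[[i]]
    covered <- !is.na(m$values[i, ])
    lo <- m$bin_edges_s[which(covered)[1]] + tl$onset_s
    hi <- m$bin_edges_s[max(which(covered)) + 1] + tl$onset_s
    ev <- events[events$contest_id == tl$contest_id &
                   events$behavior == "wing_flick", ]
    expect_equal(sum(m$values[i, ], na.rm = TRUE),
                 sum(ev$start_s >= lo & ev$start_s < hi))
  }
})

test_that("incompatible measures and unknown behaviors are rejected", {
  tl <- simple_timeline(300)
  ev <- events_tbl(contest_id = "t1", fly = "A", behavior = "lunge",
                   start_s = 1, end_s = 1)
  expect_error(align_and_bin(ev, list(tl), "lunge",
                             measure = "fraction_of_time"),
               class = "flydom_config_error")
  expect_error(align_and_bin(ev, list(tl), "groom"),
               class = "flydom_vocab_error")
  nev <- build_timeline(make_instances(numeric(0), character(0)), 1200)
  expect_error(align_and_bin(ev, list(nev), "lunge"),
               class = "flydom_validation_error")
})

test_that("per-bin summaries use type-7 quartiles and flag low-n bins", {
  tls <- lapply(1:5, function(i) simple_timeline(300, contest_id =
                                                   paste0("t", i)))
  ev <- events_tbl(contest_id = paste0("t", 1:5), fly = "A",
                   behavior = "lunge", start_s = rep(310, 5),
                   end_s = rep(310, 5))
  m <- align_and_bin(ev, tls, "lunge")
  # overwrite one bin with known values to pin the quartile convention
  b0 <- which(m$bin_edges_s == 0)
  m$values[, b0] <- 1:5
  s <- summarize_perievent(m)
  row <- s[s$bin_start_s == 0, ]
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  expect_false(row$low_n)

  # identical rows give zero IQR everywhere
  m$values[, b0] <- 2
  s2 <- summarize_perievent(m)
  expect_equal(s2$q3[s2$bin_start_s == 0] - s2$q1[s2$bin_start_s == 0], 0)

  single <- align_and_bin(ev[1, ], tls[1], "lunge")
  expect_true(all(summarize_perievent(single)$low_n))
})

test_that("paired window test handles degenerate and small inputs explicitly", {
  tls <- lapply(1:4, function(i) simple_timeline(300, contest_id =
                                                   paste0("t", i)))
  # pre == post in every contest: all differences zero
  ev <- events_tbl(contest_id = rep(paste0("t", 1:4), each = 2),
                   fly = "A", behavior = "lunge",
                   start_s = rep(c(270, 330), 4), end_s = rep(c(270, 330), 4))
  r <- paired_window_test(ev, tls, "lunge", window_min = 1)
  expect_equal(r$direction, "none")
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$stars, "n.s.")
  expect_equal(r$n_pairs, 4)

  # onsets too early for the window: insufficient data, not an error
  early <- lapply(1:2, function(i) simple_timeline(30, contest_id =
                                                     paste0("t", i)))
  r2 <- paired_window_test(ev, early, "lunge", window_min = 1)
  expect_true(r2$insufficient_data)
  expect_equal(r2$n_pairs, 0)
})

test_that("paired window p-values come from the exact signed-rank null", {
  tls <- lapply(1:6, function(i) simple_timeline(400, contest_id =
                                                   paste0("t", i)))
  # contest i has i lunges post-onset and none pre: diffs {1..6}
  ev <- events_tbl(
    contest_id = rep(paste0("t", 1:6), times = 1:6),
    fly = "A", behavior = "lunge",
    start_s = 400 + unlist(lapply(1:6, seq_len)),
    end_s = 400 + unlist(lapply(1:6, seq_len)))
  r <- paired_window_test(ev, tls, "lunge", window_min = 1)
  expect_equal(r$n_pairs, 6)
  expect_equal(r$p_two_sided, 2 / 64)
  expect_equal(r$direction, "post_greater")
  expect_equal(r$stars, "*")
})

test_that("outputs are invariant to a common time shift", {
  cohort <- cached_truth_cohort(10, key = "peri10",
                                p_pre_established = 0,
                                p_never_established = 0, seed = 91)
  events <- dplyr::bind_rows(lapply(cohort, function(ct) ct$truth$events))
  kept <- lapply(cohort, truth_timeline)
  shift <- 43
  ev2 <- events
  ev2$start_s <- ev2$start_s + shift
  ev2$end_s <- ev2$end_s + shift
  kept2 <- lapply(kept, function(tl) {
    inst <- make_instances(tl$onset_s + shift, tl$dominant_at_onset)
    build_timeline(inst, tl$duration_s + 2 * shift, tl$contest_id)
  })
  for (b in c("lunge", "fence")) {
    r1 <- paired_window_test(events, kept, b, window_min = 1)
    r2 <- paired_window_test(ev2, kept2, b, window_min = 1)
    expect_equal(r2$statistic, r1$statistic)
    expect_equal(r2$p_two_sided, r1$p_two_sided)
    expect_equal(r2$n_pairs, r1$n_pairs)
  }
})

test_that("a default cohort reproduces the pre/post significance pattern", {
  cohort <- cached_truth_cohort(45, key = "pattern45", seed = 5)
  events <- dplyr::bind_rows(lapply(cohort, function(ct) ct$truth$events))
  kept <- apply_exclusions(lapply(cohort, truth_timeline))$kept
  fence <- paired_window_test(events, kept, "fence", window_min = 5)
  lunge <- paired_window_test(events, kept, "lunge", window_min = 5)
  expect_equal(fence$direction, "pre_greater")
  expect_lt(fence$p_two_sided, 0.05)
  expect_equal(lunge$direction, "post_greater")
  expect_lt(lunge$p_two_sided, 0.001)
})

test_that("raster export aligns events to onset and orders by latency", {
  cohort <- cached_truth_cohort(10, key = "peri10",
                                p_pre_established = 0,
                                p_never_established = 0, seed = 91)
  events <- dplyr::bind_rows(lapply(cohort, function(ct) ct$truth$events))
  kept <- lapply(cohort, truth_timeline)
  r <- raster_table(events, kept, "lunge")
  expect_true(all(diff(r$onset_s) >= 0))
  one <- r[r$contest_id == kept[[1]]$contest_id, ]
  ev1 <- events[events$contest_id == kept[[1]]$contest_id &
                  events$behavior == "lunge", ]
  expect_equal(sort(one$rel_start_s + kept[[1]]$onset_s), sort(ev1$start_s))
})
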