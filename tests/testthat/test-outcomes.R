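test_that("phase partitions tile the contest and alternate statuses", {
  tl <- build_timeline(make_instances(c(100, 400, 700), c("A", "B", "A")),
                       1200)
  segs <- phase_partition(tl)
  expect_equal(segs$start_s[1], 0)
  expect_equal(segs$end_s[nrow(segs)], 1200)
  expect_equal(segs$start_s[-1], segs$end_s[-nrow(segs)])
  expect_true(all(segs$status[-1] != segs$status[-nrow(segs)]))
  nev <- build_timeline(make_instances(numeric(0), character(0)), 1200)
  expect_equal(phase_partition(nev)$status, "unestablished")
})

test_that("phase attribution conserves totals and attributes dominly lunges", {
  tl <- build_timeline(make_instances(c(100, 400), c("A", "B")), 1200,
                       contest_id = "c1")
  ev <- as_event_table(tibble::tibble(
    contest_id = "c1", fly = c("A", "A", "A", "B", "B", "both"),
    behavior = c("lunge", "lunge", "lunge", "lunge", "wing_flick", "fence"),
    start_s = c(150, 250, 390, 500, 50, 10),
    end_s = c(150, 250, 390, 500, 50, 40)))
  at <- attribute_by_phase(ev, tl)
  # per-segment tallies sum to contest totals for every behavior
  tot <- dplyr::summarise(dplyr::group_by(at$tallies, .data$behavior),
                          n = sum(.data$n_events))
  expect_equal(tot$n[tot$behavior == "lunge"], 4)
  expect_equal(tot$n[tot$behavior == "fence"], 1)
  # all four lunges are by the fly dominant at the time
  expect_equal(unname(at$fraction_by_dominant[["lunge"]]), 1)
  expect_equal(unname(at$fraction_post_onset[["lunge"]]), 1)
  expect_error(attribute_by_phase(
    dplyr::mutate(ev, fly = replace(fly, 1, "C")), tl),
    class = "flydom_validation_error")
})

test_that("pooled lunge attribution matches the configured dominant fraction", {
  cohort <- cached_truth_cohort(40, key = "ldf40",
                                p_pre_established = 0,
                                p_never_established = 0,
                                lunge_dominant_fraction = 0.9, seed = 13)
  by_dom <- 0; total <- 0
  for (ct in cohort) {
    tl <- truth_timeline(ct)
    ev <- ct$truth$events
    lunges <- ev[ev$behavior == "lunge" & ev$start_s >= tl$onset_s, ]
    st <- dominance_status(tl, lunges$start_s)
    by_dom <- by_dom + sum(paste0(lunges$fly, "_dominant") == st)
    total <- total + nrow(lunges)
  }
  ci_half <- 1.96 * sqrt(0.9 * 0.1 / total)
  expect_lt(abs(by_dom / total - 0.9), ci_half)
})

test_that("dominance-outcome tests match symmetric-null and enumeration oracles", {
  tbl <- outcome_from_contests(
    cached_truth_cohort(10, key = "out10", p_pre_established = 0,
                        p_never_established = 0, seed = 17),
    pairing_label = "same")
  expect_s3_class(tbl, "outcome_table")

  # hand-held table: 5 wins of 10 has p = 1 under the symmetric null
  fake <- tbl[1:10, ]
  fake$focal_dominant <- rep(c(TRUE, FALSE), 5)
  fake$pairing_label <- "even"
  r <- dominance_outcome_test(fake, "even")
  expect_equal(r$p_binomial, 1)
  expect_equal(r$proportion, 0.5)
  expect_equal(dominance_outcome_test(fake, "missing")$insufficient_data,
               TRUE)

  # Fisher comparison against full hypergeometric enumeration
  fake2 <- dplyr::bind_rows(fake, fake)
  fake2$pairing_label <- rep(c("p1", "p2"), each = 10)
  fake2$focal_dominant <- c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  cmp <- dominance_outcome_test(fake2, "p1", compare_to = "p2")
  m <- matrix(c(10, 0, 5, 5), nrow = 2, byrow = TRUE)
  expect_equal(cmp$comparison$p_fisher, brute_fisher_p(m))
  expect_equal(cmp$comparison$table, m)
})

test_that("binomial test of win proportions matches direct summation", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(3:10, 1); k <- sample(0:n, 1)
    expect_equal(binom.test(k, n, 0.5)$p.value, brute_binom_p(k, n, 0.5))
  }
})

test_that("lunge-count comparisons dispatch on the group structure", {
  base <- tibble::tibble(
    contest_id = as.character(1:6), pairing_label = rep(c("g1", "g2"), 3),
    focal_genotype = NA, opponent_genotype = NA, focal_fly = "A",
    focal_dominant = TRUE, focal_lunges = c(1, 4, 2, 5, 3, 6),
    opponent_lunges = 0, focal_lunged_pre_onset = FALSE)
  # two groups {1,2,3} vs {4,5,6}: exact two-sided rank-sum
  r <- lunge_count_comparisons(base)
  expect_equal(r$test, "rank_sum")
  expect_equal(r$p_value, 2 / 20)
  expect_equal(r$groups$median, c(2, 5))

  # identical groups across >= 3 levels: Kruskal-Wallis H = 0
  tri <- base
  tri$pairing_label <- rep(c("g1", "g2", "g3"), 2)
  tri$focal_lunges <- rep(c(2, 7), 3)
  r3 <- lunge_count_comparisons(tri)
  expect_equal(r3$test, "kruskal_wallis")
  expect_equal(r3$statistic, 0)

  # paired design uses the sign test
  rp <- lunge_count_comparisons(base, paired = TRUE)
  expect_equal(rp$test, "sign")
  expect_equal(rp$p_value, sign_test(c(1, 2, 3), c(4, 5, 6))$p_value)

  empty <- base[base$pairing_label == "g1", ]
  expect_true(lunge_count_comparisons(empty)$insufficient_data)
})

test_that("a five-fold lunge-rate difference separates dominant-male medians", {
  prof_hi <- default_act_profiles()
  prof_hi$lunge$value <- prof_hi$lunge$value * 5
  hi <- cached_truth_cohort(20, key = "hi_lunge", seed = 23,
                            p_pre_established = 0, p_never_established = 0,
                            act_profiles = prof_hi)
  lo <- cached_truth_cohort(20, key = "lo_lunge", seed = 29,
                            p_pre_established = 0, p_never_established = 0)
  tbl <- dplyr::bind_rows(
    outcome_from_contests(hi, pairing_label = "high"),
    outcome_from_contests(lo, pairing_label = "low"))
  r <- lunge_count_comparisons(tbl)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$groups$median[r$groups$group == "high"],
            r$groups$median[r$groups$group == "low"])
})

test_that("chi-square of precocious-lunge proportions matches hand computation", {
  mk <- function(lunged, won = TRUE) tibble::tibble(
    contest_id = as.character(seq_along(lunged)), pairing_label = "x",
    focal_genotype = NA, opponent_genotype = NA, focal_fly = "A",
    focal_dominant = won, focal_lunges = 1, opponent_lunges = 0,
    focal_lunged_pre_onset = lunged)
  # [[20, 5], [5, 20]]: expected 12.5 everywhere, chi-square = 4 * 7.5^2/12.5
  rematch <- mk(rep(c(TRUE, FALSE), c(20, 5)))
  naive <- mk(rep(c(TRUE, FALSE), c(5, 20)))
  r <- precocious_lunge_analysis(naive, rematch)
  expect_equal(r$chisq$statistic, 4 * 7.5^2 / 12.5)
  expect_equal(r$chisq$df, 1)
  expect_equal(r$p_fisher, brute_fisher_p(r$table), tolerance = 1e-7)

  # identical proportions give a zero statistic
  r0 <- precocious_lunge_analysis(naive, naive)
  expect_equal(r0$chisq$statistic, 0)

  # within-rematch comparison counts early-lunge winners vs losers
  rematch2 <- mk(rep(TRUE, 20), won = rep(c(TRUE, FALSE), c(16, 4)))
  r2 <- precocious_lunge_analysis(naive, rematch2)
  expect_equal(r2$within_rematch$won, 16)
  expect_equal(r2$within_rematch$lost, 4)
  expect_equal(r2$within_rematch$binomial_p,
               brute_binom_p(16, 20, 0.5))
})
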