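#' Tally events by dominance phase
#'
#' Splits a contest into its dominance phases ([phase_partition()]) and
#' tallies each behavior and actor within each segment, together with
#' derived summaries: the fraction of each behavior's events occurring
#' after the initial onset, the fraction of single-actor post-onset events
#' executed by the instantaneous dominant, and event counts in a window
#' around each reversal.
#'
#' @param events `fly_events` for one contest.
#' @param timeline The contest's `dominance_timeline` (must be
#'   established).
#' @param reversal_window_s Half-width (s) of the window tallied around
#'   each reversal (default 30).
#' @return List with `tallies` (tibble: segment, status, fly, behavior,
#'   n_events, time_s), `fraction_post_onset` (named by behavior),
#'   `fraction_by_dominant` (named by behavior, single-actor post-onset
#'   events), and `reversal_window` (tibble: reversal time, fly, behavior,
#'   n pre/post).
#' @export
attribute_by_phase <- function(events, timeline, reversal_window_s = 30) {
  if (timeline$classification != "established") {
    abort("Phase attribution requires an established timeline.",
          class = "flydom_validation_error")
  }
  e <- events[events$contest_id == timeline$contest_id, , drop = FALSE]
  bad <- setdiff(unique(e$fly), c(fly_ids(), "both"))
  if (length(bad) > 0) {
    abort(sprintf("Events by unknown fly id: %s.", paste(bad, collapse = ", ")),
          class = "flydom_validation_error")
  }
  segs <- phase_partition(timeline)
  rows <- list()
  for (s in seq_len(nrow(segs))) {
    in_seg <- e$start_s >= segs$start_s[s] & e$start_s < segs$end_s[s]
    es <- e[in_seg, , drop = FALSE]
    if (nrow(es) == 0) next
    agg <- dplyr::summarise(
      dplyr::group_by(es, .data$fly, .data$behavior),
      n_events = dplyr::n(),
      time_s = sum(pmin(.data$end_s, segs$end_s[s]) - .data$start_s),
      .groups = "drop")
    agg$segment <- s
    agg$status <- segs$status[s]
    rows[[length(rows) + 1]] <- agg
  }
  tallies <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(fly = character(0), behavior = character(0),
                   n_events = integer(0), time_s = numeric(0),
                   segment = integer(0), status = character(0))
  tallies <- tallies[, c("segment", "status", "fly", "behavior",
                         "n_events", "time_s")]

  behaviors <- unique(e$behavior)
  post <- vapply(behaviors, function(b) {
    eb <- e[e$behavior == b, ]
    if (nrow(eb) == 0) return(NA_real_)
    mean(eb$start_s >= timeline$onset_s)
  }, numeric(1))
  by_dom <- vapply(behaviors, function(b) {
    eb <- e[e$behavior == b & e$fly %in% fly_ids() &
              e$start_s >= timeline$onset_s, ]
    if (nrow(eb) == 0) return(NA_real_)
    mean(eb$fly == dominance_status_fly(timeline, eb$start_s))
  }, numeric(1))

  rev_rows <- list()
  for (t_r in timeline$reversals$t_s) {
    for (side in c("pre", "post")) {
      lo <- if (side == "pre") t_r - reversal_window_s else t_r
      hi <- if (side == "pre") t_r else t_r + reversal_window_s
      ew <- e[e$start_s >= lo & e$start_s < hi, , drop = FALSE]
      if (nrow(ew) == 0) next
      agg <- dplyr::summarise(dplyr::group_by(ew, .data$fly, .data$behavior),
                              n_events = dplyr::n(), .groups = "drop")
      agg$reversal_t_s <- t_r
      agg$side <- side
      rev_rows[[length(rev_rows) + 1]] <- agg
    }
  }
  reversal_window <- if (length(rev_rows)) dplyr::bind_rows(rev_rows) else
    tibble::tibble(fly = character(0), behavior = character(0),
                   n_events = integer(0), reversal_t_s = numeric(0),
                   side = character(0))
  list(tallies = tallies,
       fraction_post_onset = post,
       fraction_by_dominant = by_dom,
       reversal_window = reversal_window)
}

# fly id of the instantaneous dominant at times t ("" before onset)
dominance_status_fly <- function(timeline, t) {
  s <- dominance_status(timeline, t)
  sub("_dominant$", "", ifelse(s == "unestablished", "", s))
}

#' Build an outcome table from simulated contests
#'
#' One row per contest: a pairing label, which fly was focal, whether the
#' focal fly became dominant (at onset), each fly's total lunge count, and
#' whether the focal fly lunged before onset. "Focal" is a bookkeeping
#' label with no behavioral meaning; for rematches, the prior dominant is
#' the natural focal fly.
#'
#' @param contests List of `simulated_contest`s (established ones are
#'   used; others are skipped).
#' @param pairing_label Label describing the pairing (genotypes, housing).
#' @param focal `"A"`, `"B"`, or `"prior_dominant"` (rematches).
#' @param focal_genotype,opponent_genotype Optional genotype labels.
#' @return Tibble of class `outcome_table`.
#' @export
outcome_from_contests <- function(contests, pairing_label,
                                  focal = c("A", "B", "prior_dominant"),
                                  focal_genotype = NA_character_,
                                  opponent_genotype = NA_character_) {
  focal <- match.arg(focal)
  rows <- lapply(contests, function(ct) {
    tr <- ct$truth
    if (tr$classification == "never_established") return(NULL)
    f <- if (focal == "prior_dominant") {
      if (is.null(tr$prior_dominant_id)) {
        abort("Contest has no prior_dominant_id; not a rematch.",
              class = "flydom_validation_error")
      }
      tr$prior_dominant_id
    } else focal
    ev <- tr$events
    lunges <- ev[ev$behavior == "lunge", ]
    tibble::tibble(
      contest_id = ct$contest_id,
      pairing_label = pairing_label,
      focal_genotype = focal_genotype,
      opponent_genotype = opponent_genotype,
      focal_fly = f,
      focal_dominant = identical(tr$dominant_id, f),
      focal_lunges = sum(lunges$fly == f),
      opponent_lunges = sum(lunges$fly == other_fly(f)),
      focal_lunged_pre_onset = any(lunges$fly == f &
                                     lunges$start_s < tr$onset_s)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("outcome_table", class(tibble::tibble())))
}

#' Dominance-outcome tests for a pairing
#'
#' Exact binomial test of the focal-dominant proportion against chance
#' (0.5, two-sided) within one pairing, and optionally Fisher's exact test
#' comparing win counts between two pairings in a 2x2 table.
#'
#' @param table An `outcome_table`.
#' @param pairing_label Pairing to test.
#' @param compare_to Optional second pairing label for the Fisher
#'   comparison.
#' @return List with `n`, `wins`, `proportion`, `conf_int`, `p_binomial`,
#'   and (when `compare_to` is given) `p_fisher` and `odds_ratio`. An empty
#'   pairing yields an explicit insufficient-data result.
#' @export
dominance_outcome_test <- function(table, pairing_label,
                                   compare_to = NULL) {
  sub <- table[table$pairing_label == pairing_label, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(pairing_label = pairing_label, n = 0L,
                insufficient_data = TRUE))
  }
  k <- sum(sub$focal_dominant); n <- nrow(sub)
  bt <- binom.test(k, n, p = 0.5, alternative = "two.sided")
  out <- list(pairing_label = pairing_label, n = n, wins = k,
              proportion = k / n,
              conf_int = unname(bt$conf.int), p_binomial = bt$p.value,
              insufficient_data = FALSE)
  if (!is.null(compare_to)) {
    sub2 <- table[table$pairing_label == compare_to, , drop = FALSE]
    if (nrow(sub2) == 0) {
      out$comparison <- list(compare_to = compare_to,
                             insufficient_data = TRUE)
    } else {
      k2 <- sum(sub2$focal_dominant); n2 <- nrow(sub2)
      m <- matrix(c(k, n - k, k2, n2 - k2), nrow = 2, byrow = TRUE)
      ft <- fisher.test(m)
      out$comparison <- list(compare_to = compare_to, table = m,
                             p_fisher = ft$p.value,
                             odds_ratio = unname(ft$estimate),
                             insufficient_data = FALSE)
    }
  }
  out
}

#' Compare dominant-male lunge counts across groups
#'
#' Takes, per contest, the total number of lunges executed by whichever
#' fly became dominant, and compares groups: Kruskal-Wallis (tie-corrected)
#' across three or more groups, the two-sided rank-sum test
#' ([rank_sum_test()]) for two independent groups, or the exact sign test
#' for a paired design. Group medians and interquartile ranges are
#' reported.
#'
#' @param table An `outcome_table`.
#' @param grouping Column name whose values define the groups (default
#'   `"pairing_label"`).
#' @param paired If `TRUE` (two groups of equal size, matched by position),
#'   uses the sign test.
#' @return List with `groups` (tibble: group, n, median, q1, q3), `test`
#'   (`"kruskal_wallis"`, `"rank_sum"` or `"sign"`), `statistic`,
#'   `p_value`. Any empty group yields an insufficient-data result.
#' @export
lunge_count_comparisons <- function(table, grouping = "pairing_label",
                                    paired = FALSE) {
  dom_lunges <- ifelse(table$focal_dominant, table$focal_lunges,
                       table$opponent_lunges)
  g <- as.character(table[[grouping]])
  groups <- split(dom_lunges, g)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    return(list(insufficient_data = TRUE, groups = names(groups)))
  }
  summ <- dplyr::bind_rows(lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    tibble::tibble(group = nm, n = length(v), median = median(v),
                   q1 = unname(quantile(v, 0.25, type = 7)),
                   q3 = unname(quantile(v, 0.75, type = 7)))
  }))
  if (paired) {
    if (length(groups) != 2 || length(groups[[1]]) != length(groups[[2]])) {
      return(list(insufficient_data = TRUE,
                  reason = "paired design needs two equal-size groups"))
    }
    st <- sign_test(groups[[1]], groups[[2]])
    return(list(groups = summ, test = "sign", statistic = st$n_positive,
                p_value = st$p_value, insufficient_data = FALSE))
  }
  if (length(groups) == 2) {
    rs <- rank_sum_test(groups[[1]], groups[[2]])
    list(groups = summ, test = "rank_sum", statistic = rs$statistic,
         z = rs$z, p_value = rs$p_value, method = rs$method,
         insufficient_data = FALSE)
  } else {
    kw <- kruskal.test(dom_lunges, factor(g))
    list(groups = summ, test = "kruskal_wallis",
         statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, insufficient_data = FALSE)
  }
}

#' Precocious-lunge analysis for rematch designs
#'
#' Compares the proportion of contests in which the focal fly lunged
#' before establishing dominance between two cohorts (e.g. prior dominants
#' in rematches vs randomly chosen flies from naive pairs) with a 2x2
#' chi-square test with one degree of freedom (no continuity correction by
#' default); Fisher's exact test is always reported alongside, and a
#' warning recommends it when any expected cell is below 1. Also performs
#' the within-rematch comparison of lunged-early-and-won versus
#' lunged-early-and-lost counts (chi-square goodness of fit against an
#' even split, plus the exact binomial).
#'
#' @param first `outcome_table` for the naive-pair cohort.
#' @param rematch `outcome_table` for the rematch cohort.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return List with `proportions`, `table`, `chisq` (statistic, df,
#'   p_value), `p_fisher`, and `within_rematch` (won, lost, chisq_p,
#'   binomial_p).
#' @export
precocious_lunge_analysis <- function(first, rematch, yates = FALSE) {
  x1 <- sum(rematch$focal_lunged_pre_onset); n1 <- nrow(rematch)
  x2 <- sum(first$focal_lunged_pre_onset); n2 <- nrow(first)
  m <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE,
              dimnames = list(c("rematch", "naive"),
                              c("lunged_pre", "did_not")))
  cs <- suppressWarnings(chisq.test(m, correct = yates))
  if (any(cs$expected < 1)) {
    warn("An expected cell count is below 1; prefer Fisher's exact test.")
  }
  ft <- fisher.test(m)
  early <- rematch[rematch$focal_lunged_pre_onset, , drop = FALSE]
  won <- sum(early$focal_dominant); lost <- nrow(early) - won
  within <- if (nrow(early) == 0) {
    list(insufficient_data = TRUE)
  } else {
    gof <- suppressWarnings(chisq.test(c(won, lost)))
    list(won = won, lost = lost,
         chisq = unname(gof$statistic), chisq_p = gof$p.value,
         binomial_p = binom.test(won, won + lost, 0.5)$p.value,
         insufficient_data = FALSE)
  }
  list(
    proportions = c(rematch = x1 / n1, naive = x2 / n2),
    table = m,
    chisq = list(statistic = unname(cs$statistic),
                 df = unname(cs$parameter), p_value = cs$p.value,
                 yates = yates),
    p_fisher = ft$p.value,
    within_rematch = within
  )
}
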