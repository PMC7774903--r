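default_measure <- function(behavior) {
  if (behavior_class(behavior) == "point") "count_per_min"
  else "fraction_of_time"
}

check_measure <- function(behavior, measure) {
  if (is.null(measure)) return(default_measure(behavior))
  measure <- match.arg(measure, c("count_per_min", "fraction_of_time"))
  if (measure == "fraction_of_time" && behavior_class(behavior) == "point") {
    abort(sprintf(
      "`fraction_of_time` is incompatible with point-like behavior '%s'.",
      behavior), class = "flydom_config_error")
  }
  measure
}

# Total length of the union of [starts, ends) clipped to [lo, hi).
union_overlap <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Align events to dominance onset and bin them
#'
#' Shifts each contest's event times by its onset so that time 0 is the
#' establishment of dominance, and tallies one behavior into onset-aligned
#' half-open time bins (1-min bins by default). Point-like behaviors are
#' counted per bin; state-like behaviors contribute the fraction of bin time
#' occupied (union over both flies). Bins not fully covered by a contest's
#' recording are marked missing (`NA`). Alignment uses the initial onset
#' only; post-reversal periods are not re-aligned.
#'
#' @param events `fly_events` covering the contests in `timelines`.
#' @param timelines Named list of established `dominance_timeline`s (e.g.
#'   `apply_exclusions(...)$kept`).
#' @param behavior One behavior label from [behavior_vocabulary()].
#' @param measure `"count_per_min"` or `"fraction_of_time"`; defaults to the
#'   behavior's natural measure (counts for point-like acts, time fraction
#'   for state-like acts). `fraction_of_time` is rejected for point events.
#' @param bin_s Bin width in seconds (default 60).
#' @return An object of class `perievent_matrix`: `values` is a contest-by-
#'   bin matrix, `bin_edges_s` the onset-aligned bin edges.
#' @export
align_and_bin <- function(events, timelines, behavior, measure = NULL,
                          bin_s = 60) {
  check_behavior(behavior)
  measure <- check_measure(behavior, measure)
  if (inherits(timelines, "dominance_timeline")) timelines <- list(timelines)
  cls <- vapply(timelines, function(tl) tl$classification, character(1))
  if (any(cls != "established")) {
    abort("All timelines must be classified `established`; apply exclusions first.",
          class = "flydom_validation_error")
  }
  ids <- vapply(timelines, function(tl) tl$contest_id, character(1))
  onsets <- vapply(timelines, function(tl) tl$onset_s, numeric(1))
  durations <- vapply(timelines, function(tl) tl$duration_s, numeric(1))
  lo_bin <- min(floor(-onsets / bin_s))
  hi_bin <- max(ceiling((durations - onsets) / bin_s))
  bin_edges <- seq(lo_bin, hi_bin) * bin_s
  n_bins <- length(bin_edges) - 1
  values <- matrix(NA_real_, nrow = length(ids), ncol = n_bins,
                   dimnames = list(ids, NULL))
  ev <- events[events$behavior == behavior, , drop = FALSE]
  for (i in seq_along(ids)) {
    e <- ev[ev$contest_id == ids[i], , drop = FALSE]
    rel_start <- e$start_s - onsets[i]
    rel_end <- e$end_s - onsets[i]
    covered_lo <- -onsets[i]
    covered_hi <- durations[i] - onsets[i]
    for (b in seq_len(n_bins)) {
      b_lo <- bin_edges[b]; b_hi <- bin_edges[b + 1]
      if (b_lo < covered_lo - 1e-9 || b_hi > covered_hi + 1e-9) next
      if (measure == "count_per_min") {
        values[i, b] <- sum(rel_start >= b_lo & rel_start < b_hi)
      } else {
        values[i, b] <- union_overlap(rel_start, rel_end, b_lo, b_hi) / bin_s
      }
    }
  }
  structure(
    list(behavior = behavior, measure = measure, bin_s = bin_s,
         bin_edges_s = bin_edges, values = values, contest_ids = ids),
    class = "perievent_matrix"
  )
}

#' @export
print.perievent_matrix <- function(x, ...) {
  cat(sprintf("<perievent_matrix> %s (%s): %d contests x %d bins of %g s\n",
              x$behavior, x$measure, nrow(x$values), ncol(x$values),
              x$bin_s))
  invisible(x)
}

#' Per-bin medians and interquartile ranges
#'
#' Collective medians and IQR envelopes over contests, per onset-aligned
#' bin, ignoring missing entries. Quartiles use linear interpolation between
#' order statistics (R quantile type 7); bins supported by fewer than
#' `min_n` contests are flagged `low_n`.
#'
#' @param m A `perievent_matrix`.
#' @param min_n Minimum contests per bin before flagging (default 5).
#' @return Tibble with `bin_start_s`, `bin_mid_s`, `n`, `median`, `q1`,
#'   `q3`, `low_n`.
#' @export
summarize_perievent <- function(m, min_n = 5) {
  edges <- m$bin_edges_s
  n_bins <- ncol(m$values)
  out <- lapply(seq_len(n_bins), function(b) {
    v <- m$values[, b]
    v <- v[!is.na(v)]
    tibble::tibble(
      bin_start_s = edges[b],
      bin_mid_s = (edges[b] + edges[b + 1]) / 2,
      n = length(v),
      median = if (length(v)) median(v) else NA_real_,
      q1 = if (length(v)) unname(quantile(v, 0.25, type = 7)) else NA_real_,
      q3 = if (length(v)) unname(quantile(v, 0.75, type = 7)) else NA_real_,
      low_n = length(v) < min_n
    )
  })
  dplyr::bind_rows(out)
}

#' Paired pre/post window comparison at dominance onset
#'
#' For each contest whose recording fully contains both the pre-onset window
#' `[-w, 0)` and the post-onset window `[0, w)`, aggregates the behavior's
#' measure over each window and applies the two-sided exact Wilcoxon
#' signed-rank test ([signed_rank_test()]) to the paired differences
#' (post minus pre). Contests lacking a full window are dropped from this
#' test only. No correction across behaviors is applied; each behavior is
#' tested on its own, as on per-panel significance annotations.
#'
#' @inheritParams align_and_bin
#' @param window_min Window length in minutes (1 and 5 are the conventional
#'   choices).
#' @return List of class `paired_window_result`: `behavior`, `window_min`,
#'   `measure`, `n_pairs`, `statistic` (signed-rank W), `p_two_sided`,
#'   `direction` (`pre_greater`, `post_greater` or `none`), `stars`, and
#'   `insufficient_data`. With fewer than 2 contributing pairs an explicit
#'   insufficient-data result is returned rather than an error.
#' @export
paired_window_test <- function(events, timelines, behavior,
                               window_min = 5, measure = NULL) {
  check_behavior(behavior)
  measure <- check_measure(behavior, measure)
  if (inherits(timelines, "dominance_timeline")) timelines <- list(timelines)
  w <- window_min * 60
  ev <- events[events$behavior == behavior, , drop = FALSE]
  pre <- numeric(0); post <- numeric(0)
  for (tl in timelines) {
    if (tl$classification != "established") next
    if (tl$onset_s < w || tl$duration_s - tl$onset_s < w) next
    e <- ev[ev$contest_id == tl$contest_id, , drop = FALSE]
    rel_start <- e$start_s - tl$onset_s
    rel_end <- e$end_s - tl$onset_s
    if (measure == "count_per_min") {
      pre <- c(pre, sum(rel_start >= -w & rel_start < 0))
      post <- c(post, sum(rel_start >= 0 & rel_start < w))
    } else {
      pre <- c(pre, union_overlap(rel_start, rel_end, -w, 0) / w)
      post <- c(post, union_overlap(rel_start, rel_end, 0, w) / w)
    }
  }
  n_pairs <- length(pre)
  if (n_pairs < 2) {
    return(structure(
      list(behavior = behavior, window_min = window_min, measure = measure,
           n_pairs = n_pairs, statistic = NA_real_, p_two_sided = NA_real_,
           direction = "none", stars = NA_character_,
           insufficient_data = TRUE),
      class = "paired_window_result"))
  }
  sr <- signed_rank_test(post, pre)
  direction <- switch(sr$trend, greater = "post_greater",
                      less = "pre_greater", none = "none")
  structure(
    list(behavior = behavior, window_min = window_min, measure = measure,
         n_pairs = n_pairs, statistic = sr$statistic,
         p_two_sided = sr$p_value, direction = direction,
         stars = stars_from_p(sr$p_value), method = sr$method,
         correction = "none", insufficient_data = FALSE),
    class = "paired_window_result"
  )
}

#' @export
print.paired_window_result <- function(x, ...) {
  if (isTRUE(x$insufficient_data)) {
    cat(sprintf("<paired_window_result> %s, %g-min windows: insufficient data (n=%d)\n",
                x$behavior, x$window_min, x$n_pairs))
  } else {
    cat(sprintf(
      "<paired_window_result> %s, %g-min windows (%s): n=%d, W=%g, p=%.4g (%s), %s\n",
      x$behavior, x$window_min, x$measure, x$n_pairs, x$statistic,
      x$p_two_sided, x$stars, x$direction))
  }
  invisible(x)
}

#' Onset-aligned raster table
#'
#' Plot-ready export: every event of one behavior with its interval
#' expressed relative to each contest's dominance onset, one row per event,
#' contests ordered by onset latency.
#'
#' @inheritParams align_and_bin
#' @return Tibble `(contest_id, onset_s, fly, rel_start_s, rel_end_s)`.
#' @export
raster_table <- function(events, timelines, behavior) {
  check_behavior(behavior)
  if (inherits(timelines, "dominance_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    e <- events[events$behavior == behavior &
                  events$contest_id == tl$contest_id, , drop = FALSE]
    if (nrow(e) == 0 || is.null(tl$onset_s)) return(NULL)
    tibble::tibble(contest_id = tl$contest_id, onset_s = tl$onset_s,
                   fly = e$fly, rel_start_s = e$start_s - tl$onset_s,
                   rel_end_s = e$end_s - tl$onset_s)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, .data$onset_s, .data$contest_id, .data$rel_start_s)
}
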