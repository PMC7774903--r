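new_timeline <- function(contest_id, classification, onset_s,
                         dominant_at_onset, reversals, duration_s) {
  stopifnot(classification %in% c("established", "pre_established",
                                  "never_established"))
  if (nrow(reversals) > 0) {
    if (is.null(onset_s)) {
      abort("Reversals require an onset.", class = "flydom_timeline_error")
    }
    if (any(diff(c(onset_s, reversals$t_s)) <= 0)) {
      abort("Reversal times must be strictly increasing and after onset.",
            class = "flydom_timeline_error")
    }
    doms <- c(dominant_at_onset, reversals$new_dominant)
    if (any(doms[-1] == doms[-length(doms)])) {
      abort("Consecutive reversals must alternate dominant identity.",
            class = "flydom_timeline_error")
    }
  }
  structure(
    list(contest_id = contest_id, classification = classification,
         onset_s = onset_s, dominant_at_onset = dominant_at_onset,
         reversals = reversals, duration_s = duration_s),
    class = "dominance_timeline"
  )
}

#' @export
print.dominance_timeline <- function(x, ...) {
  cat(sprintf("<dominance_timeline> contest %s: %s", x$contest_id,
              x$classification))
  if (!is.null(x$onset_s)) {
    cat(sprintf("; onset %.2f s, dominant %s, %d reversal(s)",
                x$onset_s, x$dominant_at_onset, nrow(x$reversals)))
  }
  cat("\n")
  invisible(x)
}

#' Find pursue-to-climb diagnostic instances
#'
#' The diagnostic criterion for social dominance: one fly pursues the other
#' until the retreating fly leaves the floor by climbing the arena wall. An
#' instance exists when a climb by fly X starts during, or within
#' `link_max_s` after, a pursuit bout whose actor is the other fly Y and
#' whose target is X. The instance time is the climb start, and the pursuer
#' is classified as (the would-be) dominant. Candidate pairs in which the
#' pursuit actor equals the climber are rejected as self-pairs.
#'
#' @param pursuits Bout tibble of pursuit bouts (rows with other `kind`s are
#'   ignored; chases do not count as pursuits).
#' @param climbs Bout tibble of climb bouts.
#' @param params [detector_params()] (uses `link_max_s`).
#' @return Tibble `(time_s, pursuer, climber, pursuit_start_s,
#'   pursuit_end_s)` sorted by time; the attribute `n_self_rejected` counts
#'   rejected self-pairs.
#' @export
find_diagnostic_instances <- function(pursuits, climbs,
                                      params = detector_params()) {
  pursuits <- pursuits[pursuits$kind == "pursuit", , drop = FALSE]
  climbs <- climbs[climbs$kind == "climb", , drop = FALSE]
  empty <- tibble::tibble(time_s = numeric(0), pursuer = character(0),
                          climber = character(0),
                          pursuit_start_s = numeric(0),
                          pursuit_end_s = numeric(0))
  n_self <- 0L
  if (nrow(climbs) == 0 || nrow(pursuits) == 0) {
    return(structure(empty, n_self_rejected = n_self))
  }
  rows <- list()
  for (i in seq_len(nrow(climbs))) {
    x <- climbs$fly[i]
    c_start <- climbs$start_s[i]
    in_window <- pursuits$start_s <= c_start &
      c_start <= pursuits$end_s + params$link_max_s
    cand <- pursuits[in_window, , drop = FALSE]
    n_self <- n_self + sum(cand$fly == x)
    cand <- cand[cand$fly == other_fly(x) & cand$target_fly == x, ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    j <- which.min(cand$start_s)
    rows[[length(rows) + 1]] <- tibble::tibble(
      time_s = c_start, pursuer = cand$fly[j], climber = x,
      pursuit_start_s = cand$start_s[j], pursuit_end_s = cand$end_s[j]
    )
  }
  if (n_self > 0) {
    rlang::inform(sprintf("Rejected %d self-paired candidate instance(s).",
                          n_self))
  }
  if (length(rows) == 0) return(structure(empty, n_self_rejected = n_self))
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$time_s,
                        .data$pursuit_start_s)
  structure(out, n_self_rejected = n_self)
}

#' Build a dominance timeline from diagnostic instances
#'
#' The first diagnostic instance (or, with `k_confirm > 1`, the instance at
#' which some pursuer has accumulated `k_confirm` instances) sets the onset
#' of dominance, with the pursuer classified as dominant. Every later
#' instance whose pursuer is the current subordinate triggers a reversal at
#' its time; instances confirming the current dominant change nothing.
#' Contests with no instance are `never_established`. If the onset
#' instance's pursuit bout was already in progress at `observation_start_s`,
#' the hierarchy formed before observation and the contest is
#' `pre_established` (onset set to the observation start). Two instances at
#' the same timestamp with opposite roles are resolved in favor of the one
#' whose pursuit bout started earlier.
#'
#' @param instances Output of [find_diagnostic_instances()].
#' @param duration_s Contest duration in seconds.
#' @param contest_id Identifier stored on the timeline.
#' @param params [detector_params()] (uses `k_confirm`,
#'   `observation_start_s`).
#' @return A `dominance_timeline`: classification, `onset_s`,
#'   `dominant_at_onset`, and a tibble of reversals `(t_s, new_dominant)`.
#' @export
build_timeline <- function(instances, duration_s, contest_id = "contest",
                           params = detector_params()) {
  inst <- dplyr::arrange(tibble::as_tibble(instances), .data$time_s,
                         .data$pursuit_start_s)
  # degenerate same-timestamp opposite-role instances: keep earlier pursuit
  if (nrow(inst) > 1) {
    dup <- duplicated(inst$time_s)
    if (any(dup)) {
      rlang::inform(sprintf(
        "Dropped %d same-timestamp duplicate instance(s); kept the earlier pursuit.",
        sum(dup)))
      inst <- inst[!dup, , drop = FALSE]
    }
  }
  no_rev <- tibble::tibble(t_s = numeric(0), new_dominant = character(0))
  if (nrow(inst) == 0) {
    return(new_timeline(contest_id, "never_established", NULL, NULL,
                        no_rev, duration_s))
  }
  # onset: first pursuer to accumulate k_confirm instances
  onset_idx <- NA_integer_
  if (params$k_confirm <= 1) {
    onset_idx <- 1L
  } else {
    counts <- c(A = 0L, B = 0L)
    for (i in seq_len(nrow(inst))) {
      p <- inst$pursuer[i]
      counts[p] <- counts[p] + 1L
      if (counts[p] >= params$k_confirm) { onset_idx <- i; break }
    }
    if (is.na(onset_idx)) {
      return(new_timeline(contest_id, "never_established", NULL, NULL,
                          no_rev, duration_s))
    }
  }
  dominant <- inst$pursuer[onset_idx]
  pre_established <-
    inst$pursuit_start_s[onset_idx] <= params$observation_start_s
  onset <- if (pre_established) params$observation_start_s
           else inst$time_s[onset_idx]
  revs <- list()
  current <- dominant
  later <- inst[seq_len(nrow(inst)) > onset_idx, , drop = FALSE]
  for (i in seq_len(nrow(later))) {
    if (later$pursuer[i] != current) {
      current <- later$pursuer[i]
      revs[[length(revs) + 1]] <-
        tibble::tibble(t_s = later$time_s[i], new_dominant = current)
    }
  }
  rev_tbl <- if (length(revs) == 0) no_rev else dplyr::bind_rows(revs)
  new_timeline(contest_id,
               if (pre_established) "pre_established" else "established",
               onset, dominant, rev_tbl, duration_s)
}

#' Instantaneous dominance status
#'
#' Evaluates the timeline's step function at times `t`: `unestablished`
#' before onset, then `A_dominant` / `B_dominant`, switching at each
#' reversal.
#'
#' @param timeline A `dominance_timeline`.
#' @param t Numeric vector of times (s).
#' @return Character vector of statuses.
#' @export
dominance_status <- function(timeline, t) {
  out <- rep("unestablished", length(t))
  if (timeline$classification == "never_established" ||
      is.null(timeline$onset_s)) {
    return(out)
  }
  change_t <- c(timeline$onset_s, timeline$reversals$t_s)
  doms <- c(timeline$dominant_at_onset, timeline$reversals$new_dominant)
  idx <- findInterval(t, change_t)
  est <- idx > 0
  out[est] <- paste0(doms[idx[est]], "_dominant")
  out
}

#' Partition a contest into dominance phases
#'
#' Tiles `[0, duration_s)` into maximal segments of constant dominance
#' status derived from a timeline. Consecutive segments always differ in
#' status.
#'
#' @inheritParams dominance_status
#' @param duration_s Contest duration; defaults to the timeline's.
#' @return Tibble `(start_s, end_s, status)`.
#' @export
phase_partition <- function(timeline, duration_s = timeline$duration_s) {
  if (timeline$classification == "never_established") {
    return(tibble::tibble(start_s = 0, end_s = duration_s,
                          status = "unestablished"))
  }
  change_t <- c(timeline$onset_s, timeline$reversals$t_s)
  doms <- c(timeline$dominant_at_onset, timeline$reversals$new_dominant)
  starts <- c(0, change_t)
  ends <- c(change_t, duration_s)
  status <- c("unestablished", paste0(doms, "_dominant"))
  keep <- ends > starts
  tibble::tibble(start_s = starts[keep], end_s = ends[keep],
                 status = status[keep])
}

#' Apply the contest exclusion rules
#'
#' Contests in which the hierarchy formed before observation
#' (`pre_established`) or never formed (`never_established`) are moved to an
#' excluded set with machine-readable reasons; analyses downstream run on
#' the kept contests, all of which have a finite onset after the
#' observation start.
#'
#' @param timelines List of `dominance_timeline` objects.
#' @return List with `kept` (named list of timelines) and `excluded`
#'   (tibble `contest_id`, `classification`, `reason`).
#' @export
apply_exclusions <- function(timelines) {
  if (inherits(timelines, "dominance_timeline")) timelines <- list(timelines)
  cls <- vapply(timelines, function(tl) tl$classification, character(1))
  ids <- vapply(timelines, function(tl) tl$contest_id, character(1))
  keep <- cls == "established"
  reasons <- c(pre_established = "hierarchy formed prior to observation",
               never_established = "hierarchy never formed")
  kept <- timelines[keep]
  names(kept) <- ids[keep]
  list(
    kept = kept,
    excluded = tibble::tibble(
      contest_id = ids[!keep],
      classification = cls[!keep],
      reason = unname(reasons[cls[!keep]])
    )
  )
}

#' Timeline from an event table
#'
#' Convenience wrapper: extracts pursuit and climb bouts from an ethogram
#' event table (manual annotations or simulator truth) and applies
#' [find_diagnostic_instances()] and [build_timeline()].
#'
#' @param events `fly_events` for a single contest.
#' @param duration_s Contest duration (s).
#' @param contest_id Defaults to the table's (unique) contest id.
#' @param params [detector_params()].
#' @return A `dominance_timeline`.
#' @export
timeline_from_events <- function(events, duration_s, contest_id = NULL,
                                 params = detector_params()) {
  contest_id <- contest_id %||% unique(events$contest_id)
  if (length(contest_id) != 1) {
    abort("Events must belong to a single contest.",
          class = "flydom_validation_error")
  }
  bouts <- events_to_bouts(events[events$contest_id == contest_id, ])
  inst <- find_diagnostic_instances(bouts[bouts$kind == "pursuit", ],
                                    bouts[bouts$kind == "climb", ], params)
  build_timeline(inst, duration_s, contest_id, params)
}
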