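# ---- small generative helpers ------------------------------------------

# Piecewise-linear profile value, clamped to the end knots.
pl_value <- function(t, knots_t, knots_v) {
  if (length(knots_t) == 1) return(rep(knots_v, length(t)))
  t2 <- pmin(pmax(t, knots_t[1]), knots_t[length(knots_t)])
  stats::approx(knots_t, knots_v, xout = t2)$y
}

# Inhomogeneous Poisson times on [lo, hi] by thinning; rate in events/min
# given as a piecewise-linear profile over absolute time.
sample_nhpp <- function(knots_t, knots_v, lo, hi) {
  if (hi <= lo) return(numeric(0))
  grid <- sort(unique(c(lo, hi, knots_t[knots_t > lo & knots_t < hi])))
  rmax <- max(pl_value(grid, knots_t, knots_v))
  if (rmax <= 0) return(numeric(0))
  n <- rpois(1, (hi - lo) * rmax / 60)
  if (n == 0) return(numeric(0))
  ts <- sort(runif(n, lo, hi))
  keep <- runif(n) < pl_value(ts, knots_t, knots_v) / rmax
  ts[keep]
}

# State-behavior bouts targeting a piecewise-linear occupancy profile:
# bout starts follow an NHPP with rate occupancy / bout_mean, durations are
# exponential around bout_mean. Returns merged (union) intervals.
sample_state_bouts <- function(knots_t, knots_occ, bout_mean, lo, hi) {
  starts <- sample_nhpp(knots_t, 60 * knots_occ / bout_mean, lo, hi)
  if (length(starts) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  dur <- pmin(pmax(rexp(length(starts), 1 / bout_mean), 0.6), 3 * bout_mean)
  merge_intervals(starts, pmin(starts + dur, hi))
}

merge_intervals <- function(starts, ends) {
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    k <- length(out_s)
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

# Drop intervals that overlap any guard window or come within min_gap of an
# already-kept interval (greedy in start order).
keep_clear <- function(starts, ends, guard_s, guard_e, min_gap = 0) {
  keep_s <- numeric(0); keep_e <- numeric(0)
  o <- order(starts)
  for (i in o) {
    s <- starts[i]; e <- ends[i]
    if (length(guard_s) > 0 && any(s < guard_e & e > guard_s)) next
    if (length(keep_s) > 0 && s < max(keep_e) + min_gap) next
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
  }
  data.frame(start_s = keep_s, end_s = keep_e)
}

snap <- function(t, fps) round(t * fps) / fps

# ---- ground-truth generator --------------------------------------------

# Builds the contest's true dominance timeline, event streams and the
# motion script used by the trajectory synthesizer. Consumes RNG; callers
# wrap it in with_seed().
build_truth <- function(config, contest_id, forced = list()) {
  dur <- config$duration_s
  fps <- config$fps
  prof <- config$act_profiles

  classification <- forced$classification %||% {
    u <- runif(1)
    if (u < config$p_pre_established) "pre_established"
    else if (u < config$p_pre_established + config$p_never_established)
      "never_established"
    else "established"
  }
  dominant <- forced$dominant %||% sample(fly_ids(), 1)

  margin <- min(60, dur / 4)
  onset <- switch(classification,
    established = snap(min(max(rlnorm(1, log(config$onset_median_s),
                                      config$onset_shape), margin),
                           dur - margin), fps),
    pre_established = 0,
    never_established = NULL)

  # reversals (established or pre-established contests only)
  rev_times <- numeric(0)
  if (!is.null(onset) && runif(1) < config$p_reversal) {
    lo <- max(onset + 120, 120); hi <- dur - 60
    if (hi > lo) {
      n_rev <- 1 + rgeom(1, config$reversal_geom_p)
      cand <- sort(runif(n_rev, lo, hi))
      for (t in cand) {
        if (length(rev_times) == 0 || t >= max(rev_times) + 90) {
          rev_times <- c(rev_times, t)
        }
      }
      rev_times <- snap(rev_times, fps)
    }
  }
  dom_seq <- dominant
  for (i in seq_along(rev_times)) {
    dom_seq <- c(dom_seq, other_fly(dom_seq[length(dom_seq)]))
  }
  dom_at <- function(t) {
    if (is.null(onset)) return(NA_character_)
    dom_seq[findInterval(t, c(onset, rev_times))]
  }

  segments <- list()   # scripted pursuit/chase motion
  climbs <- list()     # scripted wall excursions
  add_terminal <- function(t_event, pursuer, climber, first = FALSE) {
    if (first && t_event == 0) {
      p_start <- 0; p_end <- 1.2; c_start <- 1.6
    } else {
      p_dur <- runif(1, config$pursuit_bout_s[1], config$pursuit_bout_s[2])
      gap <- runif(1, 0.15, 0.9 * config$climb_latency_s)
      p_start <- t_event - gap - p_dur; p_end <- t_event - gap
      c_start <- t_event
    }
    segments[[length(segments) + 1]] <<- data.frame(
      kind = "pursuit", actor = pursuer, target = climber,
      start_s = snap(p_start, fps), end_s = snap(p_end, fps),
      speed = config$pursuit_speed_mm_s, gap = config$pursuit_gap_mm,
      terminal = TRUE, dirsign = sample(c(-1, 1), 1))
    climbs[[length(climbs) + 1]] <<- data.frame(
      actor = climber, start_s = snap(c_start, fps),
      end_s = snap(min(c_start + config$climb_duration_s, dur - 1 / fps),
                   fps))
  }

  if (!is.null(onset)) {
    add_terminal(onset, dominant, other_fly(dominant),
                 first = classification == "pre_established")
    for (i in seq_along(rev_times)) {
      add_terminal(rev_times[i], dom_seq[i + 1], dom_seq[i])
    }
  }

  # short alternating pursuit bouts before establishment (or throughout
  # contests in which no hierarchy ever forms)
  alt_rate <- if (classification == "never_established") 1
              else config$prealt_rate_per_min
  alt_lo <- if (classification == "never_established") 60
            else if (!is.null(onset) && onset > 0) min(60, onset / 2)
            else NA
  alt_hi <- if (classification == "never_established") dur - 10
            else if (!is.null(onset) && onset > 0) onset - 12 else NA
  if (!is.na(alt_lo) && alt_hi > alt_lo) {
    starts <- sample_nhpp(c(0, 1), c(alt_rate, alt_rate), alt_lo, alt_hi)
    durs <- runif(length(starts), config$pursuit_bout_s[1],
                  config$pursuit_bout_s[2])
    kept <- keep_clear(starts, pmin(starts + durs, alt_hi),
                       guard_s = numeric(0), guard_e = numeric(0),
                       min_gap = 3)
    actor0 <- sample(fly_ids(), 1)
    for (i in seq_len(nrow(kept))) {
      a <- if (i %% 2 == 1) actor0 else other_fly(actor0)
      segments[[length(segments) + 1]] <- data.frame(
        kind = "pursuit", actor = a, target = other_fly(a),
        start_s = snap(kept$start_s[i], fps), end_s = snap(kept$end_s[i], fps),
        speed = config$pursuit_speed_mm_s, gap = config$pursuit_gap_mm,
        terminal = FALSE, dirsign = sample(c(-1, 1), 1))
    }
  }

  # guard windows around each establishment/reversal terminal sequence
  guard_s <- numeric(0); guard_e <- numeric(0)
  if (!is.null(onset)) {
    ev_t <- c(onset, rev_times)
    guard_s <- ev_t - 50
    guard_e <- ev_t + config$climb_duration_s + 2
  }

  # chases: long high-speed trailing bouts by the instantaneous dominant
  if (!is.null(onset) && !is.null(prof$chase)) {
    p <- prof$chase
    starts <- sample_nhpp(p$t_rel_s + onset, p$value, onset, dur - 1)
    durs <- runif(length(starts), p$bout_range_s[1], p$bout_range_s[2])
    kept <- keep_clear(starts, pmin(starts + durs, dur - 1),
                       guard_s, guard_e, min_gap = 3)
    for (i in seq_len(nrow(kept))) {
      a <- dom_at(kept$start_s[i])
      segments[[length(segments) + 1]] <- data.frame(
        kind = "chase", actor = a, target = other_fly(a),
        start_s = snap(kept$start_s[i], fps), end_s = snap(kept$end_s[i], fps),
        speed = config$chase_speed_mm_s, gap = config$pursuit_gap_mm,
        terminal = FALSE, dirsign = sample(c(-1, 1), 1))
    }
  }

  segments <- if (length(segments)) do.call(rbind, segments) else
    data.frame(kind = character(0), actor = character(0),
               target = character(0), start_s = numeric(0),
               end_s = numeric(0), speed = numeric(0), gap = numeric(0),
               terminal = logical(0), dirsign = numeric(0))
  climbs <- if (length(climbs)) do.call(rbind, climbs) else
    data.frame(actor = character(0), start_s = numeric(0),
               end_s = numeric(0))

  # lunges: point events, nearly absent before onset, ramping after, with
  # clusters in the half-minute preceding each reversal
  lunge_t <- numeric(0)
  if (!is.null(prof$lunge)) {
    p <- prof$lunge
    if (!is.null(onset)) {
      lunge_t <- sample_nhpp(p$t_rel_s + onset, p$value, 0, dur - 2)
      cl_rate <- p$reversal_cluster_rate_min %||% 0
      cl_win <- p$reversal_cluster_window_s %||% 30
      for (t_r in rev_times) {
        lunge_t <- c(lunge_t, sample_nhpp(c(0, 1), c(cl_rate, cl_rate),
                                          t_r - cl_win, t_r - 2))
      }
    } else {
      v0 <- p$value[1]
      lunge_t <- sample_nhpp(c(0, 1), c(v0, v0), 0, dur - 2)
    }
    if (isTRUE(forced$no_base_prelunge) && !is.null(onset)) {
      lunge_t <- lunge_t[lunge_t >= onset]
    }
  }
  # precocious pre-onset lunges (rematch design)
  prelunge_by <- character(0); prelunge_t <- numeric(0)
  if (!is.null(forced$prelunge_p) && !is.null(onset) && onset > 40) {
    for (id in fly_ids()) {
      if (runif(1) < forced$prelunge_p[[id]]) {
        k <- 1 + rpois(1, 1.2)
        prelunge_t <- c(prelunge_t, runif(k, 20, onset - 8))
        prelunge_by <- c(prelunge_by, rep(id, k))
      }
    }
  }
  all_lunge_t <- c(lunge_t, prelunge_t)
  all_lunge_by <- c(rep(NA_character_, length(lunge_t)), prelunge_by)
  o <- order(all_lunge_t)
  all_lunge_t <- all_lunge_t[o]; all_lunge_by <- all_lunge_by[o]
  # keep lunges clear of scripted motion and of each other
  seg_guard_s <- c(segments$start_s - 2, climbs$start_s - 2)
  seg_guard_e <- c(segments$end_s + 1, climbs$end_s + 1)
  keep_t <- numeric(0); keep_by <- character(0)
  for (i in seq_along(all_lunge_t)) {
    t <- all_lunge_t[i]
    if (length(seg_guard_s) > 0 && any(t > seg_guard_s & t < seg_guard_e))
      next
    if (length(keep_t) > 0 && t < max(keep_t) + 1.5) next
    keep_t <- c(keep_t, t); keep_by <- c(keep_by, all_lunge_by[i])
  }
  keep_t <- snap(keep_t, fps)
  # attribution: instantaneous dominant with prob lunge_dominant_fraction
  lunge_actor <- character(length(keep_t))
  for (i in seq_along(keep_t)) {
    if (!is.na(keep_by[i])) {
      lunge_actor[i] <- keep_by[i]
    } else if (!is.null(onset) && keep_t[i] >= onset) {
      d <- dom_at(keep_t[i])
      lunge_actor[i] <- if (runif(1) < config$lunge_dominant_fraction) d
                        else other_fly(d)
    } else {
      lunge_actor[i] <- sample(fly_ids(), 1)
    }
  }
  lunges <- data.frame(actor = lunge_actor,
                       target = if (length(lunge_actor))
                         other_fly(lunge_actor) else character(0),
                       t_s = keep_t)

  # wing flicks: one independent stream per fly
  wf <- list()
  if (!is.null(prof$wing_flick)) {
    p <- prof$wing_flick
    for (id in fly_ids()) {
      ts <- if (!is.null(onset)) {
        sample_nhpp(p$t_rel_s + onset, p$value, 0, dur - 1 / fps)
      } else {
        sample_nhpp(c(0, 1), rep(p$value[1], 2), 0, dur - 1 / fps)
      }
      if (length(ts)) wf[[id]] <- data.frame(fly = id, t_s = ts)
    }
  }
  wf <- if (length(wf)) do.call(rbind, wf) else
    data.frame(fly = character(0), t_s = numeric(0))

  # mutual state acts: fencing and boxing/tussling
  state_rows <- list()
  add_state <- function(behavior, iv) {
    if (nrow(iv) == 0) return()
    state_rows[[length(state_rows) + 1]] <<- data.frame(
      fly = "both", behavior = behavior, start_s = iv$start_s,
      end_s = iv$end_s)
  }
  if (!is.null(prof$fence)) {
    p <- prof$fence
    iv <- if (!is.null(onset)) {
      sample_state_bouts(p$t_rel_s + onset, p$value, p$bout_mean_s, 0, dur)
    } else {
      sample_state_bouts(c(0, 1), rep(p$value[1], 2), p$bout_mean_s, 0, dur)
    }
    add_state("fence", iv)
  }
  if (!is.null(prof$box_tussle)) {
    p <- prof$box_tussle
    if (!is.null(onset)) {
      iv <- sample_state_bouts(p$t_rel_s + onset, p$value, p$bout_mean_s,
                               0, dur)
      if (!is.null(p$reversal_t_rel_s)) {
        for (t_r in rev_times) {
          iv2 <- sample_state_bouts(p$reversal_t_rel_s + t_r,
                                    p$reversal_value, p$bout_mean_s,
                                    max(0, t_r - 90), t_r)
          iv <- merge_intervals(c(iv$start_s, iv2$start_s),
                                c(iv$end_s, iv2$end_s))
        }
      }
      add_state("box_tussle", iv)
    } else {
      iv <- sample_state_bouts(c(0, 1), rep(p$value[1], 2), p$bout_mean_s,
                               0, dur)
      add_state("box_tussle", iv)
    }
  }
  states <- if (length(state_rows)) do.call(rbind, state_rows) else
    data.frame(fly = character(0), behavior = character(0),
               start_s = numeric(0), end_s = numeric(0))

  # assemble the true event table
  ev <- dplyr::bind_rows(
    if (nrow(segments))
      tibble::tibble(fly = segments$actor, behavior = segments$kind,
                     start_s = segments$start_s, end_s = segments$end_s),
    if (nrow(climbs))
      tibble::tibble(fly = climbs$actor, behavior = "climb",
                     start_s = climbs$start_s, end_s = climbs$end_s),
    if (nrow(lunges))
      tibble::tibble(fly = lunges$actor, behavior = "lunge",
                     start_s = lunges$t_s, end_s = lunges$t_s),
    if (nrow(wf))
      tibble::tibble(fly = wf$fly, behavior = "wing_flick",
                     start_s = wf$t_s, end_s = wf$t_s),
    if (nrow(states))
      tibble::tibble(fly = states$fly, behavior = states$behavior,
                     start_s = states$start_s, end_s = states$end_s)
  )
  if (is.null(ev) || nrow(ev) == 0) {
    ev <- tibble::tibble(fly = character(0), behavior = character(0),
                         start_s = numeric(0), end_s = numeric(0))
  }
  ev$start_s <- pmax(ev$start_s, 0)
  ev$end_s <- pmin(ev$end_s, dur - 1e-9)
  cls <- behavior_class(if (nrow(ev)) ev$behavior else character(0))
  ev <- ev[(cls == "point" & ev$end_s >= ev$start_s) |
             (cls == "state" & ev$end_s > ev$start_s), , drop = FALSE]
  ev <- as_event_table(tibble::tibble(contest_id = contest_id, ev),
                       duration_s = dur)

  truth <- structure(
    list(classification = classification,
         dominant_id = if (is.null(onset)) NULL else dominant,
         onset_s = onset,
         reversal_times_s = rev_times,
         dominant_sequence = if (is.null(onset)) character(0) else dom_seq,
         prior_dominant_id = forced$prior_dominant_id %||% NULL,
         events = ev,
         params_used = config),
    class = "ground_truth")
  list(truth = truth,
       script = list(segments = segments, climbs = climbs, lunges = lunges))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s", x$classification))
  if (!is.null(x$onset_s)) {
    cat(sprintf("; dominant %s at %.1f s, %d reversal(s)", x$dominant_id,
                x$onset_s, length(x$reversal_times_s)))
  }
  cat(sprintf("; %d true events\n", nrow(x$events)))
  invisible(x)
}

#' @export
print.simulated_contest <- function(x, ...) {
  cat(sprintf("<simulated_contest> %s (%s)%s\n", x$contest_id,
              x$truth$classification,
              if (is.null(x$trajectory)) ", events only" else ""))
  invisible(x)
}
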