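#' Per-frame kinematic features
#'
#' Computes, for every frame and fly: speed (mm/s, central differences with
#' one-sided differences at the ends), radial position as a fraction of the
#' arena radius, inter-fly distance (mm), bearing error (absolute angle
#' between the fly's heading and the direction to its opponent, in
#' \[0, 180\] degrees) and wall occupancy. Positions are carried along so
#' that displacement-based detectors can reuse the table.
#'
#' @param traj A `fly_trajectory` from [as_trajectory()] or the simulator.
#' @param geometry [arena_geometry()]; defaults to the trajectory's own.
#' @return A tibble of class `fly_features` with attributes `fps` and
#'   `geometry`.
#' @export
compute_features <- function(traj, geometry = NULL) {
  geometry <- geometry %||% attr(traj, "geometry") %||% arena_geometry()
  fps <- attr(traj, "fps") %||% 30
  df <- tibble::as_tibble(traj)
  wide <- lapply(fly_ids(), function(id) {
    d <- df[df$fly == id, ]
    d[order(d$frame), ]
  })
  names(wide) <- fly_ids()
  n <- nrow(wide$A)
  per_fly <- lapply(fly_ids(), function(id) {
    d <- wide[[id]]
    o <- wide[[other_fly(id)]]
    x <- d$x_mm; y <- d$y_mm
    if (n >= 3) {
      vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
      vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
    } else if (n == 2) {
      vx <- c(x[2] - x[1], x[2] - x[1]); vy <- c(y[2] - y[1], y[2] - y[1])
    } else {
      vx <- 0; vy <- 0
    }
    dist <- sqrt((o$x_mm - x)^2 + (o$y_mm - y)^2)
    dir_to_opp <- atan2(o$y_mm - y, o$x_mm - x) * 180 / pi
    bearing <- abs(((d$heading_deg - dir_to_opp + 180) %% 360) - 180)
    tibble::tibble(
      frame = d$frame,
      t_s = d$t_s,
      fly = id,
      x_mm = x,
      y_mm = y,
      speed_mm_s = sqrt(vx^2 + vy^2) * fps,
      radial_fraction = sqrt(x^2 + y^2) / geometry$radius_mm,
      inter_fly_distance_mm = dist,
      bearing_error_deg = bearing,
      on_wall = d$on_wall
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(per_fly), .data$frame, .data$fly)
  structure(out, class = c("fly_features", class(tibble::tibble())),
            fps = fps, geometry = geometry)
}

# Runs of TRUE in a logical vector as inclusive [start, end] index pairs.
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_i = starts[keep], end_i = ends[keep])
}

merge_runs <- function(runs, gap_frames) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, ]
  for (i in seq(2, nrow(runs))) {
    if (runs$start_i[i] - out$end_i[nrow(out)] - 1 <= gap_frames) {
      out$end_i[nrow(out)] <- runs$end_i[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

empty_bouts <- function() {
  tibble::tibble(fly = character(0), kind = character(0),
                 start_s = numeric(0), end_s = numeric(0),
                 mean_speed_mm_s = numeric(0), target_fly = character(0))
}

#' Detect pursuit bouts
#'
#' A pursuit bout is a maximal run of frames on which the actor is close to
#' its opponent (`pursuit_d_max_mm`), moving (`pursuit_v_min_mm_s`), oriented
#' toward it (`pursuit_theta_max_deg`) and not on the wall. The frame mask is
#' computed first, qualifying runs separated by gaps up to
#' `pursuit_gap_max_s` are merged, and runs shorter than `pursuit_t_min_s`
#' are then discarded — in that fixed order. Long high-speed bouts are still
#' labeled `pursuit` here; re-labeling as chase is done by [detect_chase()].
#'
#' @param features A `fly_features` table from [compute_features()].
#' @param params [detector_params()].
#' @return Bout tibble with columns `fly`, `kind`, `start_s`, `end_s`
#'   (half-open interval), `mean_speed_mm_s`, `target_fly`.
#' @export
detect_pursuit <- function(features, params = detector_params()) {
  fps <- attr(features, "fps") %||% 30
  gap_frames <- floor(params$pursuit_gap_max_s * fps)
  min_frames <- ceiling(params$pursuit_t_min_s * fps)
  out <- lapply(fly_ids(), function(id) {
    d <- features[features$fly == id, ]
    d <- d[order(d$frame), ]
    mask <- d$inter_fly_distance_mm <= params$pursuit_d_max_mm &
      d$speed_mm_s >= params$pursuit_v_min_mm_s &
      d$bearing_error_deg <= params$pursuit_theta_max_deg &
      !d$on_wall
    runs <- merge_runs(mask_runs(mask), gap_frames)
    runs <- runs[runs$end_i - runs$start_i + 1 >= min_frames, , drop = FALSE]
    if (nrow(runs) == 0) return(empty_bouts())
    tibble::tibble(
      fly = id, kind = "pursuit",
      start_s = d$t_s[runs$start_i],
      end_s = d$t_s[runs$end_i] + 1 / fps,
      mean_speed_mm_s = vapply(seq_len(nrow(runs)), function(i)
        mean(d$speed_mm_s[runs$start_i[i]:runs$end_i[i]]), numeric(1)),
      target_fly = other_fly(id)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start_s, .data$fly)
}

#' Re-label long, high-speed pursuit bouts as chases
#'
#' Chasing is a long, high-speed trailing behavior, distinct from the
#' shorter pursuits. Bouts of duration at least `chase_min_s` with mean
#' speed at least `chase_v_min_mm_s` are re-labeled `chase`; all other bouts
#' keep the label `pursuit`. The partition is exhaustive and exclusive.
#'
#' @param pursuit_bouts Output of [detect_pursuit()].
#' @inheritParams detect_pursuit
#' @return The same bout tibble with `kind` set to `pursuit` or `chase`.
#' @export
detect_chase <- function(pursuit_bouts, params = detector_params()) {
  if (nrow(pursuit_bouts) == 0) return(pursuit_bouts)
  dur <- pursuit_bouts$end_s - pursuit_bouts$start_s
  is_chase <- dur >= params$chase_min_s &
    pursuit_bouts$mean_speed_mm_s >= params$chase_v_min_mm_s
  pursuit_bouts$kind <- ifelse(is_chase, "chase", "pursuit")
  pursuit_bouts
}

#' Detect wall-climb bouts
#'
#' A climb is a maximal run of wall occupancy (`on_wall`) lasting at least
#' `climb_min_s`. Wall occupancy proxies a fly leaving the floor, since
#' top-down tracking has no height information.
#'
#' @inheritParams detect_pursuit
#' @return Bout tibble (`kind = "climb"`, `target_fly = NA`).
#' @export
detect_climb <- function(features, params = detector_params()) {
  fps <- attr(features, "fps") %||% 30
  min_frames <- ceiling(params$climb_min_s * fps)
  out <- lapply(fly_ids(), function(id) {
    d <- features[features$fly == id, ]
    d <- d[order(d$frame), ]
    runs <- mask_runs(d$on_wall)
    runs <- runs[runs$end_i - runs$start_i + 1 >= min_frames, , drop = FALSE]
    if (nrow(runs) == 0) return(empty_bouts())
    tibble::tibble(
      fly = id, kind = "climb",
      start_s = d$t_s[runs$start_i],
      end_s = d$t_s[runs$end_i] + 1 / fps,
      mean_speed_mm_s = vapply(seq_len(nrow(runs)), function(i)
        mean(d$speed_mm_s[runs$start_i[i]:runs$end_i[i]]), numeric(1)),
      target_fly = NA_character_
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start_s, .data$fly)
}

#' Heuristic lunge detector
#'
#' Flags a point event at frames where the actor's net displacement over
#' `lunge_window_s` reaches `lunge_disp_min_mm`, the opponent is within
#' `lunge_d_max_mm` at the window start, and the actor is oriented toward
#' the opponent (`lunge_theta_max_deg`). Detections closer than
#' `lunge_refractory_s` are merged into the first.
#'
#' @inheritParams detect_pursuit
#' @return Bout tibble of point events (`start_s == end_s`, `kind =
#'   "lunge"`).
#' @export
detect_lunge <- function(features, params = detector_params()) {
  fps <- attr(features, "fps") %||% 30
  w <- max(1L, as.integer(round(params$lunge_window_s * fps)))
  out <- lapply(fly_ids(), function(id) {
    d <- features[features$fly == id, ]
    d <- d[order(d$frame), ]
    n <- nrow(d)
    if (n <= w) return(empty_bouts())
    i <- seq_len(n - w)
    disp <- sqrt((d$x_mm[i + w] - d$x_mm[i])^2 +
                   (d$y_mm[i + w] - d$y_mm[i])^2)
    hit <- disp >= params$lunge_disp_min_mm &
      d$inter_fly_distance_mm[i] <= params$lunge_d_max_mm &
      d$bearing_error_deg[i] <= params$lunge_theta_max_deg
    times <- d$t_s[i][hit]
    if (length(times) == 0) return(empty_bouts())
    kept <- times[1]
    for (t in times[-1]) {
      if (t - kept[length(kept)] >= params$lunge_refractory_s) {
        kept <- c(kept, t)
      }
    }
    tibble::tibble(fly = id, kind = "lunge", start_s = kept, end_s = kept,
                   mean_speed_mm_s = NA_real_, target_fly = other_fly(id))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$start_s, .data$fly)
}

#' Run all kinematic detectors
#'
#' Convenience wrapper: pursuit detection, chase re-labeling, climb and
#' lunge detection on one feature table.
#'
#' @inheritParams detect_pursuit
#' @return Combined bout tibble sorted by start time.
#' @export
detect_bouts <- function(features, params = detector_params()) {
  trailing <- detect_chase(detect_pursuit(features, params), params)
  out <- dplyr::bind_rows(trailing,
                          detect_climb(features, params),
                          detect_lunge(features, params))
  dplyr::arrange(out, .data$start_s, .data$fly)
}

#' Convert bouts to / from ethogram event rows
#'
#' Detected bouts are exported as standard event-table rows so that the
#' dominance and peri-event stages accept manual annotations and detector
#' output interchangeably.
#'
#' @param bouts Bout tibble from the detectors.
#' @param contest_id Contest identifier for the event rows.
#' @return [bouts_to_events()] returns a `fly_events` table;
#'   [events_to_bouts()] the inverse for behaviors that are bouts
#'   (pursuit, chase, climb, lunge).
#' @export
bouts_to_events <- function(bouts, contest_id) {
  as_event_table(tibble::tibble(
    contest_id = contest_id,
    fly = bouts$fly,
    behavior = bouts$kind,
    start_s = bouts$start_s,
    end_s = bouts$end_s
  ))
}

#' @param events A `fly_events` table.
#' @rdname bouts_to_events
#' @export
events_to_bouts <- function(events) {
  keep <- events$behavior %in% c("pursuit", "chase", "climb", "lunge")
  e <- events[keep, ]
  if (any(e$fly == "both")) {
    abort("Bout-like behaviors must have a single actor (A or B).",
          class = "flydom_validation_error")
  }
  tibble::tibble(
    fly = e$fly, kind = e$behavior, start_s = e$start_s, end_s = e$end_s,
    mean_speed_mm_s = NA_real_,
    target_fly = ifelse(e$behavior == "climb", NA_character_,
                        other_fly(e$fly))
  )
}
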