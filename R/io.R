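#' Validate and construct a trajectory table
#'
#' A trajectory holds the per-frame kinematic state of both flies: 0-based
#' `frame`, time `t_s = frame / fps`, fly label (`"A"` or `"B"`),
#' arena-centered coordinates in mm, heading in degrees in \[0, 360), and a
#' logical `on_wall` flag. When `on_wall` is absent it is filled from the
#' radial wall threshold in `geometry`.
#'
#' @param df Data frame with columns `frame`, `fly`, `x_mm`, `y_mm`,
#'   `heading_deg` and optionally `on_wall`.
#' @param fps Frames per second (default 30).
#' @param geometry [arena_geometry()].
#' @param tolerance_mm Coordinates may exceed the arena radius by up to this
#'   much (tracking jitter) before validation fails.
#' @return A tibble of class `fly_trajectory` with attributes `fps` and
#'   `geometry`, ordered by frame then fly.
#' @export
as_trajectory <- function(df, fps = 30, geometry = arena_geometry(),
                          tolerance_mm = 0.5) {
  check_scalar_number(fps, "fps", min = 0, strict_min = TRUE)
  required <- c("frame", "fly", "x_mm", "y_mm", "heading_deg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Trajectory is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "flydom_validation_error")
  }
  df <- tibble::as_tibble(df)
  bad_fly <- which(!df$fly %in% fly_ids())
  if (length(bad_fly) > 0) {
    abort(sprintf("Invalid fly label at row(s) %s (must be A or B).",
                  paste(head(bad_fly, 5), collapse = ", ")),
          class = "flydom_validation_error")
  }
  if (any(df$frame != floor(df$frame)) || any(df$frame < 0)) {
    abort("`frame` must contain non-negative integers.",
          class = "flydom_validation_error")
  }
  frames <- sort(unique(df$frame))
  if (length(frames) > 1 && any(diff(frames) != 1)) {
    abort("Frames must be contiguous (no gaps).",
          class = "flydom_validation_error")
  }
  for (id in fly_ids()) {
    f <- df$frame[df$fly == id]
    if (anyDuplicated(f)) {
      abort(sprintf("fly %s appears more than once in a frame.", id),
            class = "flydom_validation_error")
    }
    absent <- setdiff(frames, f)
    if (length(absent) > 0) {
      abort(sprintf("fly %s absent from frame(s) %s.", id,
                    paste(head(absent, 5), collapse = ", ")),
            class = "flydom_validation_error")
    }
  }
  r <- sqrt(df$x_mm^2 + df$y_mm^2)
  out_of_arena <- which(r > geometry$radius_mm + tolerance_mm)
  if (length(out_of_arena) > 0) {
    abort(sprintf("Coordinates beyond the arena at row(s) %s.",
                  paste(head(out_of_arena, 5), collapse = ", ")),
          class = "flydom_validation_error")
  }
  df$heading_deg <- df$heading_deg %% 360
  if (!"on_wall" %in% names(df)) {
    df$on_wall <- r / geometry$radius_mm >= geometry$wall_fraction
  }
  df$on_wall <- as.logical(df$on_wall)
  df$t_s <- df$frame / fps
  df <- dplyr::arrange(
    df[, c("frame", "t_s", "fly", "x_mm", "y_mm", "heading_deg", "on_wall")],
    .data$frame, .data$fly
  )
  structure(df, class = c("fly_trajectory", class(tibble::tibble())),
            fps = fps, geometry = geometry)
}

#' Read / write trajectory CSV
#'
#' The on-disk format is a plain CSV with header
#' `frame,fly,x_mm,y_mm,heading_deg[,on_wall]`. Times are not stored; they
#' are reconstructed from `fps`. An `on_wall` column, when present, is
#' preserved verbatim and overrides the radial wall proxy.
#'
#' @param path File path.
#' @inheritParams as_trajectory
#' @return [read_trajectory()] returns a validated `fly_trajectory`;
#'   [write_trajectory()] invisibly returns `path`.
#' @export
read_trajectory <- function(path, fps = 30, geometry = arena_geometry(),
                            tolerance_mm = 0.5) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trajectory(df, fps = fps, geometry = geometry,
                tolerance_mm = tolerance_mm)
}

#' @param traj A `fly_trajectory`.
#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("frame", "fly", "x_mm", "y_mm", "heading_deg", "on_wall")
  readr::write_csv(tibble::as_tibble(traj)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Validate and construct an ethogram event table
#'
#' Event tables carry typed behavioral events: one row per act with the
#' contest it belongs to, the acting fly (`"A"`, `"B"`, or `"both"` for
#' mutual acts such as fencing), a behavior label from
#' [behavior_vocabulary()], and a half-open interval `[start_s, end_s)`.
#' State-like behaviors must have positive duration; point-like behaviors
#' (lunge, wing flick) may have `start_s == end_s`.
#'
#' @param df Data frame with columns `contest_id`, `fly`, `behavior`,
#'   `start_s`, `end_s`.
#' @param duration_s Optional contest duration; events must end at or before
#'   it when supplied.
#' @return A tibble of class `fly_events` sorted by contest and start time.
#' @export
as_event_table <- function(df, duration_s = NULL) {
  required <- c("contest_id", "fly", "behavior", "start_s", "end_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Event table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "flydom_validation_error")
  }
  df <- tibble::as_tibble(df)[required]
  df$contest_id <- as.character(df$contest_id)
  bad_fly <- which(!df$fly %in% c(fly_ids(), "both"))
  if (length(bad_fly) > 0) {
    abort(sprintf("Invalid fly label at row(s) %s (must be A, B or both).",
                  paste(head(bad_fly, 5), collapse = ", ")),
          class = "flydom_validation_error")
  }
  check_behavior(df$behavior)
  neg <- which(df$start_s < 0)
  if (length(neg) > 0) {
    abort(sprintf("Negative start time at row(s) %s.",
                  paste(head(neg, 5), collapse = ", ")),
          class = "flydom_validation_error")
  }
  cls <- behavior_class(df$behavior)
  bad_int <- which((cls == "state" & df$start_s >= df$end_s) |
                     (cls == "point" & df$start_s > df$end_s))
  if (length(bad_int) > 0) {
    abort(sprintf(
      "start_s must precede end_s (state-like acts) at row(s) %s.",
      paste(head(bad_int, 5), collapse = ", ")),
      class = "flydom_validation_error")
  }
  if (!is.null(duration_s)) {
    over <- which(df$end_s > duration_s | df$start_s >= duration_s)
    if (length(over) > 0) {
      abort(sprintf("Event outside [0, duration_s) at row(s) %s.",
                    paste(head(over, 5), collapse = ", ")),
            class = "flydom_validation_error")
    }
  }
  df <- dplyr::arrange(df, .data$contest_id, .data$start_s, .data$behavior)
  structure(df, class = c("fly_events", class(tibble::tibble())))
}

#' Read / write ethogram event CSV
#'
#' Plain CSV with header `contest_id,fly,behavior,start_s,end_s`. Unknown
#' behavior labels are rejected with a message listing the allowed
#' vocabulary. Accepted files round-trip losslessly.
#'
#' @param path File path.
#' @inheritParams as_event_table
#' @return [read_events()] returns a validated `fly_events` tibble;
#'   [write_events()] invisibly returns `path`.
#' @export
read_events <- function(path, duration_s = NULL) {
  df <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      contest_id = readr::col_character(),
      fly = readr::col_character(),
      behavior = readr::col_character(),
      start_s = readr::col_double(),
      end_s = readr::col_double()
    )
  )
  as_event_table(df, duration_s = duration_s)
}

#' @param events A `fly_events` table.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  cols <- c("contest_id", "fly", "behavior", "start_s", "end_s")
  readr::write_csv(tibble::as_tibble(events)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write dominance timelines as JSON
#'
#' Serializes a list of [build_timeline()] results to a JSON array of
#' objects `{contest_id, classification, onset_s, dominant_at_onset,
#' duration_s, reversals: [{t_s, new_dominant}]}`.
#'
#' @param timelines List of `dominance_timeline` objects.
#' @param path File path.
#' @return [read_timelines()] returns a named list of `dominance_timeline`
#'   objects; [write_timelines()] invisibly returns `path`.
#' @export
write_timelines <- function(timelines, path) {
  if (inherits(timelines, "dominance_timeline")) timelines <- list(timelines)
  payload <- lapply(unname(timelines), function(tl) {
    list(
      contest_id = tl$contest_id,
      classification = tl$classification,
      onset_s = tl$onset_s,
      dominant_at_onset = tl$dominant_at_onset,
      duration_s = tl$duration_s,
      reversals = unname(Map(function(t, d) list(t_s = t, new_dominant = d),
                             tl$reversals$t_s, tl$reversals$new_dominant))
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_timelines
#' @export
read_timelines <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(x) {
    rev_tbl <- if (length(x$reversals) == 0) {
      tibble::tibble(t_s = numeric(0), new_dominant = character(0))
    } else {
      tibble::tibble(
        t_s = vapply(x$reversals, function(r) as.numeric(r$t_s), numeric(1)),
        new_dominant = vapply(x$reversals, function(r) r$new_dominant,
                              character(1))
      )
    }
    new_timeline(
      contest_id = x$contest_id,
      classification = x$classification,
      onset_s = if (is.null(x$onset_s)) NULL else as.numeric(x$onset_s),
      dominant_at_onset = x$dominant_at_onset,
      reversals = rev_tbl,
      duration_s = as.numeric(x$duration_s)
    )
  })
  names(out) <- vapply(out, function(tl) tl$contest_id, character(1))
  out
}
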