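# Hand-built fixtures and small shared simulations.

# A feature table constructed directly (bypassing trajectories), for
# detector unit tests. Vectors are recycled to the frame count.
make_features <- function(n, fps = 30,
                          dist = 10, speed_a = 0, speed_b = 0,
                          bearing_a = 180, bearing_b = 180,
                          on_wall_a = FALSE, on_wall_b = FALSE,
                          xa = 0, ya = 0, xb = NULL, yb = 0) {
  if (is.null(xb)) xb <- xa + dist
  f <- 0:(n - 1)
  df <- dplyr::bind_rows(
    tibble::tibble(frame = f, t_s = f / fps, fly = "A",
                   x_mm = rep_len(xa, n), y_mm = rep_len(ya, n),
                   speed_mm_s = rep_len(speed_a, n),
                   radial_fraction = sqrt(rep_len(xa, n)^2 +
                                            rep_len(ya, n)^2) / 8,
                   inter_fly_distance_mm = rep_len(dist, n),
                   bearing_error_deg = rep_len(bearing_a, n),
                   on_wall = rep_len(on_wall_a, n)),
    tibble::tibble(frame = f, t_s = f / fps, fly = "B",
                   x_mm = rep_len(xb, n), y_mm = rep_len(yb, n),
                   speed_mm_s = rep_len(speed_b, n),
                   radial_fraction = sqrt(rep_len(xb, n)^2 +
                                            rep_len(yb, n)^2) / 8,
                   inter_fly_distance_mm = rep_len(dist, n),
                   bearing_error_deg = rep_len(bearing_b, n),
                   on_wall = rep_len(on_wall_b, n))
  )
  df <- dplyr::arrange(df, frame, fly)
  structure(df, class = c("fly_features", class(tibble::tibble())),
            fps = fps, geometry = flydom::arena_geometry())
}

make_bout <- function(fly, kind, start_s, end_s, speed = 8) {
  tibble::tibble(fly = fly, kind = kind, start_s = start_s, end_s = end_s,
                 mean_speed_mm_s = speed,
                 target_fly = ifelse(kind == "climb", NA_character_,
                                     ifelse(fly == "A", "B", "A")))
}

make_instances <- function(time_s, pursuer,
                           pursuit_start_s = time_s - 3,
                           pursuit_end_s = time_s - 0.5) {
  tibble::tibble(time_s = time_s, pursuer = pursuer,
                 climber = ifelse(pursuer == "A", "B", "A"),
                 pursuit_start_s = pursuit_start_s,
                 pursuit_end_s = pursuit_end_s)
}

# timeline with given onset/reversals, built through the public API
make_timeline <- function(onset, pursuers, duration_s = 1200,
                          contest_id = "t1") {
  inst <- make_instances(c(onset, attr(pursuers, "rev_t")),
                         pursuers)
  flydom::build_timeline(inst, duration_s, contest_id)
}

simple_timeline <- function(onset, duration_s = 1200, contest_id = "t1",
                            dominant = "A") {
  flydom::build_timeline(make_instances(onset, dominant), duration_s,
                         contest_id)
}

# cached small cohorts shared across tests (events only, fast)
.fixture_env <- new.env(parent = emptyenv())

cached_truth_cohort <- function(n, key = paste0("default", n), ...) {
  if (is.null(.fixture_env[[key]])) {
    cfg <- flydom::sim_config(...)
    .fixture_env[[key]] <- flydom::simulate_cohort(cfg, n,
                                                   trajectory = FALSE)
  }
  .fixture_env[[key]]
}
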