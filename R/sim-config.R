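#' Default act-rate profiles for the contest simulator
#'
#' Each behavior has a piecewise-linear rate profile in time relative to
#' dominance onset (`t_rel_s` knots, values interpolated linearly and held
#' constant beyond the end knots). Point-like acts use events per minute;
#' state-like acts use the target fraction of time occupied, realized as
#' bouts of exponential duration around `bout_mean_s`. `actor` is `"both"`
#' (mutual act, one shared stream), `"each"` (independent stream per fly),
#' or `"dominant"` (attributed to the instantaneous dominant, for lunges
#' subject to `lunge_dominant_fraction`).
#'
#' The default shapes encode the reproducible contest structure: fencing
#' high from the start of the contest until onset and sporadic after;
#' boxing/tussling appearing late, peaking in the final pre-onset minute and
#' collapsing at onset (with a transient recurrence before each reversal);
#' wing flicks stepping up at onset; lunges nearly absent before onset and
#' ramping up after; chases absent before onset and emerging a couple of
#' minutes after establishment.
#'
#' @return Named list of profile specifications.
#' @export
default_act_profiles <- function() {
  list(
    fence = list(type = "state", actor = "both",
                 t_rel_s = c(-1, 0), value = c(0.15, 0.02),
                 bout_mean_s = 3),
    box_tussle = list(type = "state", actor = "both",
                      t_rel_s = c(-180, -60, 0, 0.5),
                      value = c(0, 0.18, 0.30, 0),
                      bout_mean_s = 2,
                      reversal_t_rel_s = c(-60, -2),
                      reversal_value = c(0, 0.15)),
    wing_flick = list(type = "point", actor = "each",
                      t_rel_s = c(-1, 0), value = c(1, 4)),
    lunge = list(type = "point", actor = "dominant",
                 t_rel_s = c(-1, 0, 300), value = c(0.02, 0.2, 6),
                 reversal_cluster_rate_min = 4,
                 reversal_cluster_window_s = 30),
    chase = list(type = "state", actor = "dominant",
                 t_rel_s = c(0, 120, 300), value = c(0, 0, 1.2),
                 bout_range_s = c(6, 12))
  )
}

#' Phase-independent (null) act-rate profiles
#'
#' Constant rates with no relation to dominance onset, for calibration
#' experiments (e.g. the type-I error rate of the paired pre/post tests).
#'
#' @return Named list of profile specifications, as
#'   [default_act_profiles()].
#' @export
null_act_profiles <- function() {
  list(
    fence = list(type = "state", actor = "both",
                 t_rel_s = c(0, 1), value = c(0.08, 0.08),
                 bout_mean_s = 3),
    box_tussle = list(type = "state", actor = "both",
                      t_rel_s = c(0, 1), value = c(0.05, 0.05),
                      bout_mean_s = 2),
    wing_flick = list(type = "point", actor = "each",
                      t_rel_s = c(0, 1), value = c(2, 2)),
    lunge = list(type = "point", actor = "dominant",
                 t_rel_s = c(0, 1), value = c(1, 1)),
    chase = list(type = "state", actor = "dominant",
                 t_rel_s = c(0, 1), value = c(0.3, 0.3),
                 bout_range_s = c(6, 12))
  )
}

#' Contest simulator configuration
#'
#' Parameters of the agent-based two-fly contest generator. Defaults encode
#' the standard assay conditions: 20-min contests recorded at 30 frames per
#' second in a 16-mm diameter enclosed circular arena, with one in five
#' contests including at least one reversal in dominance after the initial
#' establishment. Onset latency is log-normal (strictly positive and
#' right-skewed, as observed latencies are); its median and shape are
#' configuration, not empirical claims — no quantitative per-act rates are
#' published for this assay, so all magnitudes here are tunable.
#'
#' @param duration_s Contest duration, seconds (default 1200).
#' @param fps Frames per second (default 30).
#' @param arena_radius_mm Arena radius, mm (default 8).
#' @param onset_median_s Median dominance-onset latency, s (default 300).
#' @param onset_shape Log-normal shape (sdlog) of onset latency.
#' @param p_pre_established Probability a contest's hierarchy formed before
#'   observation began.
#' @param p_never_established Probability a hierarchy never forms.
#' @param p_reversal Probability that an established contest includes at
#'   least one reversal (default 0.2, i.e. one in five contests).
#' @param reversal_geom_p Geometric success parameter for the number of
#'   reversals beyond the first.
#' @param act_profiles Per-behavior rate profiles; see
#'   [default_act_profiles()].
#' @param pursuit_speed_mm_s Speed of scripted pursuit bouts (mm/s).
#' @param pursuit_gap_mm Trigger/following distance between pursuer and
#'   pursued (mm); must not exceed the arena diameter.
#' @param pursuit_bout_s Length-2 range (s) of scripted pursuit bout
#'   durations.
#' @param prealt_rate_per_min Rate of the short, alternating pursuit bouts
#'   that precede establishment (bouts/min).
#' @param climb_latency_s Maximum delay from the end of the culminating
#'   pursuit to the subordinate's wall excursion (s).
#' @param climb_duration_s Duration of scripted wall excursions (s).
#' @param chase_speed_mm_s Speed of scripted chases (mm/s); chases are the
#'   long, high-speed trailing bouts distinct from pursuits.
#' @param lunge_dominant_fraction Probability that a post-onset lunge is
#'   executed by the instantaneous dominant (default 0.9).
#' @param walk_speed_mm_s Mean speed of the baseline correlated random walk
#'   (mm/s).
#' @param turn_sd_deg Per-frame heading noise of the random walk (degrees).
#' @param seed Integer master seed; per-contest seeds are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 1200,
                       fps = 30,
                       arena_radius_mm = 8,
                       onset_median_s = 300,
                       onset_shape = 0.5,
                       p_pre_established = 0.12,
                       p_never_established = 0.06,
                       p_reversal = 0.2,
                       reversal_geom_p = 0.6,
                       act_profiles = default_act_profiles(),
                       pursuit_speed_mm_s = 8,
                       pursuit_gap_mm = 2.5,
                       pursuit_bout_s = c(2, 3),
                       prealt_rate_per_min = 2,
                       climb_latency_s = 1,
                       climb_duration_s = 2,
                       chase_speed_mm_s = 12,
                       lunge_dominant_fraction = 0.9,
                       walk_speed_mm_s = 4,
                       turn_sd_deg = 20,
                       seed = 1) {
  check_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar_number(fps, "fps", min = 0, strict_min = TRUE)
  check_scalar_number(arena_radius_mm, "arena_radius_mm", min = 0,
                      strict_min = TRUE)
  for (nm in c("p_pre_established", "p_never_established", "p_reversal",
               "reversal_geom_p", "lunge_dominant_fraction")) {
    check_scalar_number(get(nm), nm, min = 0, max = 1)
  }
  if (p_pre_established + p_never_established > 1) {
    abort("p_pre_established + p_never_established must not exceed 1.",
          class = "flydom_config_error")
  }
  if (pursuit_gap_mm > 2 * arena_radius_mm) {
    abort("Pursuit trigger distance exceeds the arena diameter.",
          class = "flydom_config_error")
  }
  for (nm in c("onset_median_s", "onset_shape", "pursuit_speed_mm_s",
               "pursuit_gap_mm", "prealt_rate_per_min", "climb_latency_s",
               "climb_duration_s", "chase_speed_mm_s", "walk_speed_mm_s",
               "turn_sd_deg")) {
    check_scalar_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  stopifnot(length(pursuit_bout_s) == 2, all(pursuit_bout_s > 0),
            diff(pursuit_bout_s) >= 0)
  for (p in act_profiles) {
    if (any(p$value < 0)) {
      abort("Act-rate profile values must be non-negative.",
            class = "flydom_config_error")
    }
  }
  structure(
    list(duration_s = duration_s, fps = fps,
         arena_radius_mm = arena_radius_mm,
         onset_median_s = onset_median_s, onset_shape = onset_shape,
         p_pre_established = p_pre_established,
         p_never_established = p_never_established,
         p_reversal = p_reversal, reversal_geom_p = reversal_geom_p,
         act_profiles = act_profiles,
         pursuit_speed_mm_s = pursuit_speed_mm_s,
         pursuit_gap_mm = pursuit_gap_mm,
         pursuit_bout_s = pursuit_bout_s,
         prealt_rate_per_min = prealt_rate_per_min,
         climb_latency_s = climb_latency_s,
         climb_duration_s = climb_duration_s,
         chase_speed_mm_s = chase_speed_mm_s,
         lunge_dominant_fraction = lunge_dominant_fraction,
         walk_speed_mm_s = walk_speed_mm_s, turn_sd_deg = turn_sd_deg,
         seed = seed),
    class = "sim_config"
  )
}

#' Derive a per-contest seed
#'
#' Deterministic mixing of the cohort master seed and a contest index, so
#' cohort generation is order-independent: contest `i` of a cohort equals a
#' standalone simulation with the derived seed.
#'
#' @param seed Master seed (integer).
#' @param index Contest index (1-based).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_contest_seed <- function(seed, index) {
  m <- 2147483647
  s <- (seed %% m) * 48271 %% m
  (s + index * 69621 + 1) %% m
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
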