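#' Simulate a single two-fly contest
#'
#' Draws the contest's classification (established / established prior to
#' observation / never established), dominance onset latency and reversal
#' times, generates true behavioral event streams from the configured
#' act-rate profiles, and (optionally) synthesizes both flies' trajectories
#' so that every scripted pursuit, climb, chase and lunge is realized
#' kinematically. By construction, every establishment and reversal of
#' dominance is preceded by a pursuit bout by the (new) dominant whose end
#' is followed within the configured climb latency by the subordinate's
#' wall excursion — the pursue-to-climb pattern the detectors target.
#' Fully reproducible: identical `(config, contest_seed)` give identical
#' output.
#'
#' @param config A [sim_config()].
#' @param contest_seed Integer seed for this contest.
#' @param contest_id Identifier string.
#' @param trajectory If `FALSE`, only ground-truth events are generated
#'   (much faster; sufficient for event-level analyses and calibration
#'   experiments).
#' @return A `simulated_contest`: list with `contest_id`, `trajectory` (a
#'   `fly_trajectory` or `NULL`) and `truth` (a `ground_truth` holding the
#'   classification, onset, reversal times, true events and the config
#'   echo).
#' @export
simulate_contest <- function(config, contest_seed,
                             contest_id = paste0("contest-", contest_seed),
                             trajectory = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pursuit_gap_mm > 2 * config$arena_radius_mm) {
    abort("Pursuit trigger distance exceeds the arena diameter.",
          class = "flydom_config_error")
  }
  built <- with_seed(contest_seed, build_truth(config, contest_id))
  geometry <- arena_geometry(radius_mm = config$arena_radius_mm)
  traj <- NULL
  if (trajectory) {
    traj_seed <- (contest_seed * 69069 + 12345) %% 2147483647
    traj <- with_seed(traj_seed,
                      synth_trajectory(config, built$script, geometry))
  }
  structure(list(contest_id = contest_id, trajectory = traj,
                 truth = built$truth),
            class = "simulated_contest")
}

#' Simulate a cohort of contests
#'
#' Per-contest seeds are derived deterministically from `config$seed` and
#' the contest index ([derive_contest_seed()]), so the cohort is
#' order-independent: element `i` equals a standalone
#' [simulate_contest()] call with the derived seed.
#'
#' @inheritParams simulate_contest
#' @param n Number of contests (>= 1).
#' @param id_prefix Prefix for contest identifiers.
#' @return List of `simulated_contest` objects.
#' @export
simulate_cohort <- function(config, n, trajectory = TRUE,
                            id_prefix = "contest") {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    simulate_contest(config, derive_contest_seed(config$seed, i),
                     contest_id = sprintf("%s-%03d", id_prefix, i),
                     trajectory = trajectory)
  })
}

#' Simulate a rematch of a prior winner against a naive opponent
#'
#' Pairs the dominant fly of a previous contest with a naive male in a
#' fresh arena. The prior dominant lunges before establishing dominance
#' with elevated probability (precocious lunging, a winner effect) and wins
#' the rematch with probability `p_win`; the naive opponent rarely lunges
#' early. The prior dominant keeps its fly label from the first contest and
#' is recorded in `truth$prior_dominant_id`.
#'
#' @inheritParams simulate_contest
#' @param first A `simulated_contest` whose hierarchy was established.
#' @param seed Integer seed for the rematch.
#' @param p_win Probability the prior dominant wins the rematch.
#' @param p_precocious Probability the prior dominant lunges before onset.
#' @param p_naive_precocious Probability the naive opponent lunges before
#'   onset.
#' @return A `simulated_contest` for the rematch.
#' @export
winner_rematch <- function(config, first, seed,
                           p_win = 0.75, p_precocious = 0.7,
                           p_naive_precocious = 0.08,
                           trajectory = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (first$truth$classification != "established") {
    abort("The first contest must have an established hierarchy.",
          class = "flydom_sim_error")
  }
  prior <- first$truth$dominant_id
  naive <- other_fly(prior)
  contest_id <- paste0(first$contest_id, "-rematch")
  prelunge_p <- setNames(c(p_precocious, p_naive_precocious),
                         c(prior, naive))
  built <- with_seed(seed, {
    winner <- if (runif(1) < p_win) prior else naive
    build_truth(config, contest_id,
                forced = list(classification = "established",
                              dominant = winner,
                              prelunge_p = as.list(prelunge_p),
                              no_base_prelunge = TRUE,
                              prior_dominant_id = prior))
  })
  geometry <- arena_geometry(radius_mm = config$arena_radius_mm)
  traj <- NULL
  if (trajectory) {
    traj_seed <- (seed * 69069 + 54321) %% 2147483647
    traj <- with_seed(traj_seed,
                      synth_trajectory(config, built$script, geometry))
  }
  structure(list(contest_id = contest_id, trajectory = traj,
                 truth = built$truth),
            class = "simulated_contest")
}

#' Ground truth as a dominance timeline
#'
#' Converts a simulated contest's ground truth into the same
#' `dominance_timeline` representation produced by [build_timeline()], for
#' direct comparison with pipeline output.
#'
#' @param contest A `simulated_contest`.
#' @return A `dominance_timeline`.
#' @export
truth_timeline <- function(contest) {
  tr <- contest$truth
  dur <- tr$params_used$duration_s
  no_rev <- tibble::tibble(t_s = numeric(0), new_dominant = character(0))
  if (tr$classification == "never_established") {
    return(new_timeline(contest$contest_id, "never_established", NULL, NULL,
                        no_rev, dur))
  }
  revs <- if (length(tr$reversal_times_s) == 0) no_rev else tibble::tibble(
    t_s = tr$reversal_times_s,
    new_dominant = tr$dominant_sequence[-1]
  )
  new_timeline(contest$contest_id, tr$classification, tr$onset_s,
               tr$dominant_id, revs, dur)
}
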