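#' Arena geometry
#'
#' Geometry of the circular contest arena. The default is an enclosed arena of
#' 16 mm diameter (radius 8 mm). `wall_fraction` is the radial fraction of the
#' arena radius at or beyond which a fly is considered to be on the wall;
#' top-down tracking cannot see height, so wall occupancy is the operational
#' proxy for a fly leaving the floor.
#'
#' @param radius_mm Arena radius in mm (default 8).
#' @param wall_fraction Radial threshold in (0, 1) for wall occupancy
#'   (default 0.95).
#' @return An object of class `arena_geometry`.
#' @export
#' @examples
#' arena_geometry()
arena_geometry <- function(radius_mm = 8, wall_fraction = 0.95) {
  check_scalar_number(radius_mm, "radius_mm", min = 0, strict_min = TRUE)
  check_scalar_number(wall_fraction, "wall_fraction", min = 0, max = 1,
                      strict_min = TRUE)
  if (wall_fraction >= 1) {
    abort("`wall_fraction` must be strictly less than 1.",
          class = "flydom_config_error")
  }
  structure(list(radius_mm = radius_mm, wall_fraction = wall_fraction),
            class = "arena_geometry")
}

#' Bout-detector parameters
#'
#' Thresholds for the kinematic detectors and for linking pursuit bouts to
#' wall climbs when applying the pursue-to-climb dominance criterion. All of
#' these acts are defined verbally in the field; the thresholds here are
#' explicit, tunable operationalizations at plausible fly scales.
#'
#' @param pursuit_d_max_mm Maximum inter-fly distance during pursuit (mm).
#' @param pursuit_v_min_mm_s Minimum pursuer speed during pursuit (mm/s).
#' @param pursuit_theta_max_deg Maximum pursuer bearing error toward the
#'   opponent (degrees).
#' @param pursuit_t_min_s Minimum pursuit bout duration (s); shorter runs are
#'   discarded after gap merging.
#' @param pursuit_gap_max_s Gaps between qualifying runs up to this length (s)
#'   are merged into one bout.
#' @param chase_min_s Minimum duration (s) for a trailing bout to be
#'   re-labeled a chase: chasing is a long, high-speed trailing behavior,
#'   distinct from the shorter pursuits.
#' @param chase_v_min_mm_s Minimum mean speed (mm/s) for the chase re-label.
#' @param climb_min_s Minimum wall-occupancy duration (s) to count as a climb.
#' @param lunge_window_s Window (s) over which forward displacement is
#'   measured for the lunge detector.
#' @param lunge_disp_min_mm Minimum displacement (mm) over the window.
#' @param lunge_d_max_mm Maximum inter-fly distance at window start (mm).
#' @param lunge_theta_max_deg Maximum bearing error at window start (degrees).
#' @param lunge_refractory_s Detections closer than this (s) are merged into
#'   the first.
#' @param link_max_s A climb starting during, or within this many seconds
#'   after, a pursuit bout by the other fly constitutes a diagnostic
#'   pursue-to-climb instance.
#' @param k_confirm Number of diagnostic instances by the same pursuer
#'   required before declaring dominance onset (default 1).
#' @param observation_start_s Time (s) at which observation begins; a
#'   diagnostic pursuit already in progress at this time marks the contest as
#'   established prior to observation.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(pursuit_d_max_mm = 5,
                            pursuit_v_min_mm_s = 3,
                            pursuit_theta_max_deg = 45,
                            pursuit_t_min_s = 1,
                            pursuit_gap_max_s = 0.2,
                            chase_min_s = 5,
                            chase_v_min_mm_s = 10,
                            climb_min_s = 0.5,
                            lunge_window_s = 0.1,
                            lunge_disp_min_mm = 1.5,
                            lunge_d_max_mm = 3,
                            lunge_theta_max_deg = 30,
                            lunge_refractory_s = 0.3,
                            link_max_s = 2,
                            k_confirm = 1,
                            observation_start_s = 0) {
  p <- list(
    pursuit_d_max_mm = pursuit_d_max_mm,
    pursuit_v_min_mm_s = pursuit_v_min_mm_s,
    pursuit_theta_max_deg = pursuit_theta_max_deg,
    pursuit_t_min_s = pursuit_t_min_s,
    pursuit_gap_max_s = pursuit_gap_max_s,
    chase_min_s = chase_min_s,
    chase_v_min_mm_s = chase_v_min_mm_s,
    climb_min_s = climb_min_s,
    lunge_window_s = lunge_window_s,
    lunge_disp_min_mm = lunge_disp_min_mm,
    lunge_d_max_mm = lunge_d_max_mm,
    lunge_theta_max_deg = lunge_theta_max_deg,
    lunge_refractory_s = lunge_refractory_s,
    link_max_s = link_max_s,
    k_confirm = k_confirm,
    observation_start_s = observation_start_s
  )
  positive <- setdiff(names(p), "observation_start_s")
  for (nm in positive) {
    check_scalar_number(p[[nm]], nm, min = 0, strict_min = TRUE)
  }
  check_scalar_number(observation_start_s, "observation_start_s", min = 0)
  if (k_confirm != round(k_confirm)) {
    abort("`k_confirm` must be a whole number.", class = "flydom_config_error")
  }
  structure(p, class = "detector_params")
}
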