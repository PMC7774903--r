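# Frame-by-frame synthesis of both flies' positions from the motion script.
# Baseline movement is a correlated random walk with a soft reflecting
# boundary just inside the wall threshold; scripted pursuit/chase bouts move
# the pursued fly along a circular path (spiralling outward for terminal,
# pursue-to-climb bouts) with the pursuer trailing at the configured gap;
# scripted climbs pin the climber to the wall radius; scripted lunges stage
# an approach, a fast forward thrust, and a short retreat. Consumes RNG.
# State is kept in frame-by-fly matrices and the inner loop avoids any
# data-frame access: the loop runs 36k frames per 20-min contest.
synth_trajectory <- function(config, script, geometry) {
  n <- round(config$duration_s * config$fps)
  fps <- config$fps
  R <- config$arena_radius_mm
  r_max <- 0.945 * R
  r_wall <- 0.975 * R
  turn_sd <- config$turn_sd_deg * pi / 180
  ws <- config$walk_speed_mm_s

  # pre-drawn randomness for the walk (A's stream first, then B's)
  dhm <- cbind(rnorm(n, 0, turn_sd), rnorm(n, 0, turn_sd))
  stm <- cbind(pmax(0, rnorm(n, ws, 0.4 * ws)) / fps,
               pmax(0, rnorm(n, ws, 0.4 * ws)) / fps)

  f_of <- function(t) pmin(pmax(round(t * fps) + 1, 1), n)
  j_of <- function(id) ifelse(id == "A", 1L, 2L)

  segs <- script$segments
  n_segs <- nrow(segs)
  pseg <- integer(n)
  sk_fol <- sk_led <- integer(0)
  sk_fs <- sk_fe <- integer(0)
  sk_speed <- sk_gap <- sk_dir <- numeric(0)
  sk_term <- logical(0)
  if (n_segs > 0) {
    sk_fol <- j_of(segs$actor); sk_led <- j_of(segs$target)
    sk_fs <- f_of(segs$start_s); sk_fe <- f_of(segs$end_s)
    sk_speed <- segs$speed; sk_gap <- segs$gap
    sk_dir <- segs$dirsign; sk_term <- segs$terminal
    for (k in seq_len(n_segs)) {
      fe <- sk_fe[k] - 1L
      if (fe >= sk_fs[k]) pseg[sk_fs[k]:fe] <- k
    }
  }
  climb_m <- matrix(FALSE, n, 2)
  if (nrow(script$climbs) > 0) {
    for (k in seq_len(nrow(script$climbs))) {
      fs <- f_of(script$climbs$start_s[k])
      fe <- f_of(script$climbs$end_s[k]) - 1L
      if (fe >= fs) climb_m[fs:fe, j_of(script$climbs$actor[k])] <- TRUE
    }
  }
  # lunge codes: 1 approach, 2 dash, 3 retreat; freeze flags for the target
  lcode_m <- matrix(0L, n, 2)
  freeze_m <- matrix(FALSE, n, 2)
  if (nrow(script$lunges) > 0) {
    n_app <- round(1.0 * fps); n_dash <- max(2L, round(0.1 * fps))
    n_ret <- round(0.3 * fps)
    for (k in seq_len(nrow(script$lunges))) {
      f0 <- f_of(script$lunges$t_s[k])
      a <- j_of(script$lunges$actor[k])
      tg <- j_of(script$lunges$target[k])
      lcode_m[seq(max(1, f0 - n_app), f0 - 1), a] <- 1L
      lcode_m[seq(f0, min(n, f0 + n_dash - 1)), a] <- 2L
      lcode_m[seq(min(n, f0 + n_dash),
                  min(n, f0 + n_dash + n_ret - 1)), a] <- 3L
      freeze_m[seq(f0, min(n, f0 + n_dash - 1)), tg] <- TRUE
    }
  }

  X <- matrix(0, n, 2); Y <- matrix(0, n, 2); H <- matrix(0, n, 2)
  # start on opposite sides, mid-arena
  phi0 <- runif(1, 0, 2 * pi)
  X[1, 1] <- 0.4 * R * cos(phi0); Y[1, 1] <- 0.4 * R * sin(phi0)
  X[1, 2] <- -X[1, 1]; Y[1, 2] <- -Y[1, 1]
  H[1, 1] <- runif(1, 0, 2 * pi); H[1, 2] <- runif(1, 0, 2 * pi)

  cur_seg <- 0L
  seg_phi <- 0; seg_r0 <- 0
  dash_step <- c(0, 0)
  wall_phi <- c(0, 0)

  # a pursuit already in progress at the first observed frame (hierarchy
  # formed before observation): start both flies on the scripted circle
  if (pseg[1] > 0) {
    k <- pseg[1]
    cur_seg <- k
    seg_r0 <- 0.5 * R
    seg_phi <- phi0
    led <- sk_led[k]; fol <- sk_fol[k]
    X[1, led] <- seg_r0 * cos(seg_phi)
    Y[1, led] <- seg_r0 * sin(seg_phi)
    H[1, led] <- seg_phi + sk_dir[k] * pi / 2
    phi_f <- seg_phi - sk_dir[k] * (sk_gap[k] / seg_r0)
    X[1, fol] <- seg_r0 * cos(phi_f)
    Y[1, fol] <- seg_r0 * sin(phi_f)
    H[1, fol] <- atan2(Y[1, led] - Y[1, fol], X[1, led] - X[1, fol])
  }

  r_spiral <- 0.92 * R
  r_lo <- 0.30 * R; r_hi <- 0.83 * R
  for (i in seq(2, n)) {
    k <- pseg[i]
    if (k > 0) {
      led <- sk_led[k]; fol <- sk_fol[k]
      if (cur_seg != k) {
        cur_seg <- k
        xl0 <- X[i - 1, led]; yl0 <- Y[i - 1, led]
        seg_r0 <- min(max(sqrt(xl0 * xl0 + yl0 * yl0), r_lo), r_hi)
        seg_phi <- atan2(yl0, xl0)
      }
      frac <- if (sk_term[k] && sk_fe[k] > sk_fs[k])
        (i - sk_fs[k]) / (sk_fe[k] - sk_fs[k]) else 0
      r_now <- seg_r0 + frac * (r_spiral - seg_r0)
      seg_phi <- seg_phi + sk_dir[k] * (sk_speed[k] / r_now) / fps
      xl <- r_now * cos(seg_phi); yl <- r_now * sin(seg_phi)
      X[i, led] <- xl; Y[i, led] <- yl
      H[i, led] <- seg_phi + sk_dir[k] * pi / 2
      phi_f <- seg_phi - sk_dir[k] * (sk_gap[k] / r_now)
      xf <- r_now * cos(phi_f); yf <- r_now * sin(phi_f)
      X[i, fol] <- xf; Y[i, fol] <- yf
      H[i, fol] <- atan2(yl - yf, xl - xf)
      next
    }
    for (j in 1:2) {
      xi <- X[i - 1, j]; yi <- Y[i - 1, j]
      if (climb_m[i, j]) {
        if (!climb_m[i - 1, j]) wall_phi[j] <- atan2(yi, xi)
        X[i, j] <- r_wall * cos(wall_phi[j])
        Y[i, j] <- r_wall * sin(wall_phi[j])
        H[i, j] <- wall_phi[j]
      } else if (freeze_m[i, j]) {
        X[i, j] <- xi; Y[i, j] <- yi; H[i, j] <- H[i - 1, j]
      } else if (lcode_m[i, j] > 0L) {
        tg <- 3L - j
        tx <- X[i - 1, tg]; ty <- Y[i - 1, tg]
        d <- sqrt((tx - xi)^2 + (ty - yi)^2)
        ang <- atan2(ty - yi, tx - xi)
        code <- lcode_m[i, j]
        if (code == 1L) {
          # close in on, or back off to, the staging distance
          step <- max(min(d - 2.8, 20 / fps), -20 / fps)
        } else if (code == 2L) {
          if (lcode_m[i - 1, j] != 2L) {
            dash_step[j] <- max(d - 0.8, 0.5) / max(2, round(0.1 * fps))
          }
          step <- min(dash_step[j], max(d - 0.3, 0))
        } else {
          step <- -3 / fps
        }
        xn <- xi + step * cos(ang); yn <- yi + step * sin(ang)
        r <- sqrt(xn * xn + yn * yn)
        if (r > r_max) { xn <- xn * r_max / r; yn <- yn * r_max / r }
        X[i, j] <- xn; Y[i, j] <- yn
        # faces the opponent while staging and thrusting, away on retreat
        H[i, j] <- if (code == 3L) ang + pi else ang
      } else {
        hn <- H[i - 1, j] + dhm[i, j]
        s <- stm[i, j]
        xn <- xi + s * cos(hn)
        yn <- yi + s * sin(hn)
        r <- sqrt(xn * xn + yn * yn)
        if (r > r_max) {
          xn <- xn * r_max / r; yn <- yn * r_max / r
          hn <- atan2(-yn, -xn) + dhm[i, j]
        }
        X[i, j] <- xn; Y[i, j] <- yn; H[i, j] <- hn
      }
    }
  }

  df <- tibble::tibble(
    frame = rep(0:(n - 1), each = 2),
    fly = rep(c("A", "B"), n),
    x_mm = as.vector(t(X)),
    y_mm = as.vector(t(Y)),
    heading_deg = (as.vector(t(H)) * 180 / pi) %% 360,
    on_wall = as.vector(t(climb_m))
  )
  as_trajectory(df, fps = fps, geometry = geometry)
}
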