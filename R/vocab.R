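#' Behavioral vocabulary
#'
#' The fixed set of behavior labels used throughout the package. `fence`,
#' `box_tussle`, `chase` and `pursuit` are state-like acts (they occupy an
#' interval of time); `lunge` and `wing_flick` are point-like acts (a single
#' thrust or wing movement, allowed zero duration); `climb` is the state of
#' occupying the arena wall. Boxing and tussling are merged into the single
#' category `box_tussle` because they are hard to tell apart at scoring time.
#'
#' @return Character vector of allowed behavior labels.
#' @export
#' @examples
#' behavior_vocabulary()
behavior_vocabulary <- function() {
  c("fence", "wing_flick", "box_tussle", "lunge", "chase", "pursuit", "climb")
}

#' Behavior class: state-like or point-like
#'
#' @param behavior Character vector of behavior labels.
#' @return Character vector, `"state"` or `"point"` per element.
#' @export
#' @examples
#' behavior_class(c("lunge", "fence"))
behavior_class <- function(behavior) {
  point <- c("lunge", "wing_flick")
  check_behavior(behavior)
  ifelse(behavior %in% point, "point", "state")
}

check_behavior <- function(behavior, arg = "behavior") {
  bad <- setdiff(unique(behavior), behavior_vocabulary())
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Unknown %s label(s): %s. Allowed labels: %s.",
        arg, paste(bad, collapse = ", "),
        paste(behavior_vocabulary(), collapse = ", ")
      ),
      class = "flydom_vocab_error"
    )
  }
  invisible(behavior)
}

fly_ids <- function() c("A", "B")

other_fly <- function(fly) {
  unname(c(A = "B", B = "A")[fly])
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "flydom_config_error")
  }
  ok <- if (strict_min) x > min else x >= min
  if (!ok || x > max) {
    abort(sprintf("`%s` = %g is outside its allowed range.", name, x),
          class = "flydom_config_error")
  }
  invisible(x)
}
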