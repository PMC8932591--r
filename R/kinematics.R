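#' Single-fish burst-and-coast kinematics
#'
#' A fish's state between two kicks is the position and heading at the onset
#' of the current kick together with the kick's start time, duration and
#' length. During the glide the speed decays quasi-exponentially,
#' `v(s) = v_peak * exp(-s / tau0)` with `s` the time since kick onset, and
#' the peak speed is derived from the kick length and duration,
#' `v_peak = l / (tau0 * (1 - exp(-tau / tau0)))`, so that the integrated
#' displacement equals the kick length exactly.
#'
#' @param id integer fish identifier.
#' @param position length-2 numeric, metres (position at kick onset).
#' @param heading radians; stored wrapped to (-pi, pi].
#' @param kick_start kick onset time, seconds.
#' @param kick_duration kick duration, seconds, > 0.
#' @param kick_length kick length, metres, > 0.
#' @param relaxation_time glide relaxation time tau0, seconds.
#' @return an object of class `fish_state`.
#' @export
fish_state <- function(id, position, heading, kick_start,
                       kick_duration, kick_length, relaxation_time = 0.8) {
  stop_unless(kick_duration > 0, "kick_duration must be > 0")
  stop_unless(kick_length > 0, "kick_length must be > 0")
  structure(list(id = as.integer(id), position = as.numeric(position),
                 heading = wrap_angle(heading), kick_start = kick_start,
                 kick_duration = kick_duration, kick_length = kick_length,
                 relaxation_time = relaxation_time),
            class = "fish_state")
}

#' Sample one kick
#'
#' Draws a (length, duration) pair. In `"fixed"` mode the means are returned
#' exactly. In `"sampled"` mode length and duration are drawn independently
#' from gamma distributions with the configured means and coefficient of
#' variation, truncated below at 10% of the mean by rejection.
#'
#' @param stats a [kick_statistics()] object.
#' @return list with `length` (m) and `duration` (s).
#' @export
sample_kick <- function(stats) {
  if (stats$mode == "fixed" || stats$variability_cv == 0)
    return(list(length = stats$mean_length, duration = stats$mean_duration))
  list(length = rgamma_truncated(stats$mean_length, stats$variability_cv),
       duration = rgamma_truncated(stats$mean_duration, stats$variability_cv))
}

# gamma draw with given mean and CV, rejected below 10% of the mean
rgamma_truncated <- function(mean, cv) {
  shape <- 1 / cv^2
  repeat {
    x <- stats::rgamma(1L, shape = shape, rate = shape / mean)
    if (x >= 0.1 * mean) return(x)
  }
}

# fraction of the kick length covered s seconds after kick onset;
# integrates v_peak * exp(-s/tau0) and normalizes so f(tau) = 1
glide_fraction <- function(s, duration, tau0) {
  (1 - exp(-s / tau0)) / (1 - exp(-duration / tau0))
}

#' Position during the glide
#'
#' Interpolates a fish's position within its current kick. At `t` equal to
#' the kick start the position is unchanged; at kick end the displacement is
#' exactly `kick_length` along the heading.
#'
#' @param state a [fish_state()] object.
#' @param t time, seconds; must lie within the kick window.
#' @return length-2 numeric position, metres.
#' @export
glide_position <- function(state, t) {
  s <- t - state$kick_start
  stop_unless(s >= 0 && s <= state$kick_duration,
              "t outside the kick window")
  f <- glide_fraction(s, state$kick_duration, state$relaxation_time)
  state$position + state$kick_length * f *
    c(cos(state$heading), sin(state$heading))
}

#' Peak speed of a kick
#'
#' Speed at kick onset, derived from the kick length and duration so that the
#' exponentially decaying glide covers exactly the kick length:
#' `v_peak = l / (tau0 * (1 - exp(-tau / tau0)))`.
#'
#' @param state a [fish_state()] object.
#' @return scalar, m/s.
#' @export
peak_speed <- function(state) {
  tau0 <- state$relaxation_time
  state$kick_length / (tau0 * (1 - exp(-state$kick_duration / tau0)))
}

#' Speed during the glide
#'
#' `v(t) = v_peak * exp(-(t - kick_start) / tau0)`.
#'
#' @inheritParams glide_position
#' @return scalar speed, m/s.
#' @export
glide_speed <- function(state, t) {
  s <- t - state$kick_start
  stop_unless(s >= 0 && s <= state$kick_duration,
              "t outside the kick window")
  peak_speed(state) * exp(-s / state$relaxation_time)
}

#' Apply a kick decision
#'
#' Advances a fish across a kick boundary: moves it to the glide endpoint of
#' the finished kick, turns it by `delta_phi` (wrapped after addition, so
#' turns larger than pi are meaningful before wrapping), advances the kick
#' clock by the finished kick's duration and installs the newly sampled kick.
#'
#' @param state a [fish_state()] at the end of its current kick.
#' @param delta_phi heading change, radians (social + noise).
#' @param new_length,new_duration the next kick's length (m) and duration (s).
#' @return the updated `fish_state`.
#' @export
apply_kick <- function(state, delta_phi, new_length, new_duration) {
  stop_unless(new_length > 0, "new_length must be > 0")
  stop_unless(new_duration > 0, "new_duration must be > 0")
  endpoint <- state$position + state$kick_length *
    c(cos(state$heading), sin(state$heading))
  fish_state(state$id, endpoint, state$heading + delta_phi,
             state$kick_start + state$kick_duration,
             new_duration, new_length, state$relaxation_time)
}

#' Spontaneous heading fluctuation
#'
#' Gaussian white noise added to the heading at each kick onset:
#' `gamma_r` times a standard normal draw.
#'
#' @param gamma_r noise intensity, >= 0.
#' @param n number of draws.
#' @return numeric vector of heading perturbations, radians.
#' @export
heading_noise <- function(gamma_r, n = 1L) {
  stop_unless(gamma_r >= 0, "gamma_r must be >= 0")
  if (gamma_r == 0) rep(0, n) else gamma_r * stats::rnorm(n)
}
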