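# shared small configurations and random-geometry helpers

default_params <- function(...) interaction_params(...)

# the phase-diagram study condition: l_att = l_ali = 0.28 m, gamma_r = 0.2
study_params <- function(gamma_att, gamma_ali, k = 1L) {
  interaction_params(gamma_att = gamma_att, gamma_ali = gamma_ali,
                     l_att = 0.28, l_ali = 0.28, k = k)
}

small_config <- function(n_fish = 3, n_kicks = 50, seed = 1,
                         params = study_params(0.04, 0.1),
                         gamma_r = 0.2, mode = "fixed", ...) {
  simulation_config(n_fish = n_fish, params = params, gamma_r = gamma_r,
                    kick_stats = kick_statistics(mode = mode),
                    n_kicks_per_fish = n_kicks, transient_seconds = 1,
                    seed = seed, ...)
}

random_snapshot <- function(n, spread = 0.5) {
  school_snapshot(0, cbind(stats::runif(n, -spread, spread),
                           stats::runif(n, -spread, spread)),
                  stats::runif(n, -pi, pi), stats::runif(n, 0.05, 0.3))
}

# rotate + translate a snapshot rigidly (headings co-rotated)
transform_snapshot <- function(snap, angle, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  school_snapshot(snap$time,
                  sweep(snap$positions %*% t(rot), 2, shift, "+"),
                  wrap_angle(snap$headings + angle), snap$speeds)
}
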