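#' Social interaction parameters
#'
#' Container for the constants of the pairwise attraction/alignment kernels
#' and the influential-neighbor interaction strategy. Defaults are the values
#' measured for *Hemigrammus rhodostomus*: attraction and alignment strengths
#' `gamma_att = 0.12`, `gamma_ali = 0.09` (dimensionless), interaction ranges
#' `l_att = l_ali = 0.20` m, repulsion crossover `d_att = 0.03` m (attraction
#' turns repulsive below this distance, roughly one body length) and alignment
#' distance scale `d_ali = 0.06` m. `k` is the number of most influential
#' neighbors whose contributions are summed at each kick.
#'
#' @param gamma_att attraction strength, dimensionless, >= 0.
#' @param gamma_ali alignment strength, dimensionless, >= 0.
#' @param l_att attraction range, metres, > 0.
#' @param l_ali alignment range, metres, > 0.
#' @param d_att repulsion crossover distance, metres, > 0.
#' @param d_ali alignment distance scale, metres, > 0.
#' @param k number of influential neighbors, positive integer.
#' @return an object of class `interaction_params`.
#' @examples
#' interaction_params()
#' interaction_params(gamma_att = 0.04, gamma_ali = 0.2, l_att = 0.28,
#'                    l_ali = 0.28, k = 1)
#' @export
interaction_params <- function(gamma_att = 0.12, gamma_ali = 0.09,
                               l_att = 0.20, l_ali = 0.20,
                               d_att = 0.03, d_ali = 0.06, k = 1L) {
  stop_unless(is_scalar_num(gamma_att) && gamma_att >= 0, "gamma_att must be >= 0")
  stop_unless(is_scalar_num(gamma_ali) && gamma_ali >= 0, "gamma_ali must be >= 0")
  stop_unless(is_scalar_num(l_att) && l_att > 0, "l_att must be > 0")
  stop_unless(is_scalar_num(l_ali) && l_ali > 0, "l_ali must be > 0")
  stop_unless(is_scalar_num(d_att) && d_att > 0, "d_att must be > 0")
  stop_unless(is_scalar_num(d_ali) && d_ali > 0, "d_ali must be > 0")
  stop_unless(is_scalar_num(k) && k >= 1 && k == as.integer(k),
              "k must be a positive integer")
  structure(list(gamma_att = gamma_att, gamma_ali = gamma_ali,
                 l_att = l_att, l_ali = l_ali,
                 d_att = d_att, d_ali = d_ali, k = as.integer(k)),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Pairwise interaction parameters (H. rhodostomus kernels)\n")
  cat(sprintf("  attraction: gamma_att = %g, l_att = %g m, d_att = %g m\n",
              x$gamma_att, x$l_att, x$d_att))
  cat(sprintf("  alignment:  gamma_ali = %g, l_ali = %g m, d_ali = %g m\n",
              x$gamma_ali, x$l_ali, x$d_ali))
  cat(sprintf("  strategy:   k = %d most influential neighbor%s\n",
              x$k, if (x$k > 1) "s" else ""))
  invisible(x)
}

#' Reference mean peak speed after a kick
#'
#' Mean speed maximum measured right after a kick in *H. rhodostomus*
#' (0.14 m/s). Exposed as a reference constant only: the simulator derives
#' each kick's peak speed from its length and duration so that the glide
#' displacement integrates exactly to the kick length.
#' @export
V0_REFERENCE <- 0.14

#' Kick statistics
#'
#' Marginal statistics of the burst-and-coast kicks. Mean kick length 0.07 m
#' and mean duration 0.5 s are the values measured for *H. rhodostomus*; the
#' glide speed relaxes quasi-exponentially with time constant
#' `relaxation_time` (0.8 s). The experimental length/duration distributions
#' are bell-shaped but not published; in `mode = "sampled"` the simulator
#' draws them independently from gamma distributions with the stated means and
#' coefficient of variation `variability_cv`, truncated below at 10% of the
#' mean. `mode = "fixed"` always returns the means (deterministic baseline).
#'
#' @param mean_length mean kick length, metres.
#' @param mean_duration mean kick duration, seconds.
#' @param mean_peak_speed reference mean peak speed, m/s (not used to advance
#'   the dynamics; see [V0_REFERENCE]).
#' @param relaxation_time glide speed relaxation time tau0, seconds.
#' @param variability_cv coefficient of variation of sampled lengths and
#'   durations; 0 reduces sampled mode to fixed mode.
#' @param mode `"fixed"` or `"sampled"`.
#' @return an object of class `kick_statistics`.
#' @examples
#' kick_statistics()
#' kick_statistics(mode = "fixed")
#' @export
kick_statistics <- function(mean_length = 0.07, mean_duration = 0.5,
                            mean_peak_speed = V0_REFERENCE,
                            relaxation_time = 0.8,
                            variability_cv = 0.3,
                            mode = c("sampled", "fixed")) {
  mode <- match.arg(mode)
  stop_unless(is_scalar_num(mean_length) && mean_length > 0,
              "mean_length must be > 0")
  stop_unless(is_scalar_num(mean_duration) && mean_duration > 0,
              "mean_duration must be > 0")
  stop_unless(is_scalar_num(mean_peak_speed) && mean_peak_speed > 0,
              "mean_peak_speed must be > 0")
  stop_unless(is_scalar_num(relaxation_time) && relaxation_time > 0,
              "relaxation_time must be > 0")
  stop_unless(is_scalar_num(variability_cv) && variability_cv >= 0,
              "variability_cv must be >= 0")
  structure(list(mean_length = mean_length, mean_duration = mean_duration,
                 mean_peak_speed = mean_peak_speed,
                 relaxation_time = relaxation_time,
                 variability_cv = variability_cv, mode = mode),
            class = "kick_statistics")
}

#' @export
print.kick_statistics <- function(x, ...) {
  cat(sprintf("Kick statistics (%s mode): mean length %g m, mean duration %g s\n",
              x$mode, x$mean_length, x$mean_duration))
  cat(sprintf("  glide relaxation time %g s, CV %g\n",
              x$relaxation_time, x$variability_cv))
  invisible(x)
}

#' Simulation configuration
#'
#' Full description of one simulation run of a school of `n_fish` fish in an
#' unbounded plane.
#'
#' @param n_fish group size N, positive integer.
#' @param params [interaction_params()] object.
#' @param gamma_r heading noise intensity, dimensionless, >= 0. The value
#'   measured for pairs of *H. rhodostomus* is 0.45; the phase-diagram study
#'   condition is 0.2.
#' @param kick_stats [kick_statistics()] object.
#' @param n_kicks_per_fish total kick events processed is
#'   `n_fish * n_kicks_per_fish`; with fixed kick statistics every fish
#'   performs exactly this many kicks.
#' @param transient_seconds initial time span discarded from averages.
#' @param sampling_dt observable sampling interval, seconds.
#' @param seed integer RNG seed; the full trajectory is a deterministic
#'   function of the configuration.
#' @param n_replicates default replicate count used by the experiment helpers.
#' @return an object of class `simulation_config`.
#' @examples
#' simulation_config(n_fish = 10, n_kicks_per_fish = 200, seed = 1)
#' @export
simulation_config <- function(n_fish = 100L,
                              params = interaction_params(),
                              gamma_r = 0.2,
                              kick_stats = kick_statistics(),
                              n_kicks_per_fish = 2000L,
                              transient_seconds = 100,
                              sampling_dt = 1.0,
                              seed = 1L,
                              n_replicates = 20L) {
  stop_unless(is_scalar_num(n_fish) && n_fish >= 1 && n_fish == as.integer(n_fish),
              "n_fish must be a positive integer")
  stop_unless(inherits(params, "interaction_params"),
              "params must be an interaction_params object")
  stop_unless(is_scalar_num(gamma_r) && gamma_r >= 0, "gamma_r must be >= 0")
  stop_unless(inherits(kick_stats, "kick_statistics"),
              "kick_stats must be a kick_statistics object")
  stop_unless(is_scalar_num(n_kicks_per_fish) && n_kicks_per_fish >= 1,
              "n_kicks_per_fish must be a positive integer")
  stop_unless(is_scalar_num(transient_seconds) && transient_seconds >= 0,
              "transient_seconds must be >= 0")
  stop_unless(is_scalar_num(sampling_dt) && sampling_dt > 0,
              "sampling_dt must be > 0")
  stop_unless(is_scalar_num(seed), "seed must be a number")
  stop_unless(n_kicks_per_fish * kick_stats$mean_duration > transient_seconds,
              "run too short: n_kicks_per_fish * mean_duration must exceed transient_seconds")
  structure(list(n_fish = as.integer(n_fish), params = params,
                 gamma_r = gamma_r, kick_stats = kick_stats,
                 n_kicks_per_fish = as.integer(n_kicks_per_fish),
                 transient_seconds = transient_seconds,
                 sampling_dt = sampling_dt, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: N = %d fish, gamma_r = %g, %d kicks/fish, seed %d\n",
              x$n_fish, x$gamma_r, x$n_kicks_per_fish, x$seed))
  print(x$params)
  print(x$kick_stats)
  invisible(x)
}

config_flat_keys <- c("n_fish", "gamma_att", "gamma_ali", "l_att", "l_ali",
                      "d_att", "d_ali", "k", "gamma_r", "mean_length",
                      "mean_duration", "mean_peak_speed", "relaxation_time",
                      "variability_cv", "kick_mode", "n_kicks_per_fish",
                      "transient_seconds", "sampling_dt", "seed",
                      "n_replicates")

config_to_flat <- function(config) {
  p <- config$params; ks <- config$kick_stats
  list(n_fish = config$n_fish, gamma_att = p$gamma_att,
       gamma_ali = p$gamma_ali, l_att = p$l_att, l_ali = p$l_ali,
       d_att = p$d_att, d_ali = p$d_ali, k = p$k, gamma_r = config$gamma_r,
       mean_length = ks$mean_length, mean_duration = ks$mean_duration,
       mean_peak_speed = ks$mean_peak_speed,
       relaxation_time = ks$relaxation_time,
       variability_cv = ks$variability_cv, kick_mode = ks$mode,
       n_kicks_per_fish = config$n_kicks_per_fish,
       transient_seconds = config$transient_seconds,
       sampling_dt = config$sampling_dt, seed = config$seed,
       n_replicates = config$n_replicates)
}

flat_to_config <- function(x) {
  unknown <- setdiff(names(x), config_flat_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  d <- config_to_flat(simulation_config(n_fish = 2, n_kicks_per_fish = 201))
  d[names(x)] <- x
  simulation_config(
    n_fish = d$n_fish,
    params = interaction_params(d$gamma_att, d$gamma_ali, d$l_att, d$l_ali,
                                d$d_att, d$d_ali, d$k),
    gamma_r = d$gamma_r,
    kick_stats = kick_statistics(d$mean_length, d$mean_duration,
                                 d$mean_peak_speed, d$relaxation_time,
                                 d$variability_cv, d$kick_mode),
    n_kicks_per_fish = d$n_kicks_per_fish,
    transient_seconds = d$transient_seconds,
    sampling_dt = d$sampling_dt, seed = d$seed,
    n_replicates = d$n_replicates)
}

#' Read / write a simulation configuration file
#'
#' Flat key-value document (YAML or JSON, decided by the file extension) with
#' all physical values in metres and seconds. Unknown keys are rejected.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param config a [simulation_config()] object.
#' @return `read_config` returns a [simulation_config()];
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  flat_to_config(x)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stop_unless(inherits(config, "simulation_config"),
              "config must be a simulation_config object")
  x <- config_to_flat(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
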