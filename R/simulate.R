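#' Initialize a school
#'
#' Draws the initial condition of a run: positions uniform in a disc of
#' radius `R = sqrt(N / pi) * l_att / 2` (so the mean inter-fish distance is
#' of the order of half the attraction range), headings uniform in
#' (-pi, pi), one sampled kick per fish, and first kick onsets staggered
#' uniformly in `[0, mean_duration)` to realize asynchrony. Consumes the
#' current R RNG stream; callers seed beforehand.
#'
#' @param config a [simulation_config()] object.
#' @return list with vectors `x`, `y`, `heading`, `kick_start`,
#'   `kick_length`, `kick_duration`, and the disc radius `radius`.
#' @export
init_school <- function(config) {
  n <- config$n_fish
  ks <- config$kick_stats
  radius <- sqrt(n / pi) * config$params$l_att / 2
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, -pi, pi)
  heading <- stats::runif(n, -pi, pi)
  stagger <- stats::runif(n, 0, ks$mean_duration)
  len <- numeric(n); dur <- numeric(n)
  for (i in seq_len(n)) {
    kick <- sample_kick(ks)
    len[i] <- kick$length
    dur[i] <- kick$duration
  }
  list(x = r * cos(a), y = r * sin(a), heading = heading,
       kick_start = stagger, kick_length = len, kick_duration = dur,
       radius = radius)
}

#' Simulate a burst-and-coast fish school
#'
#' Runs the asynchronous event-driven simulation: kick-end events are
#' processed in time order (ties by fish id); at each event the kicking fish
#' perceives all others at their glide-interpolated positions, sums the
#' pairwise turns of its `k` most influential neighbors, adds Gaussian
#' heading noise, and starts a newly sampled kick. Exactly
#' `n_fish * n_kicks_per_fish` events are processed. The run is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config a [simulation_config()] object.
#' @param record_kicks keep the per-event record (time, fish, position,
#'   social and noise turns)? Disable for large sweeps to save memory.
#' @param record_neighbors additionally record the identities and focal-frame
#'   positions of the (up to two) selected influential neighbors at each
#'   kick; needed for [influential_position_density()].
#' @return an object of class `school_sim` with components `config`, `init`,
#'   `snapshots` (sampling times plus T x N matrices `x`, `y`, `heading`,
#'   `speed`), `kicks` (data frame or NULL), `kick_count`, `final`.
#' @examples
#' cfg <- simulation_config(n_fish = 10, n_kicks_per_fish = 100, seed = 42,
#'                          kick_stats = kick_statistics(mode = "fixed"),
#'                          transient_seconds = 10)
#' sim <- simulate_school(cfg)
#' summary(sim)
#' @export
simulate_school <- function(config, record_kicks = TRUE,
                            record_neighbors = FALSE) {
  stop_unless(inherits(config, "simulation_config"),
              "config must be a simulation_config object")
  set.seed(config$seed)
  init <- init_school(config)
  p <- config$params
  ks <- config$kick_stats
  res <- cpp_run_school(
    init$x, init$y, init$heading, init$kick_start,
    init$kick_length, init$kick_duration,
    p$gamma_att, p$gamma_ali, p$l_att, p$l_ali, p$d_att, p$d_ali, p$k,
    config$gamma_r,
    ks$mean_length, ks$mean_duration, ks$variability_cv,
    ks$mode == "sampled", ks$relaxation_time,
    config$n_fish * config$n_kicks_per_fish, config$sampling_dt,
    record_kicks, record_kicks && record_neighbors)
  structure(list(
    config = config, init = init,
    snapshots = list(times = res$snap_times, x = res$snap_x, y = res$snap_y,
                     heading = res$snap_heading, speed = res$snap_speed),
    kicks = res$kicks, kick_count = res$kick_count,
    final = list(x = res$final_x, y = res$final_y,
                 heading = res$final_heading,
                 kick_start = res$final_kick_start,
                 kick_length = res$final_kick_length,
                 kick_duration = res$final_kick_duration)),
    class = "school_sim")
}

#' Fixed-step reference simulation
#'
#' Naive reference implementation used as an independent check of the
#' event-driven engine: time advances in small fixed increments and a fish
#' kicks when the step clock crosses its kick-end time (crossings within a
#' step processed in (kick end, fish id) order, kinematics evaluated at the
#' exact kick-end time). All social terms are computed through the pure-R
#' kernel functions ([relative_state()], [pairwise_turn()],
#' [select_influential()]). With the same configuration and seed it must
#' reproduce the event-driven engine's kick positions; it is practical only
#' for small N and fixed kick statistics.
#'
#' @param config a [simulation_config()] object (fixed kick statistics
#'   recommended; sampled statistics also work but slowly).
#' @param dt step size, seconds.
#' @return data frame of kick events (`time`, `fish_id`, `x`, `y`,
#'   `heading_old`, `heading_new`, `dphi_social`, `dphi_noise`).
#' @export
simulate_school_reference <- function(config, dt = 0.001) {
  stop_unless(inherits(config, "simulation_config"),
              "config must be a simulation_config object")
  set.seed(config$seed)
  init <- init_school(config)
  p <- config$params
  ks <- config$kick_stats
  tau0 <- ks$relaxation_time
  n <- config$n_fish
  x <- init$x; y <- init$y; phi <- init$heading
  kstart <- init$kick_start; klen <- init$kick_length
  kdur <- init$kick_duration
  kend <- kstart + kdur
  n_events <- n * config$n_kicks_per_fish
  out <- vector("list", n_events)
  ev <- 0L
  clock <- 0
  glide_xy <- function(j, t) {
    s <- min(max(t - kstart[j], 0), kdur[j])
    f <- glide_fraction(s, kdur[j], tau0)
    c(x[j] + klen[j] * f * cos(phi[j]), y[j] + klen[j] * f * sin(phi[j]))
  }
  while (ev < n_events) {
    clock <- clock + dt
    # threshold crossing: kicks that end within this step; fish ending at
    # exactly the same instant form one batch evaluated against the common
    # pre-update state (ids ascending)
    while (ev < n_events && any(kend <= clock)) {
      t <- min(kend)
      batch <- which(kend == t)
      batch <- batch[seq_len(min(length(batch), n_events - ev))]
      upd <- list()
      for (i in batch) {
        xi <- x[i] + klen[i] * cos(phi[i])
        yi <- y[i] + klen[i] * sin(phi[i])
        dphi_s <- 0
        if (n > 1) {
          pos <- rbind(c(xi, yi),
                       t(vapply(setdiff(seq_len(n), i), glide_xy,
                                numeric(2), t = t)))
          hds <- c(phi[i], phi[-i])
          sel <- select_influential(1L, pos, hds, p)
          if (length(sel$ids))
            dphi_s <- sum(vapply(sel$rel, pairwise_turn, numeric(1),
                                 params = p))
        }
        dphi_r <- heading_noise(config$gamma_r)
        phi_old <- phi[i]
        phi_new <- wrap_angle(phi_old + dphi_s + dphi_r)
        kick <- sample_kick(ks)
        ev <- ev + 1L
        out[[ev]] <- c(t, i, xi, yi, phi_old, phi_new, dphi_s, dphi_r)
        upd[[as.character(i)]] <- c(xi, yi, phi_new, kick$length,
                                    kick$duration)
      }
      for (i in batch) {
        u <- upd[[as.character(i)]]
        x[i] <- u[1]; y[i] <- u[2]; phi[i] <- u[3]
        kstart[i] <- t; klen[i] <- u[4]; kdur[i] <- u[5]
        kend[i] <- t + u[5]
      }
    }
  }
  m <- do.call(rbind, out)
  data.frame(time = m[, 1], fish_id = as.integer(m[, 2]), x = m[, 3],
             y = m[, 4], heading_old = m[, 5], heading_new = m[, 6],
             dphi_social = m[, 7], dphi_noise = m[, 8])
}

#' @export
print.school_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Burst-and-coast school simulation: N = %d fish, %d kicks/fish\n",
              cfg$n_fish, cfg$n_kicks_per_fish))
  cat(sprintf("  k = %d, gamma_att = %g, gamma_ali = %g, gamma_r = %g, seed = %d\n",
              cfg$params$k, cfg$params$gamma_att, cfg$params$gamma_ali,
              cfg$gamma_r, cfg$seed))
  cat(sprintf("  %d snapshots every %g s, final time %.1f s\n",
              length(x$snapshots$times), cfg$sampling_dt,
              max(x$final$kick_start + x$final$kick_duration)))
  invisible(x)
}

#' @export
summary.school_sim <- function(object, ...) {
  obs <- observable_series(object)
  keep <- obs$time > object$config$transient_seconds
  if (!any(keep)) keep <- rep(TRUE, nrow(obs))
  means <- colMeans(obs[keep, c("D", "P", "M")])
  out <- list(sim = object, means = means,
              phase = classify_phase(means["P"], means["M"], means["D"]),
              n_samples = sum(keep))
  class(out) <- "summary.school_sim"
  out
}

#' @export
print.summary.school_sim <- function(x, ...) {
  print(x$sim)
  cat(sprintf("Post-transient means over %d samples:\n", x$n_samples))
  cat(sprintf("  dispersion   D = %.3f m\n", x$means["D"]))
  cat(sprintf("  polarization P = %.3f\n", x$means["P"]))
  cat(sprintf("  milling      M = %.3f\n", x$means["M"]))
  cat(sprintf("  phase: %s\n", x$phase))
  invisible(x)
}

#' Plot a school simulation
#'
#' Two panels: the time series of the polarization and milling order
#' parameters, and the final school snapshot with headings drawn as arrows.
#'
#' @param x a `school_sim` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.school_sim <- function(x, ...) {
  obs <- observable_series(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(obs$time, obs$P, type = "l", col = "red3",
                 xlab = "time (s)", ylab = "order parameter",
                 ylim = c(0, 1), main = "polarization / milling", ...)
  graphics::lines(obs$time, obs$M, col = "blue3")
  graphics::legend("topright", legend = c("P", "M"), bty = "n",
                   col = c("red3", "blue3"), lty = 1)
  nt <- length(x$snapshots$times)
  px <- x$snapshots$x[nt, ]; py <- x$snapshots$y[nt, ]
  h <- x$snapshots$heading[nt, ]
  len <- 0.04 * max(diff(range(px)), diff(range(py)), 0.1)
  graphics::plot(px, py, asp = 1, pch = 16, cex = 0.5,
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("t = %.0f s", x$snapshots$times[nt]))
  graphics::arrows(px, py, px + len * cos(h), py + len * sin(h),
                   length = 0.03, col = "gray40")
  invisible(x)
}

#' Export a trajectory to CSV with a JSON metadata sidecar
#'
#' Writes a long-format CSV with columns
#' `time,fish_id,x,y,heading,speed,event_type` (`event_type` is `kick` or
#' `snapshot`) and a `<path>.json` sidecar echoing the full configuration
#' and package version so the run can be regenerated bit-identically.
#'
#' @param sim a `school_sim` from [simulate_school()] (with kicks recorded).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  sn <- sim$snapshots
  nt <- length(sn$times); n <- sim$config$n_fish
  snap <- data.frame(time = rep(sn$times, each = n),
                     fish_id = rep(seq_len(n), times = nt),
                     x = as.vector(t(sn$x)), y = as.vector(t(sn$y)),
                     heading = as.vector(t(sn$heading)),
                     speed = as.vector(t(sn$speed)),
                     event_type = "snapshot")
  if (!is.null(sim$kicks)) {
    kk <- sim$kicks
    kick <- data.frame(time = kk$time, fish_id = kk$fish_id, x = kk$x,
                       y = kk$y, heading = kk$heading_new,
                       speed = NA_real_, event_type = "kick")
    snap <- rbind(kick, snap)
  }
  snap <- snap[order(snap$time, snap$fish_id), ]
  utils::write.csv(snap, path, row.names = FALSE, quote = FALSE)
  meta <- list(config = config_to_flat(sim$config),
               package = "burstcoast",
               version = as.character(utils::packageVersion("burstcoast")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
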