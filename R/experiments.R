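#' Replicated simulation of one parameter-grid cell
#'
#' Runs `replicates` independent simulations at one `(gamma_att, gamma_ali)`
#' point (replicate r uses seed `seed_base + r - 1`), discards the initial
#' transient, and returns time-and-replicate averages of dispersion,
#' polarization and milling with standard errors across replicates, plus the
#' pooled post-transient samples. Optionally pools the DMIN/DFNN/nearest
#' neighbor diagnostics.
#'
#' @param gamma_att,gamma_ali attraction and alignment strengths.
#' @param n_fish group size.
#' @param k number of influential neighbors.
#' @param l interaction range `l_att = l_ali`, metres.
#' @param gamma_r heading noise intensity.
#' @param replicates number of independent runs.
#' @param n_kicks_per_fish kick budget per fish per run.
#' @param transient_kicks initial kicks per fish discarded from averages
#'   (converted to seconds with the mean kick duration).
#' @param seed_base seed of the first replicate.
#' @param kick_stats a [kick_statistics()] object.
#' @param sampling_dt observable sampling interval, seconds.
#' @param diagnostics also compute pooled DMIN / DFNN / nearest-neighbor
#'   distance means (slower)?
#' @param transient_window optional explicit `c(t_min, t_max)` in seconds
#'   overriding the kick-count transient rule.
#' @return list with cell means (`mean_D`, `mean_P`, `mean_M`), standard
#'   errors (`se_P`, `se_M`), per-replicate means, pooled samples
#'   (`P_samples`, `M_samples`), and if requested `mean_dmin`, `mean_dfnn`,
#'   `mean_nn_dist`.
#' @export
run_cell <- function(gamma_att, gamma_ali, n_fish = 100L, k = 1L, l = 0.28,
                     gamma_r = 0.2, replicates = 20L,
                     n_kicks_per_fish = 2000L, transient_kicks = 100L,
                     seed_base = 1L, kick_stats = kick_statistics(),
                     sampling_dt = 1.0, diagnostics = FALSE,
                     transient_window = NULL) {
  params <- interaction_params(gamma_att = gamma_att, gamma_ali = gamma_ali,
                               l_att = l, l_ali = l, k = k)
  t_min <- transient_kicks * kick_stats$mean_duration
  t_max <- Inf
  if (!is.null(transient_window)) {
    t_min <- transient_window[1]; t_max <- transient_window[2]
  }
  rep_means <- matrix(NA_real_, replicates, 3,
                      dimnames = list(NULL, c("D", "P", "M")))
  P_samples <- list(); M_samples <- list()
  diag_means <- matrix(NA_real_, replicates, 3,
                       dimnames = list(NULL, c("dmin", "dfnn", "nn")))
  for (r in seq_len(replicates)) {
    cfg <- simulation_config(
      n_fish = n_fish, params = params, gamma_r = gamma_r,
      kick_stats = kick_stats, n_kicks_per_fish = n_kicks_per_fish,
      transient_seconds = t_min, sampling_dt = sampling_dt,
      seed = seed_base + r - 1L)
    sim <- simulate_school(cfg, record_kicks = FALSE)
    obs <- observable_series(sim)
    keep <- obs$time > t_min & obs$time <= t_max
    rep_means[r, ] <- colMeans(obs[keep, c("D", "P", "M")])
    P_samples[[r]] <- obs$P[keep]
    M_samples[[r]] <- obs$M[keep]
    if (diagnostics) {
      dg <- diagnostic_series(sim)
      dkeep <- dg$time > t_min & dg$time <= t_max
      diag_means[r, ] <- c(mean(dg$dmin[dkeep]), mean(dg$dfnn[dkeep]),
                           mean(dg$mean_nn_dist[dkeep]))
    }
  }
  out <- list(gamma_att = gamma_att, gamma_ali = gamma_ali,
              replicates = replicates,
              mean_D = mean(rep_means[, "D"]),
              mean_P = mean(rep_means[, "P"]),
              mean_M = mean(rep_means[, "M"]),
              se_P = stats::sd(rep_means[, "P"]) / sqrt(replicates),
              se_M = stats::sd(rep_means[, "M"]) / sqrt(replicates),
              replicate_means = rep_means,
              P_samples = unlist(P_samples),
              M_samples = unlist(M_samples))
  if (diagnostics) {
    out$mean_dmin <- mean(diag_means[, "dmin"])
    out$mean_dfnn <- mean(diag_means[, "dfnn"])
    out$mean_nn_dist <- mean(diag_means[, "nn"])
  }
  out
}

#' Sweep a (gamma_att, gamma_ali) grid into a phase diagram
#'
#' Evaluates [run_cell()] on every grid point and classifies each cell with
#' [classify_phase()]. Cells are independent: replicate r of cell (i, j)
#' always gets the same seed regardless of evaluation order.
#'
#' @param gamma_att_grid,gamma_ali_grid numeric vectors of strengths.
#' @param d_threshold dispersion threshold for phase classification, metres.
#' @param seed_base base seed; cell (i, j) replicate seeds start at
#'   `seed_base + ((i - 1) * length(gamma_ali_grid) + (j - 1)) * replicates`.
#' @param ... further arguments passed to [run_cell()].
#' @param replicates replicates per cell.
#' @return a `phase_grid` data frame with columns `gamma_att`, `gamma_ali`,
#'   `mean_D`, `mean_P`, `mean_M`, `se_P`, `se_M`, `phase_label`,
#'   `n_replicates`.
#' @export
sweep_phase_diagram <- function(gamma_att_grid, gamma_ali_grid,
                                replicates = 20L, d_threshold = 5,
                                seed_base = 1L, ...) {
  cells <- expand.grid(gamma_ali = gamma_ali_grid,
                       gamma_att = gamma_att_grid)[, 2:1]
  rows <- vector("list", nrow(cells))
  for (idx in seq_len(nrow(cells))) {
    cell <- run_cell(cells$gamma_att[idx], cells$gamma_ali[idx],
                     replicates = replicates,
                     seed_base = seed_base + (idx - 1L) * replicates, ...)
    rows[[idx]] <- data.frame(
      gamma_att = cell$gamma_att, gamma_ali = cell$gamma_ali,
      mean_D = cell$mean_D, mean_P = cell$mean_P, mean_M = cell$mean_M,
      se_P = cell$se_P, se_M = cell$se_M,
      phase_label = classify_phase(cell$mean_P, cell$mean_M, cell$mean_D,
                                   d_threshold = d_threshold),
      n_replicates = replicates)
  }
  out <- do.call(rbind, rows)
  attr(out, "d_threshold") <- d_threshold
  class(out) <- c("phase_grid", "data.frame")
  out
}

#' Write a phase grid to TSV
#'
#' @param grid a `phase_grid` from [sweep_phase_diagram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phase_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Plot a phase diagram
#'
#' Colored raster of the phase labels over the `(gamma_att, gamma_ali)`
#' grid: Schooling red, Milling blue, Intermittent cyan, Swarming green,
#' Dispersion gray.
#'
#' @param x a `phase_grid`.
#' @param ... ignored.
#' @export
plot.phase_grid <- function(x, ...) {
  cols <- c(Schooling = "red3", Milling = "blue3", Intermittent = "cyan3",
            Swarming = "green4", Dispersion = "gray60")
  ga <- sort(unique(x$gamma_att)); gl <- sort(unique(x$gamma_ali))
  z <- matrix(NA_integer_, length(ga), length(gl))
  lev <- names(cols)
  z[cbind(match(x$gamma_att, ga), match(x$gamma_ali, gl))] <-
    match(x$phase_label, lev)
  graphics::image(ga, gl, z, col = cols, zlim = c(1, 5),
                  xlab = expression(gamma[Att]),
                  ylab = expression(gamma[Ali]), main = "Collective phases")
  present <- lev[sort(unique(as.vector(z)))]
  graphics::legend("topright", legend = present, fill = cols[present],
                   bg = "white", cex = 0.8)
  invisible(x)
}

#' Cut through the phase diagram with per-point PDFs
#'
#' Fixes one interaction strength and varies the other, pooling the
#' post-transient polarization and milling samples at each point into
#' normalized histograms. Bimodal PDFs expose the intermittent
#' (bistable) band where the school alternates between schooling and
#' milling.
#'
#' @param gamma_att,gamma_ali one scalar and one numeric vector; the vector
#'   axis is the cut.
#' @param breaks histogram breaks for [pdf_along_cut()].
#' @param seed_base base seed (per-point seed blocks as in
#'   [sweep_phase_diagram()]).
#' @param replicates replicates per point.
#' @param ... passed to [run_cell()].
#' @return list of per-point results, each with `gamma_att`, `gamma_ali`,
#'   `mean_P`, `mean_M`, `pdf_P`, `pdf_M` and the cell averages.
#' @export
cut_analysis <- function(gamma_att, gamma_ali, replicates = 20L,
                         breaks = seq(0, 1, length.out = 51),
                         seed_base = 1L, ...) {
  stop_unless(xor(length(gamma_att) > 1, length(gamma_ali) > 1) ||
                (length(gamma_att) == 1 && length(gamma_ali) == 1),
              "exactly one of gamma_att / gamma_ali may be a vector")
  pts <- data.frame(gamma_att = gamma_att, gamma_ali = gamma_ali)
  out <- vector("list", nrow(pts))
  for (idx in seq_len(nrow(pts))) {
    cell <- run_cell(pts$gamma_att[idx], pts$gamma_ali[idx],
                     replicates = replicates,
                     seed_base = seed_base + (idx - 1L) * replicates, ...)
    out[[idx]] <- list(gamma_att = cell$gamma_att,
                       gamma_ali = cell$gamma_ali,
                       mean_P = mean(cell$P_samples),
                       mean_M = mean(cell$M_samples),
                       pdf_P = pdf_along_cut(cell$P_samples, breaks),
                       pdf_M = pdf_along_cut(cell$M_samples, breaks),
                       cell = cell)
  }
  out
}

#' Density map of influential-neighbor positions in the focal frame
#'
#' Accumulates, over all kick events of one or more runs, the position of
#' the rank-1 (or rank-2) most influential neighbor in the focal fish's
#' frame (focal at the origin, heading pointing north), into square bins.
#' The histogram mass is normalized to 1.
#'
#' @param sims a `school_sim` or list of them, simulated with
#'   `record_neighbors = TRUE`.
#' @param rank 1 (most influential) or 2 (second most influential).
#' @param bin bin side, metres (0.01 m).
#' @param half_width map half-width, metres; events outside are dropped.
#' @param t_min discard kicks at or before this time, seconds.
#' @return list with `x_breaks`, `y_breaks`, `density` (matrix, sums to 1),
#'   `n_events`, and `front_mass` (fraction of mass ahead of the focal
#'   fish, y > 0).
#' @export
influential_position_density <- function(sims, rank = 1, bin = 0.01,
                                         half_width = 0.5, t_min = 0) {
  if (inherits(sims, "school_sim")) sims <- list(sims)
  rx <- numeric(0); ry <- numeric(0)
  for (sim in sims) {
    kk <- sim$kicks
    stop_unless(!is.null(kk) && !is.null(kk$rel_x1),
                "simulate with record_neighbors = TRUE")
    keep <- kk$time > t_min
    if (rank == 1) { rx <- c(rx, kk$rel_x1[keep]); ry <- c(ry, kk$rel_y1[keep]) }
    else { rx <- c(rx, kk$rel_x2[keep]); ry <- c(ry, kk$rel_y2[keep]) }
  }
  ok <- !is.na(rx) & abs(rx) < half_width & abs(ry) < half_width
  rx <- rx[ok]; ry <- ry[ok]
  stop_unless(length(rx) > 0, "no recorded neighbor positions")
  breaks <- seq(-half_width, half_width, by = bin)
  ix <- findInterval(rx, breaks, rightmost.closed = TRUE)
  iy <- findInterval(ry, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  dens <- matrix(0, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)),
               factor(iy, levels = seq_len(nb)))
  dens[] <- as.numeric(tab) / length(rx)
  list(x_breaks = breaks, y_breaks = breaks, density = dens,
       n_events = length(rx), front_mass = mean(ry > 0))
}

#' Locate the dispersion-to-cohesion transition
#'
#' Scans the attraction strength upward at fixed alignment strength and
#' reports the smallest `gamma_att` at which the post-transient mean
#' dispersion stays bounded (below `d_threshold`) instead of growing with
#' run length: the critical attraction below which the school breaks up.
#'
#' @param gamma_att_grid increasing vector of attraction strengths.
#' @param gamma_ali fixed alignment strength.
#' @param d_threshold cohesion criterion on mean dispersion, metres.
#' @param seed_base base seed (per-point blocks).
#' @param replicates replicates per scan point.
#' @param ... passed to [run_cell()].
#' @return list with `gamma_crit` (NA if never cohesive) and `table`
#'   (per-point mean dispersion).
#' @export
cohesion_threshold_scan <- function(gamma_att_grid, gamma_ali = 0.1,
                                    replicates = 3L, d_threshold = 5,
                                    seed_base = 1L, ...) {
  stopifnot(!is.unsorted(gamma_att_grid))
  mean_D <- numeric(length(gamma_att_grid))
  for (idx in seq_along(gamma_att_grid)) {
    cell <- run_cell(gamma_att_grid[idx], gamma_ali,
                     replicates = replicates,
                     seed_base = seed_base + (idx - 1L) * replicates, ...)
    mean_D[idx] <- cell$mean_D
  }
  cohesive <- mean_D < d_threshold
  list(gamma_crit = if (any(cohesive)) gamma_att_grid[which(cohesive)[1]]
                    else NA_real_,
       table = data.frame(gamma_att = gamma_att_grid, mean_D = mean_D,
                          cohesive = cohesive))
}

#' Scan for the attraction strength minimizing nearest-neighbor distance
#'
#' Increasing the attraction strength first tightens the school, then (by
#' inducing excessive, effectively random turns) loosens it again: the mean
#' nearest-neighbor distance has an interior minimum in `gamma_att`. Scans a
#' grid and returns the argmin (ties to the first grid point).
#'
#' @param gamma_att_grid vector of attraction strengths.
#' @param gamma_ali fixed alignment strength.
#' @param seed_base base seed (per-point blocks).
#' @param replicates replicates per point.
#' @param ... passed to [run_cell()].
#' @return list with `gamma_opt`, `min_nn_dist` and `table` of per-point
#'   mean nearest-neighbor distances.
#' @export
optimal_attraction_scan <- function(gamma_att_grid, gamma_ali = 0.1,
                                    replicates = 3L, seed_base = 1L, ...) {
  nn <- numeric(length(gamma_att_grid))
  for (idx in seq_along(gamma_att_grid)) {
    cell <- run_cell(gamma_att_grid[idx], gamma_ali,
                     replicates = replicates,
                     seed_base = seed_base + (idx - 1L) * replicates,
                     diagnostics = TRUE, ...)
    nn[idx] <- cell$mean_nn_dist
  }
  best <- which.min(nn)
  list(gamma_opt = gamma_att_grid[best], min_nn_dist = nn[best],
       table = data.frame(gamma_att = gamma_att_grid, mean_nn_dist = nn))
}

#' Experiment presets
#'
#' `"full"`: the full study protocol (20 replicates of 2000 kicks per fish,
#' first 100 kicks discarded). `"quick"`: a desk-scale protocol with the
#' identical code path (5 replicates of 600 kicks, first 100 discarded).
#'
#' @param name `"full"` or `"quick"`.
#' @return list of [run_cell()] arguments.
#' @export
experiment_preset <- function(name = c("quick", "full")) {
  name <- match.arg(name)
  if (name == "full")
    list(replicates = 20L, n_kicks_per_fish = 2000L, transient_kicks = 100L)
  else
    list(replicates = 5L, n_kicks_per_fish = 600L, transient_kicks = 100L)
}
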