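#' School snapshot
#'
#' The state of the whole school at one sampling instant: positions,
#' headings and instantaneous speeds of the N fish.
#'
#' @param time time, seconds.
#' @param positions N x 2 matrix, metres.
#' @param headings length-N vector, radians.
#' @param speeds length-N vector, m/s, >= 0.
#' @return an object of class `school_snapshot`.
#' @export
school_snapshot <- function(time, positions, headings, speeds) {
  positions <- as.matrix(positions)
  stop_unless(ncol(positions) == 2, "positions must be an N x 2 matrix")
  n <- nrow(positions)
  stop_unless(length(headings) == n, "headings must have one entry per fish")
  stop_unless(length(speeds) == n, "speeds must have one entry per fish")
  stop_unless(all(speeds >= 0), "speeds must be >= 0")
  structure(list(time = time, positions = positions,
                 headings = wrap_angle(headings), speeds = speeds),
            class = "school_snapshot")
}

#' Extract one snapshot from a simulation
#'
#' @param sim a `school_sim` object.
#' @param index snapshot index (1 to number of sampling instants).
#' @return a [school_snapshot()].
#' @export
get_snapshot <- function(sim, index) {
  sn <- sim$snapshots
  school_snapshot(sn$times[index],
                  cbind(sn$x[index, ], sn$y[index, ]),
                  sn$heading[index, ], sn$speed[index, ])
}

#' Barycenter of the school
#'
#' Arithmetic mean of positions and of velocity vectors
#' (speed times heading unit vector); the barycenter heading is the angle of
#' the mean velocity. A vanishing mean velocity leaves the heading undefined:
#' it is returned as 0 with `degenerate = TRUE`.
#'
#' @param snapshot a [school_snapshot()].
#' @return list with `position`, `velocity`, `heading`, `degenerate`.
#' @export
barycenter <- function(snapshot) {
  pos <- colMeans(snapshot$positions)
  vx <- snapshot$speeds * cos(snapshot$headings)
  vy <- snapshot$speeds * sin(snapshot$headings)
  vel <- c(mean(vx), mean(vy))
  # numerically zero mean velocity (relative to the speed scale) leaves the
  # barycenter heading undefined
  degenerate <- sqrt(sum(vel^2)) <= 1e-12 * max(mean(snapshot$speeds), 1e-300)
  list(position = pos, velocity = vel,
       heading = if (degenerate) 0 else atan2(vel[2], vel[1]),
       degenerate = degenerate)
}

#' Dispersion of the school
#'
#' Root-mean-square distance of the fish to the barycenter, in metres
#' (the metre-valued phase thresholds D > 5 m / 7 m apply to this
#' convention). `square = TRUE` returns the mean squared distance instead.
#'
#' @param snapshot a [school_snapshot()].
#' @param square return the mean squared distance (m^2) instead of its root.
#' @return scalar >= 0.
#' @export
dispersion <- function(snapshot, square = FALSE) {
  u <- sweep(snapshot$positions, 2, colMeans(snapshot$positions))
  ms <- mean(rowSums(u^2))
  if (square) ms else sqrt(ms)
}

#' Polarization order parameter
#'
#' Norm of the mean heading unit vector, in \[0, 1\]: 1 when all headings
#' coincide, ~1/sqrt(N) for uncorrelated headings, 0 for exactly canceling
#' headings (e.g. half the school pointing North and half South).
#'
#' @param snapshot a [school_snapshot()].
#' @return scalar in \[0, 1\].
#' @export
polarization <- function(snapshot) {
  sqrt(mean(cos(snapshot$headings))^2 + mean(sin(snapshot$headings))^2)
}

#' Milling order parameter
#'
#' Measures coherent rotation of the school around its barycenter: the
#' absolute mean of `sin(phibar_i - thetabar_i)`, where `thetabar_i` is the
#' angle of fish i's position and `phibar_i` the angle of its velocity, both
#' in the barycenter frame (positions and velocities relative to the
#' barycenter; note the barycenter-frame heading is not the heading minus
#' the barycenter heading). 1 for a coherent vortex, 0 for radial motion or
#' canceled rotation directions. Fish exactly at the barycenter (or with
#' zero barycenter-frame velocity) have an undefined term and are excluded
#' from the mean.
#'
#' @param snapshot a [school_snapshot()] with N >= 2.
#' @return scalar in \[0, 1\].
#' @export
milling <- function(snapshot) {
  n <- nrow(snapshot$positions)
  stop_unless(n >= 2, "milling requires at least 2 fish")
  u <- sweep(snapshot$positions, 2, colMeans(snapshot$positions))
  vx <- snapshot$speeds * cos(snapshot$headings)
  vy <- snapshot$speeds * sin(snapshot$headings)
  vbx <- vx - mean(vx); vby <- vy - mean(vy)
  # sin(phibar - thetabar) = (u x v) / (|u| |v|)
  cross <- u[, 1] * vby - u[, 2] * vbx
  norm <- sqrt(rowSums(u^2)) * sqrt(vbx^2 + vby^2)
  ok <- norm > 0
  if (!any(ok)) return(0)
  abs(mean(cross[ok] / norm[ok]))
}

#' Classify the collective phase
#'
#' Maps replicate-and-time-averaged order parameters to a phase label. The
#' dispersion test is applied first: `mean_d > d_threshold` is the
#' Dispersion phase (group break-up). Otherwise: Schooling when `P >= 0.4`
#' and `M <= 0.4`; Milling when `P <= 0.4` and `M >= 0.4`; Intermittent
#' (bistable schooling/milling) when both exceed 0.4; Swarming when both
#' are below 0.4. Boundary values are resolved by the first matching rule in
#' that order.
#'
#' @param mean_p,mean_m,mean_d averaged polarization, milling, dispersion.
#' @param d_threshold dispersion threshold, metres (5 by default; 7 is used
#'   for the group-size experiments).
#' @param pm_threshold order-parameter threshold (0.4).
#' @return one of `"Dispersion"`, `"Schooling"`, `"Milling"`,
#'   `"Intermittent"`, `"Swarming"`.
#' @export
classify_phase <- function(mean_p, mean_m, mean_d, d_threshold = 5,
                           pm_threshold = 0.4) {
  if (mean_d > d_threshold) return("Dispersion")
  if (mean_p >= pm_threshold && mean_m <= pm_threshold) return("Schooling")
  if (mean_p <= pm_threshold && mean_m >= pm_threshold) return("Milling")
  if (mean_p > pm_threshold && mean_m > pm_threshold) return("Intermittent")
  "Swarming"
}

#' Nearest-neighbor distances
#'
#' @param snapshot a [school_snapshot()] with N >= 2.
#' @return list with `distances` (per fish, min distance to any other),
#'   `nearest` (the neighbor attaining it, distance ties broken by lowest
#'   id) and `mean`.
#' @export
nearest_neighbor_distance <- function(snapshot) {
  dm <- as.matrix(stats::dist(snapshot$positions))
  diag(dm) <- Inf
  nearest <- max.col(-dm, ties.method = "first")
  d <- dm[cbind(seq_len(nrow(dm)), nearest)]
  list(distances = d, nearest = nearest, mean = mean(d))
}

# most influential neighbor (k = 1 rule) of every fish, vectorized over the
# full N x N relative-state matrices; ties by lowest neighbor id
most_influential_map <- function(snapshot, params) {
  x <- snapshot$positions[, 1]; y <- snapshot$positions[, 2]
  phi <- snapshot$headings
  n <- length(x)
  dx <- outer(x, x, function(a, b) b - a)   # dx[i, j] = x_j - x_i
  dy <- outer(y, y, function(a, b) b - a)
  d <- sqrt(dx^2 + dy^2)
  psi <- wrap_angle(atan2(dy, dx) - phi)    # phi recycles down columns = rows i
  psi[d == 0] <- 0
  phir <- wrap_angle(outer(phi, phi, function(a, b) b - a))
  p <- params
  fatt <- p$gamma_att * (d / p$d_att - 1) / (1 + (d / p$l_att)^2)
  fali <- p$gamma_ali * (d / p$d_ali + 1) * exp(-(d / p$l_ali)^2)
  infl <- abs(fatt * o_att(psi) * e_att(phir) +
              fali * e_ali(psi) * o_ali(phir))
  diag(infl) <- -Inf
  max.col(infl, ties.method = "first")
}

#' Number of distinct most-influential neighbors (DMIN)
#'
#' Identifies, for each fish, its single most influential neighbor (the
#' k = 1 selection rule) at the snapshot instant, and counts the distinct
#' identities among those N choices. A low count means influence is
#' concentrated on few individuals.
#'
#' @param snapshot a [school_snapshot()] with N >= 2.
#' @param params an [interaction_params()] object.
#' @return integer in 1..N.
#' @export
count_distinct_influential <- function(snapshot, params) {
  length(unique(most_influential_map(snapshot, params)))
}

#' Number of distinct first nearest neighbors (DFNN)
#'
#' As [count_distinct_influential()] with the nearest neighbor (argmin of
#' distance, ties by lowest id) in place of the most influential one.
#'
#' @param snapshot a [school_snapshot()] with N >= 2.
#' @return integer in 1..N.
#' @export
count_distinct_nearest <- function(snapshot) {
  length(unique(nearest_neighbor_distance(snapshot)$nearest))
}

#' Partition the school into 3-nearest-neighbor groups
#'
#' Recursive partition used to count sub-schools: seed a group with the
#' lowest-id unassigned fish, add its three nearest neighbors, then the
#' three nearest neighbors of each newly added fish, and so on; the group is
#' complete when an iteration adds no new fish. Repeat with the next
#' unassigned fish. The 3-nearest-neighbor relation is computed once over
#' the whole school (distance ties by lowest id); fish already assigned to
#' an earlier group are not re-assigned, and any resulting group with fewer
#' than 4 members is merged into the group of its nearest assigned neighbor,
#' so every returned group has at least 4 members (when N >= 4).
#'
#' @param snapshot a [school_snapshot()] with N >= 4.
#' @return list of integer vectors (disjoint cover of 1..N).
#' @export
three_group_partition <- function(snapshot) {
  n <- nrow(snapshot$positions)
  stop_unless(n >= 4, "three_group_partition requires N >= 4")
  dm <- as.matrix(stats::dist(snapshot$positions))
  diag(dm) <- Inf
  # global 3-nearest-neighbor relation
  nn3 <- lapply(seq_len(n), function(i) order(dm[i, ], seq_len(n))[1:3])
  assigned <- integer(n)   # 0 = unassigned, else group number
  g <- 0L
  while (any(assigned == 0L)) {
    g <- g + 1L
    seed <- which(assigned == 0L)[1]
    assigned[seed] <- g
    frontier <- seed
    while (length(frontier)) {
      cand <- unique(unlist(nn3[frontier]))
      new_members <- cand[assigned[cand] == 0L]
      assigned[new_members] <- g
      frontier <- sort(new_members)
    }
  }
  # merge undersized groups into the group of their nearest assigned neighbor
  repeat {
    sizes <- tabulate(assigned, g)
    small <- which(sizes > 0 & sizes < 4)
    if (!length(small) || sum(sizes > 0) == 1L) break
    gi <- small[1]
    members <- which(assigned == gi)
    others <- which(assigned != gi)
    host_fish <- others[which.min(apply(dm[members, others, drop = FALSE],
                                        2, min))]
    assigned[members] <- assigned[host_fish]
  }
  groups <- split(seq_len(n), assigned)
  unname(groups[order(vapply(groups, min, numeric(1)))])
}

#' Histogram PDF of pooled order-parameter samples
#'
#' Normalized histogram (density integrating to 1) of pooled post-transient
#' samples of an order parameter, plus the pooled mean. Used to build the
#' per-parameter-point PDFs of the phase-diagram cuts, where bimodality
#' reveals intermittent (bistable) schooling/milling.
#'
#' @param samples numeric vector of pooled samples.
#' @param breaks histogram breaks (passed to [graphics::hist()]); the
#'   default covers \[0, 1\] in 50 bins.
#' @return list with `mids`, `density`, `counts`, `mean`.
#' @export
pdf_along_cut <- function(samples, breaks = seq(0, 1, length.out = 51)) {
  stop_unless(length(samples) > 0, "no samples")
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, counts = h$counts,
       mean = mean(samples))
}

# location of the dominant histogram mode above a floor (used for the upper
# mode of bimodal polarization PDFs); ties broken toward the lower bin
pdf_mode <- function(pdf, above = -Inf) {
  keep <- pdf$mids > above
  mids <- pdf$mids[keep]; dens <- pdf$density[keep]
  mids[which.max(dens)]
}

#' Observable time series of a simulation
#'
#' Dispersion D (m), polarization P and milling index M at every sampling
#' instant, computed from the recorded snapshots.
#'
#' @param sim a `school_sim` object.
#' @return data frame with columns `time`, `D`, `P`, `M`.
#' @export
observable_series <- function(sim) {
  sn <- sim$snapshots
  x <- sn$x; y <- sn$y; h <- sn$heading; v <- sn$speed
  ux <- x - rowMeans(x); uy <- y - rowMeans(y)
  D <- sqrt(rowMeans(ux^2 + uy^2))
  P <- sqrt(rowMeans(cos(h))^2 + rowMeans(sin(h))^2)
  vx <- v * cos(h); vy <- v * sin(h)
  vbx <- vx - rowMeans(vx); vby <- vy - rowMeans(vy)
  cross <- ux * vby - uy * vbx
  norm <- sqrt(ux^2 + uy^2) * sqrt(vbx^2 + vby^2)
  s <- cross / norm
  s[norm == 0] <- NA             # degenerate terms excluded from the mean
  M <- abs(rowMeans(s, na.rm = TRUE))
  M[is.nan(M)] <- 0
  data.frame(time = sn$times, D = D, P = P, M = M)
}

#' Diagnostic time series of a simulation
#'
#' Per-snapshot information-flow and spatial diagnostics: number of distinct
#' most-influential neighbors (DMIN, k = 1 rule), number of distinct first
#' nearest neighbors (DFNN), mean nearest-neighbor distance, and number of
#' 3-nearest-neighbor groups.
#'
#' @param sim a `school_sim` object.
#' @param params interaction parameters for the influence computation;
#'   defaults to the simulation's own.
#' @param groups also compute the 3-group count (slower)?
#' @return data frame with columns `time`, `dmin`, `dfnn`, `mean_nn_dist`
#'   and (if `groups`) `n_groups`.
#' @export
diagnostic_series <- function(sim, params = sim$config$params,
                              groups = FALSE) {
  sn <- sim$snapshots
  nt <- length(sn$times)
  dmin <- integer(nt); dfnn <- integer(nt); nnd <- numeric(nt)
  ngr <- if (groups) integer(nt) else NULL
  for (r in seq_len(nt)) {
    mi <- cpp_most_influential(sn$x[r, ], sn$y[r, ], sn$heading[r, ],
                               params$gamma_att, params$gamma_ali,
                               params$l_att, params$l_ali,
                               params$d_att, params$d_ali)
    dmin[r] <- length(unique(mi))
    snap <- get_snapshot(sim, r)
    nn <- nearest_neighbor_distance(snap)
    dfnn[r] <- length(unique(nn$nearest))
    nnd[r] <- nn$mean
    if (groups) ngr[r] <- length(three_group_partition(snap))
  }
  out <- data.frame(time = sn$times, dmin = dmin, dfnn = dfnn,
                    mean_nn_dist = nnd)
  if (groups) out$n_groups <- ngr
  out
}
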