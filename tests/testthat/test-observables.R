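# Collective-state observables on analytic fixtures and random snapshots.

test_that("barycenter averages positions and velocities", {
  snap <- school_snapshot(0, rbind(c(-1, 0), c(1, 0)), c(pi / 2, pi / 2),
                          c(0.1, 0.1))
  b <- barycenter(snap)
  expect_equal(b$position, c(0, 0))
  expect_equal(b$heading, pi / 2)
  expect_false(b$degenerate)
  # symmetric milling ring: velocities cancel, heading degenerate
  b <- barycenter(school_fixture("ring", n = 4))
  expect_equal(b$velocity, c(0, 0), tolerance = 1e-15)
  expect_true(b$degenerate)
  # random snapshot against direct summation
  set.seed(10)
  snap <- random_snapshot(17)
  b <- barycenter(snap)
  expect_equal(b$position, colMeans(snap$positions), tolerance = 1e-12)
  expect_equal(b$velocity,
               c(mean(snap$speeds * cos(snap$headings)),
                 mean(snap$speeds * sin(snap$headings))), tolerance = 1e-12)
})

test_that("dispersion is the RMS distance to the barycenter", {
  snap <- school_snapshot(0, rbind(c(0, 0), c(0, 0)), c(0, 0), c(1, 1))
  expect_equal(dispersion(snap), 0)
  snap <- school_snapshot(0, rbind(c(-1, 0), c(1, 0)), c(0, 0), c(1, 1))
  expect_equal(dispersion(snap), 1)
  # unit square corners: RMS distance sqrt(1/2)
  snap <- school_snapshot(0, rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                          rep(0, 4), rep(1, 4))
  expect_equal(dispersion(snap), sqrt(0.5), tolerance = 1e-12)
  expect_equal(dispersion(snap, square = TRUE), 0.5, tolerance = 1e-12)
})

test_that("polarization handles aligned, antiparallel and symmetric cases", {
  expect_equal(polarization(school_fixture("line", n = 5)), 1)
  expect_equal(polarization(school_fixture("antiparallel", n = 6)), 0,
               tolerance = 1e-12)
  snap <- school_snapshot(0, matrix(0, 4, 2),
                          c(0, pi / 2, pi, 3 * pi / 2), rep(1, 4))
  expect_equal(polarization(snap), 0, tolerance = 1e-12)
})

test_that("milling index is 1 on a vortex, 0 for radial or canceled motion", {
  expect_equal(milling(school_fixture("ring", n = 4)), 1, tolerance = 1e-12)
  expect_equal(milling(school_fixture("ring", n = 4, clockwise = TRUE)), 1,
               tolerance = 1e-12)
  # radial outward motion
  th <- 2 * pi * (0:3) / 4
  snap <- school_snapshot(0, cbind(cos(th), sin(th)), th, rep(0.1, 4))
  expect_equal(milling(snap), 0, tolerance = 1e-12)
  # two fish clockwise, two counter-clockwise: rotation cancels
  hd <- wrap_angle(th + c(pi / 2, -pi / 2, pi / 2, -pi / 2))
  snap <- school_snapshot(0, cbind(cos(th), sin(th)), hd, rep(0.1, 4))
  expect_equal(milling(snap), 0, tolerance = 1e-12)
})

test_that("order parameters are bounded and rigid-motion invariant", {
  set.seed(31)
  for (trial in 1:10) {
    snap <- random_snapshot(sample(3:30, 1))
    P <- polarization(snap); M <- milling(snap); D <- dispersion(snap)
    expect_true(P >= 0 && P <= 1)
    expect_true(M >= 0 && M <= 1)
    expect_gte(D, 0)
    moved <- transform_snapshot(snap, runif(1, -pi, pi), runif(2, -5, 5))
    expect_equal(polarization(moved), P, tolerance = 1e-12)
    expect_equal(milling(moved), M, tolerance = 1e-12)
    expect_equal(dispersion(moved), D, tolerance = 1e-12)
  }
})

test_that("random headings give polarization decaying like 1/sqrt(N)", {
  # for uncorrelated headings E[P] ~ sqrt(pi) / (2 sqrt(N)); check the
  # scaling empirically rather than asserting the exponent analytically
  set.seed(77)
  mean_P <- function(n) mean(replicate(400, {
    h <- runif(n, -pi, pi)
    sqrt(mean(cos(h))^2 + mean(sin(h))^2)
  }))
  p25 <- mean_P(25); p100 <- mean_P(100); p400 <- mean_P(400)
  expect_gt(p25, p100)
  expect_gt(p100, p400)
  expect_equal(p100 / p400, 2, tolerance = 0.2)
  expect_equal(p100, sqrt(pi) / 2 / sqrt(100), tolerance = 0.1)
})

test_that("phase classification applies the dispersion test first", {
  expect_equal(classify_phase(0.9, 0.22, 0.2), "Schooling")
  expect_equal(classify_phase(0.16, 0.6, 0.3), "Milling")
  expect_equal(classify_phase(0.2, 0.2, 10), "Dispersion")
  expect_equal(classify_phase(0.2, 0.2, 0.5), "Swarming")
  expect_equal(classify_phase(0.7, 0.6, 0.5), "Intermittent")
  # boundary values resolve by rule order: Schooling, Milling, then the rest
  expect_equal(classify_phase(0.4, 0.4, 0.5), "Schooling")
  expect_equal(classify_phase(0.3, 0.4, 0.5), "Milling")
  # group-size experiments use the 7 m threshold
  expect_equal(classify_phase(0.2, 0.2, 6, d_threshold = 7), "Swarming")
})

test_that("nearest-neighbor distances match the exhaustive oracle", {
  snap <- school_snapshot(0, rbind(c(0, 0), c(0.3, 0)), c(0, 0), c(1, 1))
  nn <- nearest_neighbor_distance(snap)
  expect_equal(nn$distances, c(0.3, 0.3))
  expect_equal(nn$mean, 0.3)
  # equilateral triangle
  snap <- school_snapshot(0, rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                          rep(0, 3), rep(1, 3))
  expect_equal(nearest_neighbor_distance(snap)$distances, rep(1, 3),
               tolerance = 1e-12)
  # random snapshot: brute force over all pairs
  set.seed(5)
  snap <- random_snapshot(20)
  nn <- nearest_neighbor_distance(snap)
  for (i in 1:20) {
    d <- sqrt(colSums((t(snap$positions) - snap$positions[i, ])^2))
    d[i] <- Inf
    expect_equal(nn$distances[i], min(d), tolerance = 1e-12)
    expect_equal(nn$nearest[i], which.min(d))
  }
})

test_that("DMIN counts distinct most-influential neighbors", {
  p <- study_params(0.1, 0.1)
  # three fish where the argmax map is {1->2, 2->1, 3->1}: 2 distinct
  set.seed(8)
  for (trial in 1:8) {
    snap <- random_snapshot(15, spread = 0.4)
    # exhaustive oracle via select_influential (k = 1)
    choices <- sapply(1:15, function(i)
      select_influential(i, snap$positions, snap$headings,
                         study_params(0.1, 0.1, k = 1L))$ids)
    expect_equal(count_distinct_influential(snap, p),
                 length(unique(choices)))
    # compiled bulk path agrees with the R path
    mi <- burstcoast:::cpp_most_influential(
      snap$positions[, 1], snap$positions[, 2], snap$headings,
      p$gamma_att, p$gamma_ali, p$l_att, p$l_ali, p$d_att, p$d_ali)
    expect_identical(as.integer(choices), mi)
  }
  expect_true(count_distinct_influential(random_snapshot(10), p) >= 1)
})

test_that("DFNN counts distinct nearest neighbors", {
  snap <- school_snapshot(0, rbind(c(0, 0), c(0.3, 0)), c(0, 0), c(1, 1))
  expect_equal(count_distinct_nearest(snap), 2)
  # collinear fish at 0, 1, 3: map {1->2, 2->1, 3->2}
  snap <- school_snapshot(0, cbind(c(0, 1, 3), c(0, 0, 0)), rep(0, 3),
                          rep(1, 3))
  expect_equal(count_distinct_nearest(snap), 2)
  set.seed(14)
  snap <- random_snapshot(25)
  nn <- nearest_neighbor_distance(snap)
  expect_equal(count_distinct_nearest(snap), length(unique(nn$nearest)))
  expect_true(count_distinct_nearest(snap) <= 25)
})

test_that("3-group partition covers the school with groups of >= 4", {
  # N = 4: a single group
  set.seed(20)
  snap <- random_snapshot(4)
  groups <- three_group_partition(snap)
  expect_length(groups, 1)
  expect_setequal(groups[[1]], 1:4)
  # two tight clusters far apart: exactly two groups
  cl <- rbind(cbind(runif(4, 0, 0.01), runif(4, 0, 0.01)),
              cbind(runif(4, 1, 1.01), runif(4, 1, 1.01)))
  snap <- school_snapshot(0, cl, rep(0, 8), rep(1, 8))
  groups <- three_group_partition(snap)
  expect_length(groups, 2)
  expect_setequal(groups[[1]], 1:4)
  expect_setequal(groups[[2]], 5:8)
  # random snapshots: disjoint cover, sizes >= 4, count <= N/4
  for (trial in 1:10) {
    n <- sample(5:40, 1)
    snap <- random_snapshot(n)
    groups <- three_group_partition(snap)
    expect_setequal(unlist(groups), seq_len(n))
    expect_equal(length(unlist(groups)), n)       # disjoint
    expect_true(all(lengths(groups) >= 4))
    expect_lte(length(groups), floor(n / 4))
  }
})

test_that("pooled PDFs normalize and expose bimodality", {
  # constant series: one occupied bin
  pdf <- pdf_along_cut(rep(0.42, 100))
  expect_equal(sum(pdf$counts > 0), 1)
  expect_equal(pdf$mean, 0.42)
  expect_equal(sum(pdf$density * diff(seq(0, 1, length.out = 51))), 1,
               tolerance = 1e-12)
  # balanced mixture near 0.2 and 0.95: two local maxima
  set.seed(3)
  x <- c(rnorm(500, 0.2, 0.02), rnorm(500, 0.95, 0.015))
  x <- pmin(pmax(x, 0), 1)
  pdf <- pdf_along_cut(x)
  dens <- pdf$density
  local_max <- which(diff(sign(diff(c(-1, dens, -1)))) == -2)
  expect_gte(length(local_max[dens[local_max] > 1]), 2)
  expect_equal(burstcoast:::pdf_mode(pdf, above = 0.5), 0.95,
               tolerance = 0.02)
  # uniform samples: flat density
  set.seed(4)
  pdf <- pdf_along_cut(runif(4e5))
  expect_true(all(abs(pdf$density - 1) < 0.05))
  expect_error(pdf_along_cut(numeric(0)), "no samples")
})

test_that("observable series agrees with per-snapshot computation", {
  cfg <- small_config(n_fish = 8, n_kicks = 40, seed = 13,
                      params = study_params(0.05, 0.1), gamma_r = 0.2,
                      mode = "sampled")
  sim <- simulate_school(cfg)
  obs <- observable_series(sim)
  expect_true(all(obs$P >= 0 & obs$P <= 1))
  expect_true(all(obs$M >= 0 & obs$M <= 1))
  expect_true(all(obs$D >= 0))
  for (r in c(1, 5, nrow(obs))) {
    snap <- get_snapshot(sim, r)
    expect_equal(obs$D[r], dispersion(snap), tolerance = 1e-12)
    expect_equal(obs$P[r], polarization(snap), tolerance = 1e-12)
    expect_equal(obs$M[r], milling(snap), tolerance = 1e-12)
  }
  dg <- diagnostic_series(sim, groups = TRUE)
  expect_equal(nrow(dg), nrow(obs))
  expect_true(all(dg$dmin >= 1 & dg$dmin <= 8))
  expect_true(all(dg$dfnn >= 1 & dg$dfnn <= 8))
  expect_equal(dg$dmin[3], count_distinct_influential(
    get_snapshot(sim, 3), sim$config$params))
  expect_equal(dg$dfnn[3], count_distinct_nearest(get_snapshot(sim, 3)))
})
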