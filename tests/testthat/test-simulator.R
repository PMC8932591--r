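# Event-driven simulation engine: determinism, conservation laws,
# degenerate cases, symmetry, and equivalence with the fixed-step reference.

test_that("runs are deterministic and seeds matter", {
  cfg <- small_config(n_fish = 5, n_kicks = 40, seed = 11, mode = "sampled")
  s1 <- simulate_school(cfg)
  s2 <- simulate_school(cfg)
  expect_identical(s1, s2)
  cfg2 <- small_config(n_fish = 5, n_kicks = 40, seed = 12, mode = "sampled")
  s3 <- simulate_school(cfg2)
  expect_false(identical(s1$kicks, s3$kicks))
})

test_that("event count and per-fish kick budget are conserved", {
  cfg <- small_config(n_fish = 4, n_kicks = 30, seed = 5)
  sim <- simulate_school(cfg)
  expect_equal(nrow(sim$kicks), 4 * 30)
  # fixed kick statistics: every fish performs exactly n_kicks kicks,
  # finishing at first-onset + n_kicks * 0.5 s
  expect_equal(sim$kick_count, rep(30, 4))
  ends <- sim$final$kick_start
  expect_equal(ends, sim$init$kick_start + 30 * 0.5, tolerance = 1e-9)
  expect_true(!is.unsorted(sim$kicks$time))
})

test_that("a lone fish takes noise-only turns and straight glides", {
  cfg <- small_config(n_fish = 1, n_kicks = 50, seed = 8, gamma_r = 0.3)
  sim <- simulate_school(cfg)
  expect_true(all(sim$kicks$dphi_social == 0))
  expect_true(any(sim$kicks$dphi_noise != 0))
  # consecutive kick displacements each have length one kick
  k <- sim$kicks
  step <- sqrt(diff(k$x)^2 + diff(k$y)^2)
  expect_equal(step, rep(0.07, length(step)), tolerance = 1e-12)
})

test_that("zero interactions and zero noise freeze every heading", {
  cfg <- small_config(n_fish = 6, n_kicks = 20, seed = 3,
                      params = study_params(0, 0), gamma_r = 0)
  sim <- simulate_school(cfg)
  expect_equal(sim$kicks$heading_new, sim$kicks$heading_old)
  obs <- observable_series(sim)
  expect_equal(obs$P, rep(obs$P[1], nrow(obs)), tolerance = 1e-12)
})

test_that("total path length equals the sum of kick lengths", {
  cfg <- small_config(n_fish = 3, n_kicks = 40, seed = 21, gamma_r = 0.4)
  sim <- simulate_school(cfg)
  for (i in 1:3) {
    k <- sim$kicks[sim$kicks$fish_id == i, ]
    # kick rows hold the glide endpoint of the finished kick; the first
    # finished kick starts from the initial position
    seg <- sqrt(diff(c(sim$init$x[i], k$x))^2 +
                diff(c(sim$init$y[i], k$y))^2)
    expect_equal(sum(seg), 40 * 0.07, tolerance = 1e-9)
  }
})

test_that("simultaneous kick-end ties are processed lowest id first", {
  # fish 1 and 2 kick at exactly t = 0.5, fish 3 at t = 0.7
  res <- burstcoast:::cpp_run_school(
    c(0, 1, 2), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0.2),
    c(0.07, 0.07, 0.07), c(0.5, 0.5, 0.5),
    0, 0, 0.28, 0.28, 0.03, 0.06, 1L, 0, 0.07, 0.5, 0, FALSE, 0.8,
    6L, 1.0, TRUE, FALSE)
  k <- res$kicks
  expect_equal(k$time[1:3], c(0.5, 0.5, 0.7))
  expect_identical(k$fish_id[1:3], c(1L, 2L, 3L))
})

test_that("mirror-symmetric pair stays mirror-symmetric without noise", {
  # two fish reflected about the x axis with synchronized kicks: the social
  # turns are equal and opposite, so the reflection symmetry is conserved
  cfg <- small_config(n_fish = 2, n_kicks = 60, seed = 1,
                      params = study_params(0.08, 0.1), gamma_r = 0)
  init <- list(x = c(0, 0), y = c(0.1, -0.1), heading = c(0.4, -0.4),
               kick_start = c(0, 0), kick_length = c(0.07, 0.07),
               kick_duration = c(0.5, 0.5))
  res <- burstcoast:::cpp_run_school(
    init$x, init$y, init$heading, init$kick_start, init$kick_length,
    init$kick_duration, 0.08, 0.1, 0.28, 0.28, 0.03, 0.06, 1L,
    0, 0.07, 0.5, 0, FALSE, 0.8, 120L, 1.0, TRUE, FALSE)
  k <- res$kicks
  a <- k[k$fish_id == 1, ]; b <- k[k$fish_id == 2, ]
  expect_equal(a$x, b$x, tolerance = 1e-9)
  expect_equal(a$y, -b$y, tolerance = 1e-9)
  expect_equal(a$heading_new, -b$heading_new, tolerance = 1e-9)
})

test_that("rotating the initial condition rotates the whole trajectory", {
  cfg <- small_config(n_fish = 4, n_kicks = 40, seed = 17,
                      params = study_params(0.06, 0.12, k = 2L),
                      gamma_r = 0.2)
  ang <- 0.9
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  set.seed(cfg$seed)
  init <- init_school(cfg)
  run <- function(init) {
    set.seed(1234)  # same noise draws for both frames
    burstcoast:::cpp_run_school(
      init$x, init$y, init$heading, init$kick_start, init$kick_length,
      init$kick_duration, 0.06, 0.12, 0.28, 0.28, 0.03, 0.06, 2L,
      0.2, 0.07, 0.5, 0, FALSE, 0.8, 160L, 1.0, TRUE, FALSE)
  }
  r1 <- run(init)
  p2 <- rot %*% rbind(init$x, init$y)
  init2 <- init
  init2$x <- p2[1, ]; init2$y <- p2[2, ]
  init2$heading <- wrap_angle(init$heading + ang)
  r2 <- run(init2)
  expect_identical(r1$kicks$fish_id, r2$kicks$fish_id)
  pr <- rot %*% rbind(r1$kicks$x, r1$kicks$y)
  expect_equal(r2$kicks$x, pr[1, ], tolerance = 1e-9)
  expect_equal(r2$kicks$y, pr[2, ], tolerance = 1e-9)
  expect_equal(wrap_angle(r2$kicks$heading_new -
                            (r1$kicks$heading_new + ang)),
               rep(0, nrow(r1$kicks)), tolerance = 1e-9)
})

test_that("event engine matches the 1 ms fixed-step reference", {
  for (seed in c(4, 9)) {
    cfg <- small_config(n_fish = 3, n_kicks = 60, seed = seed,
                        params = study_params(0.05, 0.12, k = 2L),
                        gamma_r = 0.25)
    sim <- simulate_school(cfg)
    ref <- simulate_school_reference(cfg, dt = 0.001)
    expect_identical(sim$kicks$fish_id, ref$fish_id)
    expect_lt(max(abs(sim$kicks$x - ref$x), abs(sim$kicks$y - ref$y)), 1e-9)
    expect_lt(max(abs(wrap_angle(sim$kicks$heading_new -
                                   ref$heading_new))), 1e-9)
  }
})

test_that("initialization matches the disc-radius and staggering contracts", {
  cfg <- simulation_config(n_fish = 100,
                           params = study_params(0.04, 0.1),
                           n_kicks_per_fish = 300, seed = 42)
  # radius formula: sqrt(N / pi) * l_att / 2
  set.seed(42)
  init <- init_school(cfg)
  expect_equal(init$radius, sqrt(100 / pi) * 0.28 / 2, tolerance = 1e-12)
  expect_true(all(init$x^2 + init$y^2 <= init$radius^2 + 1e-12))
  expect_true(all(init$heading > -pi & init$heading <= pi))
  expect_true(all(init$kick_start >= 0 & init$kick_start < 0.5))
  # with l_att = 0.28, N = 100 the school starts within a 0.79 m disc
  expect_equal(init$radius, 0.790, tolerance = 1e-3)
})

test_that("config round-trips through YAML and JSON; unknown keys rejected", {
  cfg <- simulation_config(n_fish = 7, params = study_params(0.03, 0.2, k = 2L),
                           gamma_r = 0.3,
                           kick_stats = kick_statistics(mode = "fixed"),
                           n_kicks_per_fish = 500, seed = 9)
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_config(cfg, path)
    cfg2 <- read_config(path)
    expect_equal(cfg2, cfg)
  }
  bad <- file.path(tempdir(), "bad.yaml")
  yaml::write_yaml(list(n_fish = 5, tank_radius = 1), bad)
  expect_error(read_config(bad), "unknown config keys")
})

test_that("trajectory export writes the documented CSV and sidecar", {
  cfg <- small_config(n_fish = 3, n_kicks = 20, seed = 6)
  sim <- simulate_school(cfg)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(sim, path)
  out <- utils::read.csv(path)
  expect_identical(names(out), c("time", "fish_id", "x", "y", "heading",
                                 "speed", "event_type"))
  expect_setequal(unique(out$event_type), c("kick", "snapshot"))
  expect_equal(sum(out$event_type == "kick"), 60)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$config$seed, 6)
  expect_equal(meta$config$n_fish, 3)
})
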