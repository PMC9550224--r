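# config used by the closed-form motor tests: no boundary interference
free_cfg <- function(...) {
  sim_config("sliding", right_force = 1e-12, left_spring = 1e-12, ...)
}

pair_state <- function(cfg, x, orient, lines = c(0L, 1L)) {
  st <- init_state(cfg, seed = 1)
  st$filaments <- data.frame(
    mt_id = seq_along(x) - 1L, x_center_um = x,
    orientation = as.integer(orient), lattice_line = lines
  )
  st
}

test_that("configuration encodes the six addition models and their timers", {
  expect_equal(sim_config("sliding")$addition_interval, 1100)
  expect_equal(sim_config("templating_only")$addition_interval, 1100)
  expect_equal(sim_config("sliding_unbounded")$addition_interval, 435)
  expect_equal(sim_config("sliding_templating_unbounded")$addition_interval, 435)
  cfg6 <- sim_config("sliding_templating_unbounded")
  expect_true(cfg6$use_templating && cfg6$use_unbounded)
  expect_false(cfg6$random_gliding)
  expect_true(sim_config("unbounded_only")$random_gliding)
  expect_error(sim_config("sliding", dt = -1), "finite and > 0")
  expect_error(sim_config("flying"), "'arg' should be one of")
})

test_that("initialization places 10 non-overlapping filaments reproducibly", {
  cfg <- sim_config("sliding", seed = 3)
  st <- init_state(cfg)
  f <- st$filaments
  expect_equal(nrow(f), 10)
  expect_true(all(f$x_center_um >= 2 & f$x_center_um <= 4))
  # no same-line overlap
  for (ln in unique(f$lattice_line)) {
    xs <- sort(f$x_center_um[f$lattice_line == ln])
    if (length(xs) > 1) expect_true(all(diff(xs) >= cfg$l_mt))
  }
  expect_identical(init_state(cfg), init_state(cfg))
  # symmetric orientation over many seeds
  fr <- vapply(1:200, function(s) {
    mean(init_state(cfg, seed = s)$filaments$orientation == 1)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("an isolated filament experiences no force and does not move", {
  cfg <- sim_config("sliding")
  st <- pair_state(cfg, 10, 1, lines = 0L)
  expect_equal(bundle_velocities(st), 0)
  st2 <- step_bundle(st)
  expect_equal(st2$filaments$x_center_um, 10)
  expect_equal(st2$time, cfg$dt)
})

test_that("an antiparallel pair slides equal-and-opposite at the closed-form speed", {
  cfg <- free_cfg()
  st <- pair_state(cfg, c(10, 11), c(1, -1))
  v <- bundle_velocities(st)
  # overlap 3 um, N = chi*lambda*L motors, coupling c = N f_stall/(2 v0),
  # symmetric solution v = +-N f_stall / (xi l_mt + 2 c)
  nm <- cfg$chi * cfg$lambda_m * 3
  cc <- nm * cfg$f_stall / (2 * cfg$v0)
  v_expect <- nm * cfg$f_stall / (cfg$xi * cfg$l_mt + 2 * cc)
  expect_equal(v, c(v_expect, -v_expect), tolerance = 1e-9)
  # the minus-end-out filament moves proximally (toward the cell body)
  expect_lt(v[2], 0)
  # relative sliding speed never exceeds twice the free motor speed
  expect_lte(abs(v[1] - v[2]), 2 * cfg$v0 + 1e-9)
})

test_that("a parallel pair does not slide (drives cancel, coupling only)", {
  cfg <- free_cfg()
  st <- pair_state(cfg, c(10, 11), c(1, 1))
  expect_equal(bundle_velocities(st), c(0, 0))
  st_minus <- pair_state(cfg, c(10, 11), c(-1, -1))
  expect_equal(bundle_velocities(st_minus), c(0, 0))
})

test_that("non-adjacent or non-overlapping filaments are not coupled", {
  cfg <- free_cfg()
  # same line: never crosslinked
  st <- pair_state(cfg, c(10, 14.5), c(1, -1), lines = c(0L, 0L))
  expect_equal(bundle_velocities(st), c(0, 0))
  # adjacent lines but no x-overlap
  st2 <- pair_state(cfg, c(10, 15), c(1, -1))
  expect_equal(bundle_velocities(st2), c(0, 0))
})

test_that("the distal boundary stalls sub-threshold pushes", {
  cfg <- sim_config("sliding")
  # antiparallel pair at the tip: max drive 28 pN < 50 pN budget, so the
  # plus-end-out filament is held while the minus-end-out one retreats
  st <- pair_state(cfg, c(10, 11), c(1, -1))
  v <- bundle_velocities(st)
  expect_equal(v[1], 0, tolerance = 1e-9)
  expect_lt(v[2], 0)
})

test_that("templating orientation follows the local plus fraction", {
  cfg <- sim_config("sliding_templating", seed = 2)
  st <- init_state(cfg)
  # all plus-end-out, and covering every candidate position so the local
  # neighbourhood is never empty
  st$filaments <- data.frame(
    mt_id = 0:9, x_center_um = seq(-1, 8, length.out = 10),
    orientation = 1L, lattice_line = 0:9
  )
  set.seed(11)
  outcomes <- replicate(40, {
    st2 <- add_mt(st)
    add <- attr(st2, "addition")
    if (add$outcome == "added") {
      utils::tail(st2$filaments$orientation, 1)
    } else {
      NA_integer_
    }
  })
  added <- outcomes[!is.na(outcomes)]
  expect_gt(length(added), 10)
  expect_true(all(added == 1)) # templating with p = 1
  # empty neighbourhood falls back to 50/50
  st$filaments <- st$filaments[0, ]
  set.seed(12)
  oris <- replicate(400, attr(add_mt(st), "addition")$orientation)
  expect_lt(abs(mean(oris == 1) - 0.5), 0.08)
})

test_that("a zero minus-end-out likelihood gates out minus-end-out nucleation", {
  cfg <- sim_config("unbounded_only",
    p_minus_amp = 0, p_plus_amp = 1,
    p_decay = 1e6, seed = 5
  )
  run <- run_bundle(cfg, n_replicates = 2, n_iter = 3000)
  for (r in run$replicates) {
    adds <- r$events[r$events$type == 1, ]
    expect_gt(nrow(adds), 0)
    expect_true(all(adds$orientation == 1))
    rej <- r$events[r$events$type == 3, ]
    expect_true(all(rej$orientation == -1))
  }
})

test_that("runs are deterministic and keep the filament-count ledger", {
  cfg <- sim_config("sliding", seed = 17)
  r1 <- run_bundle(cfg, n_replicates = 2, n_iter = 2500)
  r2 <- run_bundle(cfg, n_replicates = 2, n_iter = 2500)
  expect_identical(r1$replicates[[1]]$events, r2$replicates[[1]]$events)
  expect_identical(r1$replicates[[2]]$snapshots, r2$replicates[[2]]$snapshots)
  for (r in r1$replicates) {
    n_add <- sum(r$events$type == 1)
    n_exit <- sum(r$events$type == 2)
    expect_equal(length(r$final$x), 10 + n_add - n_exit)
  }
  # a single step advances time by dt and total time is n_iter * dt
  one <- run_bundle(cfg, n_replicates = 1, n_iter = 1, snapshot_every = 1)
  expect_equal(unique(one$replicates[[1]]$snapshots$time_s), c(0, cfg$dt))
  long <- r1$replicates[[1]]$length
  expect_equal(long$time_s[nrow(long)], 2500 * cfg$dt)
})

test_that("sliding sorts minus-end-out filaments toward the cell body", {
  cfg <- sim_config("sliding", seed = 23)
  run <- run_bundle(cfg, n_replicates = 6, n_iter = 30000)
  gap <- vapply(run$replicates, function(r) {
    f <- r$final
    if (!any(f$orientation == -1) || !any(f$orientation == 1)) {
      return(NA_real_)
    }
    mean(f$x[f$orientation == 1]) - mean(f$x[f$orientation == -1])
  }, numeric(1))
  expect_gt(mean(gap, na.rm = TRUE), 0)
})

test_that("orientation profiles are fractions over normalized position bins", {
  cfg <- sim_config("sliding", seed = 29)
  run <- run_bundle(cfg, n_replicates = 2, n_iter = 500)
  # force a known composition: all plus gives a profile of ones
  for (i in seq_along(run$replicates)) {
    sn <- run$replicates[[i]]$snapshots
    sn$orientation <- 1L
    run$replicates[[i]]$snapshots <- sn
  }
  prof <- orientation_profile(run, n_bins = 4)
  vals <- prof$plus_fraction[!is.nan(prof$plus_fraction)]
  expect_true(all(vals == 1))
  expect_true(all(prof$bin_mid > 0 & prof$bin_mid < 1))
})

test_that("config files round-trip through JSON and YAML", {
  cfg <- sim_config("sliding_unbounded", seed = 7, n_replicates = 3)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(mode = cfg$mode, seed = 7, n_replicates = 3),
    fj,
    auto_unbox = TRUE
  )
  cfg2 <- read_sim_config(fj)
  expect_equal(cfg2$mode, "sliding_unbounded")
  expect_equal(cfg2$addition_interval, 435)
  fy <- tempfile(fileext = ".yaml")
  writeLines(c("mode: sliding", "dt: 2", "n_iter: 100"), fy)
  expect_equal(read_sim_config(fy)$n_iter, 100L)
  fz <- tempfile(fileext = ".yaml")
  writeLines(c("mode: sliding", "warp_speed: 9"), fz)
  expect_error(read_sim_config(fz), "unknown config field")
})
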