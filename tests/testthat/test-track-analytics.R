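test_that("filter rules remove exactly the engineered violators", {
  tracks <- filter_fixture()
  out <- filter_tracks(tracks)
  survivors <- unique(out$track_id)
  expect_setequal(survivors, c("clean_a", "clean_b"))
  log <- attr(out, "removal_log")
  expect_equal(log$n_removed, c(1L, 1L, 1L, 1L))
  # individual rule checks
  expect_false("r4" %in% unique(filter_tracks(tracks)$track_id)) # 3 frames
  expect_false("r3" %in% unique(filter_tracks(tracks)$track_id)) # 25 um/min
})

test_that("filtering is idempotent and rules commute", {
  tracks <- filter_fixture()
  once <- filter_tracks(tracks)
  twice <- filter_tracks(once)
  expect_equal(once, twice, ignore_attr = TRUE)
  expect_equal(attr(twice, "removal_log")$n_removed, rep(0L, 4))
  # removing the slow-speed violators first leaves the frame-count
  # removals unchanged
  ts <- filter_fixture()
  slow_first <- ts[ts$track_id != "r2", ]
  expect_equal(
    attr(filter_tracks(slow_first), "removal_log")$n_removed[4],
    attr(filter_tracks(ts), "removal_log")$n_removed[4]
  )
})

test_that("filter input validation catches bad geometry config", {
  expect_error(filter_tracks(filter_fixture(), pixel_size = 0), "pixel_size")
  expect_error(filter_tracks(filter_fixture(), frame_interval = -1), "frame_interval")
})

test_that("axon tip is the 0.95 quantile of comet positions", {
  one <- make_track("a", "t1", 1, 30, 5, 1)
  expect_equal(axon_tip(one), 30)
  same <- rbind(
    make_track("a", "t1", 1, 12, 0, 3),
    make_track("a", "t2", 1, 12, 0, 3)
  )
  expect_equal(axon_tip(same), 12)
  set.seed(1)
  unif <- data.frame(
    axon_id = "a", track_id = seq_len(200), direction = 1,
    t_s = 0, x_um = runif(200, 0, 100)
  )
  expect_equal(axon_tip(unif), quantile(unif$x_um, 0.95, type = 7),
    ignore_attr = TRUE
  )
  expect_lt(abs(axon_tip(unif) - 95), 3)
  expect_error(axon_tip(data.frame(x_um = numeric())), "no tracks")
})

test_that("orientation fraction counts tip-ward tracks and is invariant", {
  all_plus <- rbind(
    make_track("a", "t1", 1, 10, 5, 5),
    make_track("a", "t2", 1, 12, 5, 5)
  )
  expect_equal(orientation_fraction(all_plus), 1)
  mixed <- rbind(
    make_track("a", "t1", 1, 10, 5, 5),
    make_track("a", "t2", -1, 12, 5, 5)
  )
  expect_equal(orientation_fraction(mixed), 0.5)
  three_of_four <- rbind(
    make_track("a", "t1", 1, 10, 5, 5), make_track("a", "t2", 1, 14, 5, 5),
    make_track("a", "t3", 1, 18, 5, 5), make_track("a", "t4", -1, 22, 5, 5)
  )
  expect_equal(orientation_fraction(three_of_four), 0.75)
  # invariant under row reordering and uniform translation
  shuffled <- three_of_four[sample(nrow(three_of_four)), ]
  shuffled$x_um <- shuffled$x_um + 17
  expect_equal(orientation_fraction(shuffled), 0.75)
  expect_warning(of <- orientation_fraction(three_of_four[0, ]), "undefined")
  expect_true(is.na(of))
})

test_that("growth metrics recover per-track displacement and binning", {
  # constant 5 um/min for 25 s: d_g = 5/60*25 = 2.083 um
  tr <- make_track("a", "t1", 1, 10, 5, 13, frame_interval = 25 / 12)
  gm <- growth_metrics(tr, tip = 30)
  expect_equal(gm$events$d_g, 5 / 60 * 25, tolerance = 1e-9)
  expect_equal(gm$events$v_um_min, 5, tolerance = 1e-9)
  # two events straddling the 10 um boundary from the tip land in
  # different bins
  straddle <- rbind(
    make_track("a", "near", 1, 21, 5, 5), # 9 um from tip of 30
    make_track("a", "far", 1, 19, 5, 5) # 11 um from tip
  )
  gm2 <- growth_metrics(straddle, tip = 30)
  expect_setequal(gm2$events$bin, c(0, 1))
  # a start beyond the tip clamps into the first bin
  beyond <- make_track("a", "b", 1, 31, 5, 5)
  expect_equal(growth_metrics(beyond, tip = 30)$events$bin, 0)
  # empty groups are absent, not zero
  expect_false(any(gm2$by_bin$n_events == 0))
})

test_that("growth metrics recover generator truth within 10%", {
  pars <- region_params(
    f_g = rep(0.06, 4), events_per_axon = 120,
    min_duration_s = 0
  )
  g <- gen_comet_tracks(pars, n_axons = 4, seed = 21)
  gm <- growth_metrics(g$tracks, tip = mean(g$truth$tip_um))
  # pooled over all events: f_g and v_g within 10%, d_g near v_g/f_g
  f_hat <- 1 / mean(gm$events$duration_s)
  expect_lt(abs(f_hat - 0.06) / 0.06, 0.1)
  expect_lt(abs(mean(gm$events$v_um_min) - 5) / 5, 0.1)
  expect_lt(abs(mean(gm$events$d_g) - 5 / 60 / 0.06) / (5 / 60 / 0.06), 0.1)
})

test_that("shrinkage metrics compute per-event and per-axon lengths", {
  ev <- data.frame(
    axon_id = c("a", "a", "b"), t0_s = 0, x0_um = c(20, 30, 10),
    t1_s = 10, x1_um = c(18, 27, 9)
  )
  sm <- shrinkage_metrics(ev)
  expect_equal(sm$per_event$d_s, c(2, 3, 1))
  expect_equal(sm$per_axon$d_s[sm$per_axon$axon_id == "a"], 2.5)
  expect_error(shrinkage_metrics(ev[0, ]), "no shrinkage")
  bad <- ev
  bad$x1_um[1] <- bad$x0_um[1]
  expect_error(shrinkage_metrics(bad), "positive length")
  bad2 <- ev
  bad2$t1_s <- 0
  expect_error(shrinkage_metrics(bad2), "end time")
})

test_that("synthetic shrinkage ensembles distribute around the target scale", {
  g <- gen_shrinkage_events(n = 2000, n_axons = 40, seed = 5)
  sm <- shrinkage_metrics(g$events)
  expect_lt(abs(median(sm$per_axon$d_s) - 2.03) / 2.03, 0.1)
})

test_that("bootstrap median CI is ordered, reproducible, formatted, and covers", {
  const <- rep(3.5, 20)
  ci <- bootstrap_median_ci(const, n = 500, seed = 1)
  expect_equal(c(ci$lower, ci$median, ci$upper), c(3.5, 3.5, 3.5))
  set.seed(10)
  vals <- rexp(300, 1 / 2.03)
  a <- bootstrap_median_ci(vals, n = 2000, seed = 4)
  b <- bootstrap_median_ci(vals, n = 2000, seed = 4)
  expect_identical(a, b)
  expect_true(a$lower <= a$median && a$median <= a$upper)
  expect_match(format(a), "^\\d+\\.\\d{2} \\[\\d+\\.\\d{2}, \\d+\\.\\d{2}\\]$")
  expect_error(bootstrap_median_ci(vals, n = 0), "n must be")
  expect_error(bootstrap_median_ci(1), "at least 2")
  # coverage: >= 90% of 100 repeats cover the true median of Exp(1/2)
  true_med <- 2 * log(2)
  hits <- 0
  for (i in 1:100) {
    set.seed(2000 + i)
    v <- rexp(1000, 1 / 2)
    ci_i <- bootstrap_median_ci(v, n = 1000, seed = i)
    hits <- hits + (ci_i$lower <= true_med && true_med <= ci_i$upper)
  }
  expect_gte(hits, 90)
})

test_that("control-axon QC applies the orientation and speed thresholds", {
  expect_false(qc_axon(0.75, 5)) # disordered control
  expect_true(qc_axon(0.9, 2.5))
  expect_false(qc_axon(0.9, 1.9)) # sluggish growth
})
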