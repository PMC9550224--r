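#' Region- and orientation-resolved generator parameters
#'
#' Growth parameters per (region, orientation) cell, where region is
#' `near_tip` (within 10 µm of the tip) or `shaft` (further away) and
#' orientation is +1 (plus-end-out, growing tip-ward) or -1
#' (minus-end-out). The `fly_neuron` defaults use a common growth speed of
#' 5 µm/min and catastrophe rates matched so that the mean growth lengths
#' per cycle `v_g/f_g` are 2.11 / 1.39 µm (near tip, plus / minus) and
#' 1.53 / 1.16 µm (shaft, plus / minus), the scale observed in cultured
#' fly neurons.
#'
#' @param v_g_um_min Growth speed (µm/min), recycled over the four cells in
#'   the order near_tip/+1, near_tip/-1, shaft/+1, shaft/-1.
#' @param f_g Catastrophe rates (1/s), same order.
#' @param plus_fraction Probability that a generated track is plus-end-out.
#' @param events_per_axon Mean number of growth events per axon.
#' @param axon_length_um Mean axon length (µm); lengths are drawn
#'   from a +-20% uniform band around it.
#' @param frame_interval_s Acquisition interval (s).
#' @param near_tip_fraction Fraction of events starting within 10 µm of
#'   the tip (growth concentrates near the advancing tip).
#' @param min_duration_s Minimum growth duration (s); 0 disables. Setting
#'   it to 4 frame intervals guarantees the tracks survive the standard
#'   4-frame visibility filter.
#' @return A list of class `region_params`.
#' @export
region_params <- function(v_g_um_min = c(5, 5, 5, 5),
                          f_g = c(5 / 60 / 2.11, 5 / 60 / 1.39,
                                  5 / 60 / 1.53, 5 / 60 / 1.16),
                          plus_fraction = 0.75,
                          events_per_axon = 30,
                          axon_length_um = 60,
                          frame_interval_s = 2,
                          near_tip_fraction = 0.66,
                          min_duration_s = 0) {
  v_g_um_min <- rep_len(v_g_um_min, 4)
  f_g <- rep_len(f_g, 4)
  if (any(v_g_um_min <= 0) || any(f_g <= 0)) {
    stop("velocities and rates must be > 0", call. = FALSE)
  }
  structure(
    list(
      cells = data.frame(
        region = c("near_tip", "near_tip", "shaft", "shaft"),
        orientation = c(1, -1, 1, -1),
        v_g_um_min = v_g_um_min,
        f_g = f_g
      ),
      plus_fraction = plus_fraction,
      events_per_axon = events_per_axon,
      axon_length_um = axon_length_um,
      frame_interval_s = frame_interval_s,
      near_tip_fraction = near_tip_fraction,
      min_duration_s = min_duration_s
    ),
    class = "region_params"
  )
}

#' Generate synthetic EB1 comet tracks
#'
#' Emulates the statistical structure assumed by the track analytics:
#' growth durations are exponential with the region/orientation-specific
#' catastrophe rate, growth speed is constant within a track, orientation
#' is a Bernoulli mixture, and growth events concentrate near the axon tip.
#' Track points are emitted on the acquisition time grid plus the exact
#' event endpoint. Start positions respect the kymograph placement
#' constraints: tip-ward growth may start anywhere in its region (and can
#' penetrate up to 2 µm past the tip), away-growing MTs start at least
#' 4 µm from the tip.
#'
#' @param params A [region_params()] object.
#' @param n_axons Number of axons to generate.
#' @param seed Integer RNG seed.
#' @return A list with `tracks` (long-format track table, see
#'   [read_tracks()]), `truth` (a `truth_record`: generator parameters,
#'   per-axon tip positions and per-event ground truth) .
#' @export
gen_comet_tracks <- function(params = region_params(), n_axons = 50, seed = 1) {
  stopifnot(inherits(params, "region_params"))
  set.seed(seed)
  fi <- params$frame_interval_s
  rows <- vector("list", n_axons)
  truth_events <- vector("list", n_axons)
  tips <- numeric(n_axons)
  for (a in seq_len(n_axons)) {
    axon_len <- params$axon_length_um * stats::runif(1, 0.8, 1.2)
    tips[a] <- axon_len
    n_ev <- max(1L, stats::rpois(1, params$events_per_axon))
    orient <- ifelse(stats::runif(n_ev) < params$plus_fraction, 1, -1)
    near <- stats::runif(n_ev) < params$near_tip_fraction
    region <- ifelse(near, "near_tip", "shaft")
    idx <- match(paste(region, orient), paste(params$cells$region, params$cells$orientation))
    v <- params$cells$v_g_um_min[idx] / 60 # um/s
    fg <- params$cells$f_g[idx]
    dur <- stats::rexp(n_ev, fg)
    if (params$min_duration_s > 0) {
      dur <- pmax(dur, params$min_duration_s)
    }
    # distance of the start point from the tip: near-tip events within
    # 10 um, shaft events uniform over the remaining shaft; away-growing
    # (minus-end-out, direction -1) events start >= 4 um from the tip
    dist <- ifelse(near,
      stats::runif(n_ev, 0, pmin(10, axon_len)),
      stats::runif(n_ev, pmin(10, axon_len), axon_len)
    )
    dist <- ifelse(orient == -1, pmax(dist, 4), dist)
    x0 <- axon_len - dist
    ax_rows <- vector("list", n_ev)
    for (e in seq_len(n_ev)) {
      tgrid <- seq(0, dur[e], by = fi)
      if (tgrid[length(tgrid)] < dur[e]) tgrid <- c(tgrid, dur[e])
      t_start <- stats::runif(1, 0, 60)
      # direction +1 grows toward the tip (x increasing); tip-ward growth
      # may run past the nominal tip (the tip itself advances)
      x <- x0[e] + orient[e] * v[e] * tgrid
      ax_rows[[e]] <- data.frame(
        axon_id = sprintf("axon%04d", a),
        track_id = sprintf("tr%04d", e),
        direction = orient[e],
        t_s = t_start + tgrid,
        x_um = x
      )
    }
    rows[[a]] <- do.call(rbind, ax_rows)
    truth_events[[a]] <- data.frame(
      axon_id = sprintf("axon%04d", a),
      track_id = sprintf("tr%04d", seq_len(n_ev)),
      region = region, orientation = orient,
      v_g_um_min = v * 60, f_g = fg, duration_s = dur,
      d_g_true = v * dur
    )
  }
  tracks <- do.call(rbind, rows)
  rownames(tracks) <- NULL
  truth <- structure(
    list(
      generator = "gen_comet_tracks",
      params = unclass(params), n_axons = n_axons, seed = seed,
      tip_um = tips,
      events = do.call(rbind, truth_events)
    ),
    class = "truth_record"
  )
  list(tracks = tracks, truth = truth)
}

#' Generate synthetic MT shrinkage events
#'
#' Shrinkage lengths are exponential with mean `v_s/f_s`; event durations
#' follow from the shrinkage speed. The defaults (`v_s` = 0.25 µm/s,
#' `f_s` chosen so that `v_s/f_s` = 2.03 µm) put the ensemble median at
#' the experimentally observed per-cycle shrinkage scale.
#'
#' @param v_s Shrinkage speed (µm/s), > 0.
#' @param f_s Rescue rate (1/s), > 0.
#' @param n Number of events.
#' @param n_axons Number of axons the events are spread over.
#' @param seed Integer RNG seed.
#' @return A list with `events` (shrinkage table, see [read_shrinkage()])
#'   and `truth` (a `truth_record`).
#' @export
gen_shrinkage_events <- function(v_s = 0.25, f_s = 0.25 / 2.03, n = 100,
                                 n_axons = 10, seed = 1) {
  if (v_s <= 0 || f_s <= 0) stop("v_s and f_s must be > 0", call. = FALSE)
  set.seed(seed)
  if (n == 0) {
    events <- data.frame(
      axon_id = character(), t0_s = numeric(), x0_um = numeric(),
      t1_s = numeric(), x1_um = numeric()
    )
  } else {
    len <- stats::rexp(n, f_s / v_s) # mean v_s/f_s
    axon <- sprintf("axon%04d", sample.int(n_axons, n, replace = TRUE))
    x0 <- stats::runif(n, 10, 50)
    t0 <- stats::runif(n, 0, 200)
    events <- data.frame(
      axon_id = axon, t0_s = t0, x0_um = x0,
      t1_s = t0 + len / v_s, x1_um = x0 - len
    )
  }
  truth <- structure(
    list(
      generator = "gen_shrinkage_events",
      params = list(v_s = v_s, f_s = f_s, n = n, n_axons = n_axons),
      seed = seed, mean_d_s = v_s / f_s
    ),
    class = "truth_record"
  )
  list(events = events, truth = truth)
}

#' Generate synthetic binned factor-intensity profiles
#'
#' Per-axon binned profiles of a tip-referenced exponential gradient
#' `b + exp(-s (x - x0))` with multiplicative lognormal noise. Bin values
#' are the analytic bin averages of the gradient times `exp(N(0, sigma))`.
#' A "treatment" ensemble with a flattened gradient (`s` near 0) can be
#' produced by passing a small `s`.
#'
#' @param b Offset (a.u.).
#' @param s Decay rate (1/µm), > 0.
#' @param x0 Positional shift (µm).
#' @param noise_sigma Lognormal sigma of the multiplicative noise; 0 gives
#'   noiseless analytic bin means.
#' @param n_axons Number of axons.
#' @param n_bins Bins per axon (width `bin_width`).
#' @param bin_width Bin width (µm), default 10.
#' @param seed Integer RNG seed.
#' @return A list with `profile` (an `intensity_profile`-like list with
#'   per-axon and aggregated bins) and `truth` (a `truth_record`).
#' @export
gen_p150_profiles <- function(b = 1, s = 0.05, x0 = 0, noise_sigma = 0.1,
                              n_axons = 20, n_bins = 14, bin_width = 10,
                              seed = 1) {
  if (s <= 0) stop("s must be > 0 (use a tiny s for a flat profile)", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  set.seed(seed)
  lo <- (seq_len(n_bins) - 1) * bin_width
  hi <- lo + bin_width
  # analytic bin average of b + exp(-s(x - x0)) over [lo, hi]
  mean_val <- b + (exp(-s * (lo - x0)) - exp(-s * (hi - x0))) / (s * bin_width)
  per_axon <- do.call(rbind, lapply(seq_len(n_axons), function(a) {
    noise <- if (noise_sigma > 0) exp(stats::rnorm(n_bins, 0, noise_sigma)) else 1
    data.frame(
      axon_id = sprintf("axon%04d", a),
      bin_start = lo, bin_end = hi,
      p150 = mean_val * noise
    )
  }))
  agg <- do.call(rbind, lapply(split(per_axon, per_axon$bin_start), function(g) {
    data.frame(
      bin_start = g$bin_start[1], bin_end = g$bin_end[1],
      p150 = mean(g$p150), n = nrow(g)
    )
  }))
  agg <- agg[order(agg$bin_start), ]
  rownames(agg) <- NULL
  profile <- structure(
    list(bins = agg, per_axon = per_axon, condition = "synthetic",
         bin_width = bin_width),
    class = "intensity_profile"
  )
  truth <- structure(
    list(
      generator = "gen_p150_profiles",
      params = list(
        b = b, s = s, x0 = x0, noise_sigma = noise_sigma,
        n_axons = n_axons, n_bins = n_bins, bin_width = bin_width
      ),
      seed = seed
    ),
    class = "truth_record"
  )
  list(profile = profile, truth = truth)
}

#' Generate synthetic binned growth lengths from a gradient coupling
#'
#' Produces per-bin, per-direction mean growth lengths consistent with the
#' power-law coupling `d_g(x) = A p150(x)^alpha` evaluated through the
#' start/end-averaged prediction (see [predict_dg()]), with optional
#' multiplicative lognormal noise. Used for power-law recovery tests and
#' as the observable side of the gradient fit.
#'
#' @param p150fit An `exp_gradient_fit` (or a list with `b`, `s`, `x0`).
#' @param A,alpha True power-law parameters.
#' @param n_bins Number of 10 µm bins.
#' @param noise_sigma Lognormal sigma of multiplicative noise (0 = none).
#' @param seed Integer RNG seed.
#' @return A data.frame with `bin_start_um`, `bin_end_um`, `direction`,
#'   `d_g` (both directions per bin).
#' @export
gen_dg_bins <- function(p150fit, A = 2, alpha = 4, n_bins = 12,
                        noise_sigma = 0, seed = 1) {
  if (!inherits(p150fit, "exp_gradient_fit")) {
    p150fit <- structure(p150fit, class = "exp_gradient_fit")
  }
  set.seed(seed)
  lo <- (seq_len(n_bins) - 1) * 10
  hi <- lo + 10
  grid <- expand.grid(i = seq_len(n_bins), direction = c(-1, 1))
  dg <- vapply(seq_len(nrow(grid)), function(k) {
    i <- grid$i[k]
    sgn <- grid$direction[k]
    l <- lo[i]
    if (sgn > 0) l <- max(l, 4)
    if (hi[i] <= l) return(NA_real_)
    stats::integrate(
      function(x) predict_dg(x, sgn, p150fit, A, alpha, x_max = Inf),
      l, hi[i],
      rel.tol = 1e-6
    )$value / (hi[i] - l)
  }, numeric(1))
  noise <- if (noise_sigma > 0) exp(stats::rnorm(nrow(grid), 0, noise_sigma)) else 1
  data.frame(
    bin_start_um = lo[grid$i], bin_end_um = hi[grid$i],
    direction = grid$direction, d_g = dg * noise
  )
}
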