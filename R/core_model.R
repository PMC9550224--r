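#' Kinetic parameter set for one microtubule population
#'
#' Bundles the four primitive rates of MT dynamic instability -- growth
#' velocity `v_g`, shrinkage velocity `v_s`, catastrophe rate `f_g` and
#' rescue rate `f_s` -- together with the derived per-cycle quantities:
#' mean growth time `t_g = 1/f_g`, mean shrinkage time `t_s = 1/f_s`,
#' mean length added per growth cycle `d_g = v_g/f_g` and mean length lost
#' per shrinkage cycle `d_s = v_s/f_s`.
#'
#' @param v_g Growth velocity (µm/s), > 0.
#' @param v_s Shrinkage velocity (µm/s), > 0.
#' @param f_g Catastrophe rate (1/s), > 0.
#' @param f_s Rescue rate (1/s), > 0.
#'
#' @return An object of class `mt_params`: a list with the four primitives
#'   and the derived `t_g`, `t_s`, `d_g`, `d_s`.
#' @examples
#' p <- mt_params(v_g = 5 / 60, v_s = 0.25, f_g = 0.06, f_s = 0.123)
#' p$d_g # = v_g / f_g
#' @export
mt_params <- function(v_g, v_s, f_g, f_s) {
  vals <- c(v_g = v_g, v_s = v_s, f_g = f_g, f_s = f_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all of v_g, v_s, f_g, f_s must be finite and > 0", call. = FALSE)
  }
  structure(
    list(
      v_g = v_g, v_s = v_s, f_g = f_g, f_s = f_s,
      t_g = 1 / f_g, t_s = 1 / f_s,
      d_g = v_g / f_g, d_s = v_s / f_s
    ),
    class = "mt_params"
  )
}

#' @export
print.mt_params <- function(x, ...) {
  cat("MT dynamic-instability parameters\n")
  cat(sprintf("  v_g = %.4g um/s, v_s = %.4g um/s\n", x$v_g, x$v_s))
  cat(sprintf("  f_g = %.4g /s,   f_s = %.4g /s\n", x$f_g, x$f_s))
  cat(sprintf("  d_g = %.4g um/cycle, d_s = %.4g um/cycle\n", x$d_g, x$d_s))
  invisible(x)
}

#' Classify the MT growth regime (bounded vs unbounded)
#'
#' A microtubule whose mean added length per growth cycle `d_g` is at least
#' the mean lost length per shrinkage cycle `d_s` has no stationary length
#' distribution: its expected length diverges ("unbounded" growth). When
#' `d_s > d_g`, lengths are exponentially distributed with finite mean
#' `d_g * d_s / (d_s - d_g)` ("bounded" growth).
#'
#' @param d_g Mean growth length per cycle (µm), > 0.
#' @param d_s Mean shrinkage length per cycle (µm), > 0.
#'
#' @return A list of class `mt_regime` with elements `label`
#'   (`"bounded"` or `"unbounded"`) and `mean_length` (µm; `Inf` when
#'   unbounded).
#' @examples
#' classify_regime(d_g = 2.11, d_s = 2.03) # unbounded
#' classify_regime(d_g = 1.39, d_s = 2.03) # bounded, ~4.41 um
#' @export
classify_regime <- function(d_g, d_s) {
  stopifnot(is.numeric(d_g), is.numeric(d_s), length(d_g) == 1, length(d_s) == 1)
  if (!is.finite(d_g) || !is.finite(d_s) || d_g <= 0 || d_s <= 0) {
    stop("d_g and d_s must be finite and > 0", call. = FALSE)
  }
  if (d_s <= d_g) {
    out <- list(label = "unbounded", mean_length = Inf)
  } else {
    out <- list(label = "bounded", mean_length = d_g * d_s / (d_s - d_g))
  }
  structure(out, class = "mt_regime")
}

#' @export
print.mt_regime <- function(x, ...) {
  if (is.finite(x$mean_length)) {
    cat(sprintf("%s growth, mean MT length %.4g um\n", x$label, x$mean_length))
  } else {
    cat(sprintf("%s growth, mean MT length infinite\n", x$label))
  }
  invisible(x)
}

#' Long-time drift and effective diffusion of MT length
#'
#' On time scales long compared to the switching times, MT length performs a
#' drift-diffusion process. The drift is the state-occupancy-weighted mean
#' velocity and the diffusion coefficient follows from the velocity
#' autocorrelation of the two-state (telegraph) switching process:
#' \deqn{\bar v = \frac{f_s v_g - f_g v_s}{f_s + f_g}, \qquad
#'       \bar D = \frac{f_s f_g (v_g + v_s)^2}{(f_g + f_s)^3}.}
#' A positive drift means unbounded growth. The prefactor of `D_bar` was
#' validated against the event-driven stochastic simulator
#' ([simulate_two_state()]); see the package vignette.
#'
#' @param params An [mt_params()] object.
#' @return A list with `v_bar` (µm/s, signed) and `D_bar` (µm²/s, > 0).
#' @examples
#' drift_diffusion(mt_params(0.08, 0.08, 0.05, 0.04))
#' @export
drift_diffusion <- function(params) {
  stopifnot(inherits(params, "mt_params"))
  fsum <- params$f_g + params$f_s
  list(
    v_bar = (params$f_s * params$v_g - params$f_g * params$v_s) / fsum,
    D_bar = params$f_s * params$f_g * (params$v_g + params$v_s)^2 / fsum^3
  )
}

#' Mean MT length from the drift-diffusion limit
#'
#' In the bounded regime (negative drift) the stationary length distribution
#' of the drift-diffusion approximation is exponential and its mean is
#' `D_bar / |v_bar|`. Valid when catastrophe and rescue rates (and the two
#' speeds) are of comparable magnitude; in the symmetric limit it reduces to
#' [mean_length_taylor()].
#'
#' @param params An [mt_params()] object with negative drift.
#' @return Mean MT length (µm).
#' @export
mean_length_full <- function(params) {
  dd <- drift_diffusion(params)
  if (dd$v_bar >= 0) {
    stop("unbounded regime (v_bar >= 0): no finite mean length", call. = FALSE)
  }
  dd$D_bar / abs(dd$v_bar)
}

#' Mean MT length per growth/shrinkage cycle balance
#'
#' The compact per-cycle form of the mean MT length,
#' `l_MT = d_g * d_s / (d_s - d_g)`, valid in the bounded regime
#' `d_s > d_g`. It diverges as `d_g` approaches `d_s` from below, which
#' defines the bounded-to-unbounded transition.
#'
#' @param d_g Mean growth length per cycle (µm), > 0.
#' @param d_s Mean shrinkage length per cycle (µm), must exceed `d_g`.
#' @return Mean MT length (µm).
#' @examples
#' mean_length_taylor(1.5, 2.0) # 6 um
#' @export
mean_length_taylor <- function(d_g, d_s) {
  if (!is.finite(d_g) || !is.finite(d_s) || d_g < 0 || d_s <= 0) {
    stop("require finite d_g >= 0 and d_s > 0", call. = FALSE)
  }
  if (d_s <= d_g) {
    stop("unbounded regime (d_s <= d_g): no finite mean length", call. = FALSE)
  }
  d_g * d_s / (d_s - d_g)
}

#' Stationary probability density of MT length
#'
#' In the bounded regime the stationary length distribution is exponential,
#' `p(l) = (|v_bar|/D_bar) exp(-|v_bar| l / D_bar)`.
#'
#' @param params An [mt_params()] object with negative drift.
#' @param l Lengths (µm) at which to evaluate the density; vectorised.
#' @return Density values (1/µm).
#' @export
stationary_pdf <- function(params, l) {
  dd <- drift_diffusion(params)
  if (dd$v_bar >= 0) {
    stop("unbounded regime (v_bar >= 0): no stationary distribution", call. = FALSE)
  }
  rate <- abs(dd$v_bar) / dd$D_bar
  ifelse(l < 0, 0, rate * exp(-rate * l))
}

#' Event-driven stochastic simulation of the two-state growth process
#'
#' Simulates a single MT switching between growth (velocity `+v_g`, leaves
#' with rate `f_g`) and shrinkage (velocity `-v_s`, leaves with rate `f_s`)
#' with exponentially distributed dwell times (exact Gillespie scheme, no
#' time discretisation). Length is reflected at 0: a shrinking MT that
#' reaches zero length immediately re-enters the growth state.
#'
#' @param params An [mt_params()] object.
#' @param duration Total simulated time (s), > 0.
#' @param seed Integer RNG seed (reproducibility contract).
#' @param sample_dt If not `NULL`, also return lengths sampled on a regular
#'   time grid of this spacing (s).
#' @param l0 Initial length (µm), default 0 (starts growing).
#'
#' @return A list of class `mt_length_sample` with elements
#'   `times`, `lengths` (switch/boundary event times and lengths),
#'   `time_avg_length` (exact time integral of the piecewise-linear
#'   trajectory divided by `duration`), `sampled_lengths` (grid samples or
#'   `NULL`), `seed` and `duration`.
#' @examples
#' s <- simulate_two_state(mt_params(0.08, 0.08, 0.06, 0.04), 1e4, seed = 1)
#' s$time_avg_length
#' @export
simulate_two_state <- function(params, duration, seed, sample_dt = NULL, l0 = 0) {
  stopifnot(inherits(params, "mt_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  set.seed(seed)
  # preallocate generously; grow if needed
  n_guess <- max(64L, ceiling(duration * (params$f_g + params$f_s) * 1.5) + 16L)
  times <- numeric(n_guess)
  lens <- numeric(n_guess)
  t <- 0
  l <- l0
  growing <- TRUE
  k <- 1L
  times[1L] <- 0
  lens[1L] <- l
  integral <- 0
  while (t < duration) {
    rate <- if (growing) params$f_g else params$f_s
    dwell <- stats::rexp(1L, rate)
    v <- if (growing) params$v_g else -params$v_s
    # shrinking MT hitting zero: truncate the dwell at the boundary and
    # re-enter growth there (reflecting boundary)
    hit_zero <- FALSE
    if (!growing && l + v * dwell < 0) {
      dwell <- l / params$v_s
      hit_zero <- TRUE
    }
    if (t + dwell > duration) {
      dwell <- duration - t
      l_new <- l + v * dwell
      integral <- integral + (l + l_new) / 2 * dwell
      t <- duration
      l <- l_new
      k <- k + 1L
      if (k > length(times)) {
        times <- c(times, numeric(length(times)))
        lens <- c(lens, numeric(length(lens)))
      }
      times[k] <- t
      lens[k] <- l
      break
    }
    l_new <- max(0, l + v * dwell)
    integral <- integral + (l + l_new) / 2 * dwell
    t <- t + dwell
    l <- l_new
    growing <- if (hit_zero) TRUE else !growing
    k <- k + 1L
    if (k > length(times)) {
      times <- c(times, numeric(length(times)))
      lens <- c(lens, numeric(length(lens)))
    }
    times[k] <- t
    lens[k] <- l
  }
  times <- times[seq_len(k)]
  lens <- lens[seq_len(k)]
  sampled <- NULL
  if (!is.null(sample_dt)) {
    grid <- seq(0, duration, by = sample_dt)
    sampled <- stats::approx(times, lens, xout = grid, rule = 2)$y
  }
  structure(
    list(
      times = times, lengths = lens,
      time_avg_length = integral / duration,
      sampled_lengths = sampled,
      seed = seed, duration = duration
    ),
    class = "mt_length_sample"
  )
}

#' Growth-length threshold of the bounded-to-unbounded transition
#'
#' Finds, by bisection on [classify_regime()], the infimum of `d_g` for
#' which the mean MT length is infinite at a given `d_s`. Analytically this
#' is `d_g = d_s`; the function computes it from the regime classifier so
#' that the reported threshold is a property of the implementation, not a
#' restatement of the formula.
#'
#' @param d_s Mean shrinkage length per cycle (µm), > 0.
#' @param tol Bisection tolerance (µm).
#' @return The threshold growth length per cycle (µm).
#' @examples
#' divergence_threshold(2.03)
#' @export
divergence_threshold <- function(d_s, tol = 1e-9) {
  stopifnot(is.numeric(d_s), d_s > 0)
  lo <- d_s * 1e-6 # bounded here
  hi <- d_s * 2 # unbounded here
  stopifnot(
    classify_regime(lo, d_s)$label == "bounded",
    classify_regime(hi, d_s)$label == "unbounded"
  )
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify_regime(mid, d_s)$label == "unbounded") hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
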