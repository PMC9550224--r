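#' Normalize and bin per-axon fluorescence profiles
#'
#' Implements the staining normalisation used for tip-enriched
#' anti-catastrophe factors (p150): each channel (p150, tubulin,
#' CellTracker) is divided by its own median along the trace, the p150
#' channel is then divided by the median-normalised CellTracker channel
#' (volume correction), and the ratio is averaged in bins of distance from
#' the tip. Treatment (e.g. RNAi) profiles are additionally divided by the
#' mean of the paired control p150 profile.
#'
#' @param traces A data.frame with columns `axon_id`, `dist_um` (distance
#'   from the axon tip, µm), `p150`, `tubulin`, `celltracker`.
#' @param bin_width Bin width (µm), default 10.
#' @param control Optional `intensity_profile` object from a paired control
#'   condition; when given, the binned ratio is divided by the mean of the
#'   control's p150 profile.
#' @param condition Condition label stored with the result.
#' @return A list of class `intensity_profile`: `bins` (data.frame
#'   `bin_start`, `bin_end`, `p150`, `n`), per-axon binned values in
#'   `per_axon`, and `condition`.
#' @export
normalize_profiles <- function(traces, bin_width = 10, control = NULL,
                               condition = "control") {
  need <- c("axon_id", "dist_um", "p150", "tubulin", "celltracker")
  miss <- setdiff(need, names(traces))
  if (length(miss)) {
    stop("traces missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  per_axon <- lapply(split(traces, traces$axon_id), function(tr) {
    med <- vapply(tr[c("p150", "tubulin", "celltracker")], stats::median, numeric(1))
    if (any(med == 0)) {
      stop("zero-median channel in axon ", tr$axon_id[1], call. = FALSE)
    }
    p150n <- tr$p150 / med[["p150"]]
    ctn <- tr$celltracker / med[["celltracker"]]
    ratio <- p150n / ctn
    bin <- floor(tr$dist_um / bin_width)
    vals <- tapply(ratio, bin, mean)
    data.frame(
      axon_id = tr$axon_id[1],
      bin_start = as.numeric(names(vals)) * bin_width,
      bin_end = (as.numeric(names(vals)) + 1) * bin_width,
      p150 = as.numeric(vals)
    )
  })
  per_axon <- do.call(rbind, per_axon)
  rownames(per_axon) <- NULL
  if (!is.null(control)) {
    stopifnot(inherits(control, "intensity_profile"))
    per_axon$p150 <- per_axon$p150 / mean(control$bins$p150)
  }
  agg <- do.call(rbind, lapply(split(per_axon, per_axon$bin_start), function(g) {
    data.frame(
      bin_start = g$bin_start[1], bin_end = g$bin_end[1],
      p150 = mean(g$p150), n = nrow(g)
    )
  }))
  agg <- agg[order(agg$bin_start), ]
  rownames(agg) <- NULL
  structure(
    list(bins = agg, per_axon = per_axon, condition = condition,
         bin_width = bin_width),
    class = "intensity_profile"
  )
}

#' Fit an exponential model to a binned intensity profile
#'
#' Least-squares fit of `p150(x) = b + exp(-s (x - x0))` to the first
#' `n_bins` bins of the profile (bin centres as `x`). `b` is the far-field
#' offset (a.u.), `s` the decay rate (1/µm) and `x0` a positional shift
#' (µm). A near-flat profile (fitted `s` below `flat_tol`) is flagged as
#' degenerate.
#'
#' @param profile An `intensity_profile` object or a data.frame with
#'   `bin_start`, `bin_end`, `p150`.
#' @param n_bins Number of leading bins used in the fit, default 12
#'   (i.e. up to 120 µm from the tip at 10 µm bins).
#' @param flat_tol Decay rates below this value (1/µm) flag the profile as
#'   having no resolvable gradient.
#' @return A list of class `exp_gradient_fit` with `b`, `s`, `x0`,
#'   `residuals`, `degenerate` and the fitted `nls` model.
#' @export
fit_exponential <- function(profile, n_bins = 12, flat_tol = 1e-3) {
  bins <- if (inherits(profile, "intensity_profile")) profile$bins else profile
  stopifnot(all(c("bin_start", "bin_end", "p150") %in% names(bins)))
  bins <- bins[order(bins$bin_start), ]
  if (nrow(bins) < n_bins) {
    stop("need at least ", n_bins, " bins (have ", nrow(bins), ")", call. = FALSE)
  }
  bins <- bins[seq_len(n_bins), ]
  x <- (bins$bin_start + bins$bin_end) / 2
  y <- bins$p150
  # starts: offset from the far bins, decay from a log-linear regression
  b0 <- min(y) * 0.9
  amp <- max(y[1] - b0, 1e-3)
  pos <- pmax(y - b0, 1e-6)
  s0 <- max(1e-3, -stats::coef(stats::lm(log(pos) ~ x))[[2]])
  x00 <- log(amp) / s0 + x[1]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + exp(-s * (x - x0)),
      start = list(b = b0, s = s0, x0 = x00),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("exponential gradient fit failed to converge: ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(
      b = unname(cf["b"]), s = unname(cf["s"]), x0 = unname(cf["x0"]),
      residuals = unname(stats::residuals(fit)),
      degenerate = unname(abs(cf["s"]) < flat_tol),
      model = fit
    ),
    class = "exp_gradient_fit"
  )
}

# evaluate the fitted exponential intensity model
eval_p150 <- function(fit, x) fit$b + exp(-fit$s * (x - fit$x0))

#' Predicted growth length per cycle from a factor gradient
#'
#' Under the power-law coupling `d_g(x) = A * p150(x)^alpha`, the expected
#' length added by an MT that starts growing at distance `x` from the tip
#' is the mean of the point prediction at its start and at its (predicted)
#' end position: `d_g(x, sign) = 0.5 * (d_g(x + sign * d_g(x)) + d_g(x))`.
#' `sign = -1` moves the plus-end toward the tip (decreasing
#' distance-from-tip), `sign = +1` away from it. Tip-ward growth may
#' penetrate the tip by up to 2 µm (end positions clamp at -2 µm);
#' away-growing MTs are assumed to start at least 4 µm from the tip.
#'
#' @param x Distance from the axon tip (µm); vectorised.
#' @param sign Growth direction: -1 toward the tip, +1 away.
#' @param fit An `exp_gradient_fit` object.
#' @param A Power-law scale (µm/cycle per intensity^alpha).
#' @param alpha Power-law exponent.
#' @param x_max Upper end of the fitted range (µm); positions beyond it
#'   trigger an extrapolation warning. Default 120.
#' @return Predicted `d_g` (µm/cycle).
#' @export
predict_dg <- function(x, sign, fit, A, alpha, x_max = 120) {
  stopifnot(inherits(fit, "exp_gradient_fit"), sign %in% c(-1, 1))
  if (any(x > x_max | x < -2)) {
    warning("positions outside the fitted range [", -2, ", ", x_max,
      "] um: extrapolating the gradient model")
  }
  x_eff <- if (sign > 0) pmax(x, 4) else x
  dg_start <- A * eval_p150(fit, x_eff)^alpha
  x_end <- pmax(x_eff + sign * dg_start, -2)
  dg_end <- A * eval_p150(fit, x_end)^alpha
  0.5 * (dg_start + dg_end)
}

#' Fit the power-law coupling between a factor gradient and MT growth
#'
#' Finds `(A, alpha)` in `d_g(x) = A * p150(x)^alpha` by minimising the
#' summed squared difference between per-bin integrals of
#' [predict_dg()] and the observed per-bin mean growth lengths, jointly
#' over both growth directions. Bin integrals use adaptive quadrature
#' (relative tolerance 1e-6); for the away-from-tip direction the first bin
#' is integrated from 4 µm (placement constraint). The optimiser is bounded
#' (`A > 0`, `alpha` in \[-10, 10\]) L-BFGS-B with 5 multi-starts, since
#' high-exponent fits have narrow basins.
#'
#' @param dg_bins A data.frame with columns `bin_start_um`, `bin_end_um`,
#'   `direction` (-1 toward tip, +1 away) and `d_g` (observed mean growth
#'   length per cycle, µm).
#' @param p150fit An `exp_gradient_fit` object.
#' @param alpha_bounds Bounds for the exponent, default `c(-10, 10)`.
#' @param n_starts Number of optimiser starts, default 5.
#' @return A list of class `power_law_fit`: `A`, `alpha`, `rss`,
#'   `predicted` (per input bin) and `convergence`.
#' @export
fit_power_law <- function(dg_bins, p150fit, alpha_bounds = c(-10, 10),
                          n_starts = 5) {
  need <- c("bin_start_um", "bin_end_um", "direction", "d_g")
  miss <- setdiff(need, names(dg_bins))
  if (length(miss)) {
    stop("dg_bins missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(dg_bins) < 2) {
    stop("need at least 2 informative bins to fit (A, alpha)", call. = FALSE)
  }
  stopifnot(inherits(p150fit, "exp_gradient_fit"))

  bin_pred <- function(A, alpha) {
    vapply(seq_len(nrow(dg_bins)), function(i) {
      lo <- dg_bins$bin_start_um[i]
      hi <- dg_bins$bin_end_um[i]
      sgn <- dg_bins$direction[i]
      if (sgn > 0) lo <- max(lo, 4) # away-growing MTs start >= 4 um from tip
      if (hi <= lo) {
        return(NA_real_)
      }
      stats::integrate(
        function(x) predict_dg(x, sgn, p150fit, A, alpha, x_max = Inf),
        lo, hi,
        rel.tol = 1e-6
      )$value / (hi - lo)
    }, numeric(1))
  }
  obj <- function(par) {
    p <- bin_pred(exp(par[1]), par[2])
    sum((p - dg_bins$d_g)^2, na.rm = TRUE)
  }
  # multi-start over the exponent range; scale start from the data mean
  A0 <- mean(dg_bins$d_g) / mean(eval_p150(p150fit, 5:100))^1
  alphas0 <- seq(alpha_bounds[1] + 1, alpha_bounds[2] - 1,
    length.out = n_starts
  )
  best <- NULL
  for (a0 in alphas0) {
    start_A <- mean(dg_bins$d_g) /
      max(mean(eval_p150(p150fit, seq(5, 100, 5))^a0), 1e-12)
    fit <- tryCatch(
      stats::optim(
        c(log(max(start_A, 1e-8)), a0), obj,
        method = "L-BFGS-B",
        lower = c(-30, alpha_bounds[1]), upper = c(30, alpha_bounds[2]),
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("power-law fit failed from every start", call. = FALSE)
  A_hat <- exp(best$par[1])
  alpha_hat <- best$par[2]
  pred <- bin_pred(A_hat, alpha_hat)
  structure(
    list(
      A = A_hat, alpha = alpha_hat, rss = best$value,
      predicted = cbind(dg_bins, d_g_pred = pred),
      convergence = best$convergence
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law gradient coupling: d_g(x) = A * p150(x)^alpha\n  A = %.4g, alpha = %.4g (RSS %.4g)\n",
    x$A, x$alpha, x$rss
  ))
  invisible(x)
}
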