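#' @useDynLib axonmt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SIM_MODES <- c(
  "sliding", "sliding_templating", "templating_only",
  "sliding_unbounded", "unbounded_only", "sliding_templating_unbounded"
)

#' Configuration of the MT bundle sliding simulation
#'
#' Defaults follow the published parameter set for an axonal dynein-driven
#' MT bundle: all overlapping MTs cross-linked (`chi` = 1), 5 motors per µm
#' of overlap, fixed MT length 4 µm, axoplasmic drag 1 pN s/µm², dynein
#' stall force 1.4 pN and free velocity 0.86 µm/s, 2 s time step. The left
#' (cell-body) boundary is a leaky spring of 50 pN/µm whose trapped MTs
#' leave at 0.00024/s; the distal boundary resists outgrowth with a
#' constant 50 pN. New MTs arrive on a deterministic timer: every 1100 s
#' for the sliding/templating models (modes 1-3), every 435 s for models
#' with the unbounded-growth nucleation gate (modes 4-6, where not every
#' candidate nucleates).
#'
#' @param mode One of `"sliding"`, `"sliding_templating"`,
#'   `"templating_only"`, `"sliding_unbounded"`, `"unbounded_only"`,
#'   `"sliding_templating_unbounded"` (the six MT-addition models).
#' @param chi Cross-linked fraction of overlapping MT pairs.
#' @param lambda_m Motors per µm of pair overlap (1/µm).
#' @param l_mt MT length (µm; fixed, filaments neither grow nor shrink).
#' @param xi Axoplasmic drag coefficient (pN s/µm²).
#' @param f_stall Motor stall force (pN).
#' @param v0 Motor free gliding velocity (µm/s).
#' @param dt Time step (s).
#' @param n_iter Number of iterations per replicate.
#' @param n_replicates Number of replicate simulations.
#' @param addition_interval Seconds between MT addition attempts; `NULL`
#'   selects 1100 s (modes 1-3) or 435 s (modes 4-6).
#' @param left_spring Left-boundary spring constant (pN/µm).
#' @param exit_rate Exit rate (1/s) of MTs penetrating the left boundary.
#' @param right_force Distal-boundary resisting force (pN).
#' @param n_lines Number of lattice lines in the bundle cross-section
#'   (default 19, a two-ring hexagonal cross-section).
#' @param p_plus_amp,p_minus_amp,p_decay Unbounded-growth likelihood
#'   `P(orientation, d) = amp * exp(-d / p_decay)` with `d` the distance
#'   from the tip (µm); the plus-end-out amplitude exceeds the
#'   minus-end-out one near the tip.
#' @param init_n Initial number of filaments.
#' @param init_length Length (µm) of the initial lattice domain.
#' @param seed Master RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = "sliding",
                       chi = 1, lambda_m = 5, l_mt = 4, xi = 1,
                       f_stall = 1.4, v0 = 0.86, dt = 2,
                       n_iter = 50001, n_replicates = 50,
                       addition_interval = NULL,
                       left_spring = 50, exit_rate = 0.00024,
                       right_force = 50, n_lines = 19,
                       p_plus_amp = 0.7, p_minus_amp = 0.2, p_decay = 20,
                       init_n = 10, init_length = 6, seed = 1) {
  mode <- match.arg(mode, SIM_MODES)
  mode_idx <- match(mode, SIM_MODES)
  if (is.null(addition_interval)) {
    addition_interval <- if (mode_idx <= 3) 1100 else 435
  }
  num <- c(
    chi = chi, lambda_m = lambda_m, l_mt = l_mt, xi = xi,
    f_stall = f_stall, v0 = v0, dt = dt, n_iter = n_iter,
    n_replicates = n_replicates, addition_interval = addition_interval,
    left_spring = left_spring, right_force = right_force,
    n_lines = n_lines, p_decay = p_decay, init_n = init_n,
    init_length = init_length
  )
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all numeric simulation parameters must be finite and > 0",
      call. = FALSE
    )
  }
  if (exit_rate < 0 || exit_rate * dt > 1) {
    stop("exit_rate must satisfy 0 <= exit_rate * dt <= 1", call. = FALSE)
  }
  structure(
    list(
      mode = mode, chi = chi, lambda_m = lambda_m, l_mt = l_mt, xi = xi,
      f_stall = f_stall, v0 = v0, dt = dt,
      n_iter = as.integer(n_iter), n_replicates = as.integer(n_replicates),
      addition_interval = addition_interval,
      left_spring = left_spring, exit_rate = exit_rate,
      right_force = right_force, n_lines = as.integer(n_lines),
      p_plus_amp = p_plus_amp, p_minus_amp = p_minus_amp, p_decay = p_decay,
      init_n = as.integer(init_n), init_length = init_length,
      seed = as.integer(seed),
      use_templating = mode_idx %in% c(2, 3, 6),
      use_unbounded = mode_idx %in% c(4, 5, 6),
      random_gliding = mode_idx %in% c(3, 5)
    ),
    class = "sim_config"
  )
}

#' Read a simulation configuration from JSON or YAML
#'
#' @param path File path (`.json`, `.yaml` or `.yml`) holding fields of
#'   [sim_config()].
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("config must be .json, .yaml or .yml", call. = FALSE)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(sim_config, vals)
}

# adjacency matrix of the hexagonal bundle cross-section: unit-pitch
# lattice points ordered by distance from the centre; two lines are
# adjacent when their centres are one pitch apart
hex_adjacency <- function(n_lines) {
  pts <- expand.grid(q = -4:4, r = -4:4)
  xy <- cbind(pts$q + pts$r / 2, pts$r * sqrt(3) / 2)
  d0 <- sqrt(rowSums(xy^2))
  ord <- order(d0, atan2(xy[, 2], xy[, 1]))
  if (n_lines > nrow(xy)) stop("n_lines too large for the lattice template")
  xy <- xy[ord[seq_len(n_lines)], , drop = FALSE]
  dmat <- as.matrix(stats::dist(xy))
  adj <- (dmat > 1e-9) & (dmat < 1.05)
  storage.mode(adj) <- "integer"
  adj
}

#' Initialize the bundle state
#'
#' Places `init_n` filaments with independent random orientations
#' (plus/minus-end-out each with probability 0.5) at centres drawn
#' uniformly so the filaments lie within the initial domain of length
#' `init_length`, on uniformly random lattice lines subject to no same-line
#' overlap (bounded retries).
#'
#' @param config A [sim_config()] object.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list of class `bundle_state` with `filaments` (data.frame
#'   `mt_id`, `x_center_um`, `orientation`, `lattice_line`), `time` (s) and
#'   `config`.
#' @export
init_state <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  half <- config$l_mt / 2
  lo <- half
  hi <- max(config$init_length - half, lo)
  x <- numeric(0)
  line <- integer(0)
  for (i in seq_len(config$init_n)) {
    placed <- FALSE
    for (attempt in 1:100) {
      xc <- stats::runif(1, lo, hi)
      ln <- sample.int(config$n_lines, 1) - 1L
      if (!any(line == ln & abs(x - xc) < config$l_mt)) {
        x <- c(x, xc)
        line <- c(line, ln)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place initial filaments without same-line overlap",
        call. = FALSE
      )
    }
  }
  orient <- ifelse(stats::runif(config$init_n) < 0.5, 1L, -1L)
  structure(
    list(
      filaments = data.frame(
        mt_id = seq_len(config$init_n) - 1L,
        x_center_um = x, orientation = as.integer(orient),
        lattice_line = line
      ),
      time = 0, config = config
    ),
    class = "bundle_state"
  )
}

#' Filament velocities from the instantaneous force balance
#'
#' Exposes one evaluation of the motor/drag/boundary force balance for a
#' given state (used by [step_bundle()] and by closed-form verification
#' tests on small filament systems).
#'
#' @param state A `bundle_state`.
#' @return Velocities (µm/s), one per filament.
#' @export
bundle_velocities <- function(state) {
  stopifnot(inherits(state, "bundle_state"))
  f <- state$filaments
  cfg <- state$config
  bundle_velocities_cpp(
    f$x_center_um, as.integer(f$orientation), as.integer(f$lattice_line),
    hex_adjacency(cfg$n_lines), unclass(cfg)
  )
}

#' Advance the bundle by one time step
#'
#' Solves the force balance (motor drive on antiparallel overlaps, motor
#' velocity coupling on all cross-linked overlaps, viscous drag, boundary
#' forces) and advances filament centres by `v * dt`. Filament lengths
#' never change. Exit and addition events are handled by [run_bundle()];
#' this single-step form is deterministic given the state.
#'
#' @param state A `bundle_state`.
#' @return The updated `bundle_state`.
#' @export
step_bundle <- function(state) {
  v <- bundle_velocities(state)
  state$filaments$x_center_um <- state$filaments$x_center_um +
    v * state$config$dt
  state$time <- state$time + state$config$dt
  state
}

#' Attempt one MT addition event
#'
#' Draws a candidate centre uniformly along the current axon, chooses the
#' orientation (templated on the local plus-fraction of filaments covering
#' the candidate centre for the templating modes, 50/50 otherwise), applies
#' the unbounded-growth nucleation gate where the mode requires it, and
#' places the filament on a random lattice line without same-line overlap
#' (bounded retries, then skip).
#'
#' @param state A `bundle_state`.
#' @return The updated state; attribute `"addition"` records the outcome
#'   (`"added"`, `"rejected"` or `"no_space"`) plus the candidate position
#'   and orientation.
#' @export
add_mt <- function(state) {
  stopifnot(inherits(state, "bundle_state"))
  cfg <- state$config
  f <- state$filaments
  half <- cfg$l_mt / 2
  axon_len <- max(c(f$x_center_um + half, 6))
  xc <- stats::runif(1, 0, axon_len)
  if (cfg$use_templating) {
    cover <- abs(f$x_center_um - xc) <= half
    p_plus <- if (any(cover)) mean(f$orientation[cover] == 1) else 0.5
  } else {
    p_plus <- 0.5
  }
  ori <- if (stats::runif(1) < p_plus) 1L else -1L
  if (cfg$use_unbounded) {
    dist <- max(0, axon_len - xc)
    amp <- if (ori == 1) cfg$p_plus_amp else cfg$p_minus_amp
    if (stats::runif(1) >= amp * exp(-dist / cfg$p_decay)) {
      attr(state, "addition") <- list(outcome = "rejected", x = xc, orientation = ori)
      return(state)
    }
  }
  placed <- FALSE
  for (attempt in 1:30) {
    ln <- sample.int(cfg$n_lines, 1) - 1L
    if (!any(f$lattice_line == ln & abs(f$x_center_um - xc) < cfg$l_mt)) {
      state$filaments <- rbind(f, data.frame(
        mt_id = max(f$mt_id, -1L) + 1L, x_center_um = xc,
        orientation = ori, lattice_line = ln
      ))
      placed <- TRUE
      break
    }
    xc <- stats::runif(1, 0, axon_len)
  }
  attr(state, "addition") <- list(
    outcome = if (placed) "added" else "no_space", x = xc, orientation = ori
  )
  state
}

#' Run the bundle simulation
#'
#' Runs `n_replicates` independent replicates of `n_iter` steps each, with
#' per-replicate seeds derived deterministically from the master seed. The
#' stepping loop (force balance, position update, boundary exits, timed MT
#' additions) runs in compiled code.
#'
#' @param config A [sim_config()] object.
#' @param snapshot_every Record a state snapshot every this many steps
#'   (default: 20 snapshots per run).
#' @param n_replicates Override `config$n_replicates`.
#' @param n_iter Override `config$n_iter`.
#' @return A list of class `bundle_run`: `replicates` (each with
#'   `snapshots`, `events`, `length`, `final`, `seed`), `config`,
#'   `snapshot_every`.
#' @export
run_bundle <- function(config, snapshot_every = NULL,
                       n_replicates = config$n_replicates,
                       n_iter = config$n_iter) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(snapshot_every)) {
    snapshot_every <- max(1L, as.integer(floor(n_iter / 20)))
  }
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  adj <- hex_adjacency(config$n_lines)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    st <- init_state(config, seed = rep_seeds[r])
    # init_state seeded the RNG; the compiled loop continues the stream
    res <- bundle_run_cpp(
      st$filaments$x_center_um, as.integer(st$filaments$orientation),
      as.integer(st$filaments$lattice_line), adj, unclass(config),
      as.integer(n_iter), config$addition_interval,
      as.integer(snapshot_every)
    )
    res$seed <- rep_seeds[r]
    reps[[r]] <- res
  }
  structure(
    list(replicates = reps, config = config, snapshot_every = snapshot_every),
    class = "bundle_run"
  )
}

#' Final axon lengths of a bundle run
#'
#' @param run A `bundle_run`.
#' @return Numeric vector: final axon length (µm, distance from the
#'   cell-body boundary to the distal-most MT end) per replicate.
#' @export
final_axon_lengths <- function(run) {
  stopifnot(inherits(run, "bundle_run"))
  vapply(run$replicates, function(r) {
    len <- r$length
    len$axon_length_um[nrow(len)]
  }, numeric(1))
}

#' Orientation profile along the (normalized) axon
#'
#' For each requested time point and replicate, filaments are binned by
#' normalized centre position (position / axon length at that time) and
#' the per-bin fraction of plus-end-out filaments is computed; the profile
#' is then averaged over replicates with a normal-approximation 95%
#' interval. Bins with no filaments in a replicate are excluded from that
#' replicate's average (undefined, not zero).
#'
#' @param run A `bundle_run`.
#' @param n_bins Number of bins of normalized axon position.
#' @param times Time points (s); each is matched to the nearest recorded
#'   snapshot. Default: the final snapshot.
#' @return A data.frame `time_s`, `bin_mid` (normalized position),
#'   `plus_fraction`, `lower`, `upper`, `n_replicates`.
#' @export
orientation_profile <- function(run, n_bins = 10, times = NULL) {
  stopifnot(inherits(run, "bundle_run"))
  snap_times <- sort(unique(run$replicates[[1]]$snapshots$time_s))
  if (is.null(times)) times <- snap_times[length(snap_times)]
  out <- list()
  for (tt in times) {
    t_use <- snap_times[which.min(abs(snap_times - tt))]
    per_rep <- lapply(run$replicates, function(r) {
      sn <- r$snapshots
      sn <- sn[sn$time_s == t_use, , drop = FALSE]
      if (nrow(sn) == 0) {
        return(rep(NA_real_, n_bins))
      }
      half <- run$config$l_mt / 2
      axon_len <- max(sn$x_center_um + half)
      pos <- pmin(pmax(sn$x_center_um / axon_len, 0), 1)
      bin <- pmin(floor(pos * n_bins), n_bins - 1)
      vapply(seq_len(n_bins) - 1, function(b) {
        sel <- bin == b
        if (!any(sel)) NA_real_ else mean(sn$orientation[sel] == 1)
      }, numeric(1))
    })
    mat <- do.call(rbind, per_rep)
    mu <- colMeans(mat, na.rm = TRUE)
    nn <- colSums(!is.na(mat))
    se <- apply(mat, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
    out[[length(out) + 1]] <- data.frame(
      time_s = t_use,
      bin_mid = (seq_len(n_bins) - 0.5) / n_bins,
      plus_fraction = mu,
      lower = mu - 1.96 * se, upper = mu + 1.96 * se,
      n_replicates = nn
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
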