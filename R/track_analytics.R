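#' Read a comet-track table
#'
#' Long-format CSV dialect: one row per track point with columns
#' `axon_id`, `track_id`, `direction` (+1 growth toward the tip /
#' plus-end-out, -1 toward the cell body / minus-end-out), `t_s` (time, s)
#' and `x_um` (position along the axon, µm, cell body at 0).
#'
#' @param path CSV file path.
#' @return A `data.frame` with the five columns above.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("axon_id", "track_id", "direction", "t_s", "x_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track table missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df[need]
}

#' Read a shrinkage-event table
#'
#' CSV with columns `axon_id`, `t0_s`, `x0_um`, `t1_s`, `x1_um`: one row
#' per shrinkage event traced between its start and end point.
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_shrinkage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("axon_id", "t0_s", "x0_um", "t1_s", "x1_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("shrinkage table missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df[need]
}

# Per-track summary used by both filtering and metrics: one row per
# (axon_id, track_id) with displacement, duration, frame count, speed.
track_summary <- function(tracks) {
  stopifnot(all(c("axon_id", "track_id", "direction", "t_s", "x_um") %in%
    names(tracks)))
  key <- interaction(tracks$axon_id, tracks$track_id, drop = TRUE)
  ord <- order(key, tracks$t_s)
  tracks <- tracks[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  last <- !duplicated(key, fromLast = TRUE)
  data.frame(
    axon_id = tracks$axon_id[first],
    track_id = tracks$track_id[first],
    direction = tracks$direction[first],
    x_start = tracks$x_um[first],
    x_end = tracks$x_um[last],
    t_start = tracks$t_s[first],
    t_end = tracks$t_s[last],
    n_frames = as.integer(tabulate(key)[tabulate(key) > 0]),
    stringsAsFactors = FALSE
  )
}

#' Filter comet tracks with standard kymograph quality rules
#'
#' Removes tracks that (1) displace less than two pixels along the axon,
#' (2) have a mean speed below 1.5 µm/min, (3) have a mean speed above
#' 20 µm/min, or (4) span fewer than four frames. Speed is net displacement
#' over duration. Rules 2-4 are purely physical; only rule 1 depends on
#' `pixel_size`.
#'
#' @param tracks Long-format track table (see [read_tracks()]).
#' @param pixel_size Kymograph pixel size (µm), default 0.103.
#' @param frame_interval Acquisition interval (s), default 2. Retained for
#'   the table's provenance; filtering itself works on the recorded times.
#' @return The surviving rows of `tracks`, with an attribute
#'   `"removal_log"`: a data.frame with per-rule removal counts (a track
#'   violating several rules is counted under each).
#' @export
filter_tracks <- function(tracks, pixel_size = 0.103, frame_interval = 2) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a positive number", call. = FALSE)
  }
  if (is.null(frame_interval) || !is.finite(frame_interval) ||
    frame_interval <= 0) {
    stop("frame_interval must be a positive number", call. = FALSE)
  }
  if (nrow(tracks) == 0) {
    out <- tracks
    attr(out, "removal_log") <- data.frame(
      rule = c(
        "displacement_lt_2px", "speed_lt_1.5um_min",
        "speed_gt_20um_min", "lt_4_frames"
      ),
      n_removed = integer(4)
    )
    return(out)
  }
  ts <- track_summary(tracks)
  disp <- abs(ts$x_end - ts$x_start)
  dur <- ts$t_end - ts$t_start
  speed <- ifelse(dur > 0, disp / dur * 60, 0) # um/min
  v1 <- disp < 2 * pixel_size
  v2 <- speed < 1.5
  v3 <- speed > 20
  v4 <- ts$n_frames < 4
  bad <- v1 | v2 | v3 | v4
  bad_key <- paste(ts$axon_id, ts$track_id)[bad]
  keep <- !(paste(tracks$axon_id, tracks$track_id) %in% bad_key)
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_log") <- data.frame(
    rule = c(
      "displacement_lt_2px", "speed_lt_1.5um_min",
      "speed_gt_20um_min", "lt_4_frames"
    ),
    n_removed = c(sum(v1), sum(v2), sum(v3), sum(v4))
  )
  out
}

#' Axon tip position from comet positions
#'
#' The tip is taken as the 0.95 quantile of all comet point positions
#' (robust to outlier comets beyond the morphological tip). Linear
#' interpolation sample quantile (R type 7).
#'
#' @param tracks Track table with an `x_um` column (typically filtered).
#' @return Tip position (µm from the cell body).
#' @export
axon_tip <- function(tracks) {
  if (nrow(tracks) == 0) stop("no tracks: cannot locate the axon tip", call. = FALSE)
  unname(stats::quantile(tracks$x_um, 0.95, type = 7))
}

#' Fraction of plus-end-out (tip-ward growing) comets
#'
#' The number of tracks growing away from the cell body divided by all
#' growing tracks: 1 for a fully plus-end-out axon, 0.5 for mixed
#' orientation.
#'
#' @param tracks Track table (typically filtered).
#' @return Fraction in \[0, 1\], or `NA` (with a warning) for an empty table.
#' @export
orientation_fraction <- function(tracks) {
  if (nrow(tracks) == 0) {
    warning("no tracks: orientation fraction undefined")
    return(NA_real_)
  }
  ts <- track_summary(tracks)
  mean(ts$direction == 1)
}

#' Per-bin growth statistics referenced to the axon tip
#'
#' For each track: the growth length per cycle `d_g` (absolute net
#' displacement, µm), the growth duration (s) and the speed (µm/min). Tracks
#' are grouped into bins of distance from the axon tip (measured at the
#' track's start position; starts beyond the tip clamp to the first bin) and
#' by growth direction. Per group the function reports mean `d_g`, mean
#' speed `v_g`, the catastrophe rate `f_g` = 1/(mean growth duration) and
#' the event count. Empty groups are absent from the output (undefined, not
#' zero).
#'
#' @param tracks Filtered track table.
#' @param tip Axon tip position (µm), e.g. from [axon_tip()].
#' @param bin_width Bin width (µm), default 10.
#' @return A list of class `axon_metrics` with elements `events` (one row
#'   per track: `axon_id`, `track_id`, `direction`, `dist_from_tip`, `bin`,
#'   `d_g`, `duration_s`, `v_um_min`), `by_bin` (per bin x direction:
#'   `bin_start`, `bin_end`, `direction`, `d_g`, `v_um_min`, `f_g`,
#'   `n_events`), `tip` and `bin_width`.
#' @export
growth_metrics <- function(tracks, tip, bin_width = 10) {
  stopifnot(is.numeric(tip), length(tip) == 1, bin_width > 0)
  ts <- track_summary(tracks)
  if (nrow(ts) == 0) stop("no tracks to analyse", call. = FALSE)
  dist <- pmax(0, tip - ts$x_start)
  bin <- floor(dist / bin_width)
  events <- data.frame(
    axon_id = ts$axon_id, track_id = ts$track_id, direction = ts$direction,
    dist_from_tip = dist, bin = bin,
    d_g = abs(ts$x_end - ts$x_start),
    duration_s = ts$t_end - ts$t_start,
    v_um_min = abs(ts$x_end - ts$x_start) / (ts$t_end - ts$t_start) * 60,
    stringsAsFactors = FALSE
  )
  grp <- interaction(events$bin, events$direction, drop = TRUE)
  agg <- do.call(rbind, lapply(split(events, grp), function(g) {
    data.frame(
      bin_start = g$bin[1] * bin_width,
      bin_end = (g$bin[1] + 1) * bin_width,
      direction = g$direction[1],
      d_g = mean(g$d_g),
      v_um_min = mean(g$v_um_min),
      f_g = 1 / mean(g$duration_s),
      n_events = nrow(g)
    )
  }))
  agg <- agg[order(agg$bin_start, agg$direction), ]
  rownames(agg) <- NULL
  structure(
    list(events = events, by_bin = agg, tip = tip, bin_width = bin_width),
    class = "axon_metrics"
  )
}

#' Shrinkage length per cycle from traced shrinkage events
#'
#' Each event contributes `d_s` = absolute position change between its
#' start and end point; the per-axon value is the mean over that axon's
#' events.
#'
#' @param events Shrinkage-event table (see [read_shrinkage()]).
#' @return A list with `per_event` (event-level `d_s`, µm) and `per_axon`
#'   (data.frame `axon_id`, `d_s`, `n_events`).
#' @export
shrinkage_metrics <- function(events) {
  if (nrow(events) == 0) stop("no shrinkage events", call. = FALSE)
  if (any(events$t1_s <= events$t0_s)) {
    stop("shrinkage events must have end time > start time", call. = FALSE)
  }
  d_s <- abs(events$x1_um - events$x0_um)
  if (any(d_s <= 0)) {
    stop("shrinkage events must have positive length", call. = FALSE)
  }
  per_event <- data.frame(axon_id = events$axon_id, d_s = d_s)
  per_axon <- do.call(rbind, lapply(
    split(per_event, per_event$axon_id),
    function(g) data.frame(axon_id = g$axon_id[1], d_s = mean(g$d_s), n_events = nrow(g))
  ))
  rownames(per_axon) <- NULL
  list(per_event = per_event, per_axon = per_axon)
}

#' Bootstrapped 95% confidence interval of the median
#'
#' Percentile bootstrap with `n` resamples (default 10,000), reproducible
#' under `seed`.
#'
#' @param values Numeric vector, length >= 2.
#' @param n Number of bootstrap resamples, >= 1.
#' @param seed Integer RNG seed.
#' @param conf Confidence level, default 0.95.
#' @return A list of class `boot_median_ci`: `median`, `lower`, `upper`,
#'   `n_resamples`.
#' @examples
#' bootstrap_median_ci(rexp(100, 1 / 2.03), seed = 1)
#' @export
bootstrap_median_ci <- function(values, n = 10000, seed = 1, conf = 0.95) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  m <- length(values)
  boots <- vapply(
    seq_len(n),
    function(i) stats::median(sample(values, m, replace = TRUE)),
    numeric(1)
  )
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a), type = 7))
  structure(
    list(
      median = stats::median(values), lower = ci[1], upper = ci[2],
      n_resamples = as.integer(n)
    ),
    class = "boot_median_ci"
  )
}

#' @export
format.boot_median_ci <- function(x, digits = 2, ...) {
  sprintf(
    "%.*f [%.*f, %.*f]", digits, x$median, digits, x$lower,
    digits, x$upper
  )
}

#' @export
print.boot_median_ci <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Quality-control flag for a control axon
#'
#' A control axon fails QC when its overall orientation fraction is below
#' 0.8 or its mean growth speed is below 2 µm/min; a paired treatment axon
#' inherits the control's flag.
#'
#' @param orientation Orientation fraction in \[0, 1\].
#' @param mean_v_um_min Mean growth speed (µm/min).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_axon <- function(orientation, mean_v_um_min) {
  isTRUE(orientation >= 0.8) && isTRUE(mean_v_um_min >= 2)
}
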