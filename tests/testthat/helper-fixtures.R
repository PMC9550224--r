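# Fixtures built in code. Pixel size 0.103 um, frame interval 2 s
# throughout (kymograph defaults).

# one straight track: n_frames points, constant speed (um/min), given
# start position and direction
make_track <- function(axon_id, track_id, direction, x_start, speed_um_min,
                       n_frames, frame_interval = 2, t_start = 0) {
  tt <- (seq_len(n_frames) - 1) * frame_interval
  data.frame(
    axon_id = axon_id, track_id = track_id, direction = direction,
    t_s = t_start + tt,
    x_um = x_start + direction * speed_um_min / 60 * tt
  )
}

# six tracks engineered so that exactly one violates each filter rule and
# two are clean (hand-derived survivor set: "clean_a", "clean_b"):
#   r1: displacement 0.18 um < 2 px (0.206 um), speed 1.8 um/min, 4 frames
#   r2: speed 1.0 um/min (< 1.5), displacement 0.5 um, 16 frames
#   r3: speed 25 um/min (> 20), 7 frames
#   r4: 3 frames (< 4), speed 7.5 um/min, displacement 0.5 um
filter_fixture <- function() {
  rbind(
    make_track("ax1", "clean_a", 1, 20, 5, 10),
    make_track("ax1", "clean_b", -1, 25, 4, 8),
    make_track("ax1", "r1", 1, 22, 0.18 / 6 * 60, 4),
    make_track("ax1", "r2", 1, 18, 1.0, 16),
    make_track("ax1", "r3", -1, 30, 25, 7),
    make_track("ax1", "r4", 1, 15, 7.5, 3)
  )
}

# quick exponential-fit truth for gradient tests
grad_truth <- function(b = 1, s = 0.05, x0 = 0) {
  structure(list(b = b, s = s, x0 = x0), class = "exp_gradient_fit")
}
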