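# Shared fixtures and oracles, all built in code.

ANGLE_COLS <- c("s_fe", "s_aa", "h_r", "e_fe", "f_ps", "w_fe", "w_ru")
DISTAL_COLS <- c("h_r", "e_fe", "f_ps", "w_fe", "w_ru")
LOC_COLS <- c("x", "y", "z", "incl", "azim")

test_morph <- function(side = "right") arm_morphology(0.30, 0.25, 0.08, side = side)

# Uniform random postures within loose anatomical bounds.
random_postures <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      s_fe = runif(n, -pi / 3, pi * 0.9),
      s_aa = runif(n, -pi / 6, pi * 0.8),
      h_r = runif(n, -pi / 2, pi / 2),
      e_fe = runif(n, 0.3, 2.5),
      f_ps = runif(n, -1.4, 1.4),
      w_fe = runif(n, -1.2, 1.2),
      w_ru = runif(n, -0.4, 0.5)
    )
  })
}

# Assemble a minimal arm_session around an angle table.
make_session <- function(angles, morph = test_morph(), rate = 90,
                         trial = 1L, shoulder = c(0, 0, 0)) {
  n <- nrow(angles)
  samples <- dplyr::bind_cols(
    tibble::tibble(t = (seq_len(n) - 1) / rate),
    tibble::as_tibble(angles)
  )
  samples$shoulder_x <- shoulder[1]
  samples$shoulder_y <- shoulder[2]
  samples$shoulder_z <- shoulder[3]
  samples$trial <- rep_len(trial, n)
  structure(
    list(
      samples = samples,
      events = tibble::tibble(t = 0, kind = "target_shown", target = 1L),
      morph = morph, rate = rate
    ),
    class = "arm_session"
  )
}

# Independent MVEE oracle: exact minimum-volume enclosing ellipsoid from the
# cluster package, volume computed from its (cov, d2) representation.
oracle_mvee_volume <- function(points) {
  eh <- cluster::ellipsoidhull(as.matrix(points))
  (4 / 3) * pi * sqrt(det(eh$cov) * eh$d2^3) * 1000 # dm^3
}

# Small reachable target table inside the default workspace.
reachable_targets <- function(n, morph = test_morph(), seed = 10) {
  sample_plausible_targets(default_rom(), morph, n = n, seed = seed)
}
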