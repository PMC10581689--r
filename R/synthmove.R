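## Synthetic natural-movement generator: a deterministic swivel-angle synergy
## resolves the arm's redundancy, minimum-jerk joint trajectories link
## successive reach postures, and sessions are emitted at 90 Hz in the same
## shape as recorded ones. Because the generated proximal-to-distal
## relationship is a deterministic function of (proximal angles, hand
## location), a controller trained on these sessions can be scored against
## the generating synergy.

#' Synergy / session-generation parameters
#'
#' @param swivel Elbow-drop (swivel) angle in radians fixing the redundant
#'   elbow rotation about the shoulder-wrist axis; 0 drops the elbow straight
#'   down, positive values rotate it laterally. Default 0.3 rad.
#' @param noise_sd Per-sample angle jitter (radians) added to generated
#'   trajectories; default 0.5 degree.
#' @param rate Sampling rate in Hz (default 90, the tracking rate emulated).
#' @param move_duration Duration of one reach movement in seconds (default
#'   1.3, a comfortable pick-and-place pace).
#' @param shoulder_drift_amp Amplitude (m) of the slow sinusoidal shoulder
#'   drift emulating residual trunk sway; default 5 mm.
#' @param shoulder_jitter_sd Per-sample shoulder position jitter (m).
#' @return A list of class `synergy_params`.
#' @export
synergy_params <- function(swivel = 0.3, noise_sd = deg2rad(0.5), rate = 90,
                           move_duration = 1.3, shoulder_drift_amp = 0.005,
                           shoulder_jitter_sd = 5e-4) {
  check_number(rate, "rate", positive = TRUE)
  check_number(move_duration, "move_duration", positive = TRUE)
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(
      swivel = swivel, noise_sd = noise_sd, rate = rate,
      move_duration = move_duration, shoulder_drift_amp = shoulder_drift_amp,
      shoulder_jitter_sd = shoulder_jitter_sd
    ),
    class = "synergy_params"
  )
}

#' Closed-form synergy inverse kinematics
#'
#' Deterministically computes a 7-DoF posture reaching a 5-parameter hand
#' location. The hand segment lies along the hand axis, so the wrist centre is
#' the target centre minus `hand_len` along the axis; elbow flexion follows
#' from the law of cosines on the shoulder-wrist distance; the elbow circle
#' position is fixed by the swivel angle (measured from the downward
#' direction); humeral rotation aligns the forearm; the two wrist angles
#' align the hand axis while forearm pronation-supination is held at zero,
#' keeping every joint angle on a single continuous branch (no wrap-around
#' anywhere in the workspace). Forward kinematics of the result reproduces
#' the target to numerical precision.
#'
#' @param target One-row data frame (or named vector) with `x`, `y`, `z`,
#'   `incl`, `azim`.
#' @param morph An [arm_morphology()].
#' @param params A [synergy_params()] (only `swivel` is used).
#' @return A one-row tibble of joint angles.
#' @export
synergy_ik <- function(target, morph, params = synergy_params()) {
  check_morphology(morph)
  loc <- location_matrix(target)
  if (nrow(loc) != 1L) abort("`target` must be a single location.")
  L <- morph$arm_length
  center <- loc[1, c("x", "y", "z")]
  r <- vnorm(center)
  if (!is.finite(r) || r >= L || r < 0.2 * L) {
    abort(sprintf(
      "unreachable target: %.3f m from the shoulder, outside the shell [%.3f, %.3f] m.",
      r, 0.2 * L, L
    ))
  }
  if (morph$side == "left") {
    ## solve the mirror problem on the canonical right-sided chain
    mirrored <- mirror_location(as_tibble(as.data.frame(loc)))
    ang <- synergy_ik(mirrored, mirror_morphology(morph), params)
    return(mirror_angles(ang))
  }

  a <- drop(spherical_to_axis(loc[1, "incl"], loc[1, "azim"]))
  wrist <- center - morph$hand_len * a
  Lu <- morph$upper_arm_len
  Lf <- morph$forearm_len
  d <- vnorm(wrist)
  if (d >= (Lu + Lf) * (1 - 1e-9) || d <= abs(Lu - Lf) + 1e-9) {
    abort("unreachable target: the wrist position falls outside the two-link workspace for this morphology.")
  }
  cos_beta <- clamp((Lu^2 + Lf^2 - d^2) / (2 * Lu * Lf), -1, 1)
  e_fe <- pi - acos(cos_beta)
  cos_alpha <- clamp((Lu^2 + d^2 - Lf^2) / (2 * Lu * d), -1, 1)
  alpha <- acos(cos_alpha)

  dhat <- wrist / d
  u_ref <- if (abs(dhat[3]) > 0.999) c(1, 0, 0) else c(0, 0, -1)
  u1 <- u_ref - sum(u_ref * dhat) * dhat
  u1 <- u1 / vnorm(u1)
  u2 <- c(
    dhat[2] * u1[3] - dhat[3] * u1[2],
    dhat[3] * u1[1] - dhat[1] * u1[3],
    dhat[1] * u1[2] - dhat[2] * u1[1]
  )
  e_dir <- cos(params$swivel) * u1 + sin(params$swivel) * u2
  elbow <- Lu * (cos(alpha) * dhat + sin(alpha) * e_dir)

  ## shoulder angles from the upper-arm direction v1 = (sF cA, -sA, -cF cA)
  v1 <- elbow / Lu
  s_aa <- asin(clamp(-v1[2], -1, 1))
  s_fe <- if (abs(cos(s_aa)) < 1e-9) 0 else atan2(v1[1], -v1[3])

  ## humeral rotation + elbow flexion from the forearm direction
  Rsh <- rot_about_neg_x(rot_about_neg_y(rot_new(1L), s_fe), s_aa)
  Rsh_m <- cbind(Rsh$c1[1, ], Rsh$c2[1, ], Rsh$c3[1, ])
  v2 <- (wrist - elbow) / Lf
  w_loc <- drop(t(Rsh_m) %*% v2) # = (sin e cos h, -sin e sin h, -cos e)
  h_r <- if (vnorm(w_loc[1:2]) < 1e-12) 0 else atan2(-w_loc[2], w_loc[1])
  e_fe <- atan2(sqrt(sum(w_loc[1:2]^2)), -w_loc[3])

  ## wrist flexion + radial-ulnar deviation from the hand axis, forearm
  ## pronation-supination fixed at zero: in the forearm frame the axis is
  ## l = (sin w_fe cos w_ru, sin w_ru, -cos w_fe cos w_ru)
  Rf <- rot_about_neg_y(
    rot_about_neg_z(
      rot_about_neg_x(rot_about_neg_y(rot_new(1L), s_fe), s_aa), h_r
    ),
    e_fe
  )
  Rf_m <- cbind(Rf$c1[1, ], Rf$c2[1, ], Rf$c3[1, ])
  l <- drop(t(Rf_m) %*% a)
  w_ru <- asin(clamp(l[2], -1, 1))
  w_fe <- if (vnorm(l[c(1, 3)]) < 1e-12) 0 else atan2(l[1], -l[3])

  joint_angles(
    s_fe = s_fe, s_aa = s_aa, h_r = h_r, e_fe = e_fe,
    f_ps = 0, w_fe = w_fe, w_ru = w_ru
  )
}

#' Minimum-jerk joint trajectory
#'
#' Fifth-order minimum-jerk interpolation per DoF between two postures:
#' position profile `10 tau^3 - 15 tau^4 + 6 tau^5`, exact at both endpoints
#' with vanishing endpoint velocity and acceleration. The trajectory has
#' `round(duration * rate)` samples on the 1/rate grid; the realized duration
#' is quantized to that grid so the final sample is exactly the goal.
#'
#' @param start,goal One-row data frames (or named vectors) of joint angles.
#' @param duration Movement duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @return A tibble with column `t` (seconds from movement onset) and the
#'   seven angle columns.
#' @export
min_jerk_trajectory <- function(start, goal, duration, rate = 90) {
  check_number(duration, "duration", positive = TRUE)
  check_number(rate, "rate", positive = TRUE)
  a0 <- angles_matrix(start)
  a1 <- angles_matrix(goal)
  if (nrow(a0) != 1L || nrow(a1) != 1L) abort("`start` and `goal` must be single postures.")
  n <- max(2L, as.integer(round(duration * rate)))
  t <- (seq_len(n) - 1) / rate
  tau <- t / t[n]
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  A <- rep(1, n) %*% a0 + s %*% (a1 - a0)
  out <- as_tibble(as.data.frame(A))
  names(out) <- ANGLE_COLS
  dplyr::bind_cols(tibble(t = t), out)
}

## Smooth shoulder-position trace: three incommensurate slow sinusoids plus
## tiny white jitter; step-to-step displacement stays far below the 0.01 m
## jumping threshold.
shoulder_trace <- function(n, rate, params) {
  t <- (seq_len(n) - 1) / rate
  phases <- runif(3, 0, 2 * pi)
  amp <- params$shoulder_drift_amp
  cbind(
    x = amp * sin(2 * pi * t / 11 + phases[1]),
    y = amp * sin(2 * pi * t / 8.5 + phases[2]),
    z = amp * sin(2 * pi * t / 13 + phases[3])
  ) + matrix(rnorm(3 * n, 0, params$shoulder_jitter_sd), n, 3)
}

new_session <- function(samples, events, morph, rate) {
  structure(
    list(samples = as_tibble(samples), events = as_tibble(events),
         morph = morph, rate = rate),
    class = "arm_session"
  )
}

#' @export
print.arm_session <- function(x, ...) {
  cat(sprintf(
    "<arm_session> %d samples at %g Hz (%.1f s), %d events, %s arm\n",
    nrow(x$samples), x$rate, nrow(x$samples) / x$rate, nrow(x$events),
    x$morph$side
  ))
  invisible(x)
}

## Default relaxed start posture for generated sessions and simulations.
rest_posture <- function() {
  joint_angles(s_fe = deg2rad(10), s_aa = deg2rad(10), e_fe = deg2rad(60))
}

#' Generate a synthetic pick-and-place session
#'
#' Emulates a natural-movement recording: for each target in sequence, the arm
#' moves from its current posture to the synergy posture reaching the target
#' ([synergy_ik()]) along a minimum-jerk joint trajectory at `params$rate`,
#' with Gaussian angle jitter of `params$noise_sd` per sample. A
#' `target_shown` event marks each movement onset; a `validated` event is
#' emitted at arrival when the (jittered) hand is inside the hard target zone
#' (2 cm, 5 degrees), otherwise `timeout`. The shoulder position is constant
#' up to a slow drift and small jitter (subjects keep their back against the
#' chair).
#'
#' @param targets A `target_set` tibble (or any data frame of locations with
#'   the five location columns).
#' @param morph An [arm_morphology()].
#' @param params A [synergy_params()].
#' @param seed Integer seed; the session is reproducible given the seed.
#' @return An `arm_session`: list with `samples` (tibble: `t`, seven angle
#'   columns, `shoulder_x/y/z`, `trial`), `events` (tibble: `t`, `kind`,
#'   `target`), `morph`, `rate`.
#' @export
generate_session <- function(targets, morph, params = synergy_params(),
                             seed = NULL) {
  check_morphology(morph)
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) abort("`targets` must be non-empty.")
  iks <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    iks[[i]] <- tryCatch(
      synergy_ik(targets[i, LOCATION_COLS], morph, params),
      error = function(e) {
        abort(sprintf("target %d is unreachable: %s", i, conditionMessage(e)))
      }
    )
  }
  with_seed_if(seed, {
    segs <- vector("list", nrow(targets))
    current <- rest_posture()
    t0 <- 0
    events <- vector("list", 2L * nrow(targets))
    hard <- tolerance("hard")
    for (i in seq_len(nrow(targets))) {
      traj <- min_jerk_trajectory(current, iks[[i]], params$move_duration,
        rate = params$rate
      )
      if (params$noise_sd > 0) {
        jit <- matrix(rnorm(nrow(traj) * 7, 0, params$noise_sd), nrow(traj), 7)
        traj[ANGLE_COLS] <- traj[ANGLE_COLS] + jit
      }
      traj$t <- traj$t + t0
      traj$trial <- i
      events[[2L * i - 1L]] <- tibble(t = t0, kind = "target_shown", target = i)
      arrival <- traj[nrow(traj), ]
      in_zone <- validate_target(
        hand_location(arrival[ANGLE_COLS], morph),
        targets[i, ], hard
      )
      events[[2L * i]] <- tibble(
        t = arrival$t,
        kind = if (in_zone) "validated" else "timeout",
        target = i
      )
      segs[[i]] <- traj
      current <- iks[[i]] # noise-free continuation point
      t0 <- arrival$t + 1 / params$rate
    }
    samples <- dplyr::bind_rows(segs)
    ## enforce the strict 1/rate grid across concatenated segments
    samples$t <- (seq_len(nrow(samples)) - 1) / params$rate
    sh <- shoulder_trace(nrow(samples), params$rate, params)
    samples$shoulder_x <- sh[, 1]
    samples$shoulder_y <- sh[, 2]
    samples$shoulder_z <- sh[, 3]
    ev <- dplyr::bind_rows(events)
    ## re-align event times to the final grid (arrival = last sample of trial)
    ends <- vapply(split(samples$t, samples$trial), max, numeric(1))
    starts <- vapply(split(samples$t, samples$trial), min, numeric(1))
    ev$t <- ifelse(ev$kind == "target_shown", starts[as.character(ev$target)],
      ends[as.character(ev$target)]
    )
    new_session(samples, ev, morph, params$rate)
  })
}

#' Generate an elementary range-of-motion session
#'
#' Emulates the calibration recording in which each DoF is swept across its
#' full range in isolation (others held at mid-range): for each DoF in turn,
#' minimum-jerk sweeps mid -> min -> max -> mid. With zero noise the observed
#' per-DoF extrema equal the generating bounds, so [estimate_rom()] recovers
#' `rom` exactly (up to the elbow extension cap it applies).
#'
#' @param rom The generating [arm_rom()] (all seven DoFs).
#' @param params A [synergy_params()] (`rate`, `noise_sd`,
#'   `move_duration` used).
#' @param morph An [arm_morphology()] attached to the session.
#' @param seed Integer seed for the jitter.
#' @return An `arm_session` (one trial per DoF).
#' @export
generate_rom_session <- function(rom, morph, params = synergy_params(noise_sd = 0),
                                 seed = NULL) {
  if (!inherits(rom, "arm_rom")) abort("`rom` must be an arm_rom.")
  if (!all(ANGLE_COLS %in% rom$dof)) abort("`rom` must cover all seven DoFs.")
  lo <- setNames(rom$min, rom$dof)[ANGLE_COLS]
  hi <- setNames(rom$max, rom$dof)[ANGLE_COLS]
  mid <- (lo + hi) / 2
  with_seed_if(seed, {
    segs <- list()
    events <- list()
    t0 <- 0
    for (k in seq_along(ANGLE_COLS)) {
      dof <- ANGLE_COLS[k]
      base <- as_tibble(as.list(mid))
      p_min <- base
      p_min[[dof]] <- lo[[dof]]
      p_max <- base
      p_max[[dof]] <- hi[[dof]]
      sweep <- dplyr::bind_rows(
        min_jerk_trajectory(base, p_min, params$move_duration, params$rate),
        min_jerk_trajectory(p_min, p_max, 2 * params$move_duration, params$rate),
        min_jerk_trajectory(p_max, base, params$move_duration, params$rate)
      )
      if (params$noise_sd > 0) {
        jit <- matrix(rnorm(nrow(sweep) * 7, 0, params$noise_sd), nrow(sweep), 7)
        sweep[ANGLE_COLS] <- sweep[ANGLE_COLS] + jit
      }
      sweep$trial <- k
      events[[k]] <- tibble(t = t0, kind = "target_shown", target = k)
      segs[[k]] <- sweep
      t0 <- t0 + nrow(sweep) / params$rate
    }
    samples <- dplyr::bind_rows(segs)
    samples$t <- (seq_len(nrow(samples)) - 1) / params$rate
    sh <- shoulder_trace(nrow(samples), params$rate, params)
    samples$shoulder_x <- sh[, 1]
    samples$shoulder_y <- sh[, 2]
    samples$shoulder_z <- sh[, 3]
    new_session(samples, dplyr::bind_rows(events), morph, params$rate)
  })
}

#' Inject motion-capture artifacts into a session
#'
#' Adds the two artifact types the trial-cleaning filters target:
#' * freezing — within each trial in `freeze_trials`, all monitored signals
#'   (angles and shoulder position) are held constant for `freeze_duration`
#'   seconds;
#' * jumping — within each trial in `jump_trials`, the shoulder position is
#'   displaced by `jump_size` metres at a single sample.
#'
#' @param session An `arm_session`.
#' @param freeze_trials,jump_trials Integer trial indices to corrupt.
#' @param freeze_duration Stillness duration in seconds (default 0.6).
#' @param jump_size Single-sample shoulder displacement in metres
#'   (default 0.02).
#' @return The corrupted `arm_session`.
#' @export
inject_artifacts <- function(session, freeze_trials = integer(),
                             jump_trials = integer(), freeze_duration = 0.6,
                             jump_size = 0.02) {
  if (!inherits(session, "arm_session")) abort("`session` must be an arm_session.")
  s <- session$samples
  sig_cols <- c(ANGLE_COLS, "shoulder_x", "shoulder_y", "shoulder_z")
  for (tr in freeze_trials) {
    idx <- which(s$trial == tr)
    n_freeze <- as.integer(round(freeze_duration * session$rate)) + 1L
    if (length(idx) < n_freeze) {
      abort(sprintf("trial %d is shorter than the requested freeze.", tr))
    }
    start <- idx[1] + (length(idx) - n_freeze) %/% 2
    window <- start:(start + n_freeze - 1L)
    s[window, sig_cols] <- s[rep(window[1], n_freeze), sig_cols]
  }
  for (tr in jump_trials) {
    idx <- which(s$trial == tr)
    if (length(idx) < 3) abort(sprintf("trial %d too short for a jump.", tr))
    at <- idx[ceiling(length(idx) / 2)]
    s$shoulder_x[at] <- s$shoulder_x[at] + jump_size
  }
  session$samples <- s
  session
}
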