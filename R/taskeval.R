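## Closed-loop pick-and-place evaluation: target-zone validation with the
## hard (2 cm, 5 deg) and relaxed (4 cm, 10 deg) tolerances, trial simulation
## against a controller, the freezing/jumping cleaning filters, and the three
## metrics: success rate, movement time and shoulder spread volume.

#' Target-zone tolerance
#'
#' The target zone is a region of the 5-D space of hand locations centred on
#' the target: the hand centre within `pos_tol` of the target centre and the
#' hand axis within `ang_tol` of the target axis. The named presets are
#' `"hard"` (2 cm, 5 degrees — acquisition phases) and `"relaxed"` (4 cm, 10
#' degrees — hybrid-arm test phases).
#'
#' @param name `"hard"` or `"relaxed"`, or `NULL` when passing explicit
#'   tolerances.
#' @param pos_tol Spatial tolerance in metres.
#' @param ang_tol Angular tolerance in radians.
#' @return A list of class `target_tolerance`.
#' @export
tolerance <- function(name = c("hard", "relaxed"), pos_tol = NULL, ang_tol = NULL) {
  if (is.null(pos_tol) && is.null(ang_tol)) {
    name <- match.arg(name)
    preset <- switch(name,
      hard = list(pos_tol = 0.02, ang_tol = deg2rad(5)),
      relaxed = list(pos_tol = 0.04, ang_tol = deg2rad(10))
    )
    pos_tol <- preset$pos_tol
    ang_tol <- preset$ang_tol
  } else {
    name <- "custom"
    check_number(pos_tol, "pos_tol", positive = TRUE)
    check_number(ang_tol, "ang_tol", positive = TRUE)
  }
  structure(list(pos_tol = pos_tol, ang_tol = ang_tol, name = name),
    class = "target_tolerance"
  )
}

#' Is the hand inside the target zone?
#'
#' @param hand Data frame of hand locations (columns `x`, `y`, `z`, `incl`,
#'   `azim`), one row per sample.
#' @param target One-row data frame with the same five columns.
#' @param tol A [tolerance()].
#' @return Logical vector: centre within `pos_tol` AND axis within `ang_tol`.
#' @export
validate_target <- function(hand, target, tol = tolerance("hard")) {
  if (!inherits(tol, "target_tolerance")) abort("`tol` must be a tolerance().")
  h <- location_matrix(hand)
  g <- location_matrix(target)
  if (nrow(g) != 1L) abort("`target` must be a single target.")
  pos_err <- sqrt((h[, "x"] - g[, "x"])^2 + (h[, "y"] - g[, "y"])^2 +
    (h[, "z"] - g[, "z"])^2)
  ha <- spherical_to_axis(h[, "incl"], h[, "azim"])
  ga <- drop(spherical_to_axis(g[, "incl"], g[, "azim"]))
  ang_err <- acos(clamp(ha %*% ga, -1, 1))
  pos_err <= tol$pos_tol & ang_err <= tol$ang_tol
}

#' Run a closed-loop test phase
#'
#' Simulates one hybrid-arm test phase. For each target in sequence, the
#' simulated operator moves the two proximal shoulder angles along a
#' minimum-jerk profile from their current values toward the proximal angles
#' of the synergy posture reaching the target, then holds; at every sample the
#' model predicts the five distal angles from (proximal, target location), the
#' hybrid posture is rendered by forward kinematics, and the trial succeeds at
#' the first sample whose hand location is inside the target zone (the
#' simulated operator validates without press latency). Movement time is the
#' time from target appearance to that sample; trials not validated within
#' `time_limit` fail as timeouts.
#'
#' @param model An `arm_control_model` or [synergy_oracle()].
#' @param targets A `target_set` (ordered).
#' @param morph An [arm_morphology()].
#' @param tol A [tolerance()]; the test-phase default is relaxed (4 cm, 10
#'   degrees).
#' @param time_limit Trial time limit in seconds (presets: 5 acquisition-style,
#'   10 test-style; default 10).
#' @param operator A [synergy_params()] describing the simulated operator
#'   (movement duration, rate, swivel of the reference synergy).
#' @param seed Integer seed for the recorded shoulder drift/jitter trace.
#' @return An object of class `phase_result`: list with `trials` (tibble:
#'   `target`, `success`, `movement_time`, `min_pos_err`, `min_ang_err`),
#'   `session` (the simulated `arm_session`, trial-indexed), `tol` and
#'   `time_limit`.
#' @export
run_closed_loop_phase <- function(model, targets, morph,
                                  tol = tolerance("relaxed"), time_limit = 10,
                                  operator = synergy_params(noise_sd = 0),
                                  seed = NULL) {
  check_morphology(morph)
  check_number(time_limit, "time_limit")
  if (time_limit < 0) abort("`time_limit` must be >= 0.")
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) abort("`targets` must be non-empty.")
  rate <- operator$rate
  n_limit <- floor(time_limit * rate)

  current <- rest_posture()
  trials <- vector("list", nrow(targets))
  segs <- vector("list", nrow(targets))
  t0 <- 0
  for (i in seq_len(nrow(targets))) {
    goal_posture <- synergy_ik(targets[i, LOCATION_COLS], morph, operator)
    if (n_limit < 1) {
      trials[[i]] <- tibble(
        target = i, success = FALSE, movement_time = NA_real_,
        min_pos_err = NA_real_, min_ang_err = NA_real_
      )
      segs[[i]] <- NULL
      next
    }
    reach <- min_jerk_trajectory(current, goal_posture, operator$move_duration,
      rate = rate
    )
    prox <- as.matrix(reach[PROXIMAL_COLS])
    if (nrow(prox) < n_limit) {
      prox <- rbind(
        prox,
        matrix(prox[nrow(prox), ],
          n_limit - nrow(prox), 2,
          byrow = TRUE
        )
      )
    } else {
      prox <- prox[seq_len(n_limit), , drop = FALSE]
    }
    inputs <- control_inputs(prox[, 1], prox[, 2], targets[i, LOCATION_COLS])
    distal <- predict_distal(model, inputs)
    hybrid <- dplyr::bind_cols(
      tibble(s_fe = prox[, 1], s_aa = prox[, 2]), distal
    )
    hand <- hand_location(hybrid, morph)
    in_zone <- validate_target(hand, targets[i, LOCATION_COLS], tol)
    g <- location_matrix(targets[i, LOCATION_COLS])
    pos_err <- sqrt((hand$x - g[, "x"])^2 + (hand$y - g[, "y"])^2 +
      (hand$z - g[, "z"])^2)
    ga <- drop(spherical_to_axis(g[, "incl"], g[, "azim"]))
    ang_err <- acos(clamp(spherical_to_axis(hand$incl, hand$azim) %*% ga, -1, 1))
    hit <- which(in_zone)
    success <- length(hit) > 0
    n_rec <- if (success) hit[1] else n_limit
    mt <- if (success) hit[1] / rate else NA_real_

    seg <- hybrid[seq_len(n_rec), ]
    seg$t <- t0 + seq_len(n_rec) / rate
    seg$trial <- i
    segs[[i]] <- seg
    t0 <- t0 + n_rec / rate
    trials[[i]] <- tibble(
      target = i, success = success, movement_time = mt,
      min_pos_err = min(pos_err), min_ang_err = min(ang_err)
    )
    current <- hybrid[n_rec, ANGLE_COLS]
  }
  samples <- dplyr::bind_rows(segs)
  session <- NULL
  if (!is.null(samples) && nrow(samples) > 0) {
    samples$t <- (seq_len(nrow(samples)) - 1) / rate
    sh <- with_seed_if(seed, shoulder_trace(nrow(samples), rate, operator))
    samples$shoulder_x <- sh[, 1]
    samples$shoulder_y <- sh[, 2]
    samples$shoulder_z <- sh[, 3]
    starts <- vapply(split(samples$t, samples$trial), min, numeric(1))
    ends <- vapply(split(samples$t, samples$trial), max, numeric(1))
    trial_tbl <- dplyr::bind_rows(trials)
    ev <- dplyr::bind_rows(
      tibble(
        t = unname(starts), kind = "target_shown",
        target = as.integer(names(starts))
      ),
      tibble(
        t = unname(ends),
        kind = ifelse(trial_tbl$success[as.integer(names(ends))],
          "validated", "timeout"
        ),
        target = as.integer(names(ends))
      )
    )
    ev <- ev[order(ev$t, ev$kind == "target_shown"), ]
    session <- new_session(samples, ev, morph, rate)
  }
  structure(
    list(
      trials = dplyr::bind_rows(trials), session = session,
      tol = tol, time_limit = time_limit
    ),
    class = "phase_result"
  )
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf(
    "<phase_result> %d trials, %.1f%% success (%s tolerance, %g s limit)\n",
    nrow(x$trials), success_rate(x$trials), x$tol$name, x$time_limit
  ))
  invisible(x)
}

#' @export
tidy.phase_result <- function(x, ...) x$trials

#' @export
glance.phase_result <- function(x, ...) phase_metrics(x)

#' Trial-cleaning filters
#'
#' Removes trials contaminated by motion-capture-style artifacts:
#' * freezing — a monitored position stays still (consecutive-sample
#'   displacement below 1 micron) for at least `still_duration` seconds
#'   (default 0.5 s). Monitored positions: the shoulder, and for
#'   acquisition-style sessions also the hand centre recomputed by forward
#'   kinematics (`monitor = c("shoulder", "hand")`). For hybrid-arm test
#'   phases monitor the shoulder only — the hand is model-driven there.
#' * jumping — the shoulder moves more than `jump_threshold` (default 0.01 m,
#'   i.e. 0.9 m/s at 90 Hz) between two consecutive samples.
#'
#' @param session An `arm_session` with a `trial` column.
#' @param monitor Positions monitored by the freezing filter.
#' @param still_duration Freezing threshold in seconds.
#' @param jump_threshold Jumping threshold in metres per sample step.
#' @return A list: `session` (with flagged trials' samples removed) and
#'   `removed` (tibble with columns `trial`, `reason`).
#' @export
clean_trials <- function(session, monitor = c("shoulder", "hand"),
                         still_duration = 0.5, jump_threshold = 0.01) {
  if (!inherits(session, "arm_session")) abort("`session` must be an arm_session.")
  monitor <- match.arg(monitor, c("shoulder", "hand"), several.ok = TRUE)
  s <- session$samples
  if (!"trial" %in% names(s)) abort("session samples need a `trial` column.")
  min_steps <- ceiling(still_duration * session$rate)

  positions <- list()
  if ("shoulder" %in% monitor) {
    positions$shoulder <- as.matrix(s[c("shoulder_x", "shoulder_y", "shoulder_z")])
  }
  if ("hand" %in% monitor && all(ANGLE_COLS %in% names(s))) {
    k <- fk_core(as.matrix(s[ANGLE_COLS]), session$morph)
    positions$hand <- k$hand_center
  }

  removed <- list()
  for (tr in unique(s$trial)) {
    idx <- which(s$trial == tr)
    if (length(idx) < 2) next
    reason <- NULL
    if (!is.null(positions$shoulder)) {
      sh_step <- sqrt(rowSums(diff(positions$shoulder[idx, , drop = FALSE])^2))
      if (any(sh_step > jump_threshold)) reason <- "jumping"
    }
    if (is.null(reason)) {
      for (p in positions) {
        step <- sqrt(rowSums(diff(p[idx, , drop = FALSE])^2))
        runs <- rle(step < 1e-6)
        if (any(runs$lengths[runs$values] >= min_steps)) {
          reason <- "freezing"
          break
        }
      }
    }
    if (!is.null(reason)) removed[[length(removed) + 1L]] <- tibble(trial = tr, reason = reason)
  }
  removed <- if (length(removed) > 0) {
    dplyr::bind_rows(removed)
  } else {
    tibble(trial = integer(), reason = character())
  }
  session$samples <- s[!(s$trial %in% removed$trial), ]
  list(session = session, removed = removed)
}

#' Success rate and movement times
#'
#' `success_rate()` is the percentage of successful trials; `movement_times()`
#' returns the movement times of the successful trials only.
#'
#' @param trials A trial table (from `phase_result$trials` / [tidy()]) with
#'   columns `success` and `movement_time`, or a `phase_result`.
#' @return A percentage in `[0, 100]`, resp. a numeric vector of seconds.
#' @export
success_rate <- function(trials) {
  if (inherits(trials, "phase_result")) trials <- trials$trials
  if (nrow(trials) == 0) abort("no trials.")
  100 * mean(trials$success)
}

#' @rdname success_rate
#' @export
movement_times <- function(trials) {
  if (inherits(trials, "phase_result")) trials <- trials$trials
  if (nrow(trials) == 0) abort("no trials.")
  trials$movement_time[trials$success]
}

## Minimum-volume enclosing ellipsoid (Khachiyan's algorithm).
## Returns list(center, A) with the ellipsoid {x : (x-c)' A (x-c) <= 1}.
mvee <- function(P, tol = 1e-7, max_iter = 50000) {
  P <- as.matrix(P)
  n <- nrow(P)
  d <- ncol(P)
  Q <- t(cbind(P, 1)) # (d+1) x n
  u <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    maximum <- M[j]
    step <- (maximum - d - 1) / ((d + 1) * (maximum - 1))
    if (step < tol) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c_ <- drop(crossprod(P, u))
  S <- crossprod(P, u * P) - tcrossprod(c_)
  A <- solve(S) / d
  list(center = c_, A = A)
}

#' Shoulder spread volume
#'
#' Volume of the ellipsoid containing 90% of the shoulder positions of a
#' phase, a proxy for compensatory trunk movement. Construction: the 10% of
#' points farthest from the centroid in Mahalanobis distance are trimmed, and
#' the minimum-volume enclosing ellipsoid (Khachiyan's algorithm) of the
#' remaining points is computed; its volume is reported in cubic decimetres.
#'
#' @param shoulder_positions An n x 3 matrix or data frame of positions (m),
#'   n >= 10, or an `arm_session` (its `shoulder_*` columns are used).
#' @param coverage Fraction of points the ellipsoid must contain
#'   (default 0.9).
#' @return Volume in dm^3. A degenerate (rank-deficient) cloud gives 0 with a
#'   warning.
#' @export
spread_volume <- function(shoulder_positions, coverage = 0.9) {
  if (inherits(shoulder_positions, "arm_session")) {
    shoulder_positions <-
      shoulder_positions$samples[c("shoulder_x", "shoulder_y", "shoulder_z")]
  }
  P <- as.matrix(shoulder_positions)
  if (ncol(P) != 3) abort("`shoulder_positions` must have 3 columns.")
  if (nrow(P) < 10) abort("need at least 10 positions.")
  if (coverage <= 0 || coverage > 1) abort("`coverage` must be in (0, 1].")
  ctr <- colMeans(P)
  S <- cov(P)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-18 * max(max(ev), 1e-30)) {
    warn("degenerate (rank-deficient) point cloud; spread volume is 0.")
    return(0)
  }
  md <- mahalanobis(P, ctr, S)
  keep <- order(md)[seq_len(ceiling(coverage * nrow(P)))]
  fit <- mvee(P[keep, , drop = FALSE])
  vol_m3 <- (4 / 3) * pi / sqrt(det(fit$A))
  vol_m3 * 1000
}

#' Phase summary metrics
#'
#' One-row summary of a test phase: success rate (%), median movement time of
#' successful trials (s), shoulder spread volume (dm^3, from the phase's
#' recorded shoulder positions) and the number of trials kept.
#'
#' @param phase A `phase_result`, or a trial table plus an optional
#'   shoulder-position matrix via `shoulder_positions`.
#' @param shoulder_positions Optional n x 3 matrix when `phase` is a plain
#'   trial table.
#' @return A one-row tibble with `success_rate`, `median_mt`, `spread_volume`,
#'   `n_trials_kept`.
#' @export
phase_metrics <- function(phase, shoulder_positions = NULL) {
  if (inherits(phase, "phase_result")) {
    trials <- phase$trials
    if (is.null(shoulder_positions) && !is.null(phase$session)) {
      keep <- phase$session$samples$trial %in% trials$target[trials$success]
      shoulder_positions <- as.matrix(
        phase$session$samples[keep, c("shoulder_x", "shoulder_y", "shoulder_z")]
      )
    }
  } else {
    trials <- as_tibble(phase)
  }
  mt <- movement_times(trials)
  sv <- if (!is.null(shoulder_positions) && nrow(shoulder_positions) >= 10) {
    spread_volume(shoulder_positions)
  } else {
    NA_real_
  }
  tibble(
    success_rate = success_rate(trials),
    median_mt = if (length(mt) > 0) median(mt) else NA_real_,
    spread_volume = sv,
    n_trials_kept = nrow(trials)
  )
}
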