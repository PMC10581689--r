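## Target-set generation: ranges of motion, workspace filters, 'plausible'
## targets by rejection sampling of the ROM, and ordering into pick/place
## sequences.

#' Range of motion of the arm joints
#'
#' A per-DoF table of joint limits (radians). `arm_rom()` builds one from
#' explicit bounds; [default_rom()] gives a set of textbook-plausible bounds
#' used by the synthetic generator; [estimate_rom()] extracts one from a
#' recorded session.
#'
#' @param bounds A data frame with columns `dof`, `min`, `max` (radians), one
#'   row per DoF.
#' @return A tibble of class `arm_rom`.
#' @export
arm_rom <- function(bounds) {
  bounds <- as_tibble(bounds)
  if (!all(c("dof", "min", "max") %in% names(bounds))) {
    abort("`bounds` needs columns dof, min, max.")
  }
  if (!all(bounds$dof %in% ANGLE_COLS)) abort("unknown DoF name in `bounds`.")
  if (any(!is.finite(bounds$min)) || any(!is.finite(bounds$max)) ||
    any(bounds$max <= bounds$min)) {
    abort("every DoF needs finite bounds with min < max.")
  }
  structure(bounds[c("dof", "min", "max")], class = c("arm_rom", class(bounds)))
}

#' @rdname arm_rom
#' @param cap_elbow Apply the 85% elbow-extension cap (see [estimate_rom()]).
#' @export
default_rom <- function(cap_elbow = TRUE) {
  rom <- arm_rom(tibble(
    dof = ANGLE_COLS,
    min = deg2rad(c(-50, -30, -90, 0, -85, -70, -20)),
    max = deg2rad(c(170, 150, 90, 150, 85, 75, 30))
  ))
  if (cap_elbow) rom <- cap_elbow_extension(rom) else rom
}

## Pull the extension end of the elbow range in by 15% of the observed
## excursion, so the arm never gets close enough to straight to degenerate the
## shoulder-elbow-wrist triangle used for humeral rotation.
cap_elbow_extension <- function(rom, fraction = 0.15) {
  i <- which(rom$dof == "e_fe")
  if (length(i) == 1L) {
    rom$min[i] <- rom$min[i] + fraction * (rom$max[i] - rom$min[i])
  }
  rom
}

#' Estimate ranges of motion from a session
#'
#' Per-DoF minima and maxima of the angles observed in a session (intended for
#' elementary single-DoF sweeps, but applicable to any recording). The
#' extension end of the elbow range is then artificially moved to 85% of
#' maximal extension — i.e. pulled in by 15% of the observed elbow excursion —
#' to keep the arm away from straight postures where the humeral-rotation
#' triangle degenerates.
#'
#' @param session An `arm_session` (see [generate_session()] /
#'   [read_session()]) or a data frame of joint-angle samples.
#' @param cap_elbow Apply the 85% extension cap (default `TRUE`).
#' @return An [arm_rom()] tibble.
#' @export
estimate_rom <- function(session, cap_elbow = TRUE) {
  samples <- if (inherits(session, "arm_session")) session$samples else as_tibble(session)
  cols <- intersect(ANGLE_COLS, names(samples))
  if (nrow(samples) == 0 || length(cols) == 0) {
    abort("session contains no joint-angle samples.")
  }
  mins <- vapply(samples[cols], min, numeric(1))
  maxs <- vapply(samples[cols], max, numeric(1))
  if (any(maxs - mins < 1e-9)) {
    abort(paste0(
      "degenerate range of motion (no excursion) for: ",
      paste(cols[maxs - mins < 1e-9], collapse = ", ")
    ))
  }
  rom <- arm_rom(tibble(dof = cols, min = unname(mins), max = unname(maxs)))
  if (cap_elbow) cap_elbow_extension(rom) else rom
}

#' Workspace filters for candidate targets
#'
#' The three criteria a candidate target must satisfy to enter the plausible
#' set, relative to the shoulder-centred frame and the subject's arm length
#' `L` (sum of segment lengths):
#' 1. the angle between the target axis and the vertical does not exceed 80
#'    degrees (no downward- or horizontal-pointing targets): `incl <= 80deg`;
#' 2. the centre lies strictly more than `L/3` in front of the frontal plane:
#'    `x > L/3` (anterior = +x);
#' 3. the centre lies at most `2L/3` below the horizontal plane through the
#'    shoulder: `z >= -2L/3`.
#'
#' @param loc Data frame of hand locations / targets (columns `x`, `y`, `z`,
#'   `incl`, `azim`), one row per candidate.
#' @param morph An [arm_morphology()].
#' @return Logical vector, `TRUE` where all three criteria hold.
#' @export
filter_target <- function(loc, morph) {
  check_morphology(morph)
  m <- location_matrix(loc)
  L <- morph$arm_length
  ## a left-sided subject faces the same +x anterior direction; criterion 2 is
  ## side-independent
  m[, "incl"] <= deg2rad(80) &
    m[, "x"] > L / 3 &
    m[, "z"] >= -2 * L / 3
}

## Assign alternating pick/place roles to an ordered target table.
assign_roles <- function(targets) {
  targets$role <- rep_len(c("pick", "place"), nrow(targets))
  targets$index <- seq_len(nrow(targets))
  targets[c("index", "role", LOCATION_COLS)]
}

#' Sample the plausible target set
#'
#' Draws joint configurations from a multivariate uniform distribution over
#' the per-DoF ranges of motion, maps each to a hand location by forward
#' kinematics, and keeps those passing the three workspace filters
#' ([filter_target()]) until `n` suitable targets are obtained. The accepted
#' targets are then shuffled into a sequence of alternating picking and
#' placing locations.
#'
#' @param rom An [arm_rom()] covering all seven DoFs.
#' @param morph An [arm_morphology()].
#' @param n Number of targets (default 300).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param max_draws Rejection-sampling budget before failing (default
#'   `10000 * n`).
#' @return A tibble of class `target_set` with columns `index`, `role`
#'   (`"pick"`/`"place"`), `x`, `y`, `z`, `incl`, `azim`.
#' @export
sample_plausible_targets <- function(rom, morph, n = 300, seed = NULL,
                                     max_draws = 10000 * n) {
  check_morphology(morph)
  if (!inherits(rom, "arm_rom")) abort("`rom` must be an arm_rom.")
  if (!all(ANGLE_COLS %in% rom$dof)) abort("`rom` must cover all seven DoFs.")
  if (n < 1) abort("`n` must be >= 1.")
  lo <- setNames(rom$min, rom$dof)[ANGLE_COLS]
  hi <- setNames(rom$max, rom$dof)[ANGLE_COLS]
  with_seed_if(seed, {
    kept <- NULL
    drawn <- 0
    batch <- max(1000L, as.integer(ceiling(n / 2)))
    while (is.null(kept) || nrow(kept) < n) {
      if (drawn >= max_draws) {
        abort(sprintf(
          "rejection sampling exceeded %d draws with only %d/%d accepted targets; workspace filters reject almost everything for this ROM/morphology.",
          max_draws, if (is.null(kept)) 0L else nrow(kept), n
        ))
      }
      m <- min(batch, max_draws - drawn)
      draws <- vapply(
        ANGLE_COLS, function(d) runif(m, lo[[d]], hi[[d]]),
        numeric(m)
      )
      if (m == 1L) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, ANGLE_COLS))
      drawn <- drawn + m
      locs <- hand_location(as_tibble(as.data.frame(draws)), morph)
      ok <- filter_target(locs, morph)
      kept <- dplyr::bind_rows(kept, locs[ok, ])
    }
    kept <- kept[seq_len(n), ]
    kept <- kept[sample.int(n), ]
    structure(assign_roles(kept), class = c("target_set", class(kept)))
  })
}

#' Order Growing-Neural-Gas nodes into the possible target set
#'
#' Maps every GNG node (a 7-DoF posture) to a hand location by forward
#' kinematics and draws the resulting targets without replacement into a
#' sequence in which two consecutive target centres are never closer than
#' `min_separation` (20 cm by default). The draw is greedy with restarts; an
#' error is raised when no valid ordering is found within `max_restarts`
#' attempts, rather than silently relaxing the constraint.
#'
#' @param nodes Data frame of node postures (seven angle columns), e.g. from
#'   [gng_fit()].
#' @param morph An [arm_morphology()].
#' @param seed Integer seed for the sequencing draw.
#' @param min_separation Minimum consecutive centre separation in metres.
#' @param max_restarts Restart budget for the greedy draw.
#' @return A `target_set` tibble (columns as in [sample_plausible_targets()]),
#'   ordered, with alternating pick/place roles.
#' @export
possible_targets <- function(nodes, morph, seed = NULL, min_separation = 0.20,
                             max_restarts = 1000) {
  check_morphology(morph)
  locs <- hand_location(nodes, morph)
  n <- nrow(locs)
  centers <- as.matrix(locs[c("x", "y", "z")])
  with_seed_if(seed, {
    for (attempt in seq_len(max_restarts)) {
      order_idx <- integer(n)
      remaining <- seq_len(n)
      order_idx[1] <- remaining[sample.int(n, 1)]
      remaining <- setdiff(remaining, order_idx[1])
      ok <- TRUE
      for (i in seq_len(n - 1L)) {
        last <- centers[order_idx[i], ]
        d <- sqrt(colSums((t(centers[remaining, , drop = FALSE]) - last)^2))
        candidates <- remaining[d >= min_separation]
        if (length(candidates) == 0L) {
          ok <- FALSE
          break
        }
        nxt <- candidates[sample.int(length(candidates), 1)]
        order_idx[i + 1L] <- nxt
        remaining <- setdiff(remaining, nxt)
      }
      if (ok) {
        out <- locs[order_idx, ]
        return(structure(assign_roles(out), class = c("target_set", class(out))))
      }
    }
    abort(sprintf(
      "no target ordering with consecutive separation >= %.2f m found in %d attempts.",
      min_separation, max_restarts
    ))
  })
}

#' Downsample a session
#'
#' Keeps every `factor`-th sample of a session (starting from the first),
#' preserving the event table. Used to thin acquisition recordings before
#' fitting the Growing Neural Gas (factor 10 for a single session, 100 when
#' pooling many subjects).
#'
#' @param session An `arm_session`.
#' @param factor Positive integer decimation factor.
#' @return The downsampled `arm_session` (its `rate` is divided by `factor`).
#' @export
downsample_session <- function(session, factor) {
  if (!inherits(session, "arm_session")) abort("`session` must be an arm_session.")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
    factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  session$samples <- session$samples[seq(1L, nrow(session$samples), by = factor), ]
  session$rate <- session$rate / factor
  session
}
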