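## File formats. Sessions: a CSV of samples (angles in degrees in files,
## radians in memory; positions in metres) plus a JSON sidecar holding events,
## morphology, rate and provenance. Target sets: a single CSV. Models: a
## single JSON archive with a format version. All writers embed the seeds and
## config hash they were given.

SESSION_CSV_COLS <- c(
  "t_s", paste0(ANGLE_COLS, "_deg"),
  "shoulder_x_m", "shoulder_y_m", "shoulder_z_m", "trial"
)

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read and write sessions
#'
#' A session is stored as `<path>` (CSV, one row per sample: `t_s`, the seven
#' angle columns in degrees, `shoulder_{x,y,z}_m`, `trial`) plus a JSON
#' sidecar `<path with .json>` holding the events, morphology, sampling rate
#' and provenance. The round trip is lossless up to the degree/radian
#' conversion (< 1e-9 rad).
#'
#' @param session An `arm_session`.
#' @param path CSV file path (the sidecar path is derived from it).
#' @param provenance Optional named list (seeds, config hash) embedded in the
#'   sidecar.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns an `arm_session`.
#' @export
write_session <- function(session, path, provenance = NULL) {
  if (!inherits(session, "arm_session")) abort("`session` must be an arm_session.")
  s <- session$samples
  out <- tibble(t_s = s$t)
  for (a in ANGLE_COLS) out[[paste0(a, "_deg")]] <- rad2deg(s[[a]])
  out$shoulder_x_m <- s$shoulder_x
  out$shoulder_y_m <- s$shoulder_y
  out$shoulder_z_m <- s$shoulder_z
  out$trial <- if ("trial" %in% names(s)) s$trial else NA_integer_
  readr::write_csv(out, path)
  side <- list(
    format = "hybridarm-session", format_version = "1.0",
    rate_hz = session$rate,
    morphology = list(
      upper_arm_len = session$morph$upper_arm_len,
      forearm_len = session$morph$forearm_len,
      hand_len = session$morph$hand_len,
      side = session$morph$side
    ),
    events = session$events,
    provenance = provenance
  )
  jsonlite::write_json(side, sidecar_path(path),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such session file: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("missing session sidecar: %s", sp))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(SESSION_CSV_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("session CSV lacks columns: ", paste(missing, collapse = ", ")))
  }
  bad <- which(!vapply(
    raw[setdiff(SESSION_CSV_COLS, "trial")],
    is.numeric, logical(1)
  ))
  if (length(bad) > 0) {
    abort(paste0("non-numeric session columns: ", paste(names(bad), collapse = ", ")))
  }
  side <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
    error = function(e) abort(sprintf("malformed session sidecar %s: %s", sp, conditionMessage(e)))
  )
  for (field in c("rate_hz", "morphology", "events")) {
    if (is.null(side[[field]])) {
      abort(sprintf("session sidecar lacks field `%s` (truncated file?).", field))
    }
  }
  if (any(diff(raw$t_s) <= 0)) {
    i <- which(diff(raw$t_s) <= 0)[1]
    abort(sprintf("non-monotone timestamps at CSV line %d.", i + 2L))
  }
  samples <- tibble(t = raw$t_s)
  for (a in ANGLE_COLS) samples[[a]] <- deg2rad(raw[[paste0(a, "_deg")]])
  samples$shoulder_x <- raw$shoulder_x_m
  samples$shoulder_y <- raw$shoulder_y_m
  samples$shoulder_z <- raw$shoulder_z_m
  samples$trial <- raw$trial
  m <- side$morphology
  new_session(
    samples,
    as_tibble(side$events),
    arm_morphology(m$upper_arm_len, m$forearm_len, m$hand_len, m$side),
    side$rate_hz
  )
}

#' Read and write target sets
#'
#' Target sets are CSVs with columns `index`, `role`, `x_m`, `y_m`, `z_m`,
#' `incl_deg`, `azim_deg` (degrees in files, radians in memory).
#'
#' @param targets A `target_set` tibble.
#' @param path CSV file path.
#' @return `write_targets()` returns `path` invisibly; `read_targets()` a
#'   `target_set` tibble.
#' @export
write_targets <- function(targets, path) {
  targets <- as_tibble(targets)
  out <- tibble(
    index = targets$index, role = targets$role,
    x_m = targets$x, y_m = targets$y, z_m = targets$z,
    incl_deg = rad2deg(targets$incl), azim_deg = rad2deg(targets$azim)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such target file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("index", "role", "x_m", "y_m", "z_m", "incl_deg", "azim_deg")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("target CSV lacks columns: ", paste(missing, collapse = ", ")))
  }
  out <- tibble(
    index = raw$index, role = raw$role,
    x = raw$x_m, y = raw$y_m, z = raw$z_m,
    incl = deg2rad(raw$incl_deg), azim = deg2rad(raw$azim_deg)
  )
  structure(out, class = c("target_set", class(out)))
}

#' Save and load control models
#'
#' A model is a single portable JSON archive: layer weights, normalisation
#' constants, clipping ranges, the training-config snapshot, provenance and a
#' format version.
#'
#' @param model An `arm_control_model`.
#' @param path File path (`.json`).
#' @return `write_model()` returns `path` invisibly; `read_model()` an
#'   `arm_control_model`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "arm_control_model")) abort("`model` must be an arm_control_model.")
  payload <- list(
    format = "hybridarm-model", format_version = model$format_version,
    provenance = model$provenance, n_pairs = model$n_pairs,
    config = unclass(model$config),
    norm = model$norm,
    clip = model$clip,
    loss_history = model$loss_history,
    members = lapply(model$members, function(member) {
      lapply(member, function(l) list(W = l$W, b = l$b))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such model file: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "hybridarm-model") {
    abort("not a hybridarm model archive.")
  }
  members <- lapply(p$members, function(member) {
    lapply(seq_len(nrow_or_len(member)), function(i) {
      layer <- if (is.data.frame(member)) {
        list(W = member$W[[i]], b = member$b[[i]])
      } else {
        member[[i]]
      }
      list(W = as.matrix(layer$W), b = as.numeric(layer$b))
    })
  })
  clip <- as.matrix(p$clip)
  colnames(clip) <- c("min", "max")
  rownames(clip) <- DISTAL_COLS
  cfg <- p$config
  structure(
    list(
      members = members,
      norm = lapply(p$norm, function(v) setNames(as.numeric(v), names(v))),
      clip = clip,
      config = training_config(
        epochs = cfg$epochs, learning_rate = cfg$learning_rate,
        optimizer = cfg$optimizer, momentum = cfg$momentum,
        batch_size = cfg$batch_size,
        lr_decay_at = if (is.null(cfg$lr_decay_at)) Inf else as.numeric(cfg$lr_decay_at),
        tail_average = cfg$tail_average, n_models = cfg$n_models,
        input_encoding = cfg$input_encoding, seed = cfg$seed
      ),
      provenance = p$provenance,
      n_pairs = p$n_pairs,
      loss_history = lapply(p$loss_history, as.numeric),
      format_version = p$format_version
    ),
    class = "arm_control_model"
  )
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration for the end-to-end pipeline and fills
#' defaults: morphology block, target counts (300 plausible / 200 possible),
#' GNG parameters, training preset, tolerances, time limit and seed.
#'
#' @param path YAML or JSON file.
#' @return A named list of class `pipeline_config`, with a `config_hash`
#'   attribute.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(
    list(
      morphology = list(
        upper_arm_len = 0.30, forearm_len = 0.25, hand_len = 0.08,
        side = "right"
      ),
      n_plausible = 300, n_possible = 200, downsample_factor = 10,
      gng = list(), training_preset = "default", tolerance = "relaxed",
      time_limit = 10, seed = 1, move_duration = 1.3, rate = 90
    ),
    raw
  )
  attr(cfg, "config_hash") <- rlang::hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_morphology <- function(cfg) {
  m <- cfg$morphology
  arm_morphology(m$upper_arm_len, m$forearm_len, m$hand_len, m$side)
}

config_training <- function(cfg, seed = NULL) {
  switch(cfg$training_preset,
    own = preset_own(seed = seed),
    generic = preset_generic(seed = seed),
    training_config(seed = seed)
  )
}
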