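## Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Run `expr` under a fixed seed when `seed` is non-NULL, restoring RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, finite = TRUE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

## Coerce a posture argument (named vector or data frame) to an n x 7 matrix
## with columns in canonical order.
angles_matrix <- function(angles) {
  if (is.numeric(angles) && !is.null(names(angles))) {
    angles <- as_tibble(as.list(angles))
  }
  if (!is.data.frame(angles)) {
    abort("`angles` must be a data frame of joint angles or a named numeric vector.")
  }
  missing <- setdiff(ANGLE_COLS, names(angles))
  if (length(missing) > 0) {
    abort(paste0("missing joint-angle columns: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(angles[ANGLE_COLS])
  storage.mode(m) <- "double"
  if (nrow(m) == 0) abort("`angles` has no rows.")
  if (!all(is.finite(m))) abort("joint angles must all be finite.")
  m
}

location_matrix <- function(loc) {
  if (is.numeric(loc) && !is.null(names(loc))) loc <- as_tibble(as.list(loc))
  if (!is.data.frame(loc)) {
    abort("hand locations must be a data frame or a named numeric vector.")
  }
  missing <- setdiff(LOCATION_COLS, names(loc))
  if (length(missing) > 0) {
    abort(paste0("missing hand-location columns: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(loc[LOCATION_COLS])
  storage.mode(m) <- "double"
  m
}

vnorm <- function(v) sqrt(sum(v^2))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
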