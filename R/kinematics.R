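## 7-DoF arm kinematics.
##
## Frame convention (fixed, shoulder-centred): x anterior, y toward the
## subject's left, z up; right-handed. The zero posture hangs the whole arm
## along -z with the hand axis pointing along -z. Rotation sequence, intrinsic
## and proximal to distal:
##   s_fe about -y (positive = flexion, arm forward),
##   s_aa about -x' (positive = abduction; lateral, i.e. toward -y for a
##        right arm),
##   h_r about the humeral axis (local -z),
##   e_fe about the local -y elbow axis (positive = flexion, forearm forward),
##   f_ps about the forearm axis (local -z),
##   w_fe about the local -y wrist axis, w_ru about the local +x axis.
## A left-sided arm is the mirror image of the right-sided chain: the four
## axial/lateral angles (s_aa, h_r, f_ps, w_ru) change sign and y is
## reflected.

#' Arm morphology
#'
#' Segment lengths of the three-segment arm model (upper arm: shoulder to
#' elbow; forearm: elbow to wrist; hand: wrist to hand centre), plus the body
#' side. `arm_length` is the sum of the three segment lengths and scales the
#' workspace filters.
#'
#' @param upper_arm_len,forearm_len,hand_len Segment lengths in metres (> 0).
#' @param side `"right"` or `"left"`.
#' @return An object of class `arm_morphology`.
#' @examples
#' arm_morphology(0.30, 0.25, 0.08)
#' @export
arm_morphology <- function(upper_arm_len = 0.30, forearm_len = 0.25,
                           hand_len = 0.08, side = c("right", "left")) {
  side <- match.arg(side)
  check_number(upper_arm_len, "upper_arm_len", positive = TRUE)
  check_number(forearm_len, "forearm_len", positive = TRUE)
  check_number(hand_len, "hand_len", positive = TRUE)
  structure(
    list(
      upper_arm_len = upper_arm_len, forearm_len = forearm_len,
      hand_len = hand_len, side = side,
      arm_length = upper_arm_len + forearm_len + hand_len
    ),
    class = "arm_morphology"
  )
}

#' @export
print.arm_morphology <- function(x, ...) {
  cat(sprintf(
    "<arm_morphology> %s arm: upper %.3f m, forearm %.3f m, hand %.3f m (total %.3f m)\n",
    x$side, x$upper_arm_len, x$forearm_len, x$hand_len, x$arm_length
  ))
  invisible(x)
}

check_morphology <- function(morph) {
  if (!inherits(morph, "arm_morphology")) {
    abort("`morph` must be an `arm_morphology` object (see arm_morphology()).")
  }
  invisible(morph)
}

#' Joint angles of the 7-DoF arm
#'
#' Builds a one-row tibble of the seven joint angles in canonical order
#' (radians): shoulder flexion-extension `s_fe`, shoulder abduction-adduction
#' `s_aa`, humeral rotation `h_r`, elbow flexion-extension `e_fe`, forearm
#' pronation-supination `f_ps`, wrist flexion-extension `w_fe`, wrist
#' radial-ulnar deviation `w_ru`. Angle trajectories are plain tibbles with
#' these columns, one row per sample.
#'
#' @param s_fe,s_aa,h_r,e_fe,f_ps,w_fe,w_ru Angles in radians.
#' @return A one-row tibble with the seven angle columns.
#' @examples
#' joint_angles(e_fe = pi / 2)
#' @export
joint_angles <- function(s_fe = 0, s_aa = 0, h_r = 0, e_fe = 0,
                         f_ps = 0, w_fe = 0, w_ru = 0) {
  tibble(
    s_fe = s_fe, s_aa = s_aa, h_r = h_r, e_fe = e_fe,
    f_ps = f_ps, w_fe = w_fe, w_ru = w_ru
  )
}

## Rotation-composition helpers. A rotation matrix per sample is stored as
## three n x 3 column blocks c1, c2, c3 (the matrix columns); composing with a
## rotation about a fixed local axis mixes two blocks.
rot_new <- function(n) {
  list(
    c1 = cbind(rep(1, n), 0, 0),
    c2 = cbind(rep(0, n), 1, 0),
    c3 = cbind(rep(0, n), 0, 1)
  )
}
rot_about_neg_y <- function(R, th) {
  c_ <- cos(th); s_ <- sin(th)
  c1 <- R$c1 * c_ + R$c3 * s_
  c3 <- R$c3 * c_ - R$c1 * s_
  list(c1 = c1, c2 = R$c2, c3 = c3)
}
rot_about_neg_x <- function(R, th) {
  c_ <- cos(th); s_ <- sin(th)
  c2 <- R$c2 * c_ - R$c3 * s_
  c3 <- R$c2 * s_ + R$c3 * c_
  list(c1 = R$c1, c2 = c2, c3 = c3)
}
rot_about_neg_z <- function(R, th) {
  c_ <- cos(th); s_ <- sin(th)
  c1 <- R$c1 * c_ - R$c2 * s_
  c2 <- R$c1 * s_ + R$c2 * c_
  list(c1 = c1, c2 = c2, c3 = R$c3)
}
rot_about_pos_x <- function(R, th) rot_about_neg_x(R, -th)

## Vectorised forward kinematics core: angle matrix (n x 7, canonical order)
## to joint centres and hand axis, all n x 3. The left side is handled as the
## mirror image of the right-sided chain.
fk_core <- function(A, morph) {
  n <- nrow(A)
  left <- morph$side == "left"
  if (left) A[, c("s_aa", "h_r", "f_ps", "w_ru")] <- -A[, c("s_aa", "h_r", "f_ps", "w_ru")]

  R <- rot_new(n)
  R <- rot_about_neg_y(R, A[, "s_fe"])
  R <- rot_about_neg_x(R, A[, "s_aa"])
  R <- rot_about_neg_z(R, A[, "h_r"])
  elbow <- -morph$upper_arm_len * R$c3
  R <- rot_about_neg_y(R, A[, "e_fe"])
  R <- rot_about_neg_z(R, A[, "f_ps"])
  wrist <- elbow - morph$forearm_len * R$c3
  R <- rot_about_neg_y(R, A[, "w_fe"])
  R <- rot_about_pos_x(R, A[, "w_ru"])
  hand_center <- wrist - morph$hand_len * R$c3
  hand_axis <- -R$c3

  if (left) {
    elbow[, 2] <- -elbow[, 2]
    wrist[, 2] <- -wrist[, 2]
    hand_center[, 2] <- -hand_center[, 2]
    hand_axis[, 2] <- -hand_axis[, 2]
  }
  colnames(elbow) <- colnames(wrist) <- colnames(hand_center) <-
    colnames(hand_axis) <- c("x", "y", "z")
  list(
    shoulder = matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z"))),
    elbow = elbow, wrist = wrist,
    hand_center = hand_center, hand_axis = hand_axis
  )
}

#' Forward kinematics of a single arm posture
#'
#' Maps the seven joint angles to the joint centres (shoulder, elbow, wrist,
#' hand centre) and the hand axis in the shoulder-centred frame (x anterior,
#' y toward the subject's left, z up). The hand axis is the wrist-to-hand
#' direction of the grasp axis, pointing along -z in the zero posture.
#'
#' @param angles A one-row data frame with the seven angle columns (see
#'   [joint_angles()]), or a named numeric vector.
#' @param morph An [arm_morphology()].
#' @return An object of class `arm_posture`: a list with 3-vectors `shoulder`,
#'   `elbow`, `wrist`, `hand_center`, unit 3-vector `hand_axis`, and the input
#'   `angles`.
#' @examples
#' forward_kinematics(joint_angles(e_fe = pi / 2), arm_morphology())
#' @export
forward_kinematics <- function(angles, morph) {
  check_morphology(morph)
  A <- angles_matrix(angles)
  if (nrow(A) != 1L) abort("`angles` must describe a single posture; see hand_location() for trajectories.")
  k <- fk_core(A, morph)
  structure(
    list(
      shoulder = k$shoulder[1, ], elbow = k$elbow[1, ], wrist = k$wrist[1, ],
      hand_center = k$hand_center[1, ], hand_axis = k$hand_axis[1, ],
      angles = as_tibble(as.data.frame(A))
    ),
    class = "arm_posture"
  )
}

#' @export
print.arm_posture <- function(x, ...) {
  cat("<arm_posture>\n")
  cat(sprintf("  elbow       (%.3f, %.3f, %.3f) m\n", x$elbow[1], x$elbow[2], x$elbow[3]))
  cat(sprintf("  wrist       (%.3f, %.3f, %.3f) m\n", x$wrist[1], x$wrist[2], x$wrist[3]))
  cat(sprintf("  hand centre (%.3f, %.3f, %.3f) m\n", x$hand_center[1], x$hand_center[2], x$hand_center[3]))
  cat(sprintf("  hand axis   (%.3f, %.3f, %.3f)\n", x$hand_axis[1], x$hand_axis[2], x$hand_axis[3]))
  invisible(x)
}

## Unit axis (n x 3) -> (incl, azim). incl in [0, pi] is the angle from
## vertical (+z); azim in (-pi, pi] the azimuth about +z measured from +x.
## A vertical axis has undefined azimuth, resolved to 0 by convention.
axis_to_spherical <- function(axis) {
  incl <- acos(clamp(axis[, 3], -1, 1))
  azim <- atan2(axis[, 2], axis[, 1])
  azim[sin(incl) < 1e-12] <- 0
  cbind(incl = incl, azim = azim)
}

spherical_to_axis <- function(incl, azim) {
  cbind(
    x = sin(incl) * cos(azim),
    y = sin(incl) * sin(azim),
    z = cos(incl)
  )
}

#' Hand location of one or more postures
#'
#' The 5-parameter hand location: Cartesian hand-centre position (m) plus the
#' two spherical angles of the hand axis relative to vertical — inclination
#' `incl` in `[0, pi]` (0 = axis up, pi = axis down) and azimuth `azim` in
#' `(-pi, pi]` about the vertical, measured from the anterior direction.
#' When the hand axis is exactly vertical the azimuth is set to 0.
#'
#' @param angles Data frame of joint angles (one row per posture) or a named
#'   numeric vector for a single posture.
#' @param morph An [arm_morphology()].
#' @return A tibble with columns `x`, `y`, `z`, `incl`, `azim`, one row per
#'   posture.
#' @examples
#' hand_location(joint_angles(), arm_morphology())
#' @export
hand_location <- function(angles, morph) {
  check_morphology(morph)
  A <- angles_matrix(angles)
  k <- fk_core(A, morph)
  sph <- axis_to_spherical(k$hand_axis)
  tibble(
    x = unname(k$hand_center[, 1]), y = unname(k$hand_center[, 2]),
    z = unname(k$hand_center[, 3]),
    incl = unname(sph[, "incl"]), azim = unname(sph[, "azim"])
  )
}

#' Remap hand locations to a different morphology
#'
#' Recomputes the hand location of every posture of an angle trajectory under
#' a target morphology, leaving the joint angles untouched. This is the
#' donor-to-user adaptation used to build generic training data: the same
#' postures give different hand locations on different arm sizes.
#'
#' @param angle_trajectory Data frame of joint angles, one row per sample.
#' @param target_morph The [arm_morphology()] to remap onto.
#' @return A tibble of hand locations (`x`, `y`, `z`, `incl`, `azim`).
#' @export
remap_hand_locations <- function(angle_trajectory, target_morph) {
  if (is.data.frame(angle_trajectory) && nrow(angle_trajectory) == 0) {
    abort("`angle_trajectory` must be non-empty.")
  }
  hand_location(angle_trajectory, target_morph)
}

#' Humeral rotation from the shoulder-elbow-wrist triangle
#'
#' Humeral (internal/external) rotation recovered from joint centres: the
#' signed rotation of the normal of the shoulder-elbow-wrist triangle about
#' the humeral (shoulder-to-elbow) axis, measured from a reference direction.
#' The construction degenerates when the three centres are collinear (straight
#' arm), which is why the elbow range of motion is capped away from full
#' extension upstream.
#'
#' @param shoulder,elbow,wrist Joint centres, numeric 3-vectors (m).
#' @param reference_axis Unit 3-vector from which the rotation is measured; it
#'   must not be parallel to the humeral axis.
#' @return Signed angle in radians, in `(-pi, pi]`.
#' @export
humeral_rotation_from_centers <- function(shoulder, elbow, wrist, reference_axis) {
  u <- elbow - shoulder
  nu <- vnorm(u)
  if (nu < 1e-12) abort("shoulder and elbow centres coincide.")
  u <- u / nu
  nrm <- c(
    u[2] * (wrist - elbow)[3] - u[3] * (wrist - elbow)[2],
    u[3] * (wrist - elbow)[1] - u[1] * (wrist - elbow)[3],
    u[1] * (wrist - elbow)[2] - u[2] * (wrist - elbow)[1]
  )
  if (vnorm(nrm) < 1e-9 * vnorm(wrist - elbow)) {
    abort("degenerate geometry: shoulder, elbow and wrist are collinear (straight arm).")
  }
  nrm <- nrm / vnorm(nrm)
  r_perp <- reference_axis - sum(reference_axis * u) * u
  if (vnorm(r_perp) < 1e-9) {
    abort("`reference_axis` is parallel to the humeral axis.")
  }
  r_perp <- r_perp / vnorm(r_perp)
  cross_rn <- c(
    r_perp[2] * nrm[3] - r_perp[3] * nrm[2],
    r_perp[3] * nrm[1] - r_perp[1] * nrm[3],
    r_perp[1] * nrm[2] - r_perp[2] * nrm[1]
  )
  atan2(sum(cross_rn * u), sum(r_perp * nrm))
}

#' Mirror across the medial plane
#'
#' Reflects postures or hand locations across the medial (x-z) plane, mapping
#' a right-arm configuration onto the equivalent left-arm one and vice versa.
#' For hand locations: `y -> -y`, `azim -> -azim`. For joint angles the four
#' lateral/axial angles (`s_aa`, `h_r`, `f_ps`, `w_ru`) change sign. Mirroring
#' is an involution, and commutes with forward kinematics across sides:
#' mirrored angles on the mirrored morphology reproduce the mirrored hand
#' location.
#'
#' @param x A data frame of joint angles (`mirror_angles()`) or of hand
#'   locations / targets (`mirror_location()`).
#' @return The mirrored object, same shape as the input.
#' @export
mirror_angles <- function(x) {
  A <- as_tibble(x)
  missing <- setdiff(ANGLE_COLS, names(A))
  if (length(missing) > 0) abort("input is not a joint-angle table.")
  for (col in c("s_aa", "h_r", "f_ps", "w_ru")) A[[col]] <- -A[[col]]
  A
}

#' @rdname mirror_angles
#' @export
mirror_location <- function(x) {
  loc <- as_tibble(x)
  missing <- setdiff(c("y", "azim"), names(loc))
  if (length(missing) > 0) abort("input is not a hand-location table.")
  loc$y <- -loc$y
  loc$azim <- -loc$azim
  ## keep azim in (-pi, pi]: -pi maps to pi
  loc$azim[loc$azim <= -pi + 1e-15] <- loc$azim[loc$azim <= -pi + 1e-15] + 2 * pi
  loc
}

#' Mirror an arm morphology to the opposite side
#' @param morph An [arm_morphology()].
#' @return The same morphology on the opposite side.
#' @export
mirror_morphology <- function(morph) {
  check_morphology(morph)
  arm_morphology(morph$upper_arm_len, morph$forearm_len, morph$hand_len,
    side = if (morph$side == "right") "left" else "right"
  )
}
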