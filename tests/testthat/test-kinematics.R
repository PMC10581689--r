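test_that("zero posture hangs the arm straight down", {
  m <- test_morph()
  p <- forward_kinematics(joint_angles(), m)
  expect_equal(unname(p$hand_center), c(0, 0, -0.63), tolerance = 1e-12)
  expect_equal(unname(p$hand_axis), c(0, 0, -1), tolerance = 1e-12)
  expect_equal(unname(p$elbow), c(0, 0, -0.30), tolerance = 1e-12)
})

test_that("pure elbow flexion of 90 degrees points the forearm anterior", {
  p <- forward_kinematics(joint_angles(e_fe = pi / 2), test_morph())
  expect_equal(unname(p$elbow), c(0, 0, -0.30), tolerance = 1e-12)
  expect_equal(unname(p$hand_center), c(0.33, 0, -0.30), tolerance = 1e-12)
})

test_that("non-finite angles are rejected", {
  expect_error(forward_kinematics(joint_angles(s_fe = NaN), test_morph()), "finite")
  expect_error(forward_kinematics(joint_angles(e_fe = Inf), test_morph()), "finite")
})

test_that("segment lengths are conserved for random postures", {
  m <- test_morph()
  A <- random_postures(1000, seed = 4)
  k <- hybridarm:::fk_core(as.matrix(A), m)
  expect_lt(max(abs(sqrt(rowSums(k$elbow^2)) - m$upper_arm_len)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums((k$wrist - k$elbow)^2)) - m$forearm_len)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums((k$hand_center - k$wrist)^2)) - m$hand_len)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(k$hand_axis^2)) - 1)), 1e-9)
})

test_that("hand orientation round-trips through spherical coordinates", {
  m <- test_morph()
  expect_equal(hand_location(joint_angles(), m)$incl, pi)
  expect_equal(hand_location(joint_angles(), m)$azim, 0)

  A <- random_postures(100, seed = 9)
  k <- hybridarm:::fk_core(as.matrix(A), m)
  loc <- hand_location(A, m)
  rebuilt <- hybridarm:::spherical_to_axis(loc$incl, loc$azim)
  expect_lt(max(abs(rebuilt - k$hand_axis)), 1e-9)
})

test_that("a vertical hand axis gets azimuth 0 by convention", {
  # wrist flexed 180 deg from hanging: axis exactly +z
  loc <- hand_location(joint_angles(w_fe = pi), test_morph())
  expect_equal(loc$incl, 0, tolerance = 1e-12)
  expect_equal(loc$azim, 0)
})

test_that("humeral rotation is recovered from the joint-centre triangle", {
  s <- c(0, 0, 0)
  e <- c(0, 0, -0.3)
  w <- c(0.25, 0, -0.3)
  u <- (e - s) / sqrt(sum((e - s)^2))
  nrm <- c(0, -1, 0) # cross(e-s, w-e) direction
  expect_equal(humeral_rotation_from_centers(s, e, w, nrm), 0, tolerance = 1e-12)

  # rotate the wrist about the humeral axis by +pi/4; the triangle normal
  # rotates with it
  rot <- function(v, axis, th) {
    v * cos(th) + c(
      axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]
    ) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
  }
  w2 <- e + rot(w - e, u, pi / 4)
  got <- humeral_rotation_from_centers(s, e, w2, nrm)
  expect_equal(got, pi / 4, tolerance = 1e-9)

  expect_error(
    humeral_rotation_from_centers(s, e, c(0, 0, -0.55), nrm),
    "collinear"
  )
})

test_that("remapping with the same morphology is the identity", {
  m <- test_morph()
  A <- random_postures(50, seed = 3)
  expect_equal(remap_hand_locations(A, m), hand_location(A, m), tolerance = 1e-12)
})

test_that("uniform morphology scaling scales positions, not orientations", {
  m <- test_morph()
  m2 <- arm_morphology(0.30 * 1.1, 0.25 * 1.1, 0.08 * 1.1)
  A <- random_postures(50, seed = 5)
  l1 <- hand_location(A, m)
  l2 <- remap_hand_locations(A, m2)
  expect_equal(as.matrix(l2[c("x", "y", "z")]),
    1.1 * as.matrix(l1[c("x", "y", "z")]),
    tolerance = 1e-9
  )
  expect_equal(l2[c("incl", "azim")], l1[c("incl", "azim")], tolerance = 1e-9)
})

test_that("single zero posture remaps to the straight-down location", {
  loc <- remap_hand_locations(joint_angles(), test_morph())
  expect_equal(unlist(loc), c(x = 0, y = 0, z = -0.63, incl = pi, azim = 0),
    tolerance = 1e-12
  )
})

test_that("mirroring is an involution and matches the reflection definition", {
  A <- random_postures(1000, seed = 6)
  expect_equal(mirror_angles(mirror_angles(A)), A)
  loc <- tibble::tibble(x = 0.2, y = 0.1, z = -0.3, incl = 1.0, azim = 0.4)
  expect_equal(
    unlist(mirror_location(loc)),
    c(x = 0.2, y = -0.1, z = -0.3, incl = 1.0, azim = -0.4)
  )
  expect_equal(mirror_location(mirror_location(loc)), loc)
})

test_that("forward kinematics commutes with mirroring across sides", {
  mr <- test_morph("right")
  ml <- test_morph("left")
  A <- random_postures(1000, seed = 7)
  direct <- hand_location(mirror_angles(A), ml)
  mirrored <- mirror_location(hand_location(A, mr))
  expect_equal(as.matrix(direct[c("x", "y", "z")]),
    as.matrix(mirrored[c("x", "y", "z")]),
    tolerance = 1e-9
  )
  ax1 <- hybridarm:::spherical_to_axis(direct$incl, direct$azim)
  ax2 <- hybridarm:::spherical_to_axis(mirrored$incl, mirrored$azim)
  expect_lt(max(abs(ax1 - ax2)), 1e-9)
})
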