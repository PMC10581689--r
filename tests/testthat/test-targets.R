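test_that("ROM estimation recovers generator bounds and caps elbow extension", {
  rom_true <- default_rom(cap_elbow = FALSE)
  ses <- generate_rom_session(rom_true, test_morph(),
    synergy_params(noise_sd = 0), seed = 1
  )
  rom <- estimate_rom(ses, cap_elbow = FALSE)
  expect_equal(rom$min, rom_true$min, tolerance = 1e-9)
  expect_equal(rom$max, rom_true$max, tolerance = 1e-9)

  capped <- estimate_rom(ses)
  i <- which(capped$dof == "e_fe")
  expect_equal(
    capped$min[i],
    rom_true$min[i] + 0.15 * (rom_true$max[i] - rom_true$min[i]),
    tolerance = 1e-9
  )
  expect_equal(capped$max[i], rom_true$max[i], tolerance = 1e-9)
})

test_that("the 85% extension cap reproduces the worked arithmetic", {
  # elbow flexion observed between 10 and 150 degrees, extension end at 10:
  # capped extension bound is 10 + 0.15 * 140 = 31 degrees
  angles <- joint_angles()[rep(1, 11), ]
  angles$e_fe <- seq(10, 150, length.out = 11) * pi / 180
  for (d in setdiff(ANGLE_COLS, "e_fe")) angles[[d]] <- seq(0, 0.1, length.out = 11)
  rom <- estimate_rom(make_session(angles))
  expect_equal(rom$min[rom$dof == "e_fe"] * 180 / pi, 31, tolerance = 1e-9)
})

test_that("degenerate (constant) trajectories are rejected", {
  angles <- joint_angles()[rep(1, 50), ]
  expect_error(estimate_rom(make_session(angles)), "degenerate")
})

test_that("workspace filters implement the three criteria", {
  m <- test_morph() # arm length 0.63
  L <- m$arm_length
  base <- tibble::tibble(x = 0.5 * L, y = 0, z = -0.2, incl = 0.3, azim = 0)
  expect_true(filter_target(base, m))
  # criterion 1: axis at 120 deg from vertical (pointing downwards)
  expect_false(filter_target(dplyr::mutate(base, incl = 120 * pi / 180), m))
  # criterion 2: centre too close to the trunk
  expect_false(filter_target(dplyr::mutate(base, x = L / 4), m))
  # criterion 3: too far below the shoulder plane
  expect_false(filter_target(dplyr::mutate(base, z = -0.7 * L), m))
  # all three satisfied at a corner of the admissible region
  corner <- tibble::tibble(x = 0.5 * L, y = 0, z = -0.5 * L, incl = 0, azim = 0)
  expect_true(filter_target(corner, m))
})

test_that("plausible sampling returns n filtered targets with alternating roles", {
  m <- test_morph()
  rom <- default_rom()
  tg <- sample_plausible_targets(rom, m, n = 4, seed = 11)
  expect_equal(tg$role, c("pick", "place", "pick", "place"))
  expect_equal(tg$index, 1:4)

  tg1 <- sample_plausible_targets(rom, m, n = 50, seed = 5)
  tg2 <- sample_plausible_targets(rom, m, n = 50, seed = 5)
  expect_identical(tg1, tg2)
  expect_true(all(filter_target(tg1, m)))
})

test_that("plausible sampling fails loudly when filters reject everything", {
  # a ROM confined to arm-hanging postures never points the axis upward
  rom <- arm_rom(tibble::tibble(
    dof = ANGLE_COLS,
    min = rep(-0.01, 7), max = rep(0.01, 7)
  ))
  expect_error(
    sample_plausible_targets(rom, test_morph(), n = 5, seed = 1, max_draws = 2000),
    "reject"
  )
})

test_that("possible-target ordering respects the 20 cm separation", {
  m <- test_morph()
  nodes <- random_postures(60, seed = 2)
  tg <- possible_targets(nodes, m, seed = 3)
  expect_equal(nrow(tg), 60)
  centers <- as.matrix(tg[c("x", "y", "z")])
  sep <- sqrt(rowSums(diff(centers)^2))
  expect_true(all(sep >= 0.20))
  # the sequence is a permutation of the nodes' forward-kinematics image
  locs <- hand_location(nodes, m)
  expect_equal(
    dplyr::arrange(tg[LOC_COLS], .data$x, .data$y, .data$z),
    dplyr::arrange(locs, .data$x, .data$y, .data$z),
    ignore_attr = TRUE
  )
  expect_equal(tg$role, rep_len(c("pick", "place"), 60))
})

test_that("infeasible separation constraints raise an error", {
  m <- test_morph()
  two <- joint_angles(e_fe = c(1.0, 1.05))
  locs <- hand_location(two, m)
  d <- sqrt(sum((locs[1, 1:3] - locs[2, 1:3])^2))
  expect_lt(d, 0.05)
  expect_error(
    possible_targets(two, m, seed = 1, max_restarts = 10),
    "separation"
  )
})

test_that("downsampling keeps every factor-th sample", {
  angles <- joint_angles()[rep(1, 900), ]
  angles$s_fe <- seq(0, 1, length.out = 900)
  ses <- make_session(angles)
  expect_equal(nrow(downsample_session(ses, 10)$samples), 90)
  expect_equal(downsample_session(ses, 1)$samples, ses$samples)
  expect_error(downsample_session(ses, 0), "positive integer")
  expect_error(downsample_session(ses, 2.5), "positive integer")
})
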