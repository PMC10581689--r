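test_that("training pairs use the hand location of each sample's own posture", {
  m <- test_morph()
  ses <- make_session(joint_angles(), m)
  pairs <- build_training_pairs(ses)
  expect_equal(nrow(pairs), 1)
  expect_equal(
    unlist(pairs[1, c("s_fe", "s_aa", "x", "y", "z", "incl", "azim")]),
    c(s_fe = 0, s_aa = 0, x = 0, y = 0, z = -0.63, incl = pi, azim = 0),
    tolerance = 1e-12
  )
  expect_equal(unlist(pairs[1, DISTAL_COLS]),
    c(h_r = 0, e_fe = 0, f_ps = 0, w_fe = 0, w_ru = 0),
    tolerance = 1e-12
  )

  A <- random_postures(200, seed = 31)
  ses <- make_session(A, m)
  pairs <- build_training_pairs(ses)
  expect_equal(nrow(pairs), 200)
  # self-consistency: the context is the hand location of the full posture
  expect_equal(
    as.matrix(pairs[LOC_COLS]),
    as.matrix(hand_location(A, m)),
    tolerance = 1e-9
  )
})

test_that("residual-limb sessions cannot supply training pairs", {
  ses <- make_session(random_postures(10, seed = 1), test_morph())
  ses$samples$w_ru <- NULL
  ses$samples$f_ps <- NULL
  expect_error(build_training_pairs(ses), "residual-limb")
})

test_that("a donor pool of one subject equal to the user reproduces own pairs", {
  m <- test_morph()
  ses <- make_session(random_postures(150, seed = 32), m)
  expect_equal(
    build_generic_dataset(list(ses), m),
    build_training_pairs(ses),
    tolerance = 1e-12
  )
})

test_that("donor pools concatenate and mirror to the user's side", {
  m <- test_morph()
  donors <- lapply(1:3, function(i) make_session(random_postures(100, seed = 40 + i), m))
  pool <- build_generic_dataset(donors, m)
  expect_equal(nrow(pool), 300)

  # right-handed donors adapted to a left-sided user: contexts must equal the
  # mirror of the remap onto the user's mirrored (right-sided) morphology
  ml <- test_morph("left")
  pool_l <- build_generic_dataset(donors[1], ml)
  expected <- mirror_location(
    remap_hand_locations(donors[[1]]$samples[ANGLE_COLS], mirror_morphology(ml))
  )
  expect_equal(as.matrix(pool_l[LOC_COLS]), as.matrix(expected), tolerance = 1e-9)
  # outputs are the donors' distal angles mirrored to the user's side
  expect_equal(
    as.matrix(pool_l[DISTAL_COLS]),
    as.matrix(mirror_angles(donors[[1]]$samples[ANGLE_COLS])[DISTAL_COLS]),
    tolerance = 1e-12
  )
})

test_that("the published presets are recorded verbatim", {
  own <- preset_own()
  expect_equal(own$epochs, 30L)
  expect_equal(own$learning_rate, 1e-4)
  gen <- preset_generic()
  expect_equal(gen$epochs, 10L)
  expect_equal(gen$learning_rate, 1.59e-7)
  expect_equal(gen$momentum, 0.95)
  expect_equal(gen$optimizer, "sgd")
})

small_training_set <- function(n_targets = 40, seed = 33) {
  m <- test_morph()
  tg <- reachable_targets(n_targets, m, seed = seed)
  ses <- generate_session(tg, m, synergy_params(), seed = seed + 1)
  build_training_pairs(ses)
}

test_that("training is seeded-reproducible and inference deterministic", {
  pairs <- small_training_set()
  cfg <- training_config(epochs = 2, seed = 7)
  m1 <- train_model(pairs, cfg)
  m2 <- train_model(pairs, cfg)
  expect_identical(m1$members, m2$members)

  q <- pairs[1:20, ]
  p1 <- predict_distal(m1, q)
  p2 <- predict_distal(m1, q)
  expect_identical(p1, p2)
  expect_true(all(is.finite(as.matrix(p1))))
})

test_that("training reduces the loss and predictions respect the training range", {
  pairs <- small_training_set()
  mod <- train_model(pairs, training_config(epochs = 5, seed = 8))
  for (h in mod$loss_history) expect_lt(tail(h, 1), h[1])

  # probe far outside the workspace: outputs stay clipped to the seen range
  probe <- pairs[1:50, ]
  probe$x <- probe$x + 5
  probe$z <- probe$z - 5
  pred <- as.matrix(predict_distal(mod, probe))
  for (j in seq_len(5)) {
    expect_true(all(pred[, j] >= mod$clip[j, "min"] - 1e-12))
    expect_true(all(pred[, j] <= mod$clip[j, "max"] + 1e-12))
  }
})

test_that("too-small or malformed training sets are rejected", {
  pairs <- small_training_set()
  expect_error(train_model(pairs[1:50, ], training_config()), "at least 100")
  expect_error(train_model(pairs[, -3], training_config()), "lacks columns")
})

test_that("hybrid composition passes proximal angles through unchanged", {
  m <- test_morph()
  oracle <- synergy_oracle(m, synergy_params(noise_sd = 0))
  tg <- reachable_targets(5, m, seed = 35)
  post <- hybrid_step(oracle, 0.4, 0.2, tg[1, ], m)
  expect_equal(post$angles$s_fe, 0.4)
  expect_equal(post$angles$s_aa, 0.2)

  # with the oracle model and the oracle's own proximal angles, the hybrid
  # hand lands exactly on the target
  ik <- synergy_ik(tg[2, ], m)
  post2 <- hybrid_step(oracle, ik$s_fe, ik$s_aa, tg[2, ], m)
  expect_equal(unname(post2$hand_center),
    as.numeric(tg[2, c("x", "y", "z")]),
    tolerance = 1e-6
  )

  # changing the target with fixed proximal changes only distal angles
  post3 <- hybrid_step(oracle, ik$s_fe, ik$s_aa, tg[3, ], m)
  expect_equal(post3$angles$s_fe, post2$angles$s_fe)
  expect_equal(post3$angles$s_aa, post2$angles$s_aa)
  expect_false(isTRUE(all.equal(post3$angles[DISTAL_COLS], post2$angles[DISTAL_COLS])))
})

test_that("model summaries expose the layer stack and training snapshot", {
  pairs <- small_training_set()
  mod <- train_model(pairs, training_config(epochs = 2, seed = 9))
  td <- tidy(mod)
  # 8 network inputs under the default axis encoding of the 7-value pair
  expect_equal(td$input_dim, c(8, 256, 256, 64))
  expect_equal(td$output_dim, c(256, 256, 64, 5))
  spherical <- train_model(
    pairs,
    training_config(epochs = 1, input_encoding = "spherical", seed = 10)
  )
  expect_equal(tidy(spherical)$input_dim[1], 7)
  g <- glance(mod)
  expect_equal(g$epochs, 2L)
  expect_equal(g$n_pairs, nrow(pairs))
})
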