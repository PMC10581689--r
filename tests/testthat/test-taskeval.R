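test_that("tolerance presets match the task definition", {
  hard <- tolerance("hard")
  expect_equal(hard$pos_tol, 0.02)
  expect_equal(hard$ang_tol, 5 * pi / 180)
  relaxed <- tolerance("relaxed")
  expect_equal(relaxed$pos_tol, 0.04)
  expect_equal(relaxed$ang_tol, 10 * pi / 180)
})

test_that("target-zone validation separates hard and relaxed constraints", {
  tgt <- tibble::tibble(x = 0.3, y = 0, z = -0.2, incl = 0.5, azim = 0.3)
  hard <- tolerance("hard")
  relaxed <- tolerance("relaxed")
  expect_true(validate_target(tgt, tgt, hard))
  expect_true(validate_target(tgt, tgt, relaxed))

  off3cm <- dplyr::mutate(tgt, x = x + 0.03)
  expect_false(validate_target(off3cm, tgt, hard))
  expect_true(validate_target(off3cm, tgt, relaxed))

  tilt7 <- dplyr::mutate(tgt, incl = incl + 7 * pi / 180)
  expect_false(validate_target(tilt7, tgt, hard))
  expect_true(validate_target(tilt7, tgt, relaxed))
})

test_that("hard-zone success implies relaxed-zone success", {
  withr::with_seed(55, {
    tgt <- tibble::tibble(x = 0.35, y = -0.05, z = -0.15, incl = 0.7, azim = -0.2)
    hands <- tibble::tibble(
      x = tgt$x + rnorm(300, 0, 0.03),
      y = tgt$y + rnorm(300, 0, 0.03),
      z = tgt$z + rnorm(300, 0, 0.03),
      incl = tgt$incl + rnorm(300, 0, 0.1),
      azim = tgt$azim + rnorm(300, 0, 0.1)
    )
    h <- validate_target(hands, tgt, tolerance("hard"))
    r <- validate_target(hands, tgt, tolerance("relaxed"))
    expect_true(all(r[h]))
    expect_gt(sum(h), 0)
    expect_gt(sum(r), sum(h))
  })
})

test_that("the oracle controller validates every reachable target", {
  m <- test_morph()
  tg <- reachable_targets(12, m, seed = 51)
  oracle <- synergy_oracle(m, synergy_params(noise_sd = 0))
  ph <- run_closed_loop_phase(oracle, tg, m, tolerance("hard"), 10, seed = 1)
  expect_equal(success_rate(ph), 100)
  expect_true(all(ph$trials$movement_time <= 10))
  expect_true(all(ph$trials$movement_time > 0))
})

test_that("a zero time limit times every trial out", {
  m <- test_morph()
  tg <- reachable_targets(4, m, seed = 52)
  oracle <- synergy_oracle(m, synergy_params(noise_sd = 0))
  ph <- run_closed_loop_phase(oracle, tg, m, tolerance("relaxed"), 0, seed = 1)
  expect_equal(success_rate(ph), 0)
  expect_true(all(is.na(ph$trials$movement_time)))
})

test_that("success rate and movement times summarise trials", {
  trials <- tibble::tibble(
    target = 1:50,
    success = c(rep(TRUE, 49), FALSE),
    movement_time = c(runif(49, 0.5, 3), NA)
  )
  expect_equal(success_rate(trials), 98)
  expect_equal(length(movement_times(trials)), 49)
  expect_equal(success_rate(trials[1:10, ]), 100)
  expect_error(success_rate(trials[0, ]), "no trials")
})

test_that("cleaning removes exactly the injected artifact trials", {
  m <- test_morph()
  tg <- reachable_targets(8, m, seed = 53)
  ses <- generate_session(tg, m, synergy_params(), seed = 3)

  clean <- clean_trials(ses)
  expect_equal(nrow(clean$removed), 0)
  expect_equal(nrow(clean$session$samples), nrow(ses$samples))

  bad <- inject_artifacts(ses,
    freeze_trials = 3, jump_trials = 6,
    freeze_duration = 0.6, jump_size = 0.02
  )
  cleaned <- clean_trials(bad)
  expect_equal(
    dplyr::arrange(cleaned$removed, trial),
    tibble::tibble(trial = c(3L, 6L), reason = c("freezing", "jumping")),
    ignore_attr = TRUE
  )
  expect_false(any(cleaned$session$samples$trial %in% c(3, 6)))
  expect_equal(
    sort(unique(cleaned$session$samples$trial)),
    setdiff(1:8, c(3, 6))
  )
})

test_that("a freeze of exactly the threshold duration is caught", {
  m <- test_morph()
  tg <- reachable_targets(3, m, seed = 54)
  ses <- generate_session(tg, m, synergy_params(), seed = 4)
  bad <- inject_artifacts(ses, freeze_trials = 2, freeze_duration = 0.5)
  expect_equal(clean_trials(bad)$removed$reason, "freezing")
  # just below threshold: untouched
  ok <- inject_artifacts(ses, freeze_trials = 2, freeze_duration = 0.4)
  expect_equal(nrow(clean_trials(ok)$removed), 0)
})

test_that("spread volume matches the independent ellipsoid oracle", {
  withr::with_seed(60, {
    P <- matrix(rnorm(3000 * 3, 0, 0.05), ncol = 3)
  })
  got <- spread_volume(P)
  # oracle: same trim rule, MVEE from cluster::ellipsoidhull
  md <- stats::mahalanobis(P, colMeans(P), stats::cov(P))
  keep <- order(md)[seq_len(ceiling(0.9 * nrow(P)))]
  expect_equal(got, oracle_mvee_volume(P[keep, ]), tolerance = 0.02)
})

test_that("spread volume has the right invariances", {
  withr::with_seed(61, {
    P <- matrix(rnorm(1500 * 3, 0, 0.04), ncol = 3) %*% diag(c(1, 0.5, 2))
  })
  v0 <- spread_volume(P)
  # translation
  expect_equal(spread_volume(sweep(P, 2, c(0.3, -0.1, 1))), v0, tolerance = 1e-9)
  # rigid rotation (<= 1% drift allowed)
  th <- 0.7
  R <- rbind(
    c(cos(th), -sin(th), 0),
    c(sin(th), cos(th), 0),
    c(0, 0, 1)
  )
  expect_equal(spread_volume(P %*% R), v0, tolerance = 0.01)
  # isotropic scaling: volume scales with the cube
  expect_equal(spread_volume(2 * P), 8 * v0, tolerance = 1e-6)
})

test_that("degenerate shoulder clouds give zero volume with a warning", {
  P <- matrix(rep(c(0.1, 0.2, 0.3), each = 20), ncol = 3)
  expect_warning(v <- spread_volume(P), "degenerate")
  expect_equal(v, 0)
  # coplanar cloud
  withr::with_seed(62, {
    Q <- cbind(rnorm(50), rnorm(50), 0)
  })
  expect_warning(v2 <- spread_volume(Q), "degenerate")
  expect_equal(v2, 0)
  expect_error(spread_volume(P[1:5, ]), "at least 10")
})

test_that("phase metrics summarise a simulated phase", {
  m <- test_morph()
  tg <- reachable_targets(10, m, seed = 55)
  oracle <- synergy_oracle(m, synergy_params(noise_sd = 0))
  ph <- run_closed_loop_phase(oracle, tg, m, tolerance("relaxed"), 10, seed = 5)
  g <- glance(ph)
  expect_equal(g$success_rate, 100)
  expect_equal(g$n_trials_kept, 10)
  expect_gt(g$median_mt, 0)
  expect_true(is.finite(g$spread_volume))
  expect_equal(tidy(ph), ph$trials)
})
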