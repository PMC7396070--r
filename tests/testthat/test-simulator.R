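test_that("simulated sessions have the protocol frame count", {
  sim <- simulate_angles(duration_s = 150, fps = 30, seed = 1,
                         noise = quiet_noise())
  expect_equal(nrow(sim$noisy$angles), 4500)
  expect_equal(nrow(simulate_angles(duration_s = 2.5, fps = 30,
                                    seed = 1)$noisy$angles), 75)
})

test_that("same seed reproduces the noisy output exactly", {
  a <- simulate_angles(duration_s = 5, seed = 42)
  b <- simulate_angles(duration_s = 5, seed = 42)
  expect_identical(a$noisy$angles, b$noisy$angles)
  c <- simulate_angles(duration_s = 5, seed = 43)
  expect_false(identical(a$noisy$angles, c$noisy$angles))
})

test_that("noiseless channels are periodic at the cadence frequency", {
  # 3.0 km/h: f = 0.75 Hz, an exact 40-frame period at 30 fps
  tpl <- gait_template()
  fps <- 30
  sim <- simulate_angles(tpl, velocity_kmh = 3.0, duration_s = 60,
                         fps = fps, noise = quiet_noise(), seed = 1)
  x <- sim$truth$angles[, "hip_R"]
  lag <- round(fps / tpl$f0_hz)
  ac <- stats::acf(x - mean(x), lag.max = lag + 5, plot = FALSE)$acf[-1]
  # peak in the neighbourhood of one period sits exactly at the period lag
  # (small lags are excluded: any smooth signal self-correlates there)
  win <- (lag - 10):(lag + 5)
  expect_equal(win[which.max(ac[win])], lag)
  # direct lagged correlation (acf scales peaks down by (n - lag)/n)
  n <- length(x)
  expect_gt(stats::cor(x[1:(n - lag)], x[(lag + 1):n]), 0.9999)
  # cadence scales with velocity: at 4.5 km/h the period is 1/1.05 s
  sim2 <- simulate_angles(tpl, velocity_kmh = 4.5, duration_s = 60,
                          fps = fps, noise = quiet_noise(), seed = 1)
  x2 <- sim2$truth$angles[, "hip_R"]
  lag2 <- round(fps / (tpl$f0_hz + 1.5 * tpl$k_hz_per_kmh))
  ac2 <- stats::acf(x2 - mean(x2), lag.max = lag2 + 5, plot = FALSE)$acf[-1]
  win2 <- (lag2 - 8):(lag2 + 5)
  expect_lte(abs(win2[which.max(ac2[win2])] - lag2), 1)
})

test_that("homologous left/right channels are in antiphase", {
  sim <- simulate_angles(duration_s = 60, noise = quiet_noise(), seed = 2)
  fps <- 30
  f <- gait_template()$f0_hz
  half_period <- round(fps / f / 2)
  for (ch in c("hip", "knee", "shoulder")) {
    l <- sim$truth$angles[, paste0(ch, "_L")]
    r <- sim$truth$angles[, paste0(ch, "_R")]
    cc <- stats::ccf(l - mean(l), r - mean(r),
                     lag.max = half_period + 3, plot = FALSE)
    best <- cc$lag[which.max(cc$acf)]
    expect_lte(abs(abs(best) - half_period), 1)
    # and simultaneous correlation is strongly negative (the in-phase
    # second harmonic keeps it above -1)
    expect_lt(stats::cor(l, r), -0.7)
  }
})

test_that("noisy-vs-truth RMSE matches the jitter sd on long sessions", {
  sd_deg <- 0.5
  sim <- simulate_angles(duration_s = 150,
                         noise = noise_model(angle_jitter_sd = sd_deg),
                         seed = 7)
  err <- rmse(as.vector(sim$noisy$angles), as.vector(sim$truth$angles))
  expect_lt(abs(err - sd_deg) / sd_deg, 0.05)
})

test_that("skeleton simulation places static anchors and exact angles", {
  sk <- simulate_skeleton(duration_s = 3, noise = quiet_noise(), seed = 4)
  for (j in c("ShoulderLeft", "ShoulderRight", "HipLeft", "HipRight")) {
    expect_equal(max(apply(sk$positions[, j, ], 2, stats::sd)), 0)
  }
  got <- extract_angles(sk)
  expect_lt(max(abs(got$angles - attr(sk, "truth")$angles)), 1e-6)
})

test_that("full wrist dropout flags the elbow channel missing downstream", {
  sk <- simulate_skeleton(duration_s = 2, seed = 5,
                          noise = noise_model(0, 0, 0))
  sk$positions[, "WristLeft", ] <- NA_real_
  ang <- extract_angles(sk, max_gap = 5)
  expect_true(all(is.na(ang$angles[, "elbow_L"])))
  expect_false(anyNA(ang$angles[, "hip_L"]))
})

test_that("timestamp jitter keeps timestamps strictly increasing", {
  sk <- simulate_skeleton(duration_s = 5, seed = 6,
                          noise = noise_model(0, 0.002, 0))
  expect_true(all(diff(sk$time_s) > 0))
  # resampling recovers a grid close to the template truth
  rs <- resample_uniform(sk, 30)
  ang <- extract_angles(rs)
  tr <- attr(sk, "truth")
  n <- min(nrow(ang$angles), nrow(tr$angles))
  expect_lt(rmse(as.vector(ang$angles[1:n, ]),
                 as.vector(tr$angles[1:n, ])), 0.5)
})

test_that("a cohort yields subjects x velocities sequences", {
  cohort <- simulate_cohort(n_subjects = 10,
                            velocities = c(3.0, 3.5, 4.0, 4.5),
                            duration_s = 1, fps = 30, seed = 1)
  expect_length(cohort, 40)
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  vels <- vapply(cohort, function(s) s$velocity_kmh, numeric(1))
  expect_equal(length(unique(ids)), 10)
  expect_equal(as.numeric(table(vels)), rep(10, 4))
  expect_setequal(unique(vels), c(3.0, 3.5, 4.0, 4.5))
  single <- simulate_cohort(n_subjects = 1, velocities = 3.0,
                            duration_s = 1, seed = 1)
  expect_length(single, 1)
})

test_that("subjects differ parametrically under distinct sub-seeds", {
  cohort <- simulate_cohort(n_subjects = 3, velocities = 3.0,
                            duration_s = 2, seed = 9,
                            noise = quiet_noise())
  a1 <- attr(cohort[[1]], "truth")$angles
  a2 <- attr(cohort[[2]], "truth")$angles
  expect_gt(max(abs(a1 - a2)), 0.5)
})

test_that("the contralateral synergy signal is linearly decodable", {
  # lagged linear regression from right-arm channels to the left hip must
  # carry the signal the LSTM is asked to learn
  sim <- simulate_angles(duration_s = 60, noise = quiet_noise(), seed = 10)
  ang <- sim$truth$angles
  n <- nrow(ang)
  lags <- 0:9
  X <- do.call(cbind, lapply(lags, function(l) {
    cbind(ang[(10 - l):(n - 1 - l), "shoulder_R"],
          ang[(10 - l):(n - 1 - l), "elbow_R"])
  }))
  y <- ang[11:n, "hip_L"]
  fit <- stats::lm.fit(cbind(1, X), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.95)
})

test_that("templates violating the angle range are rejected", {
  expect_error(gait_template(mean_deg = c(shoulder = 5, elbow = 25,
                                          hip = 25, knee = 30)),
               "range")
  expect_error(noise_model(angle_jitter_sd = -1), "non-negative")
})
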