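test_that("prediction follows the constant-velocity model", {
  s <- kf_init(10, 10)
  s$m[3:4] <- c(1, 0)
  p <- kf_predict(s, process_noise = 0)
  expect_equal(p$m[1:2], c(11, 10))
  # zero velocity: position fixed, covariance strictly grows with noise
  s0 <- kf_init(5, 5)
  p0 <- kf_predict(s0, process_noise = 1)
  expect_equal(p0$m[1:2], c(5, 5))
  expect_gt(sum(diag(p0$P)), sum(diag(s0$P)))
})

test_that("k single-step predictions equal one k-step transition (no noise)", {
  s <- kf_init(3, -2)
  s$m <- c(3, -2, 1.5, -0.5)
  s$P <- crossprod(matrix(rnorm(16, sd = 2), 4))  # any PSD matrix
  k <- 5
  sk <- s
  for (i in 1:k) sk <- kf_predict(sk, process_noise = 0)
  Fk <- diag(4); Fk[1, 3] <- k; Fk[2, 4] <- k
  expect_equal(sk$m, as.vector(Fk %*% s$m), tolerance = 1e-12)
  expect_equal(sk$P, Fk %*% s$P %*% t(Fk), tolerance = 1e-9)
})

test_that("update limits recover prior and measurement", {
  s <- kf_predict(kf_init(10, 20), 1)
  z <- c(14, 23)
  hi <- kf_update(s, z, noise_scale = 1e12)
  expect_equal(hi$m, s$m, tolerance = 1e-6)
  lo <- kf_update(s, z, noise_scale = 1e-12)
  expect_equal(lo$m[1:2], z, tolerance = 1e-6)
  # posterior covariance never exceeds prior (position block)
  mid <- kf_update(s, z)
  expect_lte(mid$P[1, 1], s$P[1, 1])
  # non-finite measurement: no update
  expect_identical(kf_update(s, c(NA, 3)), s)
})

test_that("steady-state filtering beats raw measurement noise", {
  sigma <- 3
  set.seed(7)
  s <- kf_init(100, 100)
  est <- matrix(NA, 200, 2)
  for (f in 1:200) {
    s <- kf_predict(s, process_noise = 0.01)
    s <- kf_update(s, c(100, 100) + rnorm(2, sd = sigma),
                   base_measurement_noise = sigma^2)
    est[f, ] <- s$m[1:2]
  }
  err <- est[51:200, ] - 100
  expect_lt(mean(err^2), sigma^2)
})

test_that("association is optimal and gates correctly", {
  # identical sets: identity matching at zero cost
  pred <- data.frame(track = 1:3, x = c(0, 50, 90), y = c(0, 0, 40))
  det <- data.frame(x_shoulder = c(0, 50, 90), y_shoulder = c(0, 0, 40))
  a <- associate_detections(pred, det, gate_radius = 30)
  expect_equal(a$matches$track, 1:3)
  expect_equal(a$matches$det, 1:3)
  expect_equal(sum(a$matches$dist), 0)
  # proximity overrides list order
  pred2 <- data.frame(track = 1:2, x = c(0, 100), y = c(0, 0))
  det2 <- data.frame(x_shoulder = c(99, 1), y_shoulder = c(1, 1))
  a2 <- associate_detections(pred2, det2, gate_radius = 50)
  expect_equal(a2$matches$det[a2$matches$track == 1], 2)
  expect_equal(a2$matches$det[a2$matches$track == 2], 1)
  # 3 tracks, 2 detections: minimal-cost injection, one track unmatched
  pred3 <- data.frame(track = 1:3, x = c(0, 40, 80), y = 0)
  det3 <- data.frame(x_shoulder = c(41, 79), y_shoulder = c(0, 0))
  a3 <- associate_detections(pred3, det3, gate_radius = 20)
  expect_equal(sort(a3$matches$track), 2:3)
  expect_equal(a3$unmatched_tracks, 1L)
  expect_equal(length(a3$unmatched_detections), 0)
})

test_that("hungarian matching equals the exhaustive permutation minimum", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(1:5, 1); m <- sample(n:6, 1)
    cost <- matrix(runif(n * m, 0, 100), n, m)
    match <- pigtrackr:::solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), match)]),
                 oracle_assignment_cost(cost), tolerance = 1e-9,
                 info = paste("seed", s))
  }
})

test_that("clean detections track with stable identities and low error", {
  truth <- simulate_pen(pen_config(n_pigs = 5, seed = 42), 200)
  det <- corrupt_detections(truth, noise_config())
  tr <- track_sequence(det, tracker_config(n_pigs = 5))
  expect_equal(attr(tr, "birth_frame"), 1L)
  expect_length(attr(tr, "corrupted_frames"), 0)
  expect_true(all(tr$status == "measured"))
  ev <- classify_tracking(truth$poses, tr)
  expect_equal(ev$IDSW, 0L)
  expect_equal(ev$mota, 1.0)
})

test_that("a detection gap is bridged by prediction with continuous output", {
  truth <- simulate_pen(pen_config(n_pigs = 3, seed = 9), 100)
  det <- corrupt_detections(
    truth, noise_config(occlusion_episodes = list(list(pig_id = 2, start = 50,
                                                       end = 60))))
  tr <- track_sequence(det, tracker_config(n_pigs = 3))
  expect_equal(attr(tr, "corrupted_frames"), 50:60)
  gap <- tr[tr$id == 2 & tr$frame %in% 50:60, ]
  expect_true(all(gap$status == "predicted-only"))
  # exactly one estimate per frame per track, no gaps
  expect_equal(nrow(tr), 3 * 100)
  t2 <- tr[tr$id == 2, ]
  coast <- t2$frame %in% 50:60
  step <- sqrt(diff(t2$x)^2 + diff(t2$y)^2)
  expect_true(all(step[coast[-1] & coast[-length(coast)]] < 9))  # coasting holds still
  # identity survives the occlusion
  ev <- classify_tracking(truth$poses, tr)
  expect_equal(ev$IDSW, 0L)
})

test_that("a fully dropped frame self-feeds all tracks and stays continuous", {
  truth <- simulate_pen(pen_config(n_pigs = 2, seed = 4), 30)
  det <- as.data.frame(corrupt_detections(truth, noise_config()))
  det <- det[det$frame != 15, ]
  attr(det, "n_frames") <- 30L
  tr <- track_sequence(det, tracker_config(n_pigs = 2))
  expect_equal(attr(tr, "corrupted_frames"), 15L)
  expect_true(all(tr$status[tr$frame == 15] == "predicted-only"))
  expect_equal(nrow(tr), 60)
})

test_that("initialisation searches forward and fails cleanly", {
  truth <- simulate_pen(pen_config(n_pigs = 2, seed = 4), 20)
  det <- as.data.frame(corrupt_detections(truth, noise_config()))
  det <- det[!(det$frame <= 3), ]
  attr(det, "n_frames") <- 20L
  tr <- track_sequence(det, tracker_config(n_pigs = 2))
  expect_equal(attr(tr, "birth_frame"), 4L)
  # never a frame with the full count -> error
  one_each <- det[!duplicated(det$frame), ]
  attr(one_each, "n_frames") <- 20L
  expect_error(track_sequence(one_each, tracker_config(n_pigs = 2)),
               "initialisation failed")
})
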