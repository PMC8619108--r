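test_that("a single animal produces poses but no contacts", {
  truth <- simulate_pen(pen_config(n_pigs = 1, seed = 3), 10)
  expect_equal(nrow(truth$poses), 10)
  expect_equal(nrow(truth$contacts), 0)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cfg <- pen_config(n_pigs = 3, seed = 7)
  a <- simulate_pen(cfg, 30)
  b <- simulate_pen(cfg, 30)
  expect_identical(a, b)
  expect_false(identical(a$poses,
                         simulate_pen(pen_config(n_pigs = 3, seed = 8), 30)$poses))
})

test_that("generated keypoints stay inside the pen and orientation is consistent", {
  for (s in c(2, 11, 23)) {
    cfg <- pen_config(n_pigs = 4, seed = s)
    truth <- simulate_pen(cfg, 60)
    p <- truth$poses
    for (cl in c("x_shoulder", "x_tail", "x_lear", "x_rear")) {
      expect_true(all(p[[cl]] >= 0 & p[[cl]] < cfg$width))
    }
    for (cl in c("y_shoulder", "y_tail", "y_lear", "y_rear")) {
      expect_true(all(p[[cl]] >= 0 & p[[cl]] < cfg$height))
    }
    # orientation unit vector equals normalize(shoulder - tail), length fixed
    len <- sqrt((p$x_shoulder - p$x_tail)^2 + (p$y_shoulder - p$y_tail)^2)
    expect_equal(len, rep(cfg$body_length, nrow(p)), tolerance = 1e-9)
  }
})

test_that("per-frame displacement and heading change respect the motion bounds", {
  cfg <- pen_config(n_pigs = 3, seed = 5)
  truth <- simulate_pen(cfg, 80)
  p <- truth$poses
  for (i in 1:3) {
    pi_ <- p[p$id == i, ]
    step <- sqrt(diff(pi_$x_shoulder)^2 + diff(pi_$y_shoulder)^2)
    expect_true(all(step <= cfg$body_length / 10 + 1e-9))
    th <- atan2(pi_$y_shoulder - pi_$y_tail, pi_$x_shoulder - pi_$x_tail)
    dth <- abs(atan2(sin(diff(th)), cos(diff(th))))
    expect_true(all(dth <= 15 * pi / 180 + 1e-9))
  }
})

test_that("ground-truth contacts equal the brute-force region oracle", {
  truth <- simulate_pen(pen_config(n_pigs = 4, seed = 13), 50,
                        script = list(approach_event("head-head", 1, 2, 15, 30)))
  got <- truth$contacts
  want <- do.call(rbind, lapply(split(truth$poses, truth$poses$frame),
                                oracle_contacts))
  expect_identical(event_key(got), event_key(want))
  expect_gt(nrow(got), 0)
})

test_that("staged approaches realise their contact inside the window", {
  for (s in c(7, 19, 31)) {
    truth <- simulate_pen(pen_config(n_pigs = 2, seed = s), 40,
                          script = list(approach_event("head-head", 1, 2, 20, 30)))
    hh <- truth$contacts[truth$contacts$type == "head-head" &
                           truth$contacts$frame >= 20 &
                           truth$contacts$frame <= 30, ]
    expect_gt(nrow(hh), 0)
  }
  truth <- simulate_pen(pen_config(n_pigs = 3, seed = 4), 60,
                        script = list(approach_event("head-tail", 1, 3, 25, 45)))
  ht <- truth$contacts[truth$contacts$type == "head-tail" &
                         truth$contacts$frame >= 25 & truth$contacts$frame <= 45, ]
  expect_true(any(ht$head_id == 1 & ht$tail_id == 3))
})

test_that("overlapping staged events for the same pig are rejected", {
  expect_error(
    simulate_pen(pen_config(n_pigs = 3, seed = 1), 60,
                 script = list(approach_event("head-head", 1, 2, 10, 30),
                               approach_event("head-tail", 2, 3, 25, 40))),
    "overlap")
  expect_error(
    simulate_pen(pen_config(n_pigs = 2, seed = 1), 20,
                 script = list(approach_event("head-head", 1, 2, 10, 30))),
    "beyond")
})

test_that("zero-noise corruption is the identity with ids stripped", {
  truth <- simulate_pen(pen_config(n_pigs = 3, seed = 2), 20)
  det <- corrupt_detections(truth, noise_config())
  expect_equal(nrow(det), nrow(truth$poses))
  expect_equal(det$x_shoulder, truth$poses$x_shoulder)
  expect_equal(det$y_tail, truth$poses$y_tail)
  expect_false("id" %in% names(det))
})

test_that("fn_rate = 1 drops every detection", {
  truth <- simulate_pen(pen_config(n_pigs = 2, seed = 2), 10)
  det <- corrupt_detections(truth, noise_config(fn_rate = 1))
  expect_equal(nrow(det), 0)
})

test_that("jitter displacement follows the Rayleigh mean sigma * sqrt(pi/2)", {
  truth <- simulate_pen(pen_config(n_pigs = 10, seed = 1), 250)
  det <- corrupt_detections(truth, noise_config(jitter_sigma = 2, seed = 5))
  tp <- truth$poses
  d <- as.data.frame(det)
  disp <- c(sqrt((d$x_shoulder - tp$x_shoulder)^2 + (d$y_shoulder - tp$y_shoulder)^2),
            sqrt((d$x_tail - tp$x_tail)^2 + (d$y_tail - tp$y_tail)^2),
            sqrt((d$x_lear - tp$x_lear)^2 + (d$y_lear - tp$y_lear)^2),
            sqrt((d$x_rear - tp$x_rear)^2 + (d$y_rear - tp$y_rear)^2))
  expect_gte(length(disp), 1e4)
  expect_equal(mean(disp), 2 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("occlusion episodes drop exactly the scheduled pig-frames", {
  truth <- simulate_pen(pen_config(n_pigs = 3, seed = 6), 30)
  det <- corrupt_detections(
    truth, noise_config(occlusion_episodes = list(list(pig_id = 2, start = 10,
                                                       end = 15))))
  counts <- table(factor(det$frame, levels = 1:30))
  expect_equal(as.vector(counts[10:15]), rep(2L, 6))
  expect_equal(as.vector(counts[c(1:9, 16:30)]), rep(3L, 24))
})

test_that("shoulder-tail swaps and spurious poses behave as configured", {
  truth <- simulate_pen(pen_config(n_pigs = 2, seed = 3), 25)
  sw <- corrupt_detections(truth, noise_config(swap_rate = 1))
  expect_equal(sw$x_shoulder, truth$poses$x_tail)
  expect_equal(sw$y_tail, truth$poses$y_shoulder)
  fp <- corrupt_detections(truth, noise_config(fp_rate = 0.5, seed = 8))
  expect_gt(nrow(fp), nrow(truth$poses))
  det2 <- corrupt_detections(truth, noise_config(fp_rate = 0.5, seed = 8))
  expect_identical(as.data.frame(fp), as.data.frame(det2))
})
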