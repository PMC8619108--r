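test_that("detection-region radius is the mean shoulder-to-ear distance", {
  one <- data.frame(x_shoulder = 0, y_shoulder = 0, x_lear = 10, y_lear = 0,
                    x_rear = 0, y_rear = 14)
  expect_equal(detection_region_radius(one), 12)
  two <- data.frame(x_shoulder = c(0, 100), y_shoulder = 0,
                    x_lear = c(10, 120), y_lear = 0,
                    x_rear = c(-10, 80), y_rear = 0)
  expect_equal(detection_region_radius(two), 15)
  degen <- data.frame(x_shoulder = 5, y_shoulder = 5, x_lear = 5, y_lear = 5,
                      x_rear = 5, y_rear = 5)
  expect_equal(detection_region_radius(degen), 0)
  expect_error(detection_region_radius(
    data.frame(x_shoulder = 1, y_shoulder = 1, x_lear = NA, y_lear = NA,
               x_rear = NA, y_rear = NA)), "no ear annotations")
})

test_that("detection classification follows the region rule table", {
  truth <- data.frame(x_shoulder = c(0, 100), y_shoulder = 0,
                      x_lear = c(10, 110), y_lear = 0,
                      x_rear = c(-10, 90), y_rear = 0)  # radius 10
  # perfect detector
  perfect <- data.frame(x_shoulder = c(0, 100), y_shoulder = c(0, 0))
  expect_equal(classify_detections(truth, perfect), c(TP = 2L, FP = 0L, FN = 0L))
  # two in region A, none in B, one outside
  preds <- data.frame(x_shoulder = c(2, -3, 50), y_shoulder = c(0, 0, 50))
  expect_equal(classify_detections(truth, preds), c(TP = 1L, FP = 2L, FN = 1L))
  # no predictions
  expect_equal(classify_detections(truth, NULL), c(TP = 0L, FP = 0L, FN = 2L))
  # truth conservation TP + FN = n on random instances
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(1:6, 1); m <- sample(0:8, 1)
    tf <- data.frame(x_shoulder = runif(n, 0, 200), y_shoulder = runif(n, 0, 200),
                     x_lear = NA, y_lear = NA, x_rear = NA, y_rear = NA)
    pf <- if (m) data.frame(x_shoulder = runif(m, 0, 200),
                            y_shoulder = runif(m, 0, 200)) else NULL
    counts <- classify_detections(tf, pf, radius = 25)
    expect_equal(unname(counts["TP"] + counts["FN"]), n)
    expect_equal(unname(counts["TP"] + counts["FP"]), m)
  }
})

test_that("detection metrics match the closed formulas", {
  m <- detection_metrics(1019, 51, 35)
  expect_equal(m$sensitivity, 1019 / 1054)
  expect_equal(m$precision, 1019 / 1070)
  expect_equal(m$f1, 2 * 1019 / (2 * 1019 + 51 + 35))
  perfect <- detection_metrics(10, 0, 0)
  expect_equal(unlist(perfect), c(sensitivity = 1, precision = 1, f1 = 1))
  expect_error(detection_metrics(0, 0, 0), "denominator")
})

test_that("mota follows its formula and guards its domain", {
  expect_equal(mota(20, 8, 10, 678), 1 - 38 / 678)
  expect_equal(round(mota(20, 8, 10, 678), 3), 0.944)
  expect_equal(mota(0, 0, 0, 100), 1)
  expect_equal(mota(30, 30, 40, 100), 0)
  expect_error(mota(1, 1, 1, 0), "N must be")
  # linear decrease in each error count
  base <- mota(5, 5, 5, 300)
  expect_equal(mota(6, 5, 5, 300), base - 1 / 300)
  expect_equal(mota(5, 7, 5, 300), base - 2 / 300)
  # scale invariance
  expect_equal(mota(10, 4, 5, 339), mota(20, 8, 10, 678))
})

test_that("tracking classifier is exact on identical tracks", {
  truth <- simulate_pen(pen_config(n_pigs = 4, seed = 8), 50)
  pred <- truth$poses
  names(pred)[names(pred) == "x_shoulder"] <- "x"
  names(pred)[names(pred) == "y_shoulder"] <- "y"
  ev <- classify_tracking(truth$poses, pred)
  expect_equal(ev$FP_T, 0L); expect_equal(ev$FN_T, 0L)
  expect_equal(ev$IDSW, 0L); expect_equal(ev$mota, 1)
  expect_equal(ev$N, nrow(pred))
})

test_that("a forced label exchange counts as one identity switch", {
  # two straight trajectories crossing at frame 10; predicted labels swap
  # after the crossing and stay swapped
  fr <- 1:20
  truth <- rbind(
    data.frame(frame = fr, id = 1, x_shoulder = 10 * fr, y_shoulder = 100,
               x_lear = 10 * fr + 5, y_lear = 95, x_rear = 10 * fr + 5, y_rear = 105),
    data.frame(frame = fr, id = 2, x_shoulder = 10 * fr, y_shoulder = 300,
               x_lear = 10 * fr + 5, y_lear = 295, x_rear = 10 * fr + 5, y_rear = 305))
  pred <- rbind(
    data.frame(frame = fr, id = ifelse(fr <= 10, 1, 2), x = 10 * fr, y = 100),
    data.frame(frame = fr, id = ifelse(fr <= 10, 2, 1), x = 10 * fr, y = 300))
  ev <- classify_tracking(truth, pred, loc_threshold = 20)
  expect_equal(ev$IDSW, 1L)  # a pair exchange is one switch, not per-frame
  expect_equal(ev$FP_T, 0L)
  expect_equal(ev$events$frame, c(11, 11))
  # switching back later is a new switch event
  pred2 <- pred
  pred2$id[pred2$frame > 15] <- ifelse(pred2$id[pred2$frame > 15] == 1, 2, 1)
  ev2 <- classify_tracking(truth, pred2, loc_threshold = 20)
  expect_equal(ev2$IDSW, 2L)
  # a lone re-labelling (no exchange partner) also counts once
  pred3 <- rbind(
    data.frame(frame = fr, id = ifelse(fr <= 10, 1, 3), x = 10 * fr, y = 100),
    data.frame(frame = fr, id = 2, x = 10 * fr, y = 300))
  ev3 <- classify_tracking(truth, pred3, loc_threshold = 20)
  expect_equal(ev3$IDSW, 1L)
})

test_that("a track parked at an empty spot yields both FP and FN", {
  fr <- 1:10
  truth <- data.frame(frame = fr, id = 1, x_shoulder = 50, y_shoulder = 50,
                      x_lear = 60, y_lear = 45, x_rear = 60, y_rear = 55)
  pred <- data.frame(frame = fr, id = 1, x = 300, y = 300)
  ev <- classify_tracking(truth, pred)
  expect_equal(ev$FP_T, 10L)
  expect_equal(ev$FN_T, 10L)
  expect_equal(ev$IDSW, 0L)
  expect_equal(ev$mota, 1 - 20 / 10)
  # denominator override
  ev2 <- classify_tracking(truth, pred, n_detected = 100)
  expect_equal(ev2$mota, 1 - 20 / 100)
})
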