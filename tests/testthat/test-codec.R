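test_that("empty or partial pose lists encode to the expected channels", {
  st <- encode_poses(data.frame(x_shoulder = numeric(0), y_shoulder = numeric(0),
                                x_tail = numeric(0), y_tail = numeric(0)),
                     width = 64, height = 48)
  expect_equal(dim(unclass(st)), c(48, 64, 7))
  expect_equal(sum(unclass(st)), 0)
  # no ears: ear and ear-line channels stay empty
  st2 <- encode_poses(data.frame(x_shoulder = 20, y_shoulder = 20,
                                 x_tail = 40, y_tail = 40),
                      width = 64, height = 64)
  a <- unclass(st2)
  expect_equal(sum(a[, , c(1, 2, 6, 7)]), 0)
  expect_gt(sum(a[, , 5]), 0)
  expect_true(all(a %in% c(0, 1)))
})

test_that("a vertical shoulder-tail line renders as one connected component", {
  st <- encode_poses(data.frame(x_shoulder = 100, y_shoulder = 100,
                                x_tail = 100, y_tail = 190),
                     width = 200, height = 250)
  ch <- unclass(st)[, , 5]
  lab <- oracle_label8(ch)
  expect_equal(length(unique(lab[lab > 0])), 1)
  # the component joins the two keypoints
  expect_gt(ch[101, 101], 0)
  expect_gt(ch[191, 101], 0)
})

test_that("encoding a pose outside the image errors with the pose named", {
  expect_error(encode_poses(data.frame(x_shoulder = 70, y_shoulder = 10,
                                       x_tail = 30, y_tail = 10),
                            width = 64, height = 64),
               "pose 1")
})

test_that("extract_lines matches the brute-force component + diameter oracle", {
  set.seed(42)
  for (rep in 1:6) {
    m <- matrix(0, 64, 64)
    n_seg <- sample(1:3, 1)
    segs <- list()
    for (k in seq_len(n_seg)) {
      p1 <- runif(2, 5, 58); ang <- runif(1, 0, 2 * pi); len <- runif(1, 15, 30)
      p2 <- pmin(pmax(p1 + len * c(cos(ang), sin(ang)), 2), 61)
      segs[[k]] <- cbind(p1, p2)
      m <- pigtrackr:::draw_segment(m, p1[1], p1[2], p2[1], p2[2], 3)
    }
    got <- extract_lines(m, min_component_pixels = 10)
    lab <- oracle_label8(m)
    labs <- setdiff(unique(as.vector(lab)), 0)
    sizes <- vapply(labs, function(l) sum(lab == l), 1L)
    keep <- labs[sizes >= 10]
    expect_equal(nrow(got), length(keep))
    # endpoints equal the oracle's farthest pixel pair (as unordered sets)
    oracle_eps <- lapply(keep, function(l) {
      w <- which(lab == l, arr.ind = TRUE)
      ep <- oracle_endpoints(cbind(w[, 2] - 1, w[, 1] - 1))
      sort(c(sqrt(sum((ep[1:2] - ep[3:4])^2))))
    })
    got_d <- sort(sqrt((got$x1 - got$x2)^2 + (got$y1 - got$y2)^2))
    expect_equal(got_d, sort(unlist(oracle_eps)), tolerance = 1e-9)
  }
})

test_that("extracted endpoints approximate the drawn segment endpoints", {
  m <- matrix(0, 120, 200)
  m <- pigtrackr:::draw_segment(m, 10, 10, 90, 10, 3)   # length 80
  m <- pigtrackr:::draw_segment(m, 20, 60, 68, 96, 3)   # length 60
  got <- extract_lines(m)
  expect_equal(nrow(got), 2)
  ok_pair <- function(row, a, b) {
    e1 <- c(row$x1, row$y1); e2 <- c(row$x2, row$y2)
    d1 <- min(sqrt(sum((e1 - a)^2)), sqrt(sum((e1 - b)^2)))
    d2 <- min(sqrt(sum((e2 - a)^2)), sqrt(sum((e2 - b)^2)))
    max(d1, d2) <= 2
  }
  hits <- c(ok_pair(got[1, ], c(10, 10), c(90, 10)) ||
              ok_pair(got[1, ], c(20, 60), c(68, 96)),
            ok_pair(got[2, ], c(10, 10), c(90, 10)) ||
              ok_pair(got[2, ], c(20, 60), c(68, 96)))
  expect_true(all(hits))
  expect_equal(nrow(extract_lines(matrix(0, 10, 10))), 0)
})

test_that("decode(encode(.)) recovers isolated simulated poses", {
  truth <- simulate_pen(pen_config(n_pigs = 5, seed = 11), 4)
  for (f in 1:4) {
    pf <- truth$poses[truth$poses$frame == f, ]
    iso <- isolated_poses(pf, 2 * 4 + 90 / 4)
    dec <- decode_stack(encode_poses(pf))
    for (i in which(iso)) {
      d <- sqrt((dec$x_shoulder - pf$x_shoulder[i])^2 +
                  (dec$y_shoulder - pf$y_shoulder[i])^2)
      j <- which.min(d)
      expect_lte(d[j], 4)
      expect_lte(sqrt((dec$x_tail[j] - pf$x_tail[i])^2 +
                        (dec$y_tail[j] - pf$y_tail[i])^2), 4)
      expect_true(dec$orientation_ok[j])
      # ears recovered near truth
      expect_lte(abs(dec$x_lear[j] - pf$x_lear[i]), 4)
    }
    # never more poses than line components
    ncomp <- length(setdiff(unique(as.vector(
      oracle_label8(unclass(encode_poses(pf))[, , 5]))), 0))
    expect_lte(nrow(dec), ncomp)
  }
})

test_that("orientation falls back to ear evidence and flags true ambiguity", {
  # ears only: shoulder channel erased
  pf <- data.frame(x_shoulder = 40, y_shoulder = 40, x_tail = 90, y_tail = 40,
                   x_lear = 33, y_lear = 30, x_rear = 33, y_rear = 50)
  st <- unclass(encode_poses(pf, 128, 128))
  st[, , 3] <- 0  # drop shoulder discs
  dec <- orient_lines(extract_lines(st[, , 5]), st)
  expect_true(dec$orientation_ok[1])
  expect_lt(abs(dec$x_shoulder[1] - 40), 5)
  # fully symmetric: no shoulder, no ears -> ambiguous but retained
  st[, , c(1, 2, 6, 7)] <- 0
  dec2 <- orient_lines(extract_lines(st[, , 5]), st)
  expect_equal(nrow(dec2), 1)
  expect_false(dec2$orientation_ok[1])
})

test_that("decode thresholding behaves at the boundary and under saturation", {
  pf <- data.frame(x_shoulder = 20, y_shoulder = 20, x_tail = 50, y_tail = 50)
  st <- unclass(encode_poses(pf, 64, 64))
  low <- structure(st * 0 + 0.4, class = "channel_stack")
  expect_equal(nrow(decode_stack(low, threshold = 0.5)), 0)
  # saturated stack: one giant component; must not crash
  high <- structure(st * 0 + 0.6, class = "channel_stack")
  dec <- decode_stack(high, threshold = 0.5)
  expect_lte(nrow(dec), 1)
  # real-valued stack decodes like its binarisation
  soft <- structure(st * 0.9, class = "channel_stack")
  expect_equal(decode_stack(soft, threshold = 0.5)[, 1:4],
               decode_stack(structure(st, class = "channel_stack"))[, 1:4])
})

test_that("channel stacks round-trip through per-channel PNG files", {
  pf <- data.frame(x_shoulder = 20, y_shoulder = 30, x_tail = 45, y_tail = 55,
                   x_lear = 15, y_lear = 25, x_rear = 25, y_rear = 22)
  st <- encode_poses(pf, 80, 80)
  dir <- withr::local_tempdir()
  write_channel_stack(st, dir, frame_idx = 3)
  back <- read_channel_stack(dir, frame_idx = 3)
  expect_equal(unclass(back), unclass(st), ignore_attr = TRUE)
})
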