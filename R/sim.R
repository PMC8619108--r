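#' Pen configuration for the simulator
#'
#' Describes the rectangular pen and the animals inside it. Defaults follow
#' the video convention used throughout the package: a 640 x 400 px view at
#' 10 frames per second, with a shoulder-to-tail body length of 90 px.
#'
#' @param width,height Pen dimensions in pixels.
#' @param n_pigs Number of pigs (fixed and known; the tracker assumes this).
#' @param body_length Shoulder-to-tail distance in pixels.
#' @param ear_offset Shoulder-to-ear distance in pixels.
#' @param fps Frame rate in frames per second (metadata only; the motion
#'   bounds below are expressed per frame).
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   configuration and seed.
#' @return An object of class \code{pen_config}.
#' @export
#' @examples
#' cfg <- pen_config(n_pigs = 2, seed = 7)
pen_config <- function(width = 640, height = 400, n_pigs = 1,
                       body_length = 90, ear_offset = 18, fps = 10,
                       seed = 1L) {
  if (n_pigs < 1) stop_pigtrackr("n_pigs must be >= 1")
  if (body_length <= 0) stop_pigtrackr("body_length must be > 0")
  if (ear_offset < 0) stop_pigtrackr("ear_offset must be >= 0")
  margin <- body_length + 2
  if (width <= 2 * margin + 1 || height <= 2 * margin + 1) {
    stop_pigtrackr("pen too small for body_length ", body_length,
                   ": need width and height > ", 2 * margin + 1)
  }
  structure(list(width = width, height = height, n_pigs = as.integer(n_pigs),
                 body_length = body_length, ear_offset = ear_offset,
                 fps = fps, seed = as.integer(seed)),
            class = "pen_config")
}

#' Detector-noise configuration
#'
#' Describes the failure modes of a keypoint detector: coordinate jitter,
#' missed detections, spurious detections, shoulder/tail swaps and occlusion
#' episodes (modelled as detection dropout for the occluded animal).
#'
#' @param jitter_sigma Standard deviation (px) of isotropic Gaussian jitter
#'   added to every surviving keypoint coordinate.
#' @param fn_rate Probability per pig-frame of a missed detection.
#' @param fp_rate Expected number of spurious full poses per frame
#'   (Poisson-distributed counts).
#' @param swap_rate Probability per pig-frame that shoulder and tail
#'   coordinates are exchanged.
#' @param occlusion_episodes List of \code{list(pig_id, start, end)} entries
#'   (or a data frame with those columns): the pig is undetected on frames
#'   \code{start:end}.
#' @param seed Integer seed for the corruption draws.
#' @return An object of class \code{noise_config}.
#' @export
noise_config <- function(jitter_sigma = 0, fn_rate = 0, fp_rate = 0,
                         swap_rate = 0, occlusion_episodes = list(),
                         seed = 1L) {
  for (r in c(fn_rate, fp_rate, swap_rate)) {
    if (r < 0 || r > 1) stop_pigtrackr("rates must lie in [0, 1]")
  }
  if (jitter_sigma < 0) stop_pigtrackr("jitter_sigma must be >= 0")
  if (is.data.frame(occlusion_episodes)) {
    occlusion_episodes <- lapply(seq_len(nrow(occlusion_episodes)), function(i)
      as.list(occlusion_episodes[i, c("pig_id", "start", "end")]))
  }
  structure(list(jitter_sigma = jitter_sigma, fn_rate = fn_rate,
                 fp_rate = fp_rate, swap_rate = swap_rate,
                 occlusion_episodes = occlusion_episodes,
                 seed = as.integer(seed)),
            class = "noise_config")
}

#' Staged approach event
#'
#' Scripts a contact between two pigs: the pair steers together so that the
#' requested contact type is realised on at least one frame of
#' \code{start:end}. For \code{"head-tail"}, \code{pig_a}'s head meets
#' \code{pig_b}'s tail.
#'
#' @param type \code{"head-head"} or \code{"head-tail"}.
#' @param pig_a,pig_b Pig ids (1-based, distinct).
#' @param start,end Frame window (inclusive) in which the contact must occur.
#' @return An object of class \code{approach_event}.
#' @export
approach_event <- function(type = c("head-head", "head-tail"),
                           pig_a, pig_b, start, end) {
  type <- match.arg(type)
  if (pig_a == pig_b) stop_pigtrackr("pig_a and pig_b must differ")
  if (start > end || start < 1) stop_pigtrackr("need 1 <= start <= end")
  structure(list(type = type, pig_a = as.integer(pig_a),
                 pig_b = as.integer(pig_b), start = as.integer(start),
                 end = as.integer(end)),
            class = "approach_event")
}

# shoulder positions are confined to this inner box so that tail and ears
# stay inside the pen whatever the heading
shoulder_box <- function(cfg) {
  m <- cfg$body_length + 2
  list(xmin = m, xmax = cfg$width - 1 - m, ymin = m, ymax = cfg$height - 1 - m)
}

clamp_box <- function(p, box) {
  c(min(max(p[1], box$xmin), box$xmax), min(max(p[2], box$ymin), box$ymax))
}

#' Simulate a pen of moving pigs with known ground truth
#'
#' Generates smooth trajectories by waypoint-following with bounded per-frame
#' displacement (\code{body_length / 10}) and bounded heading change (15
#' degrees per frame), which at 10 fps corresponds to the slow apparent
#' motion typical of top-view pen video. Staged \code{\link{approach_event}}s
#' steer the scripted pair together so that the requested contact type occurs
#' within the scripted window under the proximity-region rule with
#' \code{alpha = 3}. Ground-truth contacts are computed frame-wise from the
#' generated geometry.
#'
#' Scripted pairs are initially placed close enough that the window is
#' reachable under the motion bounds, and begin steering toward each other
#' from the start of the simulation (or from the end of their previous
#' event), so realisability is guaranteed by construction.
#'
#' @param cfg A \code{\link{pen_config}}.
#' @param n_frames Number of frames to simulate (>= 1).
#' @param script List of \code{\link{approach_event}}s. Events sharing a pig
#'   must not overlap in time.
#' @param alpha Scaling factor of the contact-region radius used for the
#'   ground-truth contact table (default 3).
#' @return An object of class \code{pen_truth}: a list with \code{poses}
#'   (data frame: frame, id, keypoint coordinates), \code{contacts} (the
#'   ground-truth contact table), \code{config}, \code{n_frames} and
#'   \code{script}.
#' @export
#' @examples
#' truth <- simulate_pen(pen_config(n_pigs = 2, seed = 7), n_frames = 40,
#'                       script = list(approach_event("head-head", 1, 2, 20, 30)))
#' nrow(truth$poses)    # 2 pigs x 40 frames
#' head(truth$contacts)
simulate_pen <- function(cfg, n_frames, script = list(), alpha = 3) {
  stopifnot(inherits(cfg, "pen_config"))
  if (n_frames < 1) stop_pigtrackr("n_frames must be >= 1")
  n <- cfg$n_pigs
  for (ev in script) {
    stopifnot(inherits(ev, "approach_event"))
    if (ev$pig_a > n || ev$pig_b > n) {
      stop_pigtrackr("staged event references pig id beyond n_pigs")
    }
    if (ev$end > n_frames) stop_pigtrackr("staged event extends beyond n_frames")
  }
  # reject overlapping events for the same pig
  if (length(script) > 1) {
    for (i in seq_along(script)) for (j in seq_along(script)) {
      if (i >= j) next
      a <- script[[i]]; b <- script[[j]]
      shared <- length(intersect(c(a$pig_a, a$pig_b), c(b$pig_a, b$pig_b))) > 0
      overlap <- a$start <= b$end && b$start <= a$end
      if (shared && overlap) {
        stop_pigtrackr("staged events ", i, " and ", j,
                       " overlap in time for the same pig; stagger them")
      }
    }
  }

  box <- shoulder_box(cfg)
  L <- cfg$body_length
  max_step <- L / 10
  max_turn <- 15 * pi / 180
  contact_dist <- 2 * L / alpha   # head-center separation at which regions touch

  with_seed(cfg$seed, {
    # --- initial placement, spread out ---
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (try in 1:100) {
        p <- c(runif(1, box$xmin, box$xmax), runif(1, box$ymin, box$ymax))
        if (i == 1 || min(row_norm(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p))) > L) break
      }
      pos[i, ] <- p
    }
    theta <- runif(n, -pi, pi)
    waypoint <- cbind(runif(n, box$xmin, box$xmax), runif(n, box$ymin, box$ymax))

    # --- reachability: move scripted partners within closing range ---
    first_ev <- list()
    for (ev in script) {
      key <- paste(sort(c(ev$pig_a, ev$pig_b)), collapse = "-")
      if (is.null(first_ev[[key]]) || ev$start < first_ev[[key]]$start) {
        first_ev[[key]] <- ev
      }
    }
    for (ev in first_ev) {
      a <- ev$pig_a; b <- ev$pig_b
      bound <- contact_dist + max_step * ev$start  # both close at <= 2*max_step/frame
      d <- vec_norm(pos[b, ] - pos[a, ])
      if (d > bound) {
        centre <- c((box$xmin + box$xmax) / 2, (box$ymin + box$ymax) / 2)
        u <- (centre - pos[a, ]); u <- if (vec_norm(u) < 1) c(1, 0) else u / vec_norm(u)
        pos[b, ] <- clamp_box(pos[a, ] + 0.9 * bound * u, box)
      }
    }

    # per-pig steering plan per frame: 0 = wander, else index into script
    plan <- matrix(0L, n_frames, n)
    ev_order <- order(vapply(script, function(e) e$start, 1L))
    last_busy <- integer(n)  # last frame occupied by an earlier event
    for (k in ev_order) {
      ev <- script[[k]]
      lead <- max(1L, last_busy[ev$pig_a] + 1L, last_busy[ev$pig_b] + 1L)
      plan[lead:ev$end, c(ev$pig_a, ev$pig_b)] <- k
      last_busy[c(ev$pig_a, ev$pig_b)] <- ev$end
    }

    steer <- function(i, target, d_stop, speed = 1) {
      v <- target - pos[i, ]
      d <- vec_norm(v)
      if (d > 1e-9) {
        want <- atan2(v[2], v[1])
        dth <- angle_diff(want, theta[i])
        theta[i] <<- theta[i] + max(-max_turn, min(max_turn, dth))
      } else dth <- 0
      step <- if (d > d_stop) min(max_step * speed, d - d_stop) else 0
      if (abs(dth) > pi / 2) step <- 0   # turn in place when facing away
      pos[i, ] <<- clamp_box(pos[i, ] + step * c(cos(theta[i]), sin(theta[i])), box)
    }

    wander <- function(i, speed = 1) {
      if (vec_norm(waypoint[i, ] - pos[i, ]) < 15) {
        waypoint[i, ] <<- c(runif(1, box$xmin, box$xmax), runif(1, box$ymin, box$ymax))
      }
      steer(i, waypoint[i, ], 0, speed * runif(1, 0.7, 1))
    }

    P <- array(NA_real_, c(n_frames, n, 2))
    TH <- matrix(NA_real_, n_frames, n)
    P[1, , ] <- pos; TH[1, ] <- theta
    if (n_frames > 1) for (f in 2:n_frames) {
      handled <- rep(FALSE, n)
      active <- unique(plan[f, ])
      for (k in setdiff(active, 0L)) {
        ev <- script[[k]]
        a <- ev$pig_a; b <- ev$pig_b
        in_window <- f >= ev$start
        sep <- if (in_window) 0.8 * contact_dist else 1.6 * contact_dist
        if (ev$type == "head-head") {
          steer(a, pos[b, ], sep)
          steer(b, pos[a, ], sep)
        } else {
          tail_b <- pos[b, ] - L * c(cos(theta[b]), sin(theta[b]))
          steer(a, tail_b, sep)
          wander(b, speed = 0.15)
        }
        handled[c(a, b)] <- TRUE
      }
      for (i in which(!handled)) wander(i)
      P[f, , ] <- pos; TH[f, ] <- theta
    }

    poses <- data.frame(
      frame = rep(seq_len(n_frames), each = n),
      id = rep(seq_len(n), n_frames)
    )
    th <- as.vector(t(TH)); px <- as.vector(t(P[, , 1])); py <- as.vector(t(P[, , 2]))
    poses$x_shoulder <- px
    poses$y_shoulder <- py
    poses$x_tail <- px - L * cos(th)
    poses$y_tail <- py - L * sin(th)
    poses$x_lear <- px + cfg$ear_offset * cos(th - pi / 4)
    poses$y_lear <- py + cfg$ear_offset * sin(th - pi / 4)
    poses$x_rear <- px + cfg$ear_offset * cos(th + pi / 4)
    poses$y_rear <- py + cfg$ear_offset * sin(th + pi / 4)
  })

  contacts <- contacts_from_poses(poses, alpha = alpha, head_offset_frac = 0)

  truth <- structure(list(poses = poses, contacts = contacts, config = cfg,
                          n_frames = as.integer(n_frames), script = script,
                          alpha = alpha),
                     class = "pen_truth")
  # staged events must be realised inside their windows
  for (k in seq_along(script)) {
    ev <- script[[k]]
    ids <- sort(c(ev$pig_a, ev$pig_b))
    hit <- contacts$type == ev$type &
      contacts$id_a == ids[1] & contacts$id_b == ids[2] &
      contacts$frame >= ev$start & contacts$frame <= ev$end
    if (ev$type == "head-tail") hit <- hit & contacts$head_id == ev$pig_a
    if (!any(hit)) {
      stop_pigtrackr("staged event ", k, " (", ev$type, " ", ev$pig_a, "-",
                     ev$pig_b, ", frames ", ev$start, "-", ev$end,
                     ") was not realised; widen the window")
    }
  }
  truth
}

#' @export
print.pen_truth <- function(x, ...) {
  cat("Simulated pen:", x$config$n_pigs, "pigs,", x$n_frames, "frames (",
      x$config$width, "x", x$config$height, "px )\n")
  cat("  ground-truth contact rows:", nrow(x$contacts),
      " staged events:", length(x$script), "\n")
  invisible(x)
}

#' Corrupt ground-truth poses into detector-style detections
#'
#' Applies, in order: occlusion dropout and per-pig-frame missed detections,
#' shoulder/tail swaps, Gaussian coordinate jitter (clamped to the pen), and
#' Poisson-distributed spurious full poses placed uniformly in the pen.
#' Identities are stripped; row order within a frame follows the surviving
#' true pigs, then spurious poses.
#'
#' @param truth A \code{\link{simulate_pen}} result.
#' @param noise A \code{\link{noise_config}}.
#' @return An object of class \code{pig_detections}: a data frame with the
#'   detection columns (\code{frame}, shoulder/tail/ear coordinates) and
#'   attributes \code{n_frames} and \code{pen}.
#' @export
corrupt_detections <- function(truth, noise) {
  stopifnot(inherits(truth, "pen_truth"), inherits(noise, "noise_config"))
  poses <- truth$poses
  if (nrow(poses) == 0) stop_pigtrackr("truth is empty")
  cfg <- truth$config
  coord_cols <- c("x_shoulder", "y_shoulder", "x_tail", "y_tail",
                  "x_lear", "y_lear", "x_rear", "y_rear")

  occluded <- rep(FALSE, nrow(poses))
  for (ep in noise$occlusion_episodes) {
    occluded <- occluded | (poses$id == ep$pig_id &
                              poses$frame >= ep$start & poses$frame <= ep$end)
  }

  det <- with_seed(noise$seed, {
    keep <- !occluded & runif(nrow(poses)) >= noise$fn_rate
    swap <- runif(nrow(poses)) < noise$swap_rate
    d <- poses[, c("frame", coord_cols)]
    sw <- swap & keep
    if (any(sw)) {
      tmp <- d[sw, c("x_shoulder", "y_shoulder")]
      d[sw, c("x_shoulder", "y_shoulder")] <- d[sw, c("x_tail", "y_tail")]
      d[sw, c("x_tail", "y_tail")] <- tmp
    }
    if (noise$jitter_sigma > 0) {
      jit <- matrix(rnorm(nrow(d) * 8, sd = noise$jitter_sigma), ncol = 8)
      d[, coord_cols] <- d[, coord_cols] + jit
    }
    d <- d[keep, , drop = FALSE]
    # spurious full poses
    n_fp <- rpois(truth$n_frames, noise$fp_rate)
    if (sum(n_fp) > 0) {
      m <- sum(n_fp)
      box <- shoulder_box(cfg)
      fx <- runif(m, box$xmin, box$xmax); fy <- runif(m, box$ymin, box$ymax)
      fth <- runif(m, -pi, pi)
      fp <- data.frame(frame = rep(seq_len(truth$n_frames), n_fp),
                       x_shoulder = fx, y_shoulder = fy,
                       x_tail = fx - cfg$body_length * cos(fth),
                       y_tail = fy - cfg$body_length * sin(fth),
                       x_lear = fx + cfg$ear_offset * cos(fth - pi / 4),
                       y_lear = fy + cfg$ear_offset * sin(fth - pi / 4),
                       x_rear = fx + cfg$ear_offset * cos(fth + pi / 4),
                       y_rear = fy + cfg$ear_offset * sin(fth + pi / 4))
      d <- rbind(d, fp)
      d <- d[order(d$frame), , drop = FALSE]
    }
    d
  })
  # a detector cannot report coordinates outside the image
  for (cl in coord_cols) {
    lim <- if (startsWith(cl, "x")) cfg$width else cfg$height
    det[[cl]] <- pmin(pmax(det[[cl]], 0), lim - 1e-6)
  }
  rownames(det) <- NULL
  structure(det, class = c("pig_detections", "data.frame"),
            n_frames = truth$n_frames, pen = cfg)
}

#' @export
print.pig_detections <- function(x, ...) {
  cat("Pig detections:", nrow(x), "detections over",
      attr(x, "n_frames"), "frames\n")
  print(head(as.data.frame(x)))
  invisible(x)
}
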