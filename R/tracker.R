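#' Tracker configuration
#'
#' @param n_pigs Known number of animals (fixed-cardinality tracking; no
#'   track birth or death).
#' @param process_noise Process-noise intensity (px^2/frame^2).
#' @param base_measurement_noise Measurement variance (px^2).
#' @param inflation_factor Multiplier applied to the measurement variance on
#'   suspect measurements (corrupted-frame self-feeding, or matched
#'   detections with large innovation).
#' @param inflation_innovation Innovation threshold, in multiples of
#'   \code{gate_radius}, beyond which a matched detection's noise is
#'   inflated.
#' @param gate_radius Association gate in px; detections farther than this
#'   from every prediction stay unmatched. \code{NULL} (default) estimates
#'   it as the median shoulder-tail length of the initialisation frame.
#' @param assignment \code{"hungarian"} (globally optimal, default) or
#'   \code{"greedy"} (nearest-first).
#' @param init_velocity_var Initial velocity variance for new tracks.
#' @return An object of class \code{tracker_config}.
#' @export
tracker_config <- function(n_pigs, process_noise = 1,
                           base_measurement_noise = 4,
                           inflation_factor = 10, inflation_innovation = 3,
                           gate_radius = NULL,
                           assignment = c("hungarian", "greedy"),
                           init_velocity_var = 25) {
  assignment <- match.arg(assignment)
  if (process_noise <= 0 || base_measurement_noise <= 0 || inflation_factor <= 0) {
    stop_pigtrackr("noise scalars must be > 0")
  }
  if (!is.null(gate_radius) && gate_radius <= 0) {
    stop_pigtrackr("gate_radius must be > 0")
  }
  structure(list(n_pigs = as.integer(n_pigs), process_noise = process_noise,
                 base_measurement_noise = base_measurement_noise,
                 inflation_factor = inflation_factor,
                 inflation_innovation = inflation_innovation,
                 gate_radius = gate_radius, assignment = assignment,
                 init_velocity_var = init_velocity_var),
            class = "tracker_config")
}

det_xy <- function(d) {
  if (all(c("x_shoulder", "y_shoulder") %in% names(d))) {
    cbind(d$x_shoulder, d$y_shoulder)
  } else {
    cbind(d$x, d$y)
  }
}

#' Associate track predictions with detections
#'
#' One-to-one matching minimising total Euclidean distance among pairs
#' within \code{gate_radius} (globally optimal Hungarian matching by
#' default, greedy nearest-first as an alternative). Detections beyond the
#' gate of every prediction remain unmatched, as do surplus tracks or
#' detections.
#'
#' @param predicted Data frame with columns \code{track}, \code{x}, \code{y}
#'   (one row per live track prediction).
#' @param detections Data frame of detections (columns
#'   \code{x_shoulder}/\code{y_shoulder} or \code{x}/\code{y}).
#' @param gate_radius Gating distance in px.
#' @param method \code{"hungarian"} or \code{"greedy"}.
#' @return List with \code{matches} (data frame \code{track}, \code{det},
#'   \code{dist}), \code{unmatched_tracks}, \code{unmatched_detections}.
#' @export
associate_detections <- function(predicted, detections, gate_radius = Inf,
                                 method = c("hungarian", "greedy")) {
  method <- match.arg(method)
  n <- nrow(predicted) %||% 0
  m <- nrow(detections) %||% 0
  empty <- data.frame(track = integer(0), det = integer(0), dist = numeric(0))
  if (n == 0 || m == 0) {
    return(list(matches = empty,
                unmatched_tracks = if (n) predicted$track else integer(0),
                unmatched_detections = seq_len(m)))
  }
  pz <- cbind(predicted$x, predicted$y)
  dz <- det_xy(detections)
  cost <- sqrt(outer(pz[, 1], dz[, 1], `-`)^2 + outer(pz[, 2], dz[, 2], `-`)^2)
  BIG <- 1e8
  gated <- cost
  gated[cost > gate_radius] <- BIG
  if (method == "hungarian") {
    match <- solve_assignment(gated)
  } else {
    match <- integer(n)
    g <- gated
    repeat {
      mn <- min(g)
      if (!is.finite(mn) || mn >= BIG) break
      ij <- which(g == mn, arr.ind = TRUE)[1, ]
      match[ij[1]] <- ij[2]
      g[ij[1], ] <- BIG
      g[, ij[2]] <- BIG
    }
  }
  keep <- which(match > 0)
  keep <- keep[cost[cbind(keep, match[keep])] <= gate_radius]
  matches <- data.frame(track = predicted$track[keep], det = match[keep],
                        dist = cost[cbind(keep, match[keep])])
  list(matches = matches,
       unmatched_tracks = predicted$track[setdiff(seq_len(n), keep)],
       unmatched_detections = setdiff(seq_len(m), match[keep]))
}

#' Track a detection sequence with per-pig Kalman filters
#'
#' Links unordered per-frame detections into identity-stable tracks for a
#' known number of animals. Tracks are initialised on the first frame whose
#' detection count equals \code{cfg$n_pigs}. Thereafter each frame is
#' predicted, then:
#' \itemize{
#'   \item frames whose detection count differs from \code{n_pigs} are
#'     flagged \emph{corrupted}: the detections are discarded and every
#'     track is updated with its own previous estimate as the measurement,
#'     with the measurement noise inflated by \code{inflation_factor};
#'   \item in normal frames, predictions and detections are matched within
#'     the gate; matched tracks update from the detection (status
#'     \code{"measured"}), unmatched tracks coast on the prediction (status
#'     \code{"predicted-only"}).
#' }
#' Tail points are carried from the matched detection, otherwise carried
#' forward; only the shoulder point is filtered.
#'
#' @param detections A \code{pig_detections} object or data frame with a
#'   \code{frame} column and shoulder/tail coordinates.
#' @param cfg A \code{\link{tracker_config}}.
#' @param n_frames Total frame count; defaults to the \code{n_frames}
#'   attribute of \code{detections}, else the maximum frame index.
#' @return An object of class \code{pig_tracks}: data frame \code{frame},
#'   \code{id}, \code{x}, \code{y}, \code{x_tail}, \code{y_tail},
#'   \code{status}, with attributes \code{corrupted_frames},
#'   \code{gate_radius}, \code{birth_frame}, \code{config}.
#' @export
track_sequence <- function(detections, cfg, n_frames = NULL) {
  stopifnot(inherits(cfg, "tracker_config"))
  det <- as.data.frame(detections)
  n_frames <- n_frames %||% attr(detections, "n_frames") %||%
    (if (nrow(det)) max(det$frame) else 0L)
  n <- cfg$n_pigs
  frames <- split(seq_len(nrow(det)), factor(det$frame, levels = seq_len(n_frames)))
  counts <- vapply(frames, length, 1L)
  f0 <- unname(which(counts == n)[1])
  if (is.na(f0)) {
    stop_pigtrackr("initialisation failed: no frame contains exactly ",
                   n, " detections")
  }

  d0 <- det[frames[[f0]], , drop = FALSE]
  z0 <- det_xy(d0)
  gate <- cfg$gate_radius %||%
    median(sqrt((d0$x_shoulder - d0$x_tail)^2 + (d0$y_shoulder - d0$y_tail)^2))

  states <- lapply(seq_len(n), function(i)
    kf_init(z0[i, 1], z0[i, 2], cfg$base_measurement_noise, cfg$init_velocity_var))
  tail_xy <- cbind(d0$x_tail, d0$y_tail)

  kept <- f0:n_frames
  nf <- length(kept)
  X <- matrix(NA_real_, nf, n); Y <- X; TX <- X; TY <- X
  ST <- matrix("measured", nf, n)
  X[1, ] <- z0[, 1]; Y[1, ] <- z0[, 2]
  TX[1, ] <- tail_xy[, 1]; TY[1, ] <- tail_xy[, 2]
  corrupted <- integer(0)

  if (nf > 1) for (r in 2:nf) {
    f <- kept[r]
    prev <- cbind(X[r - 1, ], Y[r - 1, ])
    states <- lapply(states, kf_predict, process_noise = cfg$process_noise)
    rows_f <- frames[[f]]
    if (length(rows_f) != n) {
      corrupted <- c(corrupted, f)
      for (i in seq_len(n)) {
        states[[i]] <- kf_update(states[[i]], prev[i, ],
                                 noise_scale = cfg$inflation_factor,
                                 base_measurement_noise = cfg$base_measurement_noise)
      }
      ST[r, ] <- "predicted-only"
    } else {
      df <- det[rows_f, , drop = FALSE]
      pred <- data.frame(track = seq_len(n),
                         x = vapply(states, function(s) s$m[1], 1),
                         y = vapply(states, function(s) s$m[2], 1))
      asc <- associate_detections(pred, df, gate, cfg$assignment)
      matched <- rep(FALSE, n)
      if (nrow(asc$matches)) for (k in seq_len(nrow(asc$matches))) {
        i <- asc$matches$track[k]; j <- asc$matches$det[k]
        scale <- if (asc$matches$dist[k] > cfg$inflation_innovation * gate) {
          cfg$inflation_factor
        } else 1
        z <- det_xy(df[j, , drop = FALSE])[1, ]
        states[[i]] <- kf_update(states[[i]], z, noise_scale = scale,
                                 base_measurement_noise = cfg$base_measurement_noise)
        tail_xy[i, ] <- c(df$x_tail[j], df$y_tail[j])
        matched[i] <- TRUE
      }
      ST[r, !matched] <- "predicted-only"
    }
    X[r, ] <- vapply(states, function(s) s$m[1], 1)
    Y[r, ] <- vapply(states, function(s) s$m[2], 1)
    TX[r, ] <- tail_xy[, 1]; TY[r, ] <- tail_xy[, 2]
  }

  out <- data.frame(frame = rep(kept, each = n),
                    id = rep(seq_len(n), nf),
                    x = as.vector(t(X)), y = as.vector(t(Y)),
                    x_tail = as.vector(t(TX)), y_tail = as.vector(t(TY)),
                    status = as.vector(t(ST)))
  structure(out, class = c("pig_tracks", "data.frame"),
            corrupted_frames = corrupted, gate_radius = gate,
            birth_frame = f0, n_frames = n_frames, config = cfg)
}

#' @export
print.pig_tracks <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Pig tracks:", cfg$n_pigs, "animals over frames",
      attr(x, "birth_frame"), "-", attr(x, "n_frames"), "\n")
  cat("  corrupted frames:", length(attr(x, "corrupted_frames")),
      "  gate radius:", round(attr(x, "gate_radius"), 1), "px\n")
  invisible(x)
}

#' @export
summary.pig_tracks <- function(object, ...) {
  st <- table(object$status)
  cat("Track points:", nrow(object), "\n")
  print(st)
  cat("Corrupted frames:", length(attr(object, "corrupted_frames")), "\n")
  invisible(st)
}

#' Plot tracked trajectories
#'
#' @param x A \code{pig_tracks} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.pig_tracks <- function(x, ...) {
  ids <- sort(unique(x$id))
  plot(NA, xlim = range(x$x), ylim = rev(range(x$y)), xlab = "x (px)",
       ylab = "y (px)", main = "Shoulder trajectories", asp = 1, ...)
  for (i in ids) {
    xi <- x[x$id == i, ]
    lines(xi$x, xi$y, col = i)
    points(xi$x[1], xi$y[1], pch = 19, col = i)
  }
  legend("topright", legend = ids, col = ids, lty = 1, cex = 0.7, title = "id")
  invisible(x)
}
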