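# Seven-channel binary keypoint/line codec.
#
# Channel layout (R index / semantic):
#   1 left-ear disc, 2 right-ear disc, 3 shoulder disc, 4 tail disc,
#   5 shoulder-tail line, 6 shoulder-left-ear line, 7 shoulder-right-ear line.
# The shoulder-tail line channel (5) carries each animal's location; the
# point/ear channels carry the orientation evidence used to label the line
# endpoints as shoulder vs tail.

CHANNEL_NAMES <- c("left_ear", "right_ear", "shoulder", "tail",
                   "line_shoulder_tail", "line_shoulder_lear",
                   "line_shoulder_rear")

draw_disc <- function(mat, x, y, r) {
  H <- nrow(mat); W <- ncol(mat)
  cs <- max(1, floor(x - r) + 1):min(W, ceiling(x + r) + 1)
  rs <- max(1, floor(y - r) + 1):min(H, ceiling(y + r) + 1)
  mask <- outer(((rs - 1) - y)^2, ((cs - 1) - x)^2, `+`) <= r^2
  sub <- mat[rs, cs, drop = FALSE]
  sub[mask] <- 1
  mat[rs, cs] <- sub
  mat
}

draw_segment <- function(mat, x1, y1, x2, y2, width) {
  H <- nrow(mat); W <- ncol(mat)
  half <- width / 2
  cs <- max(1, floor(min(x1, x2) - half) + 1):min(W, ceiling(max(x1, x2) + half) + 1)
  rs <- max(1, floor(min(y1, y2) - half) + 1):min(H, ceiling(max(y1, y2) + half) + 1)
  px <- rep((cs - 1), each = length(rs))
  py <- rep((rs - 1), times = length(cs))
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 < 1e-12) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
  d2 <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
  sel <- d2 <= half^2
  if (any(sel)) mat[cbind(py[sel] + 1, px[sel] + 1)] <- 1
  mat
}

#' Encode one frame's poses as a seven-channel binary image stack
#'
#' Each keypoint is rendered as a filled disc in its channel and each
#' connection (shoulder-tail, shoulder-left-ear, shoulder-right-ear) as a
#' rasterised segment. Absent ear coordinates (NA) render nothing in the
#' ear and ear-line channels.
#'
#' @param poses Data frame with columns \code{x_shoulder}, \code{y_shoulder},
#'   \code{x_tail}, \code{y_tail} and optionally \code{x_lear}, \code{y_lear},
#'   \code{x_rear}, \code{y_rear}, one row per pig, all for a single frame.
#' @param width,height Stack dimensions in pixels.
#' @param marker_radius Keypoint disc radius in pixels (default 4).
#' @param line_width Rasterised segment width in pixels (default 3).
#' @return An object of class \code{channel_stack}: a \code{height x width x
#'   7} binary array with named channels.
#' @export
encode_poses <- function(poses, width = 640, height = 400,
                         marker_radius = 4, line_width = 3) {
  A <- array(0, c(height, width, 7), dimnames = list(NULL, NULL, CHANNEL_NAMES))
  if (nrow(poses) > 0) {
    for (i in seq_len(nrow(poses))) {
      p <- poses[i, ]
      pts <- list(shoulder = c(p$x_shoulder, p$y_shoulder),
                  tail = c(p$x_tail, p$y_tail),
                  lear = c(p$x_lear %||% NA_real_, p$y_lear %||% NA_real_),
                  rear = c(p$x_rear %||% NA_real_, p$y_rear %||% NA_real_))
      for (nm in c("shoulder", "tail")) {
        q <- pts[[nm]]
        if (anyNA(q)) stop_pigtrackr("pose ", i, " has missing ", nm, " coordinates")
        if (q[1] < 0 || q[1] >= width || q[2] < 0 || q[2] >= height) {
          stop_pigtrackr("pose ", i, " has ", nm, " point (", q[1], ", ", q[2],
                         ") outside the ", width, "x", height, " image")
        }
      }
      for (nm in c("lear", "rear")) {
        q <- pts[[nm]]
        if (!anyNA(q) && (q[1] < 0 || q[1] >= width || q[2] < 0 || q[2] >= height)) {
          stop_pigtrackr("pose ", i, " has ", nm, " point outside the image")
        }
      }
      A[, , 3] <- draw_disc(A[, , 3], pts$shoulder[1], pts$shoulder[2], marker_radius)
      A[, , 4] <- draw_disc(A[, , 4], pts$tail[1], pts$tail[2], marker_radius)
      A[, , 5] <- draw_segment(A[, , 5], pts$shoulder[1], pts$shoulder[2],
                               pts$tail[1], pts$tail[2], line_width)
      if (!anyNA(pts$lear)) {
        A[, , 1] <- draw_disc(A[, , 1], pts$lear[1], pts$lear[2], marker_radius)
        A[, , 6] <- draw_segment(A[, , 6], pts$shoulder[1], pts$shoulder[2],
                                 pts$lear[1], pts$lear[2], line_width)
      }
      if (!anyNA(pts$rear)) {
        A[, , 2] <- draw_disc(A[, , 2], pts$rear[1], pts$rear[2], marker_radius)
        A[, , 7] <- draw_segment(A[, , 7], pts$shoulder[1], pts$shoulder[2],
                                 pts$rear[1], pts$rear[2], line_width)
      }
    }
  }
  structure(A, class = "channel_stack")
}

# 8-connected component labelling by iterative depth/breadth-first flood
# over the set pixels. Returns a list of coordinate matrices (columns x, y,
# 0-based), one per component, in first-pixel scan order.
components8 <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  idx <- which(mat != 0)
  n <- length(idx)
  if (n == 0) return(list())
  pos <- integer(H * W)       # linear pixel index -> position in idx
  pos[idx] <- seq_len(n)
  lab <- integer(n)
  comps <- list()
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    frontier <- i
    members <- i
    while (length(frontier)) {
      pix <- idx[frontier]
      r <- (pix - 1L) %% H
      up <- pix[r > 0L] - 1L
      dn <- pix[r < H - 1L] + 1L
      nb <- c(up, dn, pix - H, pix + H, up - H, up + H, dn - H, dn + H)
      nb <- nb[nb >= 1L & nb <= H * W]
      p <- pos[nb]
      p <- p[p > 0L]
      p <- unique(p[lab[p] == 0L])
      lab[p] <- cur
      members <- c(members, p)
      frontier <- p
    }
    pix <- idx[members]
    comps[[cur]] <- cbind(x = (pix - 1L) %/% H, y = (pix - 1L) %% H)
  }
  comps
}

# farthest pixel pair of a component (its diameter), via the convex hull
component_endpoints <- function(coords) {
  m <- nrow(coords)
  if (m == 1) return(c(coords[1, ], coords[1, ]))
  h <- if (m > 3) tryCatch(grDevices::chull(coords[, 1], coords[, 2]),
                           error = function(e) seq_len(m)) else seq_len(m)
  pts <- coords[h, , drop = FALSE]
  k <- nrow(pts)
  d2 <- outer(pts[, 1], pts[, 1], `-`)^2 + outer(pts[, 2], pts[, 2], `-`)^2
  best <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- pts[best[1], ]; b <- pts[best[2], ]
  # canonical order for determinism
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) { tmp <- a; a <- b; b <- tmp }
  c(a, b)
}

#' Extract line segments from a binary line channel
#'
#' Labels 8-connected components of the set pixels (a depth-first flood
#' search), discards components smaller than \code{min_component_pixels} as
#' noise, and reports each remaining component's two pixels of maximal
#' pairwise distance as the segment endpoints.
#'
#' @param line_channel Binary matrix (rows = y, columns = x).
#' @param min_component_pixels Minimum component size kept (default 10).
#' @return Data frame with one row per component: endpoint coordinates
#'   \code{x1, y1, x2, y2} (0-based) and \code{n_pixels}.
#' @export
extract_lines <- function(line_channel, min_component_pixels = 10) {
  comps <- components8(line_channel)
  comps <- comps[vapply(comps, nrow, 1L) >= min_component_pixels]
  if (length(comps) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), n_pixels = integer(0)))
  }
  ep <- t(vapply(comps, component_endpoints, numeric(4)))
  data.frame(x1 = ep[, 1], y1 = ep[, 2], x2 = ep[, 3], y2 = ep[, 4],
             n_pixels = vapply(comps, nrow, 1L))
}

# distance from a point to the nearest set pixel of a channel (Inf if empty);
# `pts` is the cached which(..., arr.ind=TRUE) matrix
min_dist_to_pts <- function(pts, x, y) {
  if (nrow(pts) == 0) return(Inf)
  sqrt(min((pts[, 2] - 1 - x)^2 + (pts[, 1] - 1 - y)^2))
}

#' Label line endpoints as shoulder/tail and attach ear points
#'
#' For each endpoint pair from \code{\link{extract_lines}}, the endpoint
#' nearer to a shoulder-channel blob (Euclidean distance to the nearest set
#' pixel) is labelled shoulder and the other tail. Ties, or an empty
#' shoulder channel, fall back to ear evidence (ear discs and ear-line
#' channels near an endpoint mark the head end). If neither source decides,
#' the pose is kept with \code{orientation_ok = FALSE} and an arbitrary
#' endpoint order. Ear keypoints are filled from the nearest ear-channel
#' blob centroid within \code{ear_search_radius} of the shoulder.
#'
#' @param pairs Data frame from \code{\link{extract_lines}}.
#' @param stack A \code{channel_stack} (binary).
#' @param ear_search_radius Search radius in px for ear blobs (default 25).
#' @return Data frame of poses: shoulder/tail/ear coordinates,
#'   \code{orientation_ok}, \code{n_pixels}.
#' @export
orient_lines <- function(pairs, stack, ear_search_radius = 25) {
  out <- data.frame(x_shoulder = numeric(0), y_shoulder = numeric(0),
                    x_tail = numeric(0), y_tail = numeric(0),
                    x_lear = numeric(0), y_lear = numeric(0),
                    x_rear = numeric(0), y_rear = numeric(0),
                    orientation_ok = logical(0), n_pixels = integer(0))
  if (nrow(pairs) == 0) return(out)
  sh_pts <- which(stack[, , 3] != 0, arr.ind = TRUE)
  ear_pts <- lapply(c(1, 2, 6, 7), function(k) which(stack[, , k] != 0, arr.ind = TRUE))
  lear_comps <- components8(stack[, , 1])
  rear_comps <- components8(stack[, , 2])
  centroid <- function(co) c(mean(co[, 1]), mean(co[, 2]))
  lear_c <- lapply(lear_comps, centroid)
  rear_c <- lapply(rear_comps, centroid)

  nearest_ear <- function(cents, sx, sy) {
    if (length(cents) == 0) return(c(NA_real_, NA_real_))
    d <- vapply(cents, function(cc) sqrt((cc[1] - sx)^2 + (cc[2] - sy)^2), 1)
    if (min(d) > ear_search_radius) return(c(NA_real_, NA_real_))
    cents[[which.min(d)]]
  }

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e1 <- c(pairs$x1[i], pairs$y1[i]); e2 <- c(pairs$x2[i], pairs$y2[i])
    d1 <- min_dist_to_pts(sh_pts, e1[1], e1[2])
    d2 <- min_dist_to_pts(sh_pts, e2[1], e2[2])
    ok <- TRUE
    if (is.finite(d1) && abs(d1 - d2) > 1e-9) {
      if (d2 < d1) { tmp <- e1; e1 <- e2; e2 <- tmp }
    } else {
      g1 <- min(vapply(ear_pts, min_dist_to_pts, 1, x = e1[1], y = e1[2]))
      g2 <- min(vapply(ear_pts, min_dist_to_pts, 1, x = e2[1], y = e2[2]))
      if (min(g1, g2) <= ear_search_radius && abs(g1 - g2) > 1e-9) {
        if (g2 < g1) { tmp <- e1; e1 <- e2; e2 <- tmp }
      } else {
        ok <- FALSE  # ambiguous: no usable shoulder or ear evidence
      }
    }
    le <- nearest_ear(lear_c, e1[1], e1[2])
    re <- nearest_ear(rear_c, e1[1], e1[2])
    rows[[i]] <- data.frame(x_shoulder = e1[1], y_shoulder = e1[2],
                            x_tail = e2[1], y_tail = e2[2],
                            x_lear = le[1], y_lear = le[2],
                            x_rear = re[1], y_rear = re[2],
                            orientation_ok = ok,
                            n_pixels = pairs$n_pixels[i])
  }
  do.call(rbind, rows)
}

#' Decode a channel stack into located, oriented poses
#'
#' Binarises real-valued channels at \code{threshold}, extracts
#' shoulder-tail line segments from channel 5 and orients them with the
#' point/ear channels. Touching animals whose line components merge decode
#' as a single (typically ambiguous) component; splitting merged components
#' is not attempted.
#'
#' @param stack \code{channel_stack}, binary or real-valued in \[0, 1\].
#' @param threshold Binarisation threshold in (0, 1), applied as
#'   \code{>= threshold} (default 0.5).
#' @param min_component_pixels,ear_search_radius See
#'   \code{\link{extract_lines}} and \code{\link{orient_lines}}.
#' @return Data frame of unordered, unassigned poses (possibly empty).
#' @export
#' @examples
#' poses <- data.frame(x_shoulder = 40, y_shoulder = 30, x_tail = 70, y_tail = 55)
#' st <- encode_poses(poses, width = 100, height = 80)
#' decode_stack(st)
decode_stack <- function(stack, threshold = 0.5, min_component_pixels = 10,
                         ear_search_radius = 25) {
  bin <- (unclass(stack) >= threshold) * 1
  pairs <- extract_lines(bin[, , 5], min_component_pixels)
  orient_lines(pairs, bin, ear_search_radius)
}

#' Write / read a channel stack as per-channel PNG images
#'
#' Files are named \code{frame_<idx>_ch<k>.png}, with \code{k} in 0..6.
#'
#' @param stack A \code{channel_stack}.
#' @param dir Output directory (created if needed).
#' @param frame_idx Frame index used in the file names.
#' @return \code{write_channel_stack} returns the file paths invisibly;
#'   \code{read_channel_stack} returns the reassembled \code{channel_stack}.
#' @export
write_channel_stack <- function(stack, dir, frame_idx = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(7)
  for (k in 1:7) {
    paths[k] <- file.path(dir, sprintf("frame_%06d_ch%d.png", frame_idx, k - 1))
    png::writePNG(unclass(stack)[, , k], paths[k])
  }
  invisible(paths)
}

#' @rdname write_channel_stack
#' @export
read_channel_stack <- function(dir, frame_idx = 0) {
  chans <- lapply(1:7, function(k) {
    p <- file.path(dir, sprintf("frame_%06d_ch%d.png", frame_idx, k - 1))
    if (!file.exists(p)) stop_pigtrackr("missing channel image: ", p)
    png::readPNG(p)
  })
  A <- array(0, c(dim(chans[[1]]), 7), dimnames = list(NULL, NULL, CHANNEL_NAMES))
  for (k in 1:7) A[, , k] <- chans[[k]]
  structure(A, class = "channel_stack")
}
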