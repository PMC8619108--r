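# Proximity-region contact detection.
#
# Per frame, every animal gets a head circle and a tail circle of common
# radius r = (mean shoulder-tail length of the frame) / alpha. Two circles
# of equal radius intersect iff their centres are within 2r (boundary
# inclusive), which is the criterion for head-head and head-tail events.

#' Contact-region radius of one frame
#'
#' \code{r = (1 / (alpha * N)) * sum_i ||s_i - t_i||}: the mean
#' shoulder-tail Euclidean length of the frame divided by \code{alpha}.
#' Recomputing r per frame lets the regions adapt to animal size.
#'
#' @param poses Data frame with shoulder and tail coordinates (one frame).
#' @param alpha Scaling factor (default 3, the empirically useful value:
#'   large enough to cover the head/tail area, small enough to ignore
#'   animals walking by).
#' @return Radius in pixels.
#' @export
#' @examples
#' region_radius(data.frame(x_shoulder = 0, y_shoulder = 0,
#'                          x_tail = 3, y_tail = 4), alpha = 1)  # 5
region_radius <- function(poses, alpha = 3) {
  if (is.null(nrow(poses)) || nrow(poses) == 0) {
    stop_pigtrackr("region radius undefined for an empty frame")
  }
  s <- pose_shoulder(poses); t <- pose_tail(poses)
  len <- sqrt((s[, 1] - t[, 1])^2 + (s[, 2] - t[, 2])^2)
  if (anyNA(len)) stop_pigtrackr("poses with missing shoulder/tail coordinates")
  mean(len) / alpha
}

pose_shoulder <- function(p) {
  if ("x_shoulder" %in% names(p)) cbind(p$x_shoulder, p$y_shoulder) else cbind(p$x, p$y)
}
pose_tail <- function(p) cbind(p$x_tail, p$y_tail)

#' Head and tail regions for one frame
#'
#' The tail circle is centred on the tail point. The head circle is centred
#' at \code{shoulder + head_offset_frac * r * u}, where \code{u} is the unit
#' body-orientation vector \code{normalize(shoulder - tail)}; with the
#' default \code{head_offset_frac = 0} it sits on the shoulder keypoint
#' itself. Degenerate poses (shoulder == tail) are excluded with a warning.
#'
#' @param poses Data frame for one frame, with an \code{id} column (or ids
#'   are taken as row numbers).
#' @param alpha Region scaling factor (default 3).
#' @param head_offset_frac Forward offset of the head centre, as a fraction
#'   of \code{r} (default 0).
#' @return An object of class \code{region_set}: data frame \code{id},
#'   \code{head_x}, \code{head_y}, \code{tail_x}, \code{tail_y}, with
#'   attribute \code{r}.
#' @export
make_regions <- function(poses, alpha = 3, head_offset_frac = 0) {
  ids <- poses$id %||% seq_len(nrow(poses))
  s <- pose_shoulder(poses); t <- pose_tail(poses)
  len <- sqrt(rowSums((s - t)^2))
  keep <- len > 1e-9
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " degenerate pose(s) with shoulder == tail")
  }
  if (!any(keep)) {
    out <- data.frame(id = integer(0), head_x = numeric(0), head_y = numeric(0),
                      tail_x = numeric(0), tail_y = numeric(0))
    return(structure(out, class = c("region_set", "data.frame"), r = NA_real_))
  }
  s <- s[keep, , drop = FALSE]; t <- t[keep, , drop = FALSE]
  len <- len[keep]
  r <- mean(len) / alpha
  u <- (s - t) / len
  head_c <- s + head_offset_frac * r * u
  out <- data.frame(id = ids[keep], head_x = head_c[, 1], head_y = head_c[, 2],
                    tail_x = t[, 1], tail_y = t[, 2])
  structure(out, class = c("region_set", "data.frame"), r = r)
}

#' Detect contact events in one frame's regions
#'
#' For every unordered pair: a head-head event iff the two head centres are
#' within \code{2r}; a head-tail event iff one animal's head centre is
#' within \code{2r} of the other's tail centre (role-tagged; both directions
#' are checked, so one pair can yield several simultaneous events).
#'
#' @param regions A \code{\link{make_regions}} result.
#' @param frame Frame index recorded in the events (default 0).
#' @return Data frame of events: \code{frame}, \code{id_a}, \code{id_b}
#'   (canonical order \code{id_a < id_b}), \code{type}, \code{head_id},
#'   \code{tail_id} (NA for head-head).
#' @export
detect_contacts <- function(regions, frame = 0L) {
  empty <- data.frame(frame = integer(0), id_a = integer(0), id_b = integer(0),
                      type = character(0), head_id = integer(0),
                      tail_id = integer(0))
  n <- nrow(regions)
  if (n < 2) return(empty)
  r <- attr(regions, "r")
  thr2 <- (2 * r)^2
  hx <- regions$head_x; hy <- regions$head_y
  tx <- regions$tail_x; ty <- regions$tail_y
  ids <- regions$id
  rows <- list()
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lo <- min(ids[i], ids[j]); hi <- max(ids[i], ids[j])
    if ((hx[i] - hx[j])^2 + (hy[i] - hy[j])^2 <= thr2) {
      k <- k + 1L
      rows[[k]] <- data.frame(frame = frame, id_a = lo, id_b = hi,
                              type = "head-head", head_id = NA_integer_,
                              tail_id = NA_integer_)
    }
    if ((hx[i] - tx[j])^2 + (hy[i] - ty[j])^2 <= thr2) {
      k <- k + 1L
      rows[[k]] <- data.frame(frame = frame, id_a = lo, id_b = hi,
                              type = "head-tail", head_id = ids[i],
                              tail_id = ids[j])
    }
    if ((hx[j] - tx[i])^2 + (hy[j] - ty[i])^2 <= thr2) {
      k <- k + 1L
      rows[[k]] <- data.frame(frame = frame, id_a = lo, id_b = hi,
                              type = "head-tail", head_id = ids[j],
                              tail_id = ids[i])
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$frame, out$id_a, out$id_b, out$type, out$head_id), , drop = FALSE]
}

# frame-wise contact detection over a long pose/track table
contacts_from_poses <- function(poses, alpha = 3, head_offset_frac = 0) {
  empty <- data.frame(frame = integer(0), id_a = integer(0), id_b = integer(0),
                      type = character(0), head_id = integer(0),
                      tail_id = integer(0))
  if (nrow(poses) == 0) return(empty)
  res <- lapply(split(poses, poses$frame), function(pf) {
    reg <- suppressWarnings(make_regions(pf, alpha, head_offset_frac))
    detect_contacts(reg, frame = pf$frame[1])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out)) empty else out
}

#' Build the social-contact table from tracks
#'
#' Recomputes the contact-region radius on every frame from the tracked
#' shoulder and tail estimates, detects head-head and head-tail events, and
#' returns the per-frame contact table. An episode view merging temporally
#' adjacent events is available via \code{\link{contact_episodes}}.
#'
#' @param tracks A \code{pig_tracks} object (or data frame with
#'   \code{frame}, \code{id}, \code{x}, \code{y}, \code{x_tail},
#'   \code{y_tail}).
#' @param alpha Region scaling factor (default 3).
#' @param head_offset_frac Forward head-centre offset fraction (default 0).
#' @param gap_tolerance Default episode gap tolerance in frames, stored for
#'   \code{\link{contact_episodes}} (default 5, i.e. 0.5 s at 10 fps).
#' @return An object of class \code{contact_table}: the event data frame
#'   with attributes \code{ids}, \code{n_frames}, \code{alpha},
#'   \code{gap_tolerance}.
#' @export
build_contact_table <- function(tracks, alpha = 3, head_offset_frac = 0,
                                gap_tolerance = 5) {
  df <- as.data.frame(tracks)
  events <- contacts_from_poses(df, alpha, head_offset_frac)
  structure(events, class = c("contact_table", "data.frame"),
            ids = sort(unique(df$id)),
            n_frames = if (nrow(df)) max(df$frame) else 0L,
            alpha = alpha, gap_tolerance = gap_tolerance)
}

#' Merge per-frame contact events into episodes
#'
#' Events with the same pair, type and roles are merged into one episode
#' when the gap between consecutive event frames is at most
#' \code{gap_tolerance} frames.
#'
#' @param table A \code{contact_table} (or compatible data frame).
#' @param gap_tolerance Maximum bridged gap in frames; defaults to the
#'   table's stored value, else 5.
#' @return Data frame \code{id_a}, \code{id_b}, \code{type}, \code{head_id},
#'   \code{tail_id}, \code{start_frame}, \code{end_frame}, \code{n_frames}
#'   (number of event frames in the episode).
#' @export
contact_episodes <- function(table, gap_tolerance = NULL) {
  gap_tolerance <- gap_tolerance %||% attr(table, "gap_tolerance") %||% 5
  empty <- data.frame(id_a = integer(0), id_b = integer(0), type = character(0),
                      head_id = integer(0), tail_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      n_frames = integer(0))
  if (nrow(table) == 0) return(empty)
  key <- paste(table$id_a, table$id_b, table$type, table$head_id, sep = "|")
  res <- lapply(split(as.data.frame(table), key), function(g) {
    fr <- sort(unique(g$frame))
    brk <- c(0, which(diff(fr) > gap_tolerance + 1), length(fr))
    eps <- lapply(seq_len(length(brk) - 1), function(k) {
      ff <- fr[(brk[k] + 1):brk[k + 1]]
      data.frame(id_a = g$id_a[1], id_b = g$id_b[1], type = g$type[1],
                 head_id = g$head_id[1], tail_id = g$tail_id[1],
                 start_frame = min(ff), end_frame = max(ff),
                 n_frames = length(ff))
    })
    do.call(rbind, eps)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start_frame, out$id_a, out$id_b, out$type), , drop = FALSE]
}

#' @export
print.contact_table <- function(x, ...) {
  cat("Contact table:", nrow(x), "per-frame events,",
      length(attr(x, "ids")), "animals, alpha =", attr(x, "alpha"), "\n")
  if (nrow(x)) print(table(x$type))
  invisible(x)
}

#' @export
summary.contact_table <- function(object, ...) {
  eps <- contact_episodes(object)
  cat("Events:", nrow(object), " episodes:", nrow(eps), "\n")
  if (nrow(eps)) print(head(eps, 10))
  invisible(eps)
}
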