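# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the implementation they check.

# all-pairs circle-intersection contact oracle for one frame of poses
oracle_contacts <- function(poses, alpha = 3, head_offset_frac = 0) {
  n <- nrow(poses)
  lens <- numeric(n); heads <- matrix(0, n, 2); tails <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    s <- c(poses$x_shoulder[i], poses$y_shoulder[i])
    t <- c(poses$x_tail[i], poses$y_tail[i])
    lens[i] <- sqrt(sum((s - t)^2))
    tails[i, ] <- t
    heads[i, ] <- s  # filled below once r is known
  }
  r <- mean(lens) / alpha
  for (i in seq_len(n)) {
    s <- c(poses$x_shoulder[i], poses$y_shoulder[i])
    u <- (s - tails[i, ]) / lens[i]
    heads[i, ] <- s + head_offset_frac * r * u
  }
  out <- NULL
  ids <- if (is.null(poses$id)) seq_len(n) else poses$id
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    lo <- min(ids[i], ids[j]); hi <- max(ids[i], ids[j])
    if (sqrt(sum((heads[i, ] - heads[j, ])^2)) <= 2 * r) {
      out <- rbind(out, data.frame(frame = poses$frame[1] %||% 0, id_a = lo,
                                   id_b = hi, type = "head-head",
                                   head_id = NA_integer_, tail_id = NA_integer_))
    }
    if (sqrt(sum((heads[i, ] - tails[j, ])^2)) <= 2 * r) {
      out <- rbind(out, data.frame(frame = poses$frame[1] %||% 0, id_a = lo,
                                   id_b = hi, type = "head-tail",
                                   head_id = ids[i], tail_id = ids[j]))
    }
    if (sqrt(sum((heads[j, ] - tails[i, ])^2)) <= 2 * r) {
      out <- rbind(out, data.frame(frame = poses$frame[1] %||% 0, id_a = lo,
                                   id_b = hi, type = "head-tail",
                                   head_id = ids[j], tail_id = ids[i]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), id_a = integer(0), id_b = integer(0),
                      type = character(0), head_id = integer(0),
                      tail_id = integer(0))
  }
  out[order(out$frame, out$id_a, out$id_b, out$type, out$head_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonicalise an event table for set comparison
event_key <- function(ev) {
  if (nrow(ev) == 0) return(character(0))
  sort(paste(ev$frame, ev$id_a, ev$id_b, ev$type, ev$head_id, ev$tail_id))
}

# brute-force 8-connected labelling by iterated label propagation
oracle_label8 <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  lab <- matrix(0L, H, W)
  lab[mat != 0] <- seq_len(sum(mat != 0))
  repeat {
    changed <- FALSE
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      if (lab[r, cc] == 0L) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W && lab[rr, c2] > 0L &&
            lab[rr, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[rr, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# brute-force farthest pair over all component pixels
oracle_endpoints <- function(coords) {
  best <- c(0, 0, 0, 0); bd <- -1
  for (i in seq_len(nrow(coords))) for (j in seq_len(nrow(coords))) {
    d <- sum((coords[i, ] - coords[j, ])^2)
    if (d > bd) { bd <- d; best <- c(coords[i, ], coords[j, ]) }
  }
  best
}

# exhaustive minimum-cost assignment (rows <= cols)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

oracle_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  best <- Inf
  for (p in perms(seq_len(m))) {
    cc <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cc < best) best <- cc
  }
  best
}

# distance between two segments (for round-trip eligibility)
seg_dist <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    v <- b - a; L2 <- sum(v^2)
    t <- if (L2 < 1e-12) 0 else max(0, min(1, sum((p - a) * v) / L2))
    sqrt(sum((p - (a + t * v))^2))
  }
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

pose_segments <- function(pf) {
  lapply(seq_len(nrow(pf)), function(i)
    list(s = c(pf$x_shoulder[i], pf$y_shoulder[i]),
         t = c(pf$x_tail[i], pf$y_tail[i])))
}

# which poses of a frame are isolated (pairwise segment distance above thr)?
isolated_poses <- function(pf, thr) {
  segs <- pose_segments(pf)
  n <- length(segs)
  iso <- rep(TRUE, n)
  if (n > 1) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (seg_dist(segs[[i]]$s, segs[[i]]$t, segs[[j]]$s, segs[[j]]$t) <= thr) {
      iso[i] <- FALSE
    }
  }
  iso
}
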