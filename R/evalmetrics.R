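# Detection and tracking evaluation.
#
# Detection protocol: a circular detection region around each annotated
# shoulder point (radius = mean shoulder-to-ear distance of the frame)
# classifies predicted points into TP / FP / FN; sensitivity, precision and
# F1 follow from the counts. Tracking protocol: MOTA with an automated
# FP/FN/IDSW classifier (truth-anchored ID-change counting, one increment
# per change).

#' Detection-region radius of an annotated frame
#'
#' The mean, over all pigs of the frame and both ears, of the Euclidean
#' distance from the annotated shoulder point to the annotated ear point.
#'
#' @param truth_frame Data frame with \code{x_shoulder}, \code{y_shoulder},
#'   \code{x_lear}, \code{y_lear}, \code{x_rear}, \code{y_rear}.
#' @return Radius in pixels.
#' @export
detection_region_radius <- function(truth_frame) {
  dl <- sqrt((truth_frame$x_shoulder - truth_frame$x_lear)^2 +
               (truth_frame$y_shoulder - truth_frame$y_lear)^2)
  dr <- sqrt((truth_frame$x_shoulder - truth_frame$x_rear)^2 +
               (truth_frame$y_shoulder - truth_frame$y_rear)^2)
  d <- c(dl, dr)
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    stop_pigtrackr("detection region radius undefined: no ear annotations")
  }
  mean(d)
}

#' Classify predicted shoulder points of one frame as TP / FP / FN
#'
#' Each predicted point is assigned to the nearest truth region containing
#' it (ties to the lower truth index); points inside no region are FP. Per
#' region: exactly one assigned point is a TP; k > 1 points give 1 TP and
#' k - 1 FP; zero points give an FN. Hence TP + FN equals the number of
#' annotated pigs.
#'
#' @param truth_frame Annotated poses of one frame (shoulders; ears needed
#'   unless \code{radius} is supplied).
#' @param predicted Data frame or matrix of predicted shoulder points
#'   (\code{x_shoulder}/\code{y_shoulder} or \code{x}/\code{y} columns).
#' @param radius Detection-region radius; default
#'   \code{detection_region_radius(truth_frame)}.
#' @return Named integer vector \code{c(TP, FP, FN)}.
#' @export
classify_detections <- function(truth_frame, predicted, radius = NULL) {
  radius <- radius %||% detection_region_radius(truth_frame)
  tz <- pose_shoulder(truth_frame)
  n <- nrow(tz)
  m <- if (is.null(predicted) || length(predicted) == 0) 0 else nrow(predicted)
  if (m == 0) {
    return(c(TP = 0L, FP = 0L, FN = n))
  }
  pz <- if (is.matrix(predicted)) predicted else pose_shoulder(as.data.frame(predicted))
  d <- sqrt(outer(pz[, 1], tz[, 1], `-`)^2 + outer(pz[, 2], tz[, 2], `-`)^2)
  assigned <- integer(m)
  for (k in seq_len(m)) {
    inside <- which(d[k, ] <= radius)
    if (length(inside)) assigned[k] <- inside[which.min(d[k, inside])]
  }
  per_region <- tabulate(assigned[assigned > 0], nbins = n)
  TP <- sum(per_region >= 1)
  FP <- sum(assigned == 0) + sum(pmax(per_region - 1, 0))
  FN <- sum(per_region == 0)
  c(TP = as.integer(TP), FP = as.integer(FP), FN = as.integer(FN))
}

#' Sum TP/FP/FN detection counts over a sequence
#'
#' @param truth Annotated poses with a \code{frame} column.
#' @param predicted Predicted detections with a \code{frame} column.
#' @return List with the summed counts and the derived metrics.
#' @export
evaluate_detections <- function(truth, predicted) {
  counts <- c(TP = 0L, FP = 0L, FN = 0L)
  for (f in sort(unique(truth$frame))) {
    tf <- truth[truth$frame == f, , drop = FALSE]
    pf <- predicted[predicted$frame == f, , drop = FALSE]
    counts <- counts + classify_detections(tf, pf)
  }
  c(as.list(counts), detection_metrics(counts["TP"], counts["FP"], counts["FN"]))
}

#' Detection metrics from TP/FP/FN counts
#'
#' \code{sensitivity = TP / (TP + FN)}, \code{precision = TP / (TP + FP)},
#' \code{f1 = 2 TP / (2 TP + FP + FN)}.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return List with \code{sensitivity}, \code{precision}, \code{f1}.
#' @export
#' @examples
#' detection_metrics(1019, 51, 35)
detection_metrics <- function(TP, FP, FN) {
  if (TP < 0 || FP < 0 || FN < 0) stop_pigtrackr("counts must be >= 0")
  if (TP + FN == 0 || TP + FP == 0 || 2 * TP + FP + FN == 0) {
    stop_pigtrackr("metrics undefined: zero denominator")
  }
  list(sensitivity = TP / (TP + FN),
       precision = TP / (TP + FP),
       f1 = 2 * TP / (2 * TP + FP + FN))
}

#' Multiple Object Tracking Accuracy
#'
#' \code{MOTA = 1 - (FP + FN + IDSW) / N}, where \code{N} is the number of
#' detected shoulder points considered.
#'
#' @param FP,FN,IDSW Non-negative error counts (falsely tracked, untracked,
#'   identity switches).
#' @param N Number of detected points considered (> 0).
#' @return MOTA as a fraction (at most 1).
#' @export
#' @examples
#' mota(20, 8, 10, 678)  # 0.944
mota <- function(FP, FN, IDSW, N) {
  if (N <= 0) stop_pigtrackr("N must be > 0")
  if (FP < 0 || FN < 0 || IDSW < 0) stop_pigtrackr("counts must be >= 0")
  1 - (FP + FN + IDSW) / N
}

#' Classify tracking output against ground truth
#'
#' Per frame, predicted track points are matched one-to-one to truth points
#' by minimum total distance among pairs within \code{loc_threshold};
#' unmatched truth points count as FN, unmatched predicted points as FP (a
#' track held at an empty spot while its animal goes undetected therefore
#' increments both). Identity switches are counted at change events against
#' a truth-anchored mapping: each truth id remembers the predicted id last
#' matched to it, and a change counts once (not per frame). Two
#' complementary changes on the same frame — the classic case of two
#' animals exchanging their assigned ids — are merged into one switch
#' event. \code{N} defaults to the number of predicted track points
#' presented (the points the tracker emitted), overridable via
#' \code{n_detected}.
#'
#' @param truth Ground-truth poses (\code{frame}, \code{id}, shoulder
#'   coordinates; ears are used for the default threshold).
#' @param predicted Tracker output (\code{frame}, \code{id}, \code{x},
#'   \code{y}).
#' @param loc_threshold Localisation threshold in px; \code{NULL} (default)
#'   recomputes the frame's detection-region radius from the truth ears, for
#'   symmetry with the detection protocol.
#' @param n_detected Optional override for the MOTA denominator.
#' @return An object of class \code{tracking_eval}: list with \code{FP_T},
#'   \code{FN_T}, \code{IDSW}, \code{N}, \code{mota} and \code{events} (one
#'   row per identity change: frame, truth id, old and new predicted id).
#' @export
classify_tracking <- function(truth, predicted, loc_threshold = NULL,
                              n_detected = NULL) {
  truth <- as.data.frame(truth)
  predicted <- as.data.frame(predicted)
  frames <- sort(intersect(unique(truth$frame), unique(predicted$frame)))
  FP <- 0L; FN <- 0L; IDSW <- 0L
  last_pred <- list()  # truth id (character) -> predicted id
  events <- list()
  n_presented <- 0L
  for (f in frames) {
    tf <- truth[truth$frame == f, , drop = FALSE]
    pf <- predicted[predicted$frame == f, , drop = FALSE]
    n_presented <- n_presented + nrow(pf)
    thr <- loc_threshold %||% detection_region_radius(tf)
    asc <- associate_detections(
      data.frame(track = tf$id, x = pose_shoulder(tf)[, 1],
                 y = pose_shoulder(tf)[, 2]),
      data.frame(x = pf$x, y = pf$y),
      gate_radius = thr)
    FN <- FN + length(asc$unmatched_tracks)
    FP <- FP + length(asc$unmatched_detections)
    changes <- NULL
    if (nrow(asc$matches)) for (k in seq_len(nrow(asc$matches))) {
      tid <- as.character(asc$matches$track[k])
      pid <- pf$id[asc$matches$det[k]]
      old <- last_pred[[tid]]
      if (!is.null(old) && old != pid) {
        changes <- rbind(changes,
                         data.frame(frame = f, truth_id = asc$matches$track[k],
                                    prev_pred = old, new_pred = pid))
      }
      last_pred[[tid]] <- pid
    }
    if (!is.null(changes)) {
      # two complementary changes on one frame = one pair exchange
      paired <- rep(FALSE, nrow(changes))
      for (i in seq_len(nrow(changes))) {
        if (paired[i]) next
        j <- which(!paired & seq_len(nrow(changes)) > i &
                     changes$prev_pred == changes$new_pred[i] &
                     changes$new_pred == changes$prev_pred[i])
        if (length(j)) paired[j[1]] <- TRUE
        IDSW <- IDSW + 1L
      }
      events[[length(events) + 1L]] <- changes
    }
  }
  N <- as.integer(n_detected %||% n_presented)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(0), truth_id = integer(0),
               prev_pred = integer(0), new_pred = integer(0))
  structure(list(FP_T = FP, FN_T = FN, IDSW = IDSW, N = N,
                 mota = mota(FP, FN, IDSW, N), events = ev),
            class = "tracking_eval")
}

#' @export
print.tracking_eval <- function(x, ...) {
  cat(sprintf("Tracking evaluation: MOTA = %.3f (FP = %d, FN = %d, IDSW = %d, N = %d)\n",
              x$mota, x$FP_T, x$FN_T, x$IDSW, x$N))
  invisible(x)
}
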