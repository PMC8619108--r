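# CSV dialects and the end-to-end pipeline.
#
# Detection CSV: one row per pig per frame, columns frame, x_shoulder,
# y_shoulder, x_tail, y_tail, x_lear, y_lear, x_rear, y_rear (ears may be
# empty); truth files additionally carry id. Track CSV: frame, pig_id, x, y,
# x_tail, y_tail, status. Contact CSV: frame, id_a, id_b, type, head_id,
# tail_id. All coordinates 0-based pixels, x = column (rightward), y = row
# (downward); written at full float precision (round-trip lossless).

DET_COLS <- c("frame", "x_shoulder", "y_shoulder", "x_tail", "y_tail",
              "x_lear", "y_lear", "x_rear", "y_rear")

# write a data frame with doubles rendered at %.17g so that every
# coordinate survives a write/read cycle bit-exactly
fwrite_full <- function(df, path) {
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- NA_character_
      df[[cl]] <- v
    }
  }
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

check_frame_order <- function(df, path) {
  if (nrow(df) > 1 && is.unsorted(df$frame)) {
    warning("frames out of order in ", path, "; reordering")
    df <- df[order(df$frame), , drop = FALSE]
  }
  df
}

#' Read / write detection CSV files
#'
#' @param path File path.
#' @param detections,poses Data frame with the detection columns (see the
#'   package help for the dialect); an \code{id} column is preserved when
#'   present (ground-truth files).
#' @return \code{read_detections} returns a \code{pig_detections}-style data
#'   frame (with an \code{n_frames} attribute); writers return the path
#'   invisibly.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_pigtrackr("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- setdiff(c("frame", "x_shoulder", "y_shoulder", "x_tail", "y_tail"),
                  names(df))
  if (length(need)) {
    stop_pigtrackr("malformed detection CSV ", path, ": missing column(s) ",
                   paste(need, collapse = ", "))
  }
  num_cols <- intersect(DET_COLS, names(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad)) {
      stop_pigtrackr("malformed value in ", path, " column ", cl,
                     " at data line ", bad[1])
    }
    df[[cl]] <- v
  }
  df$frame <- as.integer(df$frame)
  df <- check_frame_order(df, path)
  rownames(df) <- NULL
  structure(df, class = c("pig_detections", "data.frame"),
            n_frames = if (nrow(df)) as.integer(max(df$frame)) else 0L)
}

#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  df <- as.data.frame(detections)
  cols <- intersect(c("frame", "id", DET_COLS[-1]), names(df))
  fwrite_full(df[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname read_detections
#' @export
write_poses <- function(poses, path) write_detections(poses, path)

#' Read / write track CSV files
#'
#' @param path File path.
#' @param tracks A \code{pig_tracks} object.
#' @return \code{read_tracks} returns a \code{pig_tracks}-style data frame.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_pigtrackr("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- setdiff(c("frame", "pig_id", "x", "y"), names(df))
  if (length(need)) {
    stop_pigtrackr("malformed track CSV ", path, ": missing ",
                   paste(need, collapse = ", "))
  }
  names(df)[names(df) == "pig_id"] <- "id"
  df <- check_frame_order(df, path)
  structure(df, class = c("pig_tracks", "data.frame"),
            n_frames = if (nrow(df)) as.integer(max(df$frame)) else 0L,
            birth_frame = if (nrow(df)) min(df$frame) else NA,
            gate_radius = NA,
            config = list(n_pigs = length(unique(df$id))))
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  names(df)[names(df) == "id"] <- "pig_id"
  fwrite_full(df, path)
  invisible(path)
}

#' Read / write contact-table CSV files
#'
#' @param path File path.
#' @param table A \code{contact_table}.
#' @return \code{read_contacts} returns a \code{contact_table}-style data
#'   frame.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop_pigtrackr("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- setdiff(c("frame", "id_a", "id_b", "type"), names(df))
  if (length(need)) {
    stop_pigtrackr("malformed contact CSV ", path, ": missing ",
                   paste(need, collapse = ", "))
  }
  df <- check_frame_order(df, path)
  structure(df, class = c("contact_table", "data.frame"),
            ids = sort(unique(c(df$id_a, df$id_b))), gap_tolerance = 5)
}

#' @rdname read_contacts
#' @export
write_contacts <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' Run the full pipeline on a detection file or simulated truth
#'
#' Executes detections -> tracking -> contact table -> episodes -> social
#' networks (all / head-head / head-tail), writes every artifact to
#' \code{outdir} together with a manifest (configuration, package version,
#' file checksums), and — when ground truth is supplied — a tracking
#' evaluation in \code{metrics.json}.
#'
#' @param detections Path to a detection CSV, or a \code{pig_detections}
#'   object.
#' @param n_pigs Known animal count.
#' @param outdir Output directory (created; must not pre-exist as a file).
#' @param alpha Contact-region scaling factor (default 3).
#' @param gap_tolerance Episode merge tolerance in frames (default 5).
#' @param head_offset_frac Head-circle forward offset (default 0).
#' @param truth Optional \code{pen_truth} for evaluation.
#' @param tracker Optional \code{\link{tracker_config}} override.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(detections, n_pigs, outdir, alpha = 3,
                         gap_tolerance = 5, head_offset_frac = 0,
                         truth = NULL, tracker = NULL, seed = 1L) {
  if (is.character(detections)) {
    if (!file.exists(detections)) {
      stop_pigtrackr("input detections not found: ", detections)
    }
    detections <- read_detections(detections)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- tracker %||% tracker_config(n_pigs = n_pigs)

  tracks <- track_sequence(detections, cfg)
  table <- build_contact_table(tracks, alpha = alpha,
                               head_offset_frac = head_offset_frac,
                               gap_tolerance = gap_tolerance)
  episodes <- contact_episodes(table)

  paths <- list(tracks = file.path(outdir, "tracks.csv"),
                contacts = file.path(outdir, "contacts.csv"),
                episodes = file.path(outdir, "episodes.csv"))
  write_tracks(tracks, paths$tracks)
  write_contacts(table, paths$contacts)
  data.table::fwrite(episodes, paths$episodes)

  for (tf in c("all", "head-head", "head-tail")) {
    net <- build_social_network(table, type_filter = tf)
    key <- paste0("network_", gsub("-", "", tf))
    paths[[key]] <- file.path(outdir, paste0(key, ".graphml"))
    export_network(net, paths[[key]], "graphml")
    pdf_path <- file.path(outdir, paste0(key, ".pdf"))
    plot(net, seed = seed, file = pdf_path)
    paths[[paste0(key, "_figure")]] <- pdf_path
  }

  if (!is.null(truth)) {
    ev <- classify_tracking(truth$poses, tracks)
    paths$metrics <- file.path(outdir, "metrics.json")
    jsonlite::write_json(list(FP_T = ev$FP_T, FN_T = ev$FN_T, IDSW = ev$IDSW,
                              N = ev$N, mota = ev$mota),
                         paths$metrics, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "pigtrackr",
    version = as.character(utils::packageVersion("pigtrackr")),
    n_pigs = n_pigs, alpha = alpha, gap_tolerance = gap_tolerance,
    head_offset_frac = head_offset_frac, seed = seed,
    tracker = unclass(cfg),
    checksums = as.list(tools::md5sum(unlist(paths[!grepl("figure", names(paths))]))))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
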