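TRACK_COLUMNS <- c("dish_id", "animal_id", "t_s",
                   "head_x_mm", "head_y_mm", "mid_x_mm", "mid_y_mm",
                   "tail_x_mm", "tail_y_mm")

#' Assemble a larval tracking dataset
#'
#' A dataset bundles an arena geometry with a collection of trajectories,
#' one per tracked animal (or track fragment), grouped by dish. Each
#' trajectory is a data frame with columns `t_s`, `head_x_mm`, `head_y_mm`,
#' `mid_x_mm`, `mid_y_mm`, `tail_x_mm`, `tail_y_mm` and attributes
#' `dish_id`, `animal_id` and `frame_dt_s`.
#'
#' @param trajectories list of trajectory data frames (see Details).
#' @param arena an [arena_spec()].
#' @param group_label free-text label for the experimental group.
#' @return an object of class `larva_dataset`.
#' @export
larva_dataset <- function(trajectories, arena = arena_spec(),
                          group_label = "") {
  stopifnot(inherits(arena, "arena_spec"), is.list(trajectories))
  if (length(trajectories) == 0L)
    stop("dataset contains no trajectories")
  for (tr in trajectories) {
    if (nrow(tr) < 2L)
      stop("every trajectory needs at least 2 points")
    if (is.null(attr(tr, "dish_id")) || is.null(attr(tr, "animal_id")))
      stop("trajectories must carry dish_id and animal_id attributes")
    if (is.unsorted(tr$t_s)) stop("trajectory times must be non-decreasing")
  }
  structure(list(group_label = group_label, arena = arena,
                 trajectories = trajectories),
            class = "larva_dataset")
}

#' @export
print.larva_dataset <- function(x, ...) {
  dishes <- unique(vapply(x$trajectories, attr, "", "dish_id"))
  npts <- sum(vapply(x$trajectories, nrow, 0L))
  cat(sprintf("Larval tracking dataset%s\n",
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else ""))
  cat(sprintf("  %d trajectories on %d dish(es), %d frames total\n",
              length(x$trajectories), length(dishes), npts))
  invisible(x)
}

new_trajectory <- function(df, dish_id, animal_id, frame_dt_s) {
  rownames(df) <- NULL
  attr(df, "dish_id") <- as.character(dish_id)
  attr(df, "animal_id") <- as.character(animal_id)
  attr(df, "frame_dt_s") <- frame_dt_s
  df
}

#' Read a track table in the tab-separated tracking dialect
#'
#' Ingests multi-animal tracking output with one row per animal per frame
#' and the header `dish_id animal_id t_s head_x_mm head_y_mm mid_x_mm
#' mid_y_mm tail_x_mm tail_y_mm` (tab separated, arena-centered mm).
#' Rows with any missing coordinate are dropped (a message reports the
#' count). Within each animal, rows are sorted by time; if the sampling
#' rate differs from `frame_dt_s` the positions are linearly interpolated
#' onto the uniform frame grid, and tracking gaps longer than
#' `max_gap_frames` frames split the track into independent fragments
#' (fragment ids get a `#k` suffix), mimicking tracker identity loss.
#'
#' @param path path to the TSV file.
#' @param arena an [arena_spec()].
#' @param frame_dt_s target frame interval in seconds (default 1/16 s).
#' @param max_gap_frames largest tolerated gap, in frames, before a track
#'   is split (default 2).
#' @param group_label optional label stored on the dataset.
#' @return a [larva_dataset()].
#' @export
read_tracks <- function(path, arena = arena_spec(), frame_dt_s = 0.0625,
                        max_gap_frames = 2, group_label = "") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(TRACK_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("malformed track header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) stop("empty track file: ", path)
  coord_cols <- TRACK_COLUMNS[-(1:2)]
  bad <- !stats::complete.cases(raw[coord_cols])
  if (any(bad)) {
    message(sum(bad), " row(s) with missing coordinates dropped")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no complete rows in track file: ", path)

  key <- interaction(raw$dish_id, raw$animal_id, drop = TRUE)
  trajectories <- list()
  for (grp in split(raw, key)) {
    grp <- grp[order(grp$t_s), , drop = FALSE]
    frags <- split_track(grp, frame_dt_s, max_gap_frames)
    nfrag <- length(frags)
    for (k in seq_len(nfrag)) {
      id <- if (nfrag > 1L)
        paste0(grp$animal_id[1L], "#", k) else as.character(grp$animal_id[1L])
      tr <- new_trajectory(frags[[k]][setdiff(TRACK_COLUMNS, c("dish_id", "animal_id"))],
                           grp$dish_id[1L], id, frame_dt_s)
      if (nrow(tr) >= 2L) trajectories[[length(trajectories) + 1L]] <- tr
    }
  }
  if (length(trajectories) == 0L)
    stop("no usable trajectories (all fragments shorter than 2 frames)")
  larva_dataset(trajectories, arena, group_label)
}

# split one animal's rows at gaps > max_gap_frames, resampling each
# contiguous piece onto the uniform dt grid if needed
split_track <- function(grp, frame_dt_s, max_gap_frames) {
  dts <- diff(grp$t_s)
  gap <- dts > (max_gap_frames + 0.5) * frame_dt_s
  piece_id <- cumsum(c(0L, as.integer(gap)))
  lapply(split(grp, piece_id), resample_track, frame_dt_s = frame_dt_s)
}

resample_track <- function(piece, frame_dt_s) {
  if (nrow(piece) < 2L) return(piece)
  dts <- diff(piece$t_s)
  if (all(abs(dts - frame_dt_s) < 1e-6)) return(piece)
  tt <- seq(piece$t_s[1L], piece$t_s[nrow(piece)], by = frame_dt_s)
  out <- data.frame(t_s = tt)
  for (col in c("head_x_mm", "head_y_mm", "mid_x_mm", "mid_y_mm",
                "tail_x_mm", "tail_y_mm"))
    out[[col]] <- stats::approx(piece$t_s, piece[[col]], xout = tt)$y
  out$dish_id <- piece$dish_id[1L]
  out$animal_id <- piece$animal_id[1L]
  out
}

#' Write a dataset back to the track-TSV dialect
#'
#' @param dataset a [larva_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(dataset, path) {
  stopifnot(inherits(dataset, "larva_dataset"))
  rows <- lapply(dataset$trajectories, function(tr) {
    cbind(data.frame(dish_id = attr(tr, "dish_id"),
                     animal_id = attr(tr, "animal_id"),
                     stringsAsFactors = FALSE),
          as.data.frame(tr)[setdiff(TRACK_COLUMNS, c("dish_id", "animal_id"))])
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
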