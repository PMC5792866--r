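#' Depth series container
#'
#' A nominally 1 Hz time-depth record. Depth is metres, positive down; small
#' negative values (surface sensor noise) down to -0.5 m are tolerated.
#'
#' @param timestamp strictly increasing POSIXct vector.
#' @param depth_m numeric metres, >= -0.5.
#' @return data.frame of class `depth_series`.
#' @export
depth_series <- function(timestamp, depth_m) {
  stopifnot(inherits(timestamp, "POSIXct"),
            length(timestamp) == length(depth_m))
  if (length(timestamp) > 1 && any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(depth_m < -0.5, na.rm = TRUE))
    stop("depth below -0.5 m: check sensor units/sign")
  structure(data.frame(timestamp = timestamp, depth_m = depth_m),
            class = c("depth_series", "data.frame"))
}

# indices of the bottom-phase window within one dive: the contiguous span
# from the first to the last sample at >= fraction * max depth
bottom_window <- function(depth, fraction = 0.8) {
  thr <- fraction * max(depth)
  idx <- which(depth >= thr)
  seq(min(idx), max(idx))
}

#' Bottom phase of a dive
#'
#' The contiguous sample window from the first to the last sample whose depth
#' is at least `fraction` of the dive's maximum depth.
#'
#' @param depth numeric vector of within-dive depths (m), >= 3 samples.
#' @param fraction of maximum depth defining the bottom phase (default 0.8).
#' @return integer vector of sample indices into `depth`.
#' @export
bottom_phase <- function(depth, fraction = 0.8) {
  stopifnot(length(depth) >= 3L, fraction > 0, fraction <= 1)
  bottom_window(depth, fraction)
}

#' Wiggliness of a dive
#'
#' Summed absolute vertical displacement over the bottom phase,
#' `sum(|depth[t+1] - depth[t]|)` — an index of prey-chasing intensity.
#'
#' @inheritParams bottom_phase
#' @return metres (0 for a flat bottom).
#' @export
wiggliness <- function(depth, fraction = 0.8) {
  w <- bottom_phase(depth, fraction)
  if (length(w) < 2L) return(0)
  sum(abs(diff(depth[w])))
}

#' Detect dives and compute per-dive parameters
#'
#' A dive is a maximal run of samples with depth >= `dive_threshold` lasting
#' at least `min_duration` seconds. Sampling gaps longer than `max_gap`
#' seconds split the record, and a putative dive interrupted by such a gap is
#' flagged and excluded. For each dive the four vertical movement parameters
#' are returned: total duration (s), maximum depth (m), bottom-phase
#' wiggliness (m) and post-dive surface duration (s; NA for the last dive of
#' a contiguous segment).
#'
#' @param series a [depth_series()].
#' @param dive_threshold metres (default 2).
#' @param min_duration seconds (default 5).
#' @param bottom_fraction bottom-phase fraction of max depth (default 0.8).
#' @param max_gap seconds; larger sampling gaps split the record (default 5).
#' @param release_time POSIXct origin for `time_since_release_h` (default:
#'   first sample).
#' @return data.frame of class `dive_records`, one row per dive: `start`,
#'   `end`, `duration_s`, `max_depth_m`, `wiggliness_m`, `post_dive_s`,
#'   `time_since_release_h`, `hour_mid`. Attribute `n_excluded` counts dives
#'   dropped because of internal gaps.
#' @export
detect_dives <- function(series, dive_threshold = 2, min_duration = 5,
                         bottom_fraction = 0.8, max_gap = 5,
                         release_time = NULL) {
  stopifnot(inherits(series, "depth_series"), nrow(series) >= 2L,
            dive_threshold > 0, min_duration >= 0)
  if (is.null(release_time)) release_time <- series$timestamp[1]
  tt <- as.numeric(series$timestamp)
  seg_id <- cumsum(c(0, diff(tt) > max_gap))
  rows <- list()
  n_excluded <- 0L
  for (s in unique(seg_id)) {
    sel <- seg_id == s
    d <- series$depth_m[sel]
    t <- tt[sel]
    if (length(d) < 2L) next
    r <- rle(d >= dive_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    div <- which(r$values)
    seg_rows <- list()
    dt_nominal <- stats::median(diff(t))
    for (j in div) {
      i0 <- starts[j]; i1 <- ends[j]
      dur <- t[i1] - t[i0]
      if (dur < min_duration) next
      # missing samples inside a putative dive invalidate it
      if (i1 > i0 && any(diff(t[i0:i1]) > 1.5 * dt_nominal)) {
        n_excluded <- n_excluded + 1L
        next
      }
      dd <- d[i0:i1]
      wig <- if (length(dd) >= 3L) wiggliness(dd, bottom_fraction) else 0
      t_mid <- (t[i0] + t[i1]) / 2
      lt <- as.POSIXlt(as.POSIXct(t_mid, origin = "1970-01-01", tz = "UTC"))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        start = as.POSIXct(t[i0], origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(t[i1], origin = "1970-01-01", tz = "UTC"),
        duration_s = dur,
        max_depth_m = max(dd),
        wiggliness_m = wig,
        post_dive_s = NA_real_,
        time_since_release_h =
          (t_mid - as.numeric(release_time)) / 3600,
        hour_mid = lt$hour + lt$min / 60 + lt$sec / 3600)
    }
    if (length(seg_rows)) {
      seg_df <- do.call(rbind, seg_rows)
      if (nrow(seg_df) > 1L) {
        k <- seq_len(nrow(seg_df) - 1L)
        seg_df$post_dive_s[k] <-
          as.numeric(seg_df$start[k + 1L]) - as.numeric(seg_df$end[k])
      }
      rows[[length(rows) + 1L]] <- seg_df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = as.POSIXct(character(), tz = "UTC"),
               end = as.POSIXct(character(), tz = "UTC"),
               duration_s = numeric(), max_depth_m = numeric(),
               wiggliness_m = numeric(), post_dive_s = numeric(),
               time_since_release_h = numeric(), hour_mid = numeric())
  rownames(out) <- NULL
  class(out) <- c("dive_records", "data.frame")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Linear depth-sensor drift correction
#'
#' Optional utility, OFF by default in the pipeline: fits a linear trend to
#' presumed-surface samples (depth below `surface_threshold`) and subtracts
#' it, clamping at 0. Short deployments typically show negligible drift, in
#' which case no correction should be applied.
#'
#' @param series a [depth_series()].
#' @param surface_threshold metres identifying surface samples (default 1).
#' @return a corrected [depth_series()].
#' @export
correct_depth_drift <- function(series, surface_threshold = 1) {
  stopifnot(inherits(series, "depth_series"))
  surf <- series$depth_m < surface_threshold
  if (sum(surf) < 10L) return(series)
  tt <- as.numeric(series$timestamp) - as.numeric(series$timestamp[1])
  fit <- stats::lm.fit(cbind(1, tt[surf]), series$depth_m[surf])
  offset <- fit$coefficients[1] + fit$coefficients[2] * tt
  depth_series(series$timestamp, pmax(series$depth_m - offset, 0))
}

#' Read / write a depth series CSV
#'
#' CSV columns `timestamp,depth_m`, ISO-8601 UTC timestamps.
#'
#' @param path file path.
#' @return [read_depth_csv()] returns a [depth_series()].
#' @export
read_depth_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "depth_m") %in% names(d)))
  depth_series(as.POSIXct(d$timestamp, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS")),
               d$depth_m)
}

#' @rdname read_depth_csv
#' @param series a [depth_series()].
#' @export
write_depth_csv <- function(series, path) {
  stopifnot(inherits(series, "depth_series"))
  d <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    depth_m = series$depth_m)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
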