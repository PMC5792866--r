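#' @importFrom geosphere distHaversine bearing destPoint
NULL

# mean Earth radius, metres; all great-circle work uses the same sphere
EARTH_RADIUS_M <- 6371000

# great-circle distance in metres between (lat1,lon1) and (lat2,lon2), degrees
gc_dist_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# initial bearing in degrees [0, 360)
gc_bearing <- function(lat1, lon1, lat2, lon2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

# destination point given start, bearing (deg) and distance (m)
gc_dest <- function(lat, lon, brg, dist_m) {
  p <- geosphere::destPoint(cbind(lon, lat), brg, dist_m, r = EARTH_RADIUS_M)
  c(lat = p[1, 2], lon = p[1, 1])
}

#' GPS track container
#'
#' An ordered set of surfacing GPS fixes for one individual. Timestamps must
#' be strictly increasing; coordinates are WGS84 degrees.
#'
#' @param timestamp POSIXct vector (UTC recommended).
#' @param lat,lon numeric degrees, |lat| <= 90, |lon| <= 180.
#' @return a data.frame of class `geotrack`.
#' @export
geotrack <- function(timestamp, lat, lon) {
  stopifnot(inherits(timestamp, "POSIXct"),
            length(timestamp) == length(lat),
            length(lat) == length(lon))
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  if (length(timestamp) > 1 && any(diff(as.numeric(timestamp)) <= 0))
    stop("timestamps must be strictly increasing")
  structure(data.frame(timestamp = timestamp, lat = lat, lon = lon),
            class = c("geotrack", "data.frame"))
}

#' Screen a track for positional outliers
#'
#' Removes impossible fixes: a fix is an outlier when the animal would have
#' moved towards it at an unlikely speed (> `speed_threshold` km/h) and the
#' track returns to (near) the point it came from in the subsequent move.
#' "Returns to the same site" is operationalised as the distance between the
#' fixes flanking the suspect one being smaller than
#' `max(return_floor, return_fraction * excursion distance)`. Screening is
#' applied iteratively (removing one fix and re-screening) until no fix
#' qualifies, since a single spike can mask a second.
#'
#' @param track a [geotrack()].
#' @param speed_threshold km/h (default 15).
#' @param return_fraction fraction of the excursion distance (default 0.1).
#' @param return_floor metres (default 100).
#' @return the screened `geotrack`, with attributes `removed` (count) and
#'   `removed_fixes` (data.frame of dropped records).
#' @export
screen_outliers <- function(track, speed_threshold = 15,
                            return_fraction = 0.1, return_floor = 100) {
  stopifnot(inherits(track, "geotrack"))
  if (nrow(track) < 3L) {
    warning("fewer than 3 fixes: outlier screening skipped")
    attr(track, "removed") <- 0L
    attr(track, "removed_fixes") <- track[0, ]
    return(track)
  }
  removed <- track[0, ]
  thr_ms <- speed_threshold * 1000 / 3600
  repeat {
    n <- nrow(track)
    if (n < 3L) break
    drop <- NA_integer_
    for (i in 2:(n - 1)) {
      d_in <- gc_dist_m(track$lat[i - 1], track$lon[i - 1],
                        track$lat[i], track$lon[i])
      dt <- as.numeric(difftime(track$timestamp[i], track$timestamp[i - 1],
                                units = "secs"))
      if (dt <= 0) next
      if (d_in / dt <= thr_ms) next
      d_ret <- gc_dist_m(track$lat[i - 1], track$lon[i - 1],
                         track$lat[i + 1], track$lon[i + 1])
      if (d_ret < max(return_floor, return_fraction * d_in)) {
        drop <- i
        break
      }
    }
    if (is.na(drop)) break
    removed <- rbind(removed, track[drop, ])
    track <- track[-drop, ]
  }
  rownames(track) <- NULL
  out <- structure(track, class = c("geotrack", "data.frame"))
  attr(out, "removed") <- nrow(removed)
  attr(out, "removed_fixes") <- removed
  out
}

#' Horizontal movement parameters per step
#'
#' For each step between consecutive fixes: great-circle step length (m),
#' speed (m/s), initial bearing (deg, [0,360)) and the absolute turning angle
#' (deg, [0,180]) between consecutive steps — 0 is directed linear movement,
#' 180 a full reversal. The turning angle is defined from the second step
#' onward. Steps with zero elapsed time are rejected with a warning.
#'
#' @param track a screened [geotrack()] with >= 2 fixes (>= 3 for angles).
#' @param release_time POSIXct; origin of `time_since_release` (default:
#'   first fix).
#' @return a data.frame of class `step_series` with one row per step:
#'   `t_start`, `t_end`, `elapsed_s`, `step_length_m`, `speed_ms`,
#'   `heading_deg`, `turning_angle_deg` (NA for the first step),
#'   `time_since_release_h`, `hour_mid` (fractional clock hour at the step
#'   midpoint, from the timestamps' timezone).
#' @export
compute_steps <- function(track, release_time = NULL) {
  stopifnot(inherits(track, "geotrack"), nrow(track) >= 2L)
  if (is.null(release_time)) release_time <- track$timestamp[1]
  n <- nrow(track)
  i <- seq_len(n - 1)
  elapsed <- as.numeric(difftime(track$timestamp[i + 1], track$timestamp[i],
                                 units = "secs"))
  keep <- elapsed > 0
  if (!all(keep))
    warning(sum(!keep), " step(s) with zero elapsed time rejected")
  len <- gc_dist_m(track$lat[i], track$lon[i],
                   track$lat[i + 1], track$lon[i + 1])
  hdg <- gc_bearing(track$lat[i], track$lon[i],
                    track$lat[i + 1], track$lon[i + 1])
  # a zero-length step has no defined bearing; carry the previous heading
  zero <- len < 1e-9
  if (any(zero) && !all(zero)) {
    for (j in which(zero)) if (j > 1) hdg[j] <- hdg[j - 1]
  }
  turn <- c(NA_real_, abs((diff(hdg) + 180) %% 360 - 180))
  t_mid <- track$timestamp[i] + elapsed / 2
  lt <- as.POSIXlt(t_mid)
  hour_mid <- lt$hour + lt$min / 60 + lt$sec / 3600
  out <- data.frame(
    t_start = track$timestamp[i], t_end = track$timestamp[i + 1],
    elapsed_s = elapsed, step_length_m = len, speed_ms = len / elapsed,
    heading_deg = hdg, turning_angle_deg = turn,
    time_since_release_h = as.numeric(difftime(t_mid, release_time,
                                               units = "hours")),
    hour_mid = hour_mid)
  out <- out[keep, ]
  rownames(out) <- NULL
  class(out) <- c("step_series", "data.frame")
  out
}

#' Displacement and net heading relative to a reference point
#'
#' Per-fix great-circle distance (km) to a reference (release or exposure
#' site) plus the compass heading of net movement over a trailing window:
#' for each fix, the initial bearing from the most recent fix at least
#' `window_h` hours earlier (NA while no such fix exists). Displacement is a
#' diagnostic, not a modelled parameter.
#'
#' @param track a [geotrack()].
#' @param reference numeric `c(lat, lon)` degrees.
#' @param window_h trailing window in hours (default 10).
#' @return data.frame `timestamp`, `distance_km`, `net_heading_deg`.
#' @export
displacement <- function(track, reference, window_h = 10) {
  stopifnot(inherits(track, "geotrack"), length(reference) == 2L)
  d_km <- gc_dist_m(track$lat, track$lon, reference[1], reference[2]) / 1000
  n <- nrow(track)
  hdg <- rep(NA_real_, n)
  tt <- as.numeric(track$timestamp)
  for (i in seq_len(n)) {
    past <- which(tt <= tt[i] - window_h * 3600)
    if (length(past)) {
      j <- max(past)
      if (gc_dist_m(track$lat[j], track$lon[j],
                    track$lat[i], track$lon[i]) > 1e-9)
        hdg[i] <- gc_bearing(track$lat[j], track$lon[j],
                             track$lat[i], track$lon[i])
    }
  }
  data.frame(timestamp = track$timestamp, distance_km = d_km,
             net_heading_deg = hdg)
}

#' Read / write a GPS track CSV
#'
#' CSV columns `timestamp,lat,lon` with ISO-8601 UTC timestamps.
#'
#' @param path file path.
#' @return [read_geotrack_csv()] returns a [geotrack()].
#' @export
read_geotrack_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "lat", "lon") %in% names(d)))
  geotrack(as.POSIXct(d$timestamp, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
           d$lat, d$lon)
}

#' @rdname read_geotrack_csv
#' @param track a [geotrack()].
#' @export
write_geotrack_csv <- function(track, path) {
  stopifnot(inherits(track, "geotrack"))
  d <- data.frame(
    timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = track$lat, lon = track$lon)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
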