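# shared fixtures and independent oracles, all built in code

ts_utc <- function(offset_s, origin = "2014-06-02 12:00:00") {
  as.POSIXct(origin, tz = "UTC") + offset_s
}

# track built by walking fixed bearings/distances on the sphere so expected
# geometry is known exactly
walk_track <- function(bearings_deg, dists_m, dt_s = 60,
                       start = c(lat = 56, lon = 11)) {
  lat <- start[["lat"]]; lon <- start[["lon"]]
  for (i in seq_along(bearings_deg)) {
    p <- geosphere::destPoint(cbind(lon[i], lat[i]), bearings_deg[i],
                              dists_m[i], r = 6371000)
    lat <- c(lat, p[1, 2]); lon <- c(lon, p[1, 1])
  }
  geotrack(ts_utc(seq(0, by = dt_s, length.out = length(lat))), lat, lon)
}

# continuous piecewise-linear disturbance-response curve: full capture
# effect decaying to 0 at bp1, flat to bp2 (exposure), ramp to the noise
# effect at bp3... i.e. the idealized 4-breakpoint response shape
response_curve <- function(t, capture = 5, bp = c(12, 96, 100, 130),
                           noise = 2) {
  ifelse(t < bp[1], capture * (1 - t / bp[1]),
  ifelse(t < bp[2], 0,
  ifelse(t < bp[3], noise * (t - bp[2]) / (bp[3] - bp[2]),
  ifelse(t < bp[4], noise * (1 - (t - bp[3]) / (bp[4] - bp[3])), 0))))
}

# independent oracle: exhaustive grid search for the best continuous
# broken-line fit with breakpoints restricted to observed x values
grid_piecewise_rss <- function(x, y, k, min_seg = 3) {
  cand <- unique(x)
  cand <- cand[cand > min(x) & cand < max(x)]
  rss_at <- function(psi) {
    cuts <- c(-Inf, psi, Inf)
    cnt <- tabulate(findInterval(x, cuts, left.open = TRUE),
                    nbins = length(psi) + 1)
    if (any(cnt < min_seg)) return(Inf)
    X <- cbind(1, x, outer(x, psi, function(xx, p) pmax(xx - p, 0)))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  best <- Inf
  if (k == 0) return(sum(stats::lm.fit(cbind(1, x), y)$residuals^2))
  if (k == 1) {
    for (c1 in cand) best <- min(best, rss_at(c1))
  } else if (k == 2) {
    nc <- length(cand)
    for (i in seq_len(nc - 1)) for (j in (i + 1):nc)
      best <- min(best, rss_at(c(cand[i], cand[j])))
  } else stop("grid oracle implemented for k <= 2")
  best
}

# direct haversine, written independently of the package's geodesy helpers
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# 1 Hz triangular dive: surface, linear descent to depth_max, linear ascent,
# surface; rates of 1 m/s so each metre is one sample
triangle_dive_depths <- function(depth_max = 10, surface_s = 10) {
  c(rep(0, surface_s), seq(1, depth_max, by = 1),
    seq(depth_max - 1, 1, by = -1), rep(0, surface_s))
}
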