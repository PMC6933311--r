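#' Construct a sampled depth series
#'
#' @param time sample times (POSIXct or decimal days), regularly spaced
#' @param depth depths (m, positive down, 1 m sensor resolution typical)
#' @param seal_id identifier
#' @return `data.frame` of class `depth_series` with attribute `dt`
#'   (sampling interval, seconds)
#' @export
depth_series <- function(time, depth, seal_id = NA_character_) {
  t_days <- .as_days(time)
  if (length(t_days) < 2) stop("depth series needs >= 2 samples", call. = FALSE)
  dts <- diff(t_days) * .sec_per_day
  dt <- stats::median(dts)
  if (dt <= 0 || any(abs(dts - dt) > 1e-6 * .sec_per_day))
    stop("depth series must be regularly sampled with dt > 0", call. = FALSE)
  structure(data.frame(time = t_days, depth = depth, seal_id = seal_id),
            dt = dt, class = c("depth_series", "data.frame"))
}

#' Zero-offset correction of a depth series
#'
#' Pressure sensors drift, so raw "surface" readings wander away from 0 m.
#' The correction estimates a slowly varying surface baseline as the 10th
#' percentile of depth in a centred rolling window (default 2 h), smooths
#' it with a running median so it cannot chase individual dives, and
#' subtracts it. Because the baseline is constrained to vary slowly, it is
#' evaluated at anchor samples spaced an eighth of a window apart and
#' linearly interpolated in between. Corrected depths are floored at -1 m
#' (one sensor resolution step below the surface).
#'
#' Animals that surface regularly keep the window's lower tail at the true
#' surface, so the baseline tracks drift but not diving.
#'
#' @param series a [depth_series()]
#' @param window rolling window length (seconds, default 7200); must cover
#'   at least 10 samples
#' @param probs percentile used as the surface estimate (default 0.1)
#' @return corrected `depth_series`
#' @export
zero_offset_correct <- function(series, window = 7200, probs = 0.1) {
  dt <- attr(series, "dt")
  w <- floor(window / dt)
  if (w < 10)
    stop("window must cover at least 10 samples", call. = FALSE)
  d <- series$depth
  n <- length(d)
  if (length(unique(d)) == 1L) {
    warning("all-constant depth series: returning zeroed series")
    series$depth <- rep(0, n)
    return(series)
  }
  stride <- max(1L, floor(w / 8))
  anchors <- unique(c(seq(1L, n, by = stride), n))
  half <- floor(w / 2)
  base_a <- vapply(anchors, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(d[lo:hi], probs = probs, names = FALSE)
  }, numeric(1))
  if (length(base_a) >= 3) {
    k <- min(length(base_a), 9L)
    if (k %% 2 == 0) k <- k - 1L
    base_a <- stats::runmed(base_a, k, endrule = "median")
  }
  base <- if (length(anchors) > 1)
    stats::approx(anchors, base_a, xout = seq_len(n), rule = 2)$y
  else rep(base_a, n)
  series$depth <- pmax(d - base, -1)
  series
}

#' Detect dives in a corrected depth series
#'
#' A dive is a maximal run of consecutive samples strictly deeper than
#' `threshold`; samples at exactly the threshold are surface. The dive
#' starts at the first supra-threshold sample, its duration is the number
#' of supra-threshold samples times the sampling interval, and its maximum
#' depth is the deepest sample in the run.
#'
#' @param series a zero-offset-corrected [depth_series()]
#' @param threshold dive depth threshold (m, default 3; strictly `>`)
#' @return `data.frame` with columns `start`, `end` (decimal days),
#'   `max_depth` (m), `duration` (s); zero rows when nothing exceeds the
#'   threshold
#' @export
detect_dives <- function(series, threshold = 3) {
  under <- series$depth > threshold
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  dt <- attr(series, "dt")
  if (!length(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      max_depth = numeric(0), duration = numeric(0)))
  }
  out <- do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(start = series$time[starts[i]],
               end = series$time[starts[i]] + length(idx) * dt / .sec_per_day,
               max_depth = max(series$depth[idx]),
               duration = length(idx) * dt)
  }))
  rownames(out) <- NULL
  out
}

#' Trip-level dive summary
#'
#' @param dives dive table from [detect_dives()]
#' @param trip an [attendance_record()], or a single trip duration in days
#' @param night_windows optional two-column matrix/data.frame of night
#'   interval start/end times (decimal days); when supplied,
#'   `pct_dives_night` is the percentage of dives whose midpoint falls in
#'   any window
#' @return one-row `data.frame` with `n_dives`, `mean_max_depth` (m, `NA`
#'   when no dives), `pct_time_diving` (%), `pct_dives_night` (% or `NA`)
#' @export
trip_summary <- function(dives, trip, night_windows = NULL) {
  trip_days <- if (inherits(trip, "attendance_record"))
    trip$trip_duration else as.numeric(trip)
  if (trip_days <= 0) stop("trip duration must be positive", call. = FALSE)
  n <- nrow(dives)
  pct_night <- NA_real_
  if (!is.null(night_windows) && n > 0) {
    nw <- as.matrix(night_windows)
    mid <- (dives$start + dives$end) / 2
    in_night <- vapply(mid, function(m)
      any(m >= nw[, 1] & m <= nw[, 2]), logical(1))
    pct_night <- 100 * mean(in_night)
  }
  data.frame(n_dives = n,
             mean_max_depth = if (n) mean(dives$max_depth) else NA_real_,
             pct_time_diving = 100 * sum(dives$duration) /
               (trip_days * .sec_per_day),
             pct_dives_night = pct_night)
}
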