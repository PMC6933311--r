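#' Great-circle distance between successive positions
#'
#' Haversine on a spherical Earth of radius 6371 km; sub-km accuracy is
#' ample for transit-rate filtering at a few m s-1.
#' @param lon,lat coordinate vectors (degrees)
#' @return distances between successive points (m), length `n - 1`
#' @keywords internal
.step_dist_m <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1]),
                           r = 6371000)
}

#' Remove poor-quality ARGOS locations
#'
#' Drops location classes `B` and `Z`, preserving order. The output is
#' always a subsequence of the input.
#'
#' @param locs `data.frame` with columns `time` (POSIXct or decimal days),
#'   `lat`, `lon`, `quality` (one of `3,2,1,0,A,B,Z`)
#' @return filtered `data.frame`
#' @export
quality_filter <- function(locs) {
  locs[!as.character(locs$quality) %in% c("B", "Z"), , drop = FALSE]
}

#' Transit-rate filter for ARGOS locations
#'
#' Iteratively removes locations that imply a great-circle speed above
#' `vmax` to a neighbouring retained location, in the spirit of the
#' recursive ARGOS speed filters used in movement ecology. At each pass the
#' fastest offending adjacent pair is found and the member whose *other*
#' neighbour it is also travelling faster towards is removed (later index
#' on ties); track endpoints are only removed when interior alternatives
#' are exhausted. With only two locations nothing can be removed, so the
#' speed between retained endpoints may still exceed `vmax` in that
#' degenerate case.
#'
#' @param locs time-ordered location `data.frame` (`time`, `lat`, `lon`)
#' @param vmax maximum plausible transit rate (m s-1, default 3)
#' @return filtered `data.frame` (a subsequence of the input)
#' @export
speed_filter <- function(locs, vmax = 3) {
  if (nrow(locs) < 2) return(locs)
  keep <- seq_len(nrow(locs))
  t_sec <- .as_days(locs$time) * .sec_per_day
  repeat {
    if (length(keep) < 3) break
    lon <- locs$lon[keep]; lat <- locs$lat[keep]
    sp <- .step_dist_m(lon, lat) / pmax(diff(t_sec[keep]), 1e-9)
    bad <- which(sp > vmax)
    if (!length(bad)) break
    i <- bad[which.max(sp[bad])]           # offending pair (i, i+1) in keep
    side_speed <- function(j, dir) {
      k <- j + dir
      if (k < 1 || k > length(keep)) return(-Inf)
      d <- geosphere::distHaversine(c(lon[j], lat[j]), c(lon[k], lat[k]),
                                    r = 6371000)
      d / max(abs(t_sec[keep[k]] - t_sec[keep[j]]), 1e-9)
    }
    cand <- c(i, i + 1)
    interior <- cand[cand != 1 & cand != length(keep)]
    drop_at <- if (length(interior) == 1) {
      interior
    } else {
      other <- c(side_speed(i, -1L), side_speed(i + 1, 1L))
      interior[which.max(other + c(0, 1e-12))]  # tie -> later index
    }
    keep <- keep[-drop_at]
  }
  locs[keep, , drop = FALSE]
}

# Spherical linear interpolation between two lon/lat points, f in [0, 1].
.slerp <- function(lon1, lat1, lon2, lat2, f) {
  to_xyz <- function(lon, lat) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(lon1, lat1); b <- to_xyz(lon2, lat2)
  omega <- acos(max(-1, min(1, sum(a * b))))
  p <- if (omega < 1e-12) a else
    (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
  p <- p / sqrt(sum(p^2))
  c(lon = atan2(p[2], p[1]) * 180 / pi, lat = asin(p[3]) * 180 / pi)
}

#' Interpolate a filtered track to hourly positions
#'
#' Produces a position at every whole hour of the trip. `"linear"`
#' interpolates along the great circle between the bracketing fixes.
#' `"ctcrw_lite"` runs a fixed-parameter correlated-velocity Kalman
#' smoother on a local planar projection — a lightweight stand-in for full
#' continuous-time correlated random walk models, useful when fixes are
#' noisy but dense. Hours outside the span of the fixes are flagged
#' `extrapolated` and carried at the nearest fix.
#'
#' @param locs filtered, time-ordered location `data.frame`
#' @param t_depart,t_arrive trip bounds (POSIXct or decimal days)
#' @param method `"linear"` or `"ctcrw_lite"`
#' @param beta,sigma_v `ctcrw_lite` velocity autocorrelation (h-1) and
#'   process noise (m s-1) parameters
#' @return `data.frame` with `time` (decimal days), `lon`, `lat`,
#'   `extrapolated`
#' @export
interpolate_hourly <- function(locs, t_depart, t_arrive,
                               method = c("linear", "ctcrw_lite"),
                               beta = 1, sigma_v = 1) {
  method <- match.arg(method)
  if (nrow(locs) < 2) stop("need >= 2 locations", call. = FALSE)
  t0 <- .as_days(t_depart); t1 <- .as_days(t_arrive)
  tl <- .as_days(locs$time)
  hours <- seq(ceiling(t0 * 24) / 24, t1, by = 1 / 24)
  extrap <- hours < min(tl) | hours > max(tl)
  if (any(extrap))
    warning("trip not fully covered by fixes: ", sum(extrap),
            " hourly positions extrapolated from the nearest fix")
  if (method == "linear") {
    pos <- t(vapply(hours, function(h) {
      if (h <= tl[1]) return(c(locs$lon[1], locs$lat[1]))
      n <- length(tl)
      if (h >= tl[n]) return(c(locs$lon[n], locs$lat[n]))
      i <- findInterval(h, tl, rightmost.closed = TRUE)
      f <- (h - tl[i]) / (tl[i + 1] - tl[i])
      unname(.slerp(locs$lon[i], locs$lat[i], locs$lon[i + 1],
                    locs$lat[i + 1], f))
    }, numeric(2)))
    out <- data.frame(time = hours, lon = pos[, 1], lat = pos[, 2],
                      extrapolated = extrap)
  } else {
    out <- .ctcrw_lite(locs, hours, beta = beta, sigma_v = sigma_v)
    out$extrapolated <- extrap
  }
  out
}

# Correlated-velocity Kalman smoother on a local equirectangular plane.
# State (x, vx, y, vy) in metres / m s-1; discrete OU velocity.
.ctcrw_lite <- function(locs, hours, beta = 1, sigma_v = 1,
                        obs_sd = 1000) {
  tl <- .as_days(locs$time)
  lat0 <- mean(locs$lat); lon0 <- mean(locs$lon)
  m_per_deg <- 6371000 * pi / 180
  xy <- cbind((locs$lon - lon0) * m_per_deg * cos(lat0 * pi / 180),
              (locs$lat - lat0) * m_per_deg)
  times <- sort(unique(c(tl, hours)))
  obs_at <- match(round(tl, 9), round(times, 9))
  # per-axis filter/smoother
  smooth_axis <- function(z) {
    nt <- length(times)
    xf <- matrix(0, nt, 2); Pf <- array(0, c(nt, 2, 2))
    xp <- matrix(0, nt, 2); Pp <- array(0, c(nt, 2, 2))
    x <- c(z[1], 0); P <- diag(c(obs_sd^2, 25))
    for (k in seq_len(nt)) {
      if (k > 1) {
        dt_h <- (times[k] - times[k - 1]) * 24
        a <- exp(-beta * dt_h)
        dpos <- (1 - a) / beta * 3600          # m per (m s-1) over dt
        Fm <- matrix(c(1, 0, dpos, a), 2)
        qv <- sigma_v^2 * (1 - a^2)
        Q <- diag(c(qv * dpos^2 / 3 + 1, qv))  # simple CV process noise
        x <- Fm %*% x; P <- Fm %*% P %*% t(Fm) + Q
      }
      xp[k, ] <- x; Pp[k, , ] <- P
      j <- which(obs_at == k)
      if (length(j)) {
        H <- matrix(c(1, 0), 1)
        S <- as.numeric(H %*% P %*% t(H)) + obs_sd^2
        K <- P %*% t(H) / S
        x <- x + K %*% (z[j[1]] - x[1])
        P <- P - K %*% H %*% P
      }
      xf[k, ] <- x; Pf[k, , ] <- P
    }
    xs <- xf
    for (k in (nt - 1):1) {
      dt_h <- (times[k + 1] - times[k]) * 24
      a <- exp(-beta * dt_h)
      dpos <- (1 - a) / beta * 3600
      Fm <- matrix(c(1, 0, dpos, a), 2)
      G <- Pf[k, , ] %*% t(Fm) %*% solve(Pp[k + 1, , ] + diag(1e-9, 2))
      xs[k, ] <- xf[k, ] + G %*% (xs[k + 1, ] - xp[k + 1, ])
    }
    xs[, 1]
  }
  sx <- smooth_axis(xy[, 1]); sy <- smooth_axis(xy[, 2])
  at <- match(round(hours, 9), round(times, 9))
  data.frame(time = hours,
             lon = lon0 + sx[at] / (m_per_deg * cos(lat0 * pi / 180)),
             lat = lat0 + sy[at] / m_per_deg)
}

#' Classify positions against habitat grids
#'
#' Nearest-node lookup of user-supplied regular grids. A position is
#' `shelf` when local water depth is shallower than `isobath`, `pelagic`
#' otherwise, and `unknown` outside the grid. When dive depths and a mixed
#' layer depth (MLD) field are supplied, each position/dive is also labelled
#' `below_mld` when the dive exceeds the local MLD.
#'
#' @param positions `data.frame` with `lon`, `lat`
#' @param bathy_grid `data.frame` with `lon`, `lat`, `value` (water depth,
#'   m positive) on a regular grid
#' @param mld_surface optional grid of mixed layer depths (m), same format
#' @param dive_depths optional per-position dive maximum depths (m)
#' @param isobath shelf/pelagic boundary depth (m, default 200)
#' @return `data.frame` with `habitat` (`shelf`/`pelagic`/`unknown`) and,
#'   when applicable, `mld_position` (`above_mld`/`below_mld`/`unknown`)
#' @export
classify_positions <- function(positions, bathy_grid, mld_surface = NULL,
                               dive_depths = NULL, isobath = 200) {
  depth <- .grid_lookup(bathy_grid, positions$lon, positions$lat)
  habitat <- ifelse(is.na(depth), "unknown",
                    ifelse(depth < isobath, "shelf", "pelagic"))
  out <- data.frame(habitat = habitat)
  if (!is.null(mld_surface) && !is.null(dive_depths)) {
    mld <- .grid_lookup(mld_surface, positions$lon, positions$lat)
    out$mld_position <- ifelse(is.na(mld), "unknown",
                               ifelse(dive_depths > mld, "below_mld",
                                      "above_mld"))
  }
  out
}

# Nearest-node lookup on a regular lon/lat grid; NA outside the grid hull.
.grid_lookup <- function(grid, lon, lat) {
  lons <- sort(unique(grid$lon)); lats <- sort(unique(grid$lat))
  key <- paste(grid$lon, grid$lat)
  val <- stats::setNames(grid$value, key)
  half_dx <- if (length(lons) > 1) max(diff(lons)) / 2 else Inf
  half_dy <- if (length(lats) > 1) max(diff(lats)) / 2 else Inf
  vapply(seq_along(lon), function(i) {
    if (lon[i] < min(lons) - half_dx || lon[i] > max(lons) + half_dx ||
        lat[i] < min(lats) - half_dy || lat[i] > max(lats) + half_dy)
      return(NA_real_)
    nlon <- lons[which.min(abs(lons - lon[i]))]
    nlat <- lats[which.min(abs(lats - lat[i]))]
    v <- val[paste(nlon, nlat)]
    if (is.na(v)) NA_real_ else unname(v)
  }, numeric(1))
}
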