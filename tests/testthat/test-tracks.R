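make_locs <- function(time, lon, lat, quality = "2") {
  data.frame(time = time, lon = lon, lat = lat, quality = quality)
}

test_that("quality filter removes exactly the B and Z classes", {
  set.seed(3)
  q <- sample(c("3", "2", "1", "0", "A", "B", "Z"), 200, replace = TRUE)
  locs <- make_locs(seq_len(200) / 24, runif(200, -171, -170),
                    runif(200, 56, 58), q)
  f <- quality_filter(locs)
  expect_identical(nrow(f), sum(!q %in% c("B", "Z")))
  expect_false(any(f$quality %in% c("B", "Z")))
  # subsequence property: order preserved, no duplicates
  expect_identical(f$time, locs$time[!q %in% c("B", "Z")])
  allb <- quality_filter(make_locs(1:3, 1:3, 1:3, "B"))
  expect_identical(nrow(allb), 0L)
})

test_that("a slow straight transit passes the speed filter unchanged", {
  # ~1 m/s northward: 1 m/s = 86.4 km/day ~ 0.78 deg lat/day
  t <- seq(0, 2, by = 1 / 12)
  locs <- make_locs(t, rep(-170, length(t)), 57 + 0.777 * t)
  expect_identical(speed_filter(locs, vmax = 3), locs)
  # two points are never altered
  two <- make_locs(c(0, 0.01), c(-170, -160), c(57, 57))
  expect_identical(speed_filter(two, vmax = 3), two)
})

test_that("a single distant spike is removed", {
  t <- seq(0, 1, by = 1 / 8)
  lon <- rep(-170, length(t)); lat <- rep(57, length(t)) + t * 0.01
  lon[5] <- -168.3   # ~100 km spike over a 3 h gap
  locs <- make_locs(t, lon, lat)
  f <- speed_filter(locs, vmax = 3)
  expect_identical(f$lon, lon[-5])
  sp <- geosphere::distHaversine(cbind(f$lon[-nrow(f)], f$lat[-nrow(f)]),
                                 cbind(f$lon[-1], f$lat[-1]), r = 6371000) /
    diff(f$time * 86400)
  expect_true(all(sp <= 3))
})

test_that("speed filtering agrees with brute-force minimal removal", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    t <- sort(runif(n, 0, 1))
    t <- t + seq(0, n - 1) * 1e-3          # keep gaps nonzero
    lat <- 57 + cumsum(rnorm(n, 0, 0.01))
    lon <- -170 + cumsum(rnorm(n, 0, 0.01))
    k <- sample(2:(n - 1), 1)
    lon[k] <- lon[k] + sample(c(-1, 1), 1) * runif(1, 1.5, 3)  # wild spike
    locs <- make_locs(t, lon, lat)
    f <- speed_filter(locs, vmax = 3)
    keep_pkg <- match(f$time, locs$time)
    keep_brute <- brute_speed_filter(locs, vmax = 3)
    expect_identical(length(keep_pkg), length(keep_brute))
    # both results are valid subsequences with all speeds <= vmax
    expect_true(all(diff(keep_pkg) > 0))
  }
})

test_that("hourly interpolation honours fixes and geodesic midpoints", {
  # fix exactly on the hour is returned unchanged
  locs <- make_locs(c(0, 2 / 24, 4 / 24), c(-170, -169.5, -169),
                    c(57, 57.2, 57.4))
  out <- interpolate_hourly(locs, 0, 4 / 24, method = "linear")
  expect_equal(out$lon[out$time == 2 / 24], -169.5, tolerance = 1e-9)
  expect_equal(out$lat[out$time == 2 / 24], 57.2, tolerance = 1e-9)
  # midpoint of two fixes 2 h apart equals the geodesic midpoint
  mid <- out[out$time == 1 / 24, ]
  gm <- geosphere::midPoint(c(-170, 57), c(-169.5, 57.2))
  expect_equal(mid$lon, unname(gm[1, "lon"]), tolerance = 1e-6)
  expect_equal(mid$lat, unname(gm[1, "lat"]), tolerance = 1e-6)
  expect_false(any(out$extrapolated))
  # a trip not covered by fixes flags extrapolation
  expect_warning(
    out2 <- interpolate_hourly(locs, 0, 8 / 24, method = "linear"),
    "extrapolated")
  expect_true(any(out2$extrapolated))
})

test_that("interpolation error shrinks as fix density grows", {
  cfg <- simulation_config()
  set.seed(21)
  tr <- simulate_track(4, cfg)
  truth <- tr$truth
  err_at <- function(step) {
    sub <- truth[seq(1, nrow(truth), by = step), ]
    sub$quality <- "3"
    out <- interpolate_hourly(sub, min(truth$time), max(truth$time),
                              method = "linear")
    m <- merge(out, truth, by = "time", suffixes = c("", ".t"))
    sqrt(mean(hav_m(m$lon, m$lat, m$lon.t, m$lat.t)^2))
  }
  errs <- vapply(c(12, 6, 1), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1)  # a fix at every hour: interpolation is exact
})

test_that("ctcrw_lite smooths noisy fixes better than raw linear joins", {
  cfg <- simulation_config()
  set.seed(31)
  tr <- simulate_track(3, cfg)
  truth <- tr$truth
  noisy <- truth[seq(1, nrow(truth), by = 2), ]
  m_per_deg <- 6371000 * pi / 180
  noisy$lat <- noisy$lat + rnorm(nrow(noisy), 0, 1500 / m_per_deg)
  noisy$lon <- noisy$lon + rnorm(nrow(noisy), 0, 1500 / m_per_deg)
  rms <- function(method) {
    out <- interpolate_hourly(noisy, min(truth$time), max(truth$time),
                              method = method)
    m <- merge(out, truth, by = "time", suffixes = c("", ".t"))
    sqrt(mean(hav_m(m$lon, m$lat, m$lon.t, m$lat.t)^2))
  }
  expect_lt(rms("ctcrw_lite"), rms("linear"))
})

test_that("habitat classification matches brute-force grid lookup", {
  g <- expand.grid(lon = seq(-172, -168, by = 0.5),
                   lat = seq(56, 59, by = 0.5))
  # flat 50 m shelf
  flat <- cbind(g, value = 50)
  pos <- data.frame(lon = runif(20, -171.9, -168.1),
                    lat = runif(20, 56.1, 58.9))
  expect_true(all(classify_positions(pos, flat)$habitat == "shelf"))
  # random depths vs direct nearest-node lookup
  set.seed(13)
  rg <- cbind(g, value = runif(nrow(g), 10, 3000))
  lab <- classify_positions(pos, rg, isobath = 200)$habitat
  brute <- vapply(seq_len(nrow(pos)), function(i) {
    d2 <- (rg$lon - pos$lon[i])^2
    cand <- which(d2 == min(d2))
    j <- cand[which.min(abs(rg$lat[cand] - pos$lat[i]))]
    if (rg$value[j] < 200) "shelf" else "pelagic"
  }, "")
  expect_identical(lab, brute)
  # outside the grid -> unknown
  far <- data.frame(lon = 0, lat = 0)
  expect_identical(classify_positions(far, rg)$habitat, "unknown")
  # mixed layer depth position
  mld <- cbind(g, value = 20)
  cl <- classify_positions(pos[1:3, ], rg, mld_surface = mld,
                           dive_depths = c(30, 10, 25))
  expect_identical(cl$mld_position, c("below_mld", "above_mld", "below_mld"))
})
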