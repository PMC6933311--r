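#' Default dietary fatty acids and synthetic diet-cluster centroids
#'
#' 19 dietary FAs commonly retained in pinniped milk signature work, with
#' four synthetic cluster centroids (percent, rows close to 100) emulating
#' squid-dominated (1), age-0 pollock (2), adult pollock (3) and mixed (4)
#' diets: the squid centroid is DHA(22:6n-3)- and 18:1n-9-rich, the adult
#' pollock centroid is rich in the 20:1/22:1 long-chain monounsaturates,
#' and the age-0 pollock centroid sits between with more 16:1n-7 and
#' 20:5n-3. These are synthetic, literature-plausible compositions, not
#' measured ones.
#'
#' @return named list with `fa_names` and `centroids` (4 x 19 matrix)
#' @export
default_fa_centroids <- function() {
  fa <- c("14:0", "16:0", "16:1n-7", "18:0", "18:1n-9", "18:1n-7",
          "18:2n-6", "18:3n-3", "18:4n-3", "20:1n-11", "20:1n-9",
          "20:4n-6", "20:5n-3", "22:1n-11", "22:1n-9", "21:5n-3",
          "22:5n-3", "22:6n-3", "24:1n-9")
  cen <- rbind(
    c(4.5, 16, 6,  3, 24, 5, 1.5, 0.8, 1.0, 2.0, 3.0, 0.8, 6,  2.5, 0.9, 0.6, 2.2, 18, 1.2),
    c(5,   18, 10, 3, 20, 6, 1.5, 0.8, 1.2, 2.5, 3.5, 0.8, 8,  4,   1.0, 0.6, 2.5, 10, 1.3),
    c(5.5, 17, 8,  3, 18, 5, 1.2, 0.7, 1.0, 5.0, 7.0, 0.7, 7,  8,   1.5, 0.5, 2.3, 7,  1.4),
    c(6,   22, 9,  4, 19, 8, 2.5, 1.0, 1.5, 1.5, 2.0, 1.0, 7,  2.0, 0.8, 0.7, 2.8, 8,  1.1))
  cen <- 100 * cen / rowSums(cen)
  colnames(cen) <- fa
  rownames(cen) <- paste0("cluster", 1:4)
  list(fa_names = fa, centroids = cen)
}

#' Configuration of the synthetic study generator
#'
#' Defaults are the study conditions: 33 seals of which a fraction carry
#' both a summer and a fall measurement, an at-sea FMR model with
#' intercept 7.36 W kg-1, a +7.2% fall effect and a -1.9% per-trip-day
#' effect (percent of the intercept), trip durations of 6.4 +/- 1.7 days,
#' body masses within 26-47.6 kg, water influx means by diet cluster of
#' 187.7/158.1/144.3 ml kg-1 day-1, mass gain increasing by 0.6 kg per
#' trip day and 1.8 kg in fall, and 82% of dives at night.
#'
#' @param n_seals number of seals
#' @param p_both probability a seal is measured in both seasons
#' @param p_fall_single probability a single-measurement seal is a fall one
#' @param fmr_intercept at-sea FMR intercept (W kg-1)
#' @param fall_effect_pct,trip_day_effect_pct seasonal and per-day effects
#'   as percent of the intercept
#' @param individual_sd,residual_sd random-intercept and residual SDs of
#'   at-sea FMR (W kg-1)
#' @param trip_mean,trip_sd trip duration distribution (days, truncated
#'   below at 2)
#' @param mass_mean,mass_sd,mass_range body mass distribution (kg)
#' @param tbw_fraction total body water as a fraction of body mass
#' @param onshore_mr onshore metabolic rate (W kg-1)
#' @param fasting_rate fasting mass-loss ashore (kg day-1, by season)
#' @param shore_pre,shore_post ranges (days) of pre-departure and
#'   post-arrival shore time inside the measurement interval
#' @param mass_gain_intercept,mass_gain_trip_effect,mass_gain_fall_effect,mass_gain_sd
#'   at-sea mass gain model (kg, kg day-1)
#' @param cluster_probs diet-cluster probabilities for DLW trips
#'   (clusters 1-3)
#' @param cluster_influx_means,influx_sd water influx by cluster
#'   (ml kg-1 day-1)
#' @param dose_o18_mass,dose_o18_enrichment,dose_h3_activity DLW dose
#'   (g, atom %, mCi)
#' @param assay_cv multiplicative lognormal assay noise CV
#' @param detection_limit_o18 final 18O excess (ppm) below which a
#'   measurement is flagged unusable (label washed out towards
#'   background)
#' @param pct_dive_mean,pct_dive_sd per-trip percent of time diving
#' @param depth_meanlog,depth_sdlog per-trip mean maximum dive depth
#'   (lognormal, m)
#' @param dive_duration_mean mean dive duration (s)
#' @param night_dive_prob probability a dive falls in the night window
#' @param night_window night interval as hours of day `c(start, end)`
#'   spanning midnight
#' @param tdr_dt depth sampling interval (s)
#' @param colony colony position `c(lon, lat)`
#' @param dirichlet_concentration total concentration of the FA Dirichlet
#' @param equation,dilution_space_factor see [co2_production()] and
#'   [total_body_water()]
#' @param seed integer seed fixing all randomness
#' @return list of class `simulation_config`
#' @export
simulation_config <- function(n_seals = 33, p_both = 15 / 33,
                              p_fall_single = 14 / 18,
                              fmr_intercept = 7.36,
                              fall_effect_pct = 7.2,
                              trip_day_effect_pct = -1.9,
                              individual_sd = 0.3, residual_sd = 0.8,
                              trip_mean = 6.4, trip_sd = 1.7,
                              mass_mean = 36.8, mass_sd = 5.5,
                              mass_range = c(26, 47.6),
                              tbw_fraction = 0.60,
                              onshore_mr = 3.5,
                              fasting_rate = c(summer = 0.5, fall = 0.7),
                              shore_pre = c(0.05, 0.25),
                              shore_post = c(0.5, 2),
                              mass_gain_intercept = -0.5,
                              mass_gain_trip_effect = 0.6,
                              mass_gain_fall_effect = 1.8,
                              mass_gain_sd = 2.2,
                              cluster_probs = c(0.40, 0.29, 0.31),
                              cluster_influx_means = c(187.7, 158.1, 144.3),
                              influx_sd = 25,
                              dose_o18_mass = 60, dose_o18_enrichment = 10,
                              dose_h3_activity = 1,
                              assay_cv = 0.01,
                              detection_limit_o18 = 15,
                              pct_dive_mean = 13.2, pct_dive_sd = 3.8,
                              depth_meanlog = log(22), depth_sdlog = 0.55,
                              dive_duration_mean = 90,
                              night_dive_prob = 0.818,
                              night_window = c(20, 6),
                              tdr_dt = 10,
                              colony = c(-170.28, 57.12),
                              dirichlet_concentration = 2000,
                              equation = "two_pool",
                              dilution_space_factor = 1.007,
                              seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$individual_sd >= 0, cfg$residual_sd >= 0,
            cfg$p_both >= 0, cfg$p_both <= 1,
            abs(sum(cfg$cluster_probs) - 1) < 1e-8)
  class(cfg) <- "simulation_config"
  cfg
}

#' Forward-simulate one DLW washout
#'
#' Inverse of the estimation chain: given true CO2 production, true water
#' influx and the water pools, it derives the turnover rates the
#' configured equations imply, forward-computes the equilibration and
#' final isotope concentrations, applies multiplicative lognormal assay
#' noise, and returns an [isotope_record()]. The record is flagged
#' `excluded` when the final 18O excess falls below the detection limit
#' (the label has washed out too far towards background for the
#' turnover fit to be reliable).
#'
#' @param true_rco2 CO2 production (L day-1)
#' @param true_influx water influx (ml kg-1 day-1)
#' @param tbw_initial,tbw_final water pools (kg)
#' @param mass_initial,mass_final body masses (kg)
#' @param dt measurement interval (days)
#' @param noise_cv lognormal assay noise CV (0 = noise free)
#' @param config a [simulation_config()] supplying dose, equation,
#'   dilution-space and detection-limit settings
#' @param seal_id identifier
#' @return list with `record` (an `isotope_record`), `excluded` (logical),
#'   `kd`, `ko` (the true turnover rates)
#' @export
simulate_washout <- function(true_rco2, true_influx, tbw_initial, tbw_final,
                             mass_initial, mass_final, dt, noise_cv = 0,
                             config = simulation_config(),
                             seal_id = "sim") {
  stopifnot(true_rco2 > 0, true_influx > 0, dt > 0)
  mass_ref <- (mass_initial + mass_final) / 2
  mean_pool <- (tbw_initial + tbw_final) / 2
  influx_l <- true_influx * mass_ref / 1000
  kd <- (influx_l - (tbw_final - tbw_initial) / dt) / mean_pool
  if (kd <= 0) stop("implied kd <= 0: influx too small for the pool change",
                    call. = FALSE)
  n_mol <- water_kg_to_mol(mean_pool)
  r_mol <- true_rco2 / .l_per_mol
  ko <- switch(config$equation,
    two_pool = kd + 2.078 * (r_mol + 0.0062 * kd * n_mol) / n_mol,
    single_pool = kd + r_mol / (n_mol * (1 / 2.078 - 0.0246 * 1.05)))
  dose_mol <- config$dose_o18_mass / .mw_water
  dose_excess <- config$dose_o18_enrichment * 1e4 - .o18_natural_ppm
  equil_o18 <- dose_mol * dose_excess /
    (water_kg_to_mol(tbw_initial) * config$dilution_space_factor)
  equil_h3 <- config$dose_h3_activity * .dpm_per_mci / (tbw_initial * 1000)
  noisy <- function(x) {
    if (noise_cv <= 0) return(x)
    x * exp(stats::rnorm(length(x), 0, noise_cv) - noise_cv^2 / 2)
  }
  eq_o <- noisy(equil_o18); eq_h <- noisy(equil_h3)
  fin_o <- noisy(equil_o18 * exp(-ko * dt))
  fin_h <- noisy(equil_h3 * exp(-kd * dt))
  rec <- isotope_record(
    seal_id = seal_id,
    dose_o18_mass = config$dose_o18_mass,
    dose_o18_enrichment = config$dose_o18_enrichment,
    dose_h3_activity = config$dose_h3_activity,
    background_o18 = 0, equilib_o18 = eq_o, final_o18 = fin_o,
    background_h3 = 0, equilib_h3 = eq_h, final_h3 = fin_h,
    t_equilib = 0, t_final = dt,
    mass_initial = mass_initial, mass_final = mass_final)
  list(record = rec, excluded = fin_o < config$detection_limit_o18,
       kd = kd, ko = ko)
}

# truncated normal by resampling (small n, simple and exact enough)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate milk fatty-acid profiles around diet-cluster centroids
#'
#' @param n_trips number of profiles
#' @param cluster_probs probabilities over the centroid rows
#' @param centroids percent centroid matrix (default
#'   [default_fa_centroids()])
#' @param concentration total Dirichlet concentration (larger = tighter)
#' @return list with `profiles` (`trip_id` + FA percent columns, rows
#'   closed to 100) and `labels` (true cluster of each trip)
#' @export
simulate_fa_profiles <- function(n_trips, cluster_probs = c(.3, .25, .25, .2),
                                 centroids = default_fa_centroids()$centroids,
                                 concentration = 2000) {
  k <- sample.int(nrow(centroids), n_trips, replace = TRUE,
                  prob = cluster_probs)
  prof <- t(vapply(k, function(i)
    100 * .rdirichlet(1, concentration * centroids[i, ] / 100)[1, ],
    numeric(ncol(centroids))))
  colnames(prof) <- colnames(centroids)
  list(profiles = cbind(data.frame(trip_id = sprintf("T%03d", seq_len(n_trips))),
                        as.data.frame(prof, check.names = FALSE)),
       labels = k)
}

#' Simulate a depth series with nocturnal dive bouts
#'
#' Dives are trapezoidal excursions whose midpoints fall in the night
#' window with probability `night_dive_prob`; dive count is set so the
#' expected fraction of time below the surface matches `pct_dive`.
#'
#' @param trip_days trip duration (days)
#' @param pct_dive target percent of trip time in dives
#' @param depth_mean mean of per-dive maximum depths (m)
#' @param config a [simulation_config()] (sampling interval, night window,
#'   dive durations)
#' @return list with `series` (a [depth_series()]), `dives` (true dive
#'   table: start, end, max_depth, duration), `night_windows` (matrix of
#'   day-fraction intervals)
#' @export
simulate_depth_series <- function(trip_days, pct_dive, depth_mean,
                                  config = simulation_config()) {
  dt <- config$tdr_dt
  n <- floor(trip_days * .sec_per_day / dt)
  depth <- numeric(n)
  mean_dur <- config$dive_duration_mean
  n_dives <- max(1, round(pct_dive / 100 * trip_days * .sec_per_day / mean_dur))
  nw_h <- config$night_window
  days <- seq_len(ceiling(trip_days) + 1) - 1
  night <- cbind(days + nw_h[1] / 24 - 1 + (nw_h[1] < nw_h[2]),
                 days + nw_h[2] / 24)
  night <- night[night[, 1] < trip_days & night[, 2] > 0, , drop = FALSE]
  is_night <- stats::runif(n_dives) < config$night_dive_prob
  mid <- numeric(n_dives)
  for (i in seq_len(n_dives)) {
    repeat {
      m <- stats::runif(1, 0.005, trip_days - 0.005)
      hr <- (m %% 1) * 24
      in_night <- if (nw_h[1] > nw_h[2]) (hr >= nw_h[1] | hr < nw_h[2])
                  else (hr >= nw_h[1] & hr < nw_h[2])
      if (in_night == is_night[i]) break
    }
    mid[i] <- m
  }
  mid <- sort(mid)
  dur <- pmax(3 * dt, round(stats::rgamma(n_dives, shape = 9,
                                          scale = mean_dur / 9) / dt) * dt)
  dmax <- pmax(4, stats::rlnorm(n_dives, log(depth_mean) - 0.125, 0.5))
  truth <- NULL
  last_end <- -1
  for (i in seq_len(n_dives)) {
    i0 <- round(mid[i] * .sec_per_day / dt - dur[i] / (2 * dt))
    i1 <- i0 + dur[i] / dt - 1
    if (i0 <= last_end + 1 || i1 > n - 2 || i0 < 2) next
    idx <- i0:i1
    m <- length(idx)
    ramp <- max(1, floor(m / 5))
    prof <- rep(dmax[i], m)
    prof[seq_len(ramp)] <- dmax[i] * seq_len(ramp) / (ramp + 0.5)
    prof[m + 1 - seq_len(ramp)] <- dmax[i] * seq_len(ramp) / (ramp + 0.5)
    prof <- round(prof)            # 1 m sensor resolution
    depth[idx + 1] <- prof
    last_end <- i1
    sup <- which(prof > 3)         # ramp edges can round to <= 3 m
    truth <- rbind(truth, data.frame(i0 = i0 + min(sup) - 1,
                                     i1 = i0 + max(sup) - 1,
                                     max_depth = max(prof)))
  }
  series <- depth_series(time = (seq_len(n) - 1) * dt / .sec_per_day,
                         depth = depth)
  dives <- if (is.null(truth)) {
    data.frame(start = numeric(0), end = numeric(0),
               max_depth = numeric(0), duration = numeric(0))
  } else {
    sup <- truth$max_depth > 3  # all are, by construction
    data.frame(start = truth$i0 * dt / .sec_per_day,
               end = (truth$i1 + 1) * dt / .sec_per_day,
               max_depth = truth$max_depth,
               duration = (truth$i1 - truth$i0 + 1) * dt)[sup, ]
  }
  list(series = series, dives = dives, night_windows = night)
}

#' Simulate an ARGOS-like foraging-trip track
#'
#' Out-and-back correlated random walk from the colony with fixes every
#' ~1.5 h, ARGOS location classes and class-dependent position error.
#'
#' @param trip_days trip duration (days)
#' @param config a [simulation_config()]
#' @param speed_mean mean transit speed (m s-1)
#' @return list with `fixes` (`time` days, `lon`, `lat`, `quality`) and
#'   `truth` (hourly true positions)
#' @export
simulate_track <- function(trip_days, config = simulation_config(),
                           speed_mean = 1.0) {
  hours <- seq(0, trip_days * 24)
  nh <- length(hours)
  half <- nh / 2
  heading <- stats::runif(1, 0, 2 * pi)
  dh <- cumsum(stats::rnorm(nh, 0, 0.25))
  spd <- pmax(0.1, speed_mean + stats::rnorm(nh, 0, 0.3)) * 3600  # m/h
  out_leg <- spd * cbind(cos(heading + dh), sin(heading + dh))
  xy <- apply(out_leg, 2, cumsum)
  # fold the walk back so it ends at the colony
  w <- pmin(1, pmax(0, (seq_len(nh) - half) / (nh - half)))
  xy <- xy - outer(w, xy[nh, ])
  m_per_deg <- 6371000 * pi / 180
  lat <- config$colony[2] + xy[, 2] / m_per_deg
  lon <- config$colony[1] + xy[, 1] / (m_per_deg * cos(config$colony[2] * pi / 180))
  truth <- data.frame(time = hours / 24, lon = lon, lat = lat)
  ft <- sort(stats::runif(max(4, round(trip_days * 16)), 0, trip_days))
  classes <- c("3", "2", "1", "0", "A", "B", "Z")
  cls_p <- c(.10, .15, .20, .25, .15, .12, .03)
  err_sd <- c(`3` = 150, `2` = 350, `1` = 1000, `0` = 3000,
              A = 5000, B = 10000, Z = 30000)
  q <- sample(classes, length(ft), replace = TRUE, prob = cls_p)
  ti <- pmin(nh, pmax(1, round(ft * 24) + 1))
  ex <- stats::rnorm(length(ft), 0, err_sd[q])
  ey <- stats::rnorm(length(ft), 0, err_sd[q])
  fixes <- data.frame(
    time = ft,
    lon = truth$lon[ti] + ex / (m_per_deg * cos(config$colony[2] * pi / 180)),
    lat = truth$lat[ti] + ey / m_per_deg,
    quality = q)
  list(fixes = fixes, truth = truth)
}

#' Simulate a complete DLW study with known ground truth
#'
#' Draws seals, seasons, trips, masses and diet clusters; generates true
#' at-sea FMR from the configured linear model, true water influx from
#' the cluster means, and true mass gain from the configured mass-gain
#' model; forward-computes the isotope records with
#' [simulate_washout()]; and (optionally) renders depth series, ARGOS
#' tracks and milk FA profiles per trip. Deterministic given
#' `config$seed`. Applying the estimation chain ([dlw_energetics()]) to
#' the emitted records recovers the true rates exactly in the noise-free
#' limit.
#'
#' @param config a [simulation_config()]
#' @param with_series also generate depth series and tracks (slower;
#'   default `FALSE`)
#' @return list of class `simulated_study`: `trips` (ground-truth table,
#'   one row per measurement: seal, season, attendance times, true FMR
#'   components, true rCO2 and influx, masses, cluster, `excluded` flag),
#'   `isotopes` (list of `isotope_record`), `attendance` (list of
#'   `attendance_record`), `fa_profiles`, and when requested
#'   `depth_series` / `tracks` (per-trip lists)
#' @export
simulate_study <- function(config = simulation_config(),
                           with_series = FALSE) {
  set.seed(config$seed)
  n <- config$n_seals
  both <- stats::runif(n) < config$p_both
  u <- stats::rnorm(n, 0, config$individual_sd)
  seal_ids <- sprintf("S%03d", seq_len(n))
  rows <- list(); iso <- list(); att <- list()
  series <- list(); tracks <- list(); fa_rows <- list()
  cen <- default_fa_centroids()
  for (i in seq_len(n)) {
    seasons <- if (both[i]) c("summer", "fall") else
      if (stats::runif(1) < config$p_fall_single) "fall" else "summer"
    mass0 <- .rtnorm(1, config$mass_mean, config$mass_sd,
                     config$mass_range[1], config$mass_range[2])
    for (season in seasons) {
      trip <- .rtnorm(1, config$trip_mean, config$trip_sd, lower = 2)
      pre <- stats::runif(1, config$shore_pre[1], config$shore_pre[2])
      post <- stats::runif(1, config$shore_post[1], config$shore_post[2])
      a <- attendance_record(0, pre, pre + trip, pre + trip + post, season)
      fall <- as.integer(season == "fall")
      b0 <- config$fmr_intercept
      fmr_sea <- b0 + b0 * config$fall_effect_pct / 100 * fall +
        b0 * config$trip_day_effect_pct / 100 * trip +
        u[i] + stats::rnorm(1, 0, config$residual_sd)
      cl <- sample.int(3, 1, prob = config$cluster_probs)
      influx <- .rtnorm(1, config$cluster_influx_means[cl], config$influx_sd,
                        lower = 60)
      gain_sea <- config$mass_gain_intercept +
        config$mass_gain_trip_effect * trip +
        config$mass_gain_fall_effect * fall +
        stats::rnorm(1, 0, config$mass_gain_sd)
      t_shore <- pre + post
      mass1 <- mass0 + gain_sea -
        config$fasting_rate[[season]] * t_shore
      mass1 <- max(mass1, config$mass_range[1] * 0.9)
      tbw0 <- config$tbw_fraction * mass0
      tbw1 <- config$tbw_fraction * mass1
      interval <- a$t_recapture - a$t_release
      mass_ref <- (mass0 + mass1) / 2
      fmr_tot <- (fmr_sea * trip + config$onshore_mr * t_shore) / interval
      rco2 <- fmr_tot * mass_ref * .sec_per_day / 1000 / .kj_per_l_co2
      w <- simulate_washout(rco2, influx, tbw0, tbw1, mass0, mass1,
                            dt = interval, noise_cv = config$assay_cv,
                            config = config, seal_id = seal_ids[i])
      trip_id <- paste0(seal_ids[i], "_", season)
      rows[[trip_id]] <- data.frame(
        trip_id = trip_id, seal_id = seal_ids[i], season = season,
        trip_duration = trip, t_release = a$t_release,
        t_depart = a$t_depart, t_arrive = a$t_arrive,
        t_recapture = a$t_recapture,
        mass_initial = mass0, mass_final = mass1,
        true_fmr_at_sea = fmr_sea, true_fmr_total = fmr_tot,
        true_rco2 = rco2, true_influx = influx,
        true_mass_gain_sea = gain_sea,
        true_kd = w$kd, true_ko = w$ko,
        fa_cluster = cl, excluded = w$excluded)
      iso[[trip_id]] <- w$record
      att[[trip_id]] <- a
      prof <- 100 * .rdirichlet(1, config$dirichlet_concentration *
                                  cen$centroids[cl, ] / 100)[1, ]
      fa_rows[[trip_id]] <- data.frame(trip_id = trip_id,
                                       t(prof), check.names = FALSE)
      if (with_series) {
        pd <- .rtnorm(1, config$pct_dive_mean, config$pct_dive_sd, lower = 3)
        dm <- stats::rlnorm(1, config$depth_meanlog, config$depth_sdlog)
        series[[trip_id]] <- simulate_depth_series(trip, pd, dm, config)
        tracks[[trip_id]] <- simulate_track(trip, config)
      }
      mass0 <- mass1  # fall capture mass follows the summer trip
    }
  }
  trips <- do.call(rbind, rows)
  rownames(trips) <- NULL
  fa <- do.call(rbind, fa_rows)
  rownames(fa) <- NULL
  structure(list(config = config, trips = trips, isotopes = iso,
                 attendance = att, fa_profiles = fa,
                 depth_series = if (with_series) series else NULL,
                 tracks = if (with_series) tracks else NULL),
            class = "simulated_study")
}

#' Run the DLW estimation chain over a simulated study
#'
#' @param sim a `simulated_study` from [simulate_study()]
#' @param skip_excluded drop measurements flagged as washed out
#'   (default `TRUE`)
#' @return `data.frame` of per-trip [dlw_energetics()] results joined with
#'   the ground truth columns
#' @export
estimate_study <- function(sim, skip_excluded = TRUE) {
  cfg <- dlw_config(equation = sim$config$equation,
                    dilution_space_factor = sim$config$dilution_space_factor,
                    onshore_mr = sim$config$onshore_mr,
                    fasting_rate = sim$config$fasting_rate)
  keep <- if (skip_excluded) !sim$trips$excluded else
    rep(TRUE, nrow(sim$trips))
  res <- do.call(rbind, lapply(sim$trips$trip_id[keep], function(id) {
    r <- dlw_energetics(sim$isotopes[[id]], sim$attendance[[id]], cfg)
    r$trip_id <- id
    r
  }))
  merge(res, sim$trips[keep, ], by = "trip_id",
        suffixes = c("", ".truth"))
}

#' Write a simulated study to CSV files
#'
#' Emits the same schemas the analysis functions read: `isotopes.csv`,
#' `attendance.csv`, `fa_profiles.csv` and `ground_truth.csv` (plus
#' per-trip `depths_<trip>.csv` / `track_<trip>.csv` when the study was
#' generated with series).
#'
#' @param sim a `simulated_study`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- do.call(rbind, lapply(names(sim$isotopes), function(id)
    data.frame(trip_id = id, sim$isotopes[[id]][
      c("seal_id", "dose_o18_mass", "dose_o18_enrichment",
        "dose_h3_activity", "background_o18", "equilib_o18", "final_o18",
        "background_h3", "equilib_h3", "final_h3", "t_equilib", "t_final",
        "mass_initial", "mass_final")])))
  utils::write.csv(iso, file.path(dir, "isotopes.csv"), row.names = FALSE)
  att <- do.call(rbind, lapply(names(sim$attendance), function(id) {
    a <- sim$attendance[[id]]
    data.frame(trip_id = id, t_release = a$t_release, t_depart = a$t_depart,
               t_arrive = a$t_arrive, t_recapture = a$t_recapture,
               season = a$season)
  }))
  utils::write.csv(att, file.path(dir, "attendance.csv"), row.names = FALSE)
  utils::write.csv(sim$fa_profiles, file.path(dir, "fa_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$trips, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  for (id in names(sim$depth_series %||% list())) {
    utils::write.csv(as.data.frame(sim$depth_series[[id]]$series),
                     file.path(dir, paste0("depths_", id, ".csv")),
                     row.names = FALSE)
  }
  for (id in names(sim$tracks %||% list())) {
    utils::write.csv(sim$tracks[[id]]$fixes,
                     file.path(dir, paste0("track_", id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
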