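# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately avoid the package's own code paths.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sa * sb / n2
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sn - expected) / denom
}

# Greedy Ward agglomeration by direct minimization of the merge cost
# 2 * nA*nB/(nA+nB) * ||cA - cB||^2 (the ward.D-on-squared-distance height).
# Returns the sequence of merge heights and the partition after each merge.
brute_ward <- function(x) {
  groups <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      ci <- colMeans(x[groups[[i]], , drop = FALSE])
      cj <- colMeans(x[groups[[j]], , drop = FALSE])
      ni <- length(groups[[i]]); nj <- length(groups[[j]])
      h <- 2 * ni * nj / (ni + nj) * sum((ci - cj)^2)
      if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
    }
    merged <- c(groups[[best[1]]], groups[[best[2]]])
    groups <- c(groups[-best], list(merged))
    heights <- c(heights, best_h)
    lab <- integer(nrow(x))
    for (g in seq_along(groups)) lab[groups[[g]]] <- g
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Plain-loop run-length dive detector (independent of rle()).
brute_dives <- function(depth, time, dt, threshold = 3) {
  out <- NULL
  i <- 1; n <- length(depth)
  while (i <= n) {
    if (depth[i] > threshold) {
      j <- i
      while (j < n && depth[j + 1] > threshold) j <- j + 1
      out <- rbind(out, data.frame(start = time[i],
                                   duration = (j - i + 1) * dt,
                                   max_depth = max(depth[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    out <- data.frame(start = numeric(0), duration = numeric(0),
                      max_depth = numeric(0))
  out
}

hav_m <- function(lon1, lat1, lon2, lat2) {
  r <- 6371000
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Minimal-removal speed filter by exhaustive subset search (endpoints kept).
# Returns the retained row indices of the smallest valid removal set; among
# equal-size sets the first in enumeration order.
brute_speed_filter <- function(locs, vmax = 3) {
  n <- nrow(locs)
  t_sec <- locs$time * 86400
  ok <- function(keep) {
    if (length(keep) < 2) return(TRUE)
    sp <- hav_m(locs$lon[keep[-length(keep)]], locs$lat[keep[-length(keep)]],
                locs$lon[keep[-1]], locs$lat[keep[-1]]) /
      pmax(diff(t_sec[keep]), 1e-9)
    all(sp <= vmax)
  }
  interior <- setdiff(seq_len(n), c(1, n))
  for (k in 0:length(interior)) {
    sets <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(interior, k), 2)
    for (rm in sets) {
      keep <- setdiff(seq_len(n), rm)
      if (ok(keep)) return(keep)
    }
  }
  c(1, n)
}

# A forward-consistent isotope record with known truth, built directly from
# the dilution/turnover algebra (not via the package generator).
make_known_record <- function(tbw_kg = 20, ko = 0.35, kd = 0.25, dt = 8,
                              dose_g = 60, dose_atom_pct = 10,
                              mass_i = 33, mass_f = 33, dsf = 1.007) {
  mw <- 18.0153
  dose_mol <- dose_g / mw
  dose_excess <- dose_atom_pct * 1e4 - 2005
  pool_mol <- tbw_kg * 1000 / mw
  eq_o <- dose_mol * dose_excess / (pool_mol * dsf)
  eq_h <- 5000
  isotope_record(
    seal_id = "oracle", dose_o18_mass = dose_g,
    dose_o18_enrichment = dose_atom_pct, dose_h3_activity = 1,
    background_o18 = 0, equilib_o18 = eq_o,
    final_o18 = eq_o * exp(-ko * dt),
    background_h3 = 0, equilib_h3 = eq_h,
    final_h3 = eq_h * exp(-kd * dt),
    t_equilib = 0, t_final = dt,
    mass_initial = mass_i, mass_final = mass_f)
}
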