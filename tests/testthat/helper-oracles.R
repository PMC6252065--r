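# Independent oracles. Each reimplements the quantity under test by a
# different route than the package code so the two can be compared.

# --- solar: sunrise/sunset by root-finding the solar elevation ------------
# Solar elevation at a local civil time, from first principles (Julian day,
# declination, equation of time, hour angle). Written independently of the
# package's closed-form hour-angle path.
oracle_elevation <- function(date, hour_local, lat, lon, utc_offset) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + (hour_local - utc_offset) / 24
  tc <- (jd - 2451545) / 36525
  rad <- pi / 180
  L0 <- (280.46646 + 36000.76983 * tc + 0.0003032 * tc^2) %% 360
  M <- 357.52911 + 35999.05029 * tc - 0.0001537 * tc^2
  e <- 0.016708634 - 0.000042037 * tc - 0.0000001267 * tc^2
  C <- sin(M * rad) * (1.914602 - 0.004817 * tc - 0.000014 * tc^2) +
    sin(2 * M * rad) * (0.019993 - 0.000101 * tc) +
    sin(3 * M * rad) * 0.000289
  lam <- (L0 + C - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * tc) * rad)) * rad
  eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos((125.04 - 1934.136 * tc) * rad)) * rad
  dec <- asin(sin(eps) * sin(lam))
  y <- tan(eps / 2)^2
  eqt <- 4 / rad * (y * sin(2 * L0 * rad) - 2 * e * sin(M * rad) +
                      4 * e * y * sin(M * rad) * cos(2 * L0 * rad) -
                      0.5 * y^2 * sin(4 * L0 * rad) -
                      1.25 * e^2 * sin(2 * M * rad))
  tst <- (hour_local * 60 + eqt + 4 * lon - 60 * utc_offset) %% 1440
  ha <- (tst / 4 - 180) * rad
  asin(sin(lat * rad) * sin(dec) + cos(lat * rad) * cos(dec) * cos(ha)) / rad
}

# Find the local hours at which elevation crosses -0.833 deg (rising before
# local noon-ish, setting after).
oracle_sun_times <- function(date, lat, lon, utc_offset) {
  f <- function(h) oracle_elevation(date, h, lat, lon, utc_offset) + 0.833
  rise <- uniroot(f, c(0, 12), tol = 1e-7)$root
  set <- uniroot(f, c(10, 24), tol = 1e-7)$root
  c(sunrise = rise, set = set)
}

# --- ccf: per-lag Pearson correlation from the definitional formula -------
oracle_ccf <- function(x, y, lags = -12:11) {
  sapply(lags, function(h) {
    xs <- x[((seq_along(x) - 1 + h) %% length(x)) + 1]
    mx <- mean(xs); my <- mean(y)
    sum((xs - mx) * (y - my)) /
      sqrt(sum((xs - mx)^2) * sum((y - my)^2))
  })
}

# Maximal runs of TRUE in a logical vector, by exhaustive scan.
oracle_runs <- function(sig, lags) {
  out <- NULL
  i <- 1
  while (i <= length(sig)) {
    if (sig[i]) {
      j <- i
      while (j < length(sig) && sig[j + 1]) j <- j + 1
      out <- rbind(out, data.frame(from = lags[i], to = lags[j]))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) data.frame(from = integer(), to = integer()) else out
}

# --- anova: definitional sums-of-squares decomposition --------------------
oracle_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  k <- length(unique(groups)); n <- length(values)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# --- overlap: fine quadrature of min of two analytic von Mises densities --
oracle_vm_overlap <- function(mu1, k1, mu2, k2, n_grid = 2e5) {
  g <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  mean(pmin(dvonmises(g, mu1, k1), dvonmises(g, mu2, k2))) * 2 * pi
}

# --- independence filter: greedy scan coded as an explicit loop -----------
oracle_greedy_filter <- function(times_hours, interval) {
  keep <- logical(length(times_hours))
  last <- -Inf
  for (i in order(times_hours)) {
    if (times_hours[i] - last >= interval) {
      keep[i] <- TRUE
      last <- times_hours[i]
    }
  }
  keep
}
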