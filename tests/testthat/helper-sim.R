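# Shared fixture builders: known-coefficient conditional-logit strata, a
# grid-search likelihood oracle, and small raster landscapes.

# Strata with a known softmax choice rule. Covariates default to binary
# snow ~ Bernoulli(0.5) and standard-normal continuous variables.
sim_clogit_strata <- function(n_strata, K = 10, beta = c(snow = -1.5),
                              n_individuals = 5, covgen = NULL) {
  vars <- names(beta)
  if (is.null(covgen)) covgen <- function(n) {
    out <- list()
    for (v in vars)
      out[[v]] <- if (v == "snow") stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
    as.data.frame(out)
  }
  rows <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    X <- covgen(K + 1)
    eta <- drop(as.matrix(X[vars]) %*% beta)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    ch <- sample.int(K + 1, 1, prob = p)
    rows[[s]] <- cbind(data.frame(
      stratum = sprintf("s%04d", s),
      individual = sprintf("ind%02d", ((s - 1) %% n_individuals) + 1),
      case = as.integer(seq_len(K + 1) == ch)), X)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact one-covariate conditional log-likelihood, independent of the
# package's fitter (plain arithmetic over strata).
clogit_loglik_1d <- function(df, var, beta) {
  x <- df[[var]]
  s <- as.integer(factor(df$stratum))
  vapply(beta, function(b) {
    eta <- b * x
    m <- as.numeric(tapply(eta, s, max))
    z <- as.numeric(rowsum(exp(eta - m[s]), s))
    sum(eta[df$case == 1]) - sum(log(z) + m)
  }, numeric(1))
}

# Brute-force MLE on an equally spaced grid.
oracle_clogit_grid <- function(df, var, lo = -4, hi = 2, by = 0.001) {
  grid <- seq(lo, hi, by = by)
  ll <- clogit_loglik_1d(df, var, grid)
  grid[which.max(ll)]
}

# Small landscape shared by integration-style tests.
tiny_landscape <- function(ndays = 45, noise_p = 0, seed = 1L,
                           wind_mean = c(2, 1)) {
  cfg <- snow_front_config(
    lon_min = 15, lon_max = 22, lat_min = 55, lat_max = 68,
    cell_deg = 0.25,
    dates = seq(as.Date("2016-04-01"), by = "day", length.out = ndays),
    front_lat0 = 57, front_speed = 0.2, noise_p = noise_p, seed = seed)
  list(cfg = cfg,
       series = c(list(snow = make_snow_series(cfg)),
                  make_env_fields(cfg, wind_mean = wind_mean)))
}

# Fixed movement kernel for strata fixtures too small to fit their own.
toy_dist <- function(mean_km = 50, turns = c(-30, -10, 0, 10, 30)) {
  structure(list(rate = 1 / mean_km, mean_km = mean_km, turns = turns,
                 n = length(turns)),
            class = "step_distribution")
}

# Constant-speed due-north track (for FPT / geometry fixtures).
uniform_track <- function(n_fixes, speed_km_day, start_date = as.Date("2016-04-01"),
                          lat0 = 60, lon0 = 20) {
  deg_per_day <- speed_km_day / 111.19
  data.frame(individual = "u1",
             timestamp = as.POSIXct(paste(start_date + seq_len(n_fixes) - 1,
                                          "00:00:00"), tz = "UTC"),
             lon = lon0, lat = lat0 + deg_per_day * (seq_len(n_fixes) - 1),
             year = as.integer(format(start_date, "%Y")))
}
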