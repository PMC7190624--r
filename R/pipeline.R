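# End-to-end orchestration: configuration, demo scenario, and the full
# ingest -> filter -> segment -> lag analysis -> strata -> fits -> UHC
# pipeline with per-stage accounting.

#' Pipeline configuration
#'
#' Defaults follow the study design: 10 alternatives per stratum, lag
#' window -10..+10 days, step scales of 1, 3 and 5 days, FPT radius
#' 100 km, spring window March-June.
#'
#' @param tracks_path Movebank-style tracks CSV (or `NULL` when track
#'   objects are passed directly).
#' @param out_dir Output directory.
#' @param species Species label used in output files.
#' @param step_scales Step lengths in days.
#' @param K Alternatives per stratum.
#' @param lags Lag-day window.
#' @param fpt_radius_km FPT radius.
#' @param fpt_threshold_days FPT threshold; `NULL` = bimodality valley.
#' @param spring_months Spring month window.
#' @param min_argos_class Worst acceptable Argos class.
#' @param tolerance_frac Resampling tolerance as a fraction of the step
#'   scale.
#' @param run_segmentation Run FPT segmentation (disable for data that
#'   is already spring-only)?
#' @param uhc_resamples,uhc_test_fraction UHC settings.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tracks_path = NULL, out_dir = tempfile("snowtrack_"),
                            species = "species", step_scales = c(1, 3, 5),
                            K = 10, lags = -10:10, fpt_radius_km = 100,
                            fpt_threshold_days = NULL,
                            spring_months = c(3, 6), min_argos_class = "2",
                            tolerance_frac = 0.1, run_segmentation = TRUE,
                            uhc_resamples = 1000, uhc_test_fraction = 0.3,
                            seed = 1L) {
  structure(list(tracks_path = tracks_path, out_dir = out_dir,
                 species = species, step_scales = step_scales, K = K,
                 lags = lags, fpt_radius_km = fpt_radius_km,
                 fpt_threshold_days = fpt_threshold_days,
                 spring_months = spring_months,
                 min_argos_class = min_argos_class,
                 tolerance_frac = tolerance_frac,
                 run_segmentation = run_segmentation,
                 uhc_resamples = uhc_resamples,
                 uhc_test_fraction = uhc_test_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build the demo scenario
#'
#' Simulates the three front-position phenotypes as three "species":
#' agents coupled AHEAD of (in snow), ON, and BEHIND (snow-free) the
#' receding melt front, over a shared synthetic landscape, and
#' optionally writes tracks/strata/truth files per mode.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param n_individuals Agents per coupling mode.
#' @param n_steps Decisions per agent.
#' @param beta True selection coefficients shared by all modes.
#' @param snow_cfg Landscape configuration.
#' @param seed Integer seed.
#' @return List of class `demo_data`: `snow_cfg`, `rasters` (snow +
#'   fields), per-mode `sims`, and `paths` when written.
#' @export
make_demo <- function(out_dir = NULL, n_individuals = 20, n_steps = 60,
                      beta = c(snow = 0, wind_support = 0.05,
                               crosswind = 0),
                      snow_cfg = snow_front_config(seed = seed),
                      seed = 1L) {
  rasters <- c(list(snow = make_snow_series(snow_cfg)),
               make_env_fields(snow_cfg))
  modes <- c("AHEAD", "ON_FRONT", "BEHIND")
  sims <- lapply(seq_along(modes), function(i) {
    cfg <- agent_config(n_individuals = n_individuals, n_steps = n_steps,
                        coupling = modes[i], beta = beta,
                        seed = seed + i)
    simulate_agents(cfg, rasters, snow_cfg)
  })
  names(sims) <- modes
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- lapply(modes, function(m)
      write_sim_tracks(sims[[m]], out_dir, stem = tolower(m)))
    names(paths) <- modes
    for (m in modes)
      message(sprintf("make_demo: %s -> %d fixes, %d strata rows", m,
                      nrow(sims[[m]]$tracks), nrow(sims[[m]]$strata)))
  }
  structure(list(snow_cfg = snow_cfg, rasters = rasters, sims = sims,
                 paths = paths),
            class = "demo_data")
}

#' Run the full analysis pipeline
#'
#' Executes ingest -> quality filter -> (optional) FPT segmentation ->
#' lag analysis at the one-day scale -> strata construction per step
#' scale -> conditional-logit fits with drop-one AIC comparison -> UHC
#' validation, writing CSV/JSON outputs and a per-stage accounting log
#' to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param trackset Optional `trackset` (skips reading
#'   `config$tracks_path`).
#' @param series_map Named list of [env_series] covering the tracks
#'   (must include `snow`; `wind_u`/`wind_v` enable wind covariates).
#' @return List of class `pipeline_result`: `lag_fits`, `lag_comparisons`,
#'   `ssf_fits` (per scale), `ssf_comparisons`, `uhc`, `log`.
#' @export
run_pipeline <- function(config, trackset = NULL, series_map) {
  stopifnot(inherits(config, "pipeline_config"), "snow" %in% names(series_map))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- ingest ---------------------------------------------------------
  ts <- stage("ingest", {
    if (is.null(trackset)) read_tracks(config$tracks_path) else trackset
  })
  log$ingest <- attr(ts, "log")
  if (is.null(log$ingest)) log$ingest <- list(n_kept = nrow(ts))

  # -- quality filter -------------------------------------------------
  ts <- stage("filter", filter_quality(ts, config$min_argos_class))
  log$filter <- attr(ts, "log")

  # -- segmentation ---------------------------------------------------
  tracks <- split_tracks(ts)
  if (config$run_segmentation) {
    segs <- stage("segment", lapply(tracks, function(tr) {
      if (nrow(tr) < 3) return(NULL)
      prof <- first_passage_time(tr, config$fpt_radius_km)
      thr <- if (is.null(config$fpt_threshold_days))
        fpt_threshold(prof) else config$fpt_threshold_days
      seg <- suppressWarnings(
        extract_migration(tr, prof, thr, config$spring_months))
      if (nrow(seg$segment) >= 3) seg$segment else NULL
    }))
    tracks <- Filter(Negate(is.null), segs)
    log$segment <- list(n_tracks_in = length(segs),
                        n_tracks_kept = length(tracks))
  }

  # -- resample per scale ---------------------------------------------
  has_wind <- all(c("wind_u", "wind_v") %in% names(series_map))
  bursts_by_scale <- stage("resample", lapply(config$step_scales, function(sc)
    unlist(lapply(tracks, resample_steps, step_days = sc,
                  tolerance_days = config$tolerance_frac * sc),
           recursive = FALSE)))
  names(bursts_by_scale) <- paste0("scale_", config$step_scales)
  log$resample <- lapply(bursts_by_scale, function(b)
    list(n_bursts = length(b), n_fixes = sum(vapply(b, nrow, numeric(1)))))

  # -- lag analysis at the one-day scale ------------------------------
  day1 <- bursts_by_scale[[which(config$step_scales == 1)[1]]]
  if (is.null(day1)) day1 <- bursts_by_scale[[1]]
  chosen_pts <- do.call(rbind, lapply(day1, function(b)
    data.frame(individual = b$individual, year = b$year,
               lon = b$lon, lat = b$lat, date = as.Date(b$timestamp))))
  lt <- stage("lags", lag_table(chosen_pts,
                                series_map[intersect(c("snow", "temp", "ndvi"),
                                                     names(series_map))],
                                lags = config$lags))
  utils::write.csv(lt, file.path(config$out_dir, "lag_table.csv"),
                   row.names = FALSE)
  lag_vars <- unique(lt$variable)
  lag_fits <- stage("lag_models", lapply(lag_vars, function(v)
    fit_lag_model(lt, v)))
  names(lag_fits) <- lag_vars
  lag_cmp <- lapply(lag_vars, function(v) {
    null_fit <- .fit_lag_null(lt, v, lag_fits[[v]]$family)
    compare_models(full = lag_fits[[v]], no_day = null_fit)
  })
  names(lag_cmp) <- lag_vars
  log$lags <- list(n_points = nrow(chosen_pts), n_rows = nrow(lt))

  # -- strata + SSF fits per scale ------------------------------------
  ssf_fits <- list(); ssf_cmp <- list(); strata_by_scale <- list()
  for (k in seq_along(config$step_scales)) {
    sc <- config$step_scales[k]
    bl <- bursts_by_scale[[k]]
    if (length(bl) == 0) next
    st <- stage(paste0("strata_", sc),
                build_strata(bl, series_map, K = config$K,
                             seed = config$seed + k,
                             include_wind = (sc == 1 && has_wind)))
    if (is.null(st) || !any(st$case == 1)) next
    strata_by_scale[[paste0("scale_", sc)]] <- st
    utils::write.csv(st, file.path(config$out_dir,
                                   sprintf("strata_%dd.csv", sc)),
                     row.names = FALSE)
    preds <- intersect(c("snow", "wind_support", "crosswind"), names(st))
    if (sc != 1 || !has_wind) preds <- intersect(preds, "snow")
    scr <- screen_collinearity(st, preds, threshold = 0.7)
    preds <- setdiff(preds, scr$zero_variance)
    if (length(preds) == 0) next
    fml <- stats::reformulate(preds, response = "case")
    full <- stage(paste0("ssf_", sc),
                  fit_clogit(fml, st, cluster = "individual"))
    fits <- list(full = full)
    if (length(preds) > 1) {
      for (pv in preds) {
        f2 <- stats::reformulate(setdiff(preds, pv), response = "case")
        fits[[paste0("no_", pv)]] <- fit_clogit(f2, st)
      }
    } else {
      fits$null <- .null_clogit(full)
    }
    ssf_fits[[paste0("scale_", sc)]] <- full
    ssf_cmp[[paste0("scale_", sc)]] <- compare_models(fits)
    write_fit_json(full, file.path(config$out_dir,
                                   sprintf("ssf_fit_%dd.json", sc)))
  }
  log$strata <- lapply(strata_by_scale, function(st)
    list(n_strata = length(unique(st$stratum)),
         n_skipped_first = attr(st, "n_skipped_first"),
         n_dropped_offgrid = attr(st, "n_dropped_offgrid")))

  # -- UHC on the one-day fit -----------------------------------------
  uhc <- NULL
  st1 <- strata_by_scale[["scale_1"]]
  if (!is.null(st1) && length(unique(st1$individual)) >= 3 &&
      "scale_1" %in% names(ssf_fits)) {
    uhc <- stage("uhc", {
      sp <- split_strata(st1, config$uhc_test_fraction, config$seed)
      preds <- names(coef(ssf_fits[["scale_1"]]))
      f <- fit_clogit(stats::reformulate(preds, "case"), sp$train)
      uhc_validate(f, sp$test, n_resamples = config$uhc_resamples,
                   seed = config$seed)
    })
    write_uhc_csv(uhc, file.path(config$out_dir, "uhc.csv"))
  }

  # -- summary tables -------------------------------------------------
  lag_summary <- do.call(rbind, lapply(lag_vars, function(v) {
    f <- lag_fits[[v]]
    data.frame(species = config$species, dep_var = v,
               predictor = c("(Intercept)", "day"),
               est = unname(f$coefficients), se = unname(f$se),
               statistic = unname(f$coefficients / f$se),
               dAIC = lag_cmp[[v]]$dAIC[lag_cmp[[v]]$model == "no_day"],
               weight = lag_cmp[[v]]$weight[lag_cmp[[v]]$model == "full"],
               logLik = f$logLik)
  }))
  utils::write.csv(lag_summary,
                   file.path(config$out_dir, "lag_model_table.csv"),
                   row.names = FALSE)
  ssf_summary <- do.call(rbind, lapply(names(ssf_fits), function(nm) {
    f <- ssf_fits[[nm]]
    cmp <- ssf_cmp[[nm]]
    data.frame(species = config$species, scale = nm,
               predictor = names(coef(f)), est = unname(coef(f)),
               se = unname(f$se), z = unname(coef(f) / f$se),
               logLik = f$logLik, AIC = AIC(f))
  }))
  if (!is.null(ssf_summary))
    utils::write.csv(ssf_summary,
                     file.path(config$out_dir, "ssf_model_table.csv"),
                     row.names = FALSE)
  jsonlite::write_json(log, file.path(config$out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(lag_fits = lag_fits, lag_comparisons = lag_cmp,
                 ssf_fits = ssf_fits, ssf_comparisons = ssf_cmp,
                 strata = strata_by_scale, uhc = uhc, log = log,
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

# intercept-only counterpart of a lag fit, for the drop-day comparison
.fit_lag_null <- function(lag_tab, response, family) {
  d <- lag_tab[lag_tab$variable == response & !lag_tab$missing, ]
  d <- data.frame(value = d$value, individual = factor(d$individual),
                  year = factor(d$year))
  if (nlevels(d$individual) < 2 || stats::var(d$value) == 0) {
    fit <- if (family == "gaussian") stats::lm(value ~ 1, data = d)
           else stats::glm(value ~ 1, data = d, family = stats::binomial())
  } else if (family == "gaussian") {
    fit <- lme4::lmer(value ~ 1 + (1 | individual) + (1 | individual:year),
                      data = d, REML = FALSE)
  } else {
    fit <- lme4::glmer(value ~ 1 + (1 | individual) + (1 | individual:year),
                       data = d, family = stats::binomial())
  }
  list(logLik = as.numeric(stats::logLik(fit)), AIC = stats::AIC(fit),
       n = nrow(d))
}

# null (beta = 0) counterpart of a conditional-logit fit
.null_clogit <- function(fit) {
  list(logLik = fit$null_logLik, AIC = -2 * fit$null_logLik,
       n_rows = fit$n_rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat("  lag models:", paste(names(x$lag_fits), collapse = ", "), "\n")
  cat("  SSF scales:", paste(names(x$ssf_fits), collapse = ", "), "\n")
  if (!is.null(x$uhc)) {
    cat("  UHC coverages:\n")
    for (pv in names(x$uhc$predictors))
      cat(sprintf("    %-14s %.3f\n", pv, x$uhc$predictors[[pv]]$coverage))
  }
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}
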