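# Used-habitat-calibration (UHC) validation of fitted step-selection
# models: compare the observed covariate distribution at chosen
# endpoints against the envelope of distributions predicted by the
# fitted model on held-out strata.

#' Split strata by individual into training and test sets
#'
#' Strata within an individual are dependent, so the split is by
#' individual (leave-individuals-out).
#'
#' @param strata Long stratum data frame.
#' @param test_fraction Fraction of individuals assigned to the test
#'   set.
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_strata <- function(strata, test_fraction = 0.3, seed = 1L) {
  set.seed(seed)
  ids <- unique(strata$individual)
  n_test <- max(1, round(test_fraction * length(ids)))
  test_ids <- sample(ids, n_test)
  list(train = strata[!(strata$individual %in% test_ids), ],
       test = strata[strata$individual %in% test_ids, ])
}

#' Used-habitat-calibration validation
#'
#' For each of `n_resamples` draws: sample coefficients
#' \eqn{\beta^* \sim N(\hat\beta, \hat V)}, compute softmax selection
#' weights within each test stratum, draw one "predicted used" endpoint
#' per stratum, and accumulate the distribution of each covariate at the
#' predicted endpoints. The envelope is the pointwise 2.5%-97.5%
#' percentile band across resamples; the observed distribution comes
#' from the actually chosen endpoints. Coverage is the fraction of grid
#' points where the observed density lies inside the envelope.
#'
#' Continuous covariates use a Gaussian kernel density (Silverman
#' bandwidth) on a 100-point grid, renormalised to integrate to 1 by the
#' trapezoid rule; binary covariates (values in \{0, 1\}) use the
#' two-cell proportion vector.
#'
#' @param fit An `ssf_clogit` fit (trained on strata disjoint from
#'   `test_strata`).
#' @param test_strata Held-out long stratum data frame.
#' @param predictors Covariates to validate; default the fit's.
#' @param n_resamples Number of resamples (default 1000; < 100 warns).
#' @param seed Integer seed; fixing it reproduces the envelope exactly.
#' @return A `uhc_result`: per predictor a list with `grid`, `observed`,
#'   `lo`, `hi`, `coverage`, `binary`; plus `n_resamples`.
#' @export
uhc_validate <- function(fit, test_strata, predictors = names(coef(fit)),
                         n_resamples = 1000, seed = 1L) {
  if (n_resamples < 100)
    warning("n_resamples < 100 gives an unstable envelope")
  V <- vcov(fit)
  R <- tryCatch(chol(V), error = function(e)
    stop("singular coefficient covariance; cannot resample"))
  beta <- coef(fit)
  set.seed(seed)
  s <- factor(test_strata[[fit$strata_col]])
  idx <- split(seq_len(nrow(test_strata)), s)
  X <- stats::model.matrix(
    stats::delete.response(stats::terms(fit$formula)), test_strata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  X <- X[, names(beta), drop = FALSE]

  vals <- lapply(predictors, function(pv) test_strata[[pv]])
  names(vals) <- predictors
  binary <- vapply(vals, function(v) all(v %in% c(0, 1)), logical(1))
  grids <- lapply(predictors, function(pv) {
    if (binary[pv]) c(0, 1)
    else seq(min(vals[[pv]]), max(vals[[pv]]), length.out = 100)
  })
  names(grids) <- predictors

  dens_on_grid <- function(v, pv) {
    g <- grids[[pv]]
    if (binary[pv]) {
      c(mean(v == 0), mean(v == 1))
    } else {
      if (stats::sd(v) == 0) {
        d <- as.numeric(abs(g - v[1]) == min(abs(g - v[1])))
      } else {
        d <- stats::density(v, bw = "nrd0", from = g[1], to = g[length(g)],
                            n = length(g))$y
      }
      area <- sum((d[-1] + d[-length(d)]) / 2 * diff(g))
      d / area
    }
  }

  n_s <- length(idx)
  pred <- lapply(predictors, function(pv)
    matrix(NA_real_, n_resamples, length(grids[[pv]])))
  names(pred) <- predictors
  for (r in seq_len(n_resamples)) {
    bstar <- beta + drop(crossprod(R, stats::rnorm(length(beta))))
    eta <- drop(X %*% bstar)
    gum <- -log(-log(stats::runif(length(eta))))  # Gumbel-max softmax draw
    score <- eta + gum
    pick <- vapply(idx, function(ix) ix[which.max(score[ix])], integer(1))
    for (pv in predictors)
      pred[[pv]][r, ] <- dens_on_grid(vals[[pv]][pick], pv)
  }

  chosen <- test_strata$case == 1
  out <- lapply(predictors, function(pv) {
    obs <- dens_on_grid(vals[[pv]][chosen], pv)
    lo <- apply(pred[[pv]], 2, stats::quantile, probs = 0.025)
    hi <- apply(pred[[pv]], 2, stats::quantile, probs = 0.975)
    list(grid = grids[[pv]], observed = obs, lo = lo, hi = hi,
         coverage = mean(obs >= lo & obs <= hi), binary = binary[[pv]])
  })
  names(out) <- predictors
  structure(list(predictors = out, n_resamples = n_resamples,
                 n_test_strata = n_s),
            class = "uhc_result")
}

#' @export
print.uhc_result <- function(x, ...) {
  cat(sprintf("UHC validation: %d test strata, %d resamples\n",
              x$n_test_strata, x$n_resamples))
  for (pv in names(x$predictors))
    cat(sprintf("  %-14s coverage %.3f%s\n", pv,
                x$predictors[[pv]]$coverage,
                if (x$predictors[[pv]]$binary) " (binary)" else ""))
  invisible(x)
}

#' Plot a UHC envelope
#'
#' Observed used-covariate density (line/points) over the predicted
#' 2.5-97.5% envelope (shaded band / whiskers for binary covariates).
#'
#' @param x A `uhc_result`.
#' @param predictor Which predictor to plot (default the first).
#' @param ... Passed to the underlying plot call.
#' @export
plot.uhc_result <- function(x, predictor = names(x$predictors)[1], ...) {
  p <- x$predictors[[predictor]]
  if (p$binary) {
    graphics::plot(p$grid, p$observed, ylim = c(0, 1), pch = 19,
                   xlab = predictor, ylab = "proportion",
                   main = sprintf("UHC: %s (coverage %.2f)", predictor,
                                  p$coverage), xaxt = "n", ...)
    graphics::axis(1, at = c(0, 1))
    graphics::arrows(p$grid, p$lo, p$grid, p$hi, angle = 90, code = 3,
                     length = 0.08, col = "grey40")
  } else {
    graphics::plot(p$grid, p$observed, type = "n",
                   ylim = range(c(p$observed, p$lo, p$hi)),
                   xlab = predictor, ylab = "density",
                   main = sprintf("UHC: %s (coverage %.2f)", predictor,
                                  p$coverage), ...)
    graphics::polygon(c(p$grid, rev(p$grid)), c(p$lo, rev(p$hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(p$grid, p$observed, lwd = 2)
  }
  invisible(x)
}

#' Write a UHC result to CSV
#'
#' @param x A `uhc_result`.
#' @param path Output path; one long CSV (predictor, grid, observed,
#'   lo, hi).
#' @export
write_uhc_csv <- function(x, path) {
  rows <- do.call(rbind, lapply(names(x$predictors), function(pv) {
    p <- x$predictors[[pv]]
    data.frame(predictor = pv, grid = p$grid, observed = p$observed,
               lo = p$lo, hi = p$hi)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
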