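# Model fitting: exact conditional logistic regression for step
# selection, mixed-model environmental lag regressions, AIC comparison
# machinery and the collinearity screen.

#' Exact conditional logistic regression for step-selection strata
#'
#' Maximises the exact conditional (stratum-softmax) log-likelihood
#' \deqn{\ell(\beta) = \sum_s [\beta' x_{chosen,s} -
#'   \log \sum_j \exp(\beta' x_{j,s})]}
#' by Newton-Raphson with analytic gradient and observed-information
#' Hessian, from a fixed start at \eqn{\beta = 0}, to a gradient-norm
#' tolerance of 1e-8. Standard errors come from the inverse observed
#' information; with `cluster` set, individual-level cluster-robust
#' (sandwich) standard errors are also computed, as a stand-in for a
#' stratum-in-individual random effect.
#'
#' Predictors without within-stratum variation carry no information in
#' the conditional likelihood and are dropped with a warning. Complete
#' separation (a predictor that perfectly discriminates the chosen
#' endpoint) makes the likelihood unbounded; divergence is detected and
#' reported as an error naming the predictor.
#'
#' @param formula Model formula, e.g. `case ~ snow + wind_support +
#'   crosswind`. No intercept is fitted (it is not identifiable under
#'   conditioning).
#' @param data Long stratum data frame (one row per endpoint) such as
#'   [build_strata()] output.
#' @param strata Name of the stratum id column (default `"stratum"`).
#' @param cluster Optional name of the clustering column (e.g.
#'   `"individual"`) for robust standard errors.
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `ssf_clogit` with `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `nobs`, `predict` and `simulate` methods.
#'   `AIC()` works through `logLik`.
#' @export
fit_clogit <- function(formula, data, strata = "stratum", cluster = NULL,
                       tol = 1e-8, max_iter = 50L) {
  stopifnot(strata %in% names(data))
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[vars]) & !is.na(data[[strata]])
  d0 <- data[cc, , drop = FALSE]
  mf <- stats::model.frame(formula, data = d0, na.action = NULL)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  s <- factor(d0[[strata]])
  # keep only complete strata with exactly one chosen endpoint
  ok_str <- tapply(y, s, function(v) sum(v) == 1 && length(v) >= 2)
  keep2 <- ok_str[as.character(s)]
  y <- y[keep2]; X <- X[keep2, , drop = FALSE]; s <- droplevels(s[keep2])
  n_strata <- nlevels(s)
  if (n_strata < 2) stop("need at least 2 usable strata")
  si <- as.integer(s)

  # drop predictors with no within-stratum variation
  dropped <- character(0)
  for (cn in colnames(X)) {
    wv <- tapply(X[, cn], si, function(v) max(v) - min(v))
    if (all(wv < 1e-12)) dropped <- c(dropped, cn)
  }
  if (length(dropped) > 0) {
    warning("no within-stratum variation; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  p <- ncol(X)
  null_ll <- -sum(log(tabulate(si)))

  if (p == 0) {
    fit <- list(coefficients = numeric(0), se = numeric(0),
                vcov = matrix(0, 0, 0), logLik = null_ll)
    iter <- 0L; converged <- TRUE; grad <- numeric(0)
  } else {
    beta <- rep(0, p)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      m <- as.numeric(tapply(eta, si, max))[si]
      w <- exp(eta - m)
      pr <- as.numeric(w / rowsum(w, si)[si])
      grad <- colSums(X[y == 1, , drop = FALSE]) - colSums(X * pr)
      A <- crossprod(X, X * pr)
      M <- rowsum(X * pr, si)
      H <- A - crossprod(M)                     # observed information
      if (max(abs(beta)) > 20) {
        worst <- colnames(X)[which.max(abs(beta))]
        stop("complete separation detected for predictor '", worst,
             "': conditional likelihood has no finite maximum")
      }
      if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
      step <- tryCatch(solve(H, grad), error = function(e)
        stop("singular information matrix; predictors may be collinear"))
      beta <- beta + step
    }
    if (!converged && sqrt(sum(grad^2)) >= tol)
      warning("Newton iteration did not converge in ", max_iter, " steps")
    eta <- drop(X %*% beta)
    m_s <- as.numeric(tapply(eta, si, max))
    m <- m_s[si]
    w <- exp(eta - m)
    Zs <- as.numeric(rowsum(w, si))
    ll <- sum(eta[y == 1]) - sum(log(Zs) + m_s)
    pr <- as.numeric(w / Zs[si])
    A <- crossprod(X, X * pr)
    M <- rowsum(X * pr, si)
    H <- A - crossprod(M)
    V <- solve(H)
    fit <- list(coefficients = stats::setNames(beta, colnames(X)),
                se = stats::setNames(sqrt(diag(V)), colnames(X)),
                vcov = V, logLik = ll)
  }

  robust <- NULL
  if (!is.null(cluster) && p > 0) {
    cl <- d0[[cluster]][keep2]
    # per-stratum score contributions, summed within cluster
    gsc <- rowsum(X * y, si) - rowsum(X * pr, si)
    cl_s <- tapply(as.character(cl), si, function(v) v[1])
    G <- rowsum(gsc, cl_s)
    meat <- crossprod(G)
    Vr <- fit$vcov %*% meat %*% fit$vcov
    robust <- list(vcov = Vr,
                   se = stats::setNames(sqrt(diag(Vr)), colnames(X)))
  }

  structure(list(coefficients = fit$coefficients, se = fit$se,
                 vcov = fit$vcov, logLik = fit$logLik,
                 null_logLik = null_ll, df = p, n_strata = n_strata,
                 n_rows = length(y), dropped = dropped, robust = robust,
                 iterations = if (p > 0) iter else 0L,
                 converged = converged, formula = formula,
                 strata_col = strata, cluster_col = cluster,
                 call = match.call()),
            class = "ssf_clogit")
}

#' @export
print.ssf_clogit <- function(x, ...) {
  cat("Conditional logistic step-selection fit\n")
  cat(sprintf("  %d strata, %d endpoints, logLik %.2f, AIC %.2f\n",
              x$n_strata, x$n_rows, x$logLik, AIC(x)))
  if (length(x$coefficients)) {
    print(round(rbind(coef = x$coefficients, se = x$se), 4))
  } else cat("  (no estimable predictors)\n")
  invisible(x)
}

#' @export
coef.ssf_clogit <- function(object, ...) object$coefficients

#' @export
vcov.ssf_clogit <- function(object, robust = FALSE, ...) {
  if (robust) {
    if (is.null(object$robust)) stop("fit has no cluster-robust vcov")
    object$robust$vcov
  } else object$vcov
}

#' @export
logLik.ssf_clogit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_strata,
            class = "logLik")
}

#' @export
nobs.ssf_clogit <- function(object, ...) object$n_strata

#' @export
summary.ssf_clogit <- function(object, robust = FALSE, ...) {
  se <- if (robust && !is.null(object$robust)) object$robust$se else object$se
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, logLik = object$logLik,
                 AIC = AIC(object), n_strata = object$n_strata,
                 robust = robust, dropped = object$dropped),
            class = "summary.ssf_clogit")
}

#' @export
print.summary.ssf_clogit <- function(x, ...) {
  cat("Conditional logistic step-selection fit",
      if (x$robust) "(cluster-robust SEs)" else "", "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("logLik %.2f   AIC %.2f   strata %d\n",
              x$logLik, x$AIC, x$n_strata))
  if (length(x$dropped))
    cat("dropped (no within-stratum variation):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Within-stratum choice probabilities
#'
#' @param object An `ssf_clogit` fit.
#' @param newdata Long stratum data frame with the model's predictors
#'   and stratum column.
#' @param ... Unused.
#' @return Numeric vector of softmax probabilities, summing to 1 within
#'   each stratum.
#' @export
predict.ssf_clogit <- function(object, newdata, ...) {
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           newdata)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  X <- X[, names(object$coefficients), drop = FALSE]
  s <- factor(newdata[[object$strata_col]])
  si <- as.integer(s)
  eta <- drop(X %*% object$coefficients)
  m <- as.numeric(tapply(eta, si, max))[si]
  w <- exp(eta - m)
  as.numeric(w / rowsum(w, si)[si])
}

#' Simulate chosen endpoints from a fitted step-selection model
#'
#' Draws, for each stratum in `newdata`, one endpoint according to the
#' fitted softmax probabilities.
#'
#' @param object An `ssf_clogit` fit.
#' @param nsim Number of replicate draws.
#' @param seed Optional seed.
#' @param newdata Long stratum data frame.
#' @param ... Unused.
#' @return A logical matrix (`nrow(newdata)` x `nsim`); each column has
#'   exactly one `TRUE` per stratum.
#' @export
simulate.ssf_clogit <- function(object, nsim = 1, seed = NULL,
                                newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata)
  s <- factor(newdata[[object$strata_col]])
  idx <- split(seq_len(nrow(newdata)), s)
  out <- matrix(FALSE, nrow(newdata), nsim)
  for (k in seq_len(nsim)) {
    pick <- vapply(idx, function(ix)
      ix[sample.int(length(ix), 1, prob = pr[ix])], integer(1))
    out[pick, k] <- TRUE
  }
  out
}

#' Mixed-model regression of environmental value on lag day
#'
#' Fits `value ~ day` with random intercepts for individual and
#' year-within-individual, for one variable of a lag table: gaussian
#' family by maximum likelihood (temperature, day length, NDVI) or
#' binomial by Laplace-approximated marginal likelihood (snow), via
#' lme4. With fewer than 2 individuals the model falls back to a
#' fixed-effects `lm`/`glm` with a warning. A constant response returns
#' a degenerate zero-slope fit, flagged.
#'
#' @param lag_tab Long lag table from [lag_table()] / [lag_extract()].
#' @param response Variable name to model (e.g. `"snow"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A `lag_fit`: slope estimate/SE/statistic, logLik, AIC, the
#'   underlying fit, and metadata.
#' @export
fit_lag_model <- function(lag_tab, response,
                          family = if (response == "snow") "binomial"
                                   else "gaussian") {
  d <- lag_tab[lag_tab$variable == response & !lag_tab$missing, ]
  if (nrow(d) == 0) stop("no rows for variable '", response, "'")
  d <- data.frame(value = d$value, day = d$lag,
                  individual = factor(d$individual),
                  year = factor(d$year))
  degenerate <- stats::var(d$value) == 0
  if (degenerate) {
    fit <- NULL
    est <- c(`(Intercept)` = d$value[1], day = 0)
    se <- c(NA_real_, 0)
    ll <- NA_real_; aic <- NA_real_
    warning("constant response; returning degenerate zero-slope fit")
  } else if (nlevels(d$individual) < 2) {
    warning("fewer than 2 individuals; falling back to fixed-effects fit")
    fit <- if (family == "gaussian") stats::lm(value ~ day, data = d)
           else stats::glm(value ~ day, data = d, family = stats::binomial())
    cf <- summary(fit)$coefficients
    est <- cf[, 1]; se <- cf[, 2]
    ll <- as.numeric(stats::logLik(fit)); aic <- stats::AIC(fit)
  } else {
    if (family == "gaussian") {
      fit <- lme4::lmer(value ~ day + (1 | individual) + (1 | individual:year),
                        data = d, REML = FALSE)
    } else {
      fit <- lme4::glmer(value ~ day + (1 | individual) + (1 | individual:year),
                         data = d, family = stats::binomial())
    }
    cf <- stats::coef(summary(fit))
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    ll <- as.numeric(stats::logLik(fit)); aic <- stats::AIC(fit)
  }
  structure(list(response = response, family = family,
                 coefficients = est, se = se,
                 slope = unname(est["day"]), slope_se = unname(se[2]),
                 statistic = unname(est["day"] / se[2]),
                 logLik = ll, AIC = aic, n = nrow(d),
                 n_individuals = nlevels(d$individual),
                 degenerate = degenerate, fit = fit),
            class = "lag_fit")
}

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("Lag model: %s ~ day (%s), %d rows, %d individuals\n",
              x$response, x$family, x$n, x$n_individuals))
  cat(sprintf("  day slope %.4f (SE %.4f), logLik %.1f, AIC %.1f%s\n",
              x$slope, x$slope_se, x$logLik, x$AIC,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
coef.lag_fit <- function(object, ...) object$coefficients

#' @export
logLik.lag_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' Compare models by AIC
#'
#' Computes AIC differences to the best model and Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}. Models with
#' `dAIC` strictly greater than 2 relative to the best are flagged as
#' `different` (the best-supported model is better by convention
#' `dAIC > 2`). All fits must be on identical data (same number of
#' rows), otherwise an error is raised.
#'
#' @param ... Named model fits (anything with `AIC()` and `nobs()` or an
#'   `n`/`n_rows` element), or a single named list of them.
#' @return A `model_comparison` data frame: `model`, `logLik`, `AIC`,
#'   `dAIC`, `weight`, `different`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && is.null(fits[[1]]$logLik) &&
      !inherits(fits[[1]], c("ssf_clogit", "lag_fit")))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  nrows <- vapply(fits, function(f) {
    if (!is.null(f$n_rows)) f$n_rows
    else if (!is.null(f$n)) f$n
    else as.integer(stats::nobs(f))
  }, numeric(1))
  if (length(unique(nrows)) > 1)
    stop("models were fitted to differing numbers of rows: ",
         paste(nrows, collapse = ", "))
  aic <- vapply(fits, function(f)
    if (!is.null(f$AIC) && !is.function(f$AIC)) f$AIC else stats::AIC(f),
    numeric(1))
  ll <- vapply(fits, function(f)
    if (is.numeric(f$logLik)) f$logLik else as.numeric(stats::logLik(f)),
    numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(model = names(fits), logLik = ll, AIC = aic, dAIC = d,
                    weight = w, different = d > 2, row.names = NULL)
  out <- out[order(out$AIC), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (dAIC > 2 flagged as different)\n")
  y <- as.data.frame(x)
  y$logLik <- round(y$logLik, 1); y$AIC <- round(y$AIC, 1)
  y$dAIC <- round(y$dAIC, 2); y$weight <- round(y$weight, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Pairwise collinearity screen
#'
#' Pearson correlations between candidate predictors; pairs at or above
#' the threshold (default 0.7) are flagged for exclusion from a common
#' model. Zero-variance predictors (undefined correlation) are flagged
#' separately.
#'
#' @param data Data frame containing the predictors.
#' @param predictors Character vector of column names.
#' @param threshold Absolute-correlation flag threshold.
#' @return List of class `collinearity_screen`: `correlations` (matrix),
#'   `flagged` (data frame of offending pairs), `zero_variance`
#'   (character).
#' @export
screen_collinearity <- function(data, predictors, threshold = 0.7) {
  stopifnot(nrow(data) >= 3, all(predictors %in% names(data)))
  X <- as.matrix(data[predictors])
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  zero_var <- predictors[sds == 0 | is.na(sds)]
  ok <- setdiff(predictors, zero_var)
  cm <- matrix(NA_real_, length(predictors), length(predictors),
               dimnames = list(predictors, predictors))
  if (length(ok) >= 2)
    cm[ok, ok] <- stats::cor(X[, ok, drop = FALSE],
                             use = "pairwise.complete.obs")
  diag(cm) <- 1
  pairs <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(cm)[pairs[, 1]],
                        var2 = colnames(cm)[pairs[, 2]],
                        r = cm[pairs])
  structure(list(correlations = cm, flagged = flagged,
                 zero_variance = zero_var, threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| >= %.2f flagged)\n", x$threshold))
  print(round(x$correlations, 3))
  if (nrow(x$flagged)) {
    cat("Flagged pairs:\n"); print(x$flagged, row.names = FALSE)
  } else cat("No pairs flagged.\n")
  if (length(x$zero_variance))
    cat("Zero-variance (correlation undefined):",
        paste(x$zero_variance, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' @param fit An `ssf_clogit` or `lag_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(class = class(fit)[1],
            coefficients = as.list(fit$coefficients),
            se = as.list(fit$se),
            logLik = fit$logLik,
            AIC = if (inherits(fit, "ssf_clogit")) AIC(fit) else fit$AIC,
            n = if (!is.null(fit$n_strata)) fit$n_strata else fit$n)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
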