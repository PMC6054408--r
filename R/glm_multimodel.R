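# Logistic-regression core and the multi-model machinery: univariate scale
# scans, p-value screening, collinearity pruning, all-subsets enumeration,
# Akaike weights, full model averaging with unconditional SEs, and relative
# variable importance.

#' Fit a logistic regression
#'
#' Maximum-likelihood binomial fit (IRLS via `stats::glm.fit`) on an explicit
#' design matrix. Wald standard errors come from the inverse observed
#' information at the optimum; p-values are two-sided normal. A fit whose
#' coefficients diverge (|beta| > 50 on the standardized scale) or whose
#' information matrix is singular is flagged non-converged and is excluded
#' from model ensembles.
#'
#' @param y 0/1 response vector.
#' @param X Design matrix (include the intercept column explicitly); column
#'   names label the coefficients.
#' @return A `logit_fit`: `coef`, `se`, `z`, `p`, `loglik`, `n`, `k`, `aic`,
#'   `aicc`, `converged`.
#' @export
fit_logistic <- function(y, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  n <- length(y); k <- ncol(X)
  if (nrow(X) != n) stop("nrow(X) != length(y)")
  if (n <= k) stop("need n > number of parameters")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100L)))
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  p_hat <- stats::plogis(eta)
  loglik <- sum(y * log(pmax(p_hat, 1e-300)) +
                  (1 - y) * log(pmax(1 - p_hat, 1e-300)))
  w <- p_hat * (1 - p_hat)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, k) else sqrt(diag(cov))
  names(se) <- names(beta)
  aic <- 2 * k - 2 * loglik
  aicc <- if (n > k + 1) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  converged <- isTRUE(fit$converged) && all(is.finite(beta)) &&
    all(abs(beta) <= 50) && all(is.finite(se))
  z <- beta / se
  structure(list(coef = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 loglik = loglik, n = n, k = k, aic = aic, aicc = aicc,
                 converged = converged),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, k = %d, loglik = %.3f, AIC = %.2f, AICc = %.2f%s\n",
              x$n, x$k, x$loglik, x$aic, x$aicc,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(data.frame(beta = x$coef, se = x$se, z = x$z, p = x$p), 4))
  invisible(x)
}

# ---- univariate scale scan ---------------------------------------------------

#' Univariate scale scan for one habitat covariate
#'
#' Fits `base + covariate(scale)` at each analysis scale and selects the
#' scale with the lowest AIC (ties go to the smallest radius). Non-converged
#' scales are excluded from the minimum but recorded.
#'
#' @param y 0/1 occurrence vector.
#' @param var_by_scale Named list (names = radii in metres) of station-value
#'   vectors or [extract_standardize()] results, one per scale.
#' @param base Design matrix of terms present in every fit (intercept,
#'   effort).
#' @param name Covariate name.
#' @return A `scale_scan`: per-scale AIC/coefficient/p profile, `best_scale`,
#'   and the best-scale fit.
#' @export
scale_scan <- function(y, var_by_scale, base, name = "covariate") {
  scales <- as.numeric(names(var_by_scale))
  if (anyNA(scales) || is.unsorted(scales))
    stop("`var_by_scale` must be named by ascending radii")
  fits <- lapply(var_by_scale, function(v) {
    vals <- if (inherits(v, "scaled_covariate")) v$values else as.numeric(v)
    X <- cbind(base, vals)
    colnames(X)[ncol(X)] <- name
    fit_logistic(y, X)
  })
  aic <- vapply(fits, function(f) if (f$converged) f$aic else NA_real_, 0)
  if (all(is.na(aic))) stop("no scale converged for ", name)
  best_i <- which.min(aic)                      # first minimum = smallest radius
  structure(list(
    variable = name, scales = scales, aic = aic,
    coef = vapply(fits, function(f) unname(f$coef[name]), 0),
    se = vapply(fits, function(f) unname(f$se[name]), 0),
    p = vapply(fits, function(f) unname(f$p[name]), 0),
    best_scale = scales[best_i], best_fit = fits[[best_i]],
    best_p = unname(fits[[best_i]]$p[name])),
    class = "scale_scan")
}

#' @export
print.scale_scan <- function(x, ...) {
  cat(sprintf("<scale_scan> %s: best scale %g m (AIC %.2f, p = %.4f)\n",
              x$variable, x$best_scale, min(x$aic, na.rm = TRUE), x$best_p))
  print(round(data.frame(scale_m = x$scales, AIC = x$aic, beta = x$coef,
                         p = x$p), 4))
  invisible(x)
}

#' Screen covariates on their best-scale univariate p-value
#'
#' Retains covariates whose best-scale univariate slope has p <= `p_threshold`
#' (the conventional liberal pre-screen before multi-model inference).
#'
#' @param scans List of [scale_scan()] results.
#' @param p_threshold Retention threshold (default 0.2; variables with
#'   p > 0.2 are removed).
#' @return Character vector of retained covariate names.
#' @export
screen_variables <- function(scans, p_threshold = 0.2) {
  if (!length(scans)) return(character(0))
  keep <- vapply(scans, function(s) s$best_p <= p_threshold, TRUE)
  vapply(scans[keep], `[[`, "", "variable")
}

#' Prune collinear covariates
#'
#' Resolves every pair with `|Pearson r| > r_threshold` by dropping the
#' member with the higher (worse) univariate AIC. Pairs are processed in
#' descending `|r|`; once a variable is dropped it cannot cause further
#' drops.
#'
#' @param X Matrix of station values, one column per (scale-optimised)
#'   covariate.
#' @param aic Named vector of the covariates' best-scale univariate AICs.
#' @param r_threshold Correlation threshold (strict `>`; default 0.7).
#' @return Character vector of retained column names.
#' @export
prune_collinear <- function(X, aic, r_threshold = 0.7) {
  vars <- colnames(X)
  if (is.null(vars) || !all(vars %in% names(aic)))
    stop("`X` columns must be named and matched in `aic`")
  if (ncol(X) < 2L) return(vars)
  r <- stats::cor(X)
  pairs <- which(upper.tri(r) & abs(r) > r_threshold, arr.ind = TRUE)
  if (!nrow(pairs)) return(vars)
  ord <- order(-abs(r[pairs]))
  pairs <- pairs[ord, , drop = FALSE]
  alive <- stats::setNames(rep(TRUE, length(vars)), vars)
  for (i in seq_len(nrow(pairs))) {
    a <- vars[pairs[i, 1L]]; b <- vars[pairs[i, 2L]]
    if (alive[a] && alive[b]) {
      drop_var <- if (aic[a] > aic[b]) a else b
      alive[drop_var] <- FALSE
    }
  }
  vars[alive[vars]]
}

# ---- all-subsets ensembles ---------------------------------------------------

#' All-subsets logistic regression ensemble
#'
#' Fits every subset of the free terms (2^p models), each containing the
#' forced terms (intercept, effort), and weights the converged models by
#' `exp(-delta/2)` of the chosen information criterion, normalized to sum
#' to 1.
#'
#' @param y 0/1 response.
#' @param X_free Matrix of candidate terms (at most 15 columns).
#' @param X_forced Matrix of terms forced into every model (include the
#'   intercept column).
#' @param criterion `"AICc"` (default, small-sample corrected) or `"AIC"`.
#' @return A `model_ensemble`: per-model masks, fits, delta and Akaike
#'   weight, plus the design pieces for prediction.
#' @export
all_subsets <- function(y, X_free, X_forced, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  if (!is.matrix(X_free)) X_free <- as.matrix(X_free)
  p <- ncol(X_free)
  if (p > 15L)
    stop("more than 15 free terms (", p,
         "); pre-screen candidates before all-subsets enumeration")
  free_names <- colnames(X_free)
  masks <- lapply(seq_len(2^p) - 1L, function(m)
    as.logical(bitwAnd(m, bitwShiftL(1L, seq_len(p) - 1L)) > 0L))
  if (p == 0L) masks <- list(logical(0))
  fits <- lapply(masks, function(msk)
    fit_logistic(y, cbind(X_forced, X_free[, msk, drop = FALSE])))
  ok <- vapply(fits, `[[`, TRUE, "converged")
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no subset model converged")
  masks <- masks[ok]; fits <- fits[ok]
  crit <- vapply(fits, function(f)
    if (criterion == "AICc") f$aicc else f$aic, 0)
  delta <- crit - min(crit)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(list(free_terms = free_names, forced_terms = colnames(X_forced),
                 masks = masks, fits = fits, criterion = criterion,
                 crit = crit, delta = delta, weight = w,
                 n_dropped = n_dropped, y = y,
                 X_free = X_free, X_forced = X_forced),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models over %d free terms (+%d forced), %s weights%s\n",
              length(x$fits), length(x$free_terms), length(x$forced_terms),
              x$criterion,
              if (x$n_dropped) sprintf(", %d non-converged dropped", x$n_dropped)
              else ""))
  cat(sprintf("  best model %s = %.2f, top weight %.3f\n",
              x$criterion, min(x$crit), max(x$weight)))
  invisible(x)
}

#' Full model averaging over an all-subsets ensemble
#'
#' Averaged coefficient per term is the Akaike-weighted mean with absent
#' terms contributing zero; the adjusted (unconditional) SE is the square
#' root of `sum w_i * (SE_i^2 + (beta_i - beta_bar)^2)` with absent terms
#' contributing zero for both; importance is the summed weight of models
#' containing the term (1 by construction for forced terms). z is
#' `|beta_bar| / SE` with a two-sided normal p-value.
#'
#' @param ensemble An [all_subsets()] result.
#' @return A `model_average` data frame: `term`, `estimate`, `adj_se`, `z`,
#'   `p`, `importance`.
#' @export
model_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  terms <- c(ensemble$forced_terms, ensemble$free_terms)
  w <- ensemble$weight
  rows <- lapply(terms, function(t) {
    beta_i <- vapply(ensemble$fits, function(f)
      if (t %in% names(f$coef)) unname(f$coef[t]) else 0, 0)
    se_i <- vapply(ensemble$fits, function(f)
      if (t %in% names(f$se)) unname(f$se[t]) else 0, 0)
    present <- vapply(seq_along(ensemble$fits), function(i)
      t %in% names(ensemble$fits[[i]]$coef), TRUE)
    bbar <- sum(w * beta_i)
    var_u <- sum(w * (se_i^2 + (beta_i - bbar)^2))
    se <- sqrt(var_u)
    z <- abs(bbar) / se
    data.frame(term = t, estimate = bbar, adj_se = se, z = z,
               p = 2 * stats::pnorm(-z), importance = sum(w[present]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_average", "data.frame")
  out
}
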