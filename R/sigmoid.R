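#' Four-parameter sigmoid
#'
#' \deqn{y = a + \frac{b}{1 + e^{-(x - c)/d}}}
#' `a` is the low-x asymptote, `b` the total change between asymptotes
#' (negative for a decline), `c` the inflection location in biomarker units
#' and `d > 0` the steepness.
#'
#' @param x Numeric vector.
#' @param a,b,c,d Sigmoid parameters; `d` must be positive.
#' @return Numeric vector of responses.
#' @examples
#' evaluate_sigmoid(1.228, a = -3, b = 3, c = 1.228, d = 0.02)  # -1.5
#' @export
evaluate_sigmoid <- function(x, a, b, c, d) {
  if (any(d <= 0)) stop("'d' must be > 0", call. = FALSE)
  a + b / (1 + exp(-(x - c) / d))
}

# Small-sample (second-order) Akaike criterion. k counts fitted parameters
# plus one for the residual variance. RSS = 0 maps to -Inf, which compares
# correctly (a perfect fit is always preferred).
aicc_from_rss <- function(n, rss, k, small_sample = TRUE) {
  aic <- n * log(rss / n) + 2 * k
  if (!small_sample) return(aic)
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the four-parameter sigmoid to a threshold curve
#'
#' Weighted least squares via multi-start Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with the steepness constrained positive.
#' Starting points cover `a` at both response extremes, `c` at the 25/50/75%
#' x-quantiles, `d` at x-range/30, /10 and the full range, plus one start
#' linearized from the OLS fit so the optimizer always has a configuration
#' at least as good as the straight line. The best-RSS solution is kept.
#'
#' @param curve A [threshold_curve()] (needs >= 6 points spanning a
#'   nondegenerate x range).
#' @param weights Optional per-point weights (e.g. `curve$tail_count` to
#'   down-weight noisy small-tail points); default unweighted.
#' @param small_sample Use AICc (default) rather than plain AIC.
#' @return An object of class `sigmoid_fit`: parameters `a`, `b`, `c`, `d`,
#'   diagnostics `rss`, `r_squared`, `f_stat`, `f_p`, `aicc`, `converged`,
#'   the asymptotic `c_se` and `c_ci95`, the data size `n` and `x_range`.
#'   When no start converges, `converged` is `FALSE` and the diagnostics are
#'   `NA`.
#' @export
fit_sigmoid <- function(curve, weights = NULL, small_sample = TRUE) {
  x <- curve$threshold
  y <- curve$mean_response
  n <- length(x)
  if (n < 6L) stop("need at least 6 curve points", call. = FALSE)
  if (diff(range(x)) <= 0) stop("degenerate x range", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("constant response: sigmoid location is not identified",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)

  x_rng <- diff(range(x))
  trend <- sign(stats::cor(x, y))
  if (is.na(trend) || trend == 0) trend <- 1
  b0 <- trend * diff(range(y))
  starts <- expand.grid(
    a = c(min(y), max(y)),
    c = unname(stats::quantile(x, c(0.25, 0.5, 0.75))),
    d = x_rng * c(1 / 30, 1 / 10, 1))
  starts$b <- b0
  # linearized start: a sigmoid that reproduces the OLS line over the data
  ols <- stats::lm.wfit(cbind(1, x), y, weights)
  d_lin <- 10 * x_rng
  b_lin <- ols$coefficients[2] * 4 * d_lin
  c_lin <- mean(range(x))
  a_lin <- ols$coefficients[1] + ols$coefficients[2] * c_lin - b_lin / 2
  starts <- rbind(starts,
                  data.frame(a = a_lin, c = c_lin, d = d_lin, b = b_lin))

  model <- function(p) p[1] + p[2] / (1 + exp(-(x - p[3]) / p[4]))
  resid_fn <- function(p) sw * (y - model(p))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$a[i], starts$b[i], starts$c[i], starts$d[i])
    # individual starts may fail or stall; only the best solution matters
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      lower = c(-Inf, -Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, hessian = fit$hessian)
  }
  if (is.null(best)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          d = NA_real_, rss = NA_real_, r_squared = NA_real_,
                          f_stat = NA_real_, f_p = NA_real_, aicc = NA_real_,
                          converged = FALSE, c_se = NA_real_,
                          c_ci95 = c(NA_real_, NA_real_), n = n,
                          x_range = range(x), fitted = rep(NA_real_, n)),
                     class = "sigmoid_fit"))
  }
  p <- best$par
  fitted <- model(p)
  rss <- best$rss
  tss <- sum(weights * (y - stats::weighted.mean(y, weights))^2)
  r_squared <- 1 - rss / tss
  n_par <- 4L
  f_stat <- if (rss > 0)
    ((tss - rss) / (n_par - 1)) / (rss / (n - n_par)) else Inf
  f_p <- stats::pf(f_stat, n_par - 1, n - n_par, lower.tail = FALSE)

  # asymptotic covariance from the weighted Jacobian at the solution
  jac <- sigmoid_jacobian(p, x) * sw
  c_se <- NA_real_
  if (n > n_par && rss >= 0) {
    sigma2 <- rss / (n - n_par)
    jtj_inv <- try(solve(crossprod(jac)), silent = TRUE)
    if (!inherits(jtj_inv, "try-error") && all(is.finite(diag(jtj_inv))))
      c_se <- sqrt(pmax(0, sigma2 * jtj_inv[3, 3]))
  }
  tcrit <- stats::qt(0.975, n - n_par)
  c_ci95 <- if (is.na(c_se)) c(NA_real_, NA_real_)
            else p[3] + c(-1, 1) * tcrit * c_se

  structure(list(a = p[1], b = p[2], c = p[3], d = p[4],
                 rss = rss, r_squared = r_squared,
                 f_stat = f_stat, f_p = f_p,
                 aicc = aicc_from_rss(n, rss, n_par + 1L, small_sample),
                 converged = TRUE, c_se = c_se, c_ci95 = c_ci95,
                 n = n, x_range = range(x), fitted = fitted),
            class = "sigmoid_fit")
}

sigmoid_jacobian <- function(p, x) {
  z <- (x - p[3]) / p[4]
  l <- stats::plogis(z)
  dl <- l * (1 - l)
  cbind(1, l, -p[2] * dl / p[4], -p[2] * dl * z / p[4])
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sigmoid fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Sigmoid fit: a=%.4g b=%.4g c=%.6g d=%.4g | R2=%.4f AICc=%.2f\n",
    x$a, x$b, x$c, x$d, x$r_squared, x$aicc))
  if (!is.na(x$c_se))
    cat(sprintf("  inflection c = %.6g (95%% CI %.6g to %.6g)\n",
                x$c, x$c_ci95[1], x$c_ci95[2]))
  invisible(x)
}

#' Fit a straight line to a threshold curve
#'
#' Ordinary (optionally weighted) least squares, the linear competitor for
#' the sigmoid in AICc model comparison.
#'
#' @inheritParams fit_sigmoid
#' @return List of class `linear_fit` with `slope`, `intercept`, `rss`,
#'   `r_squared`, `aicc`, `n`.
#' @export
fit_linear <- function(curve, weights = NULL, small_sample = TRUE) {
  x <- curve$threshold
  y <- curve$mean_response
  n <- length(x)
  if (n < 3L) stop("need at least 3 curve points", call. = FALSE)
  if (diff(range(x)) <= 0) stop("degenerate x range", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  fit <- stats::lm.wfit(cbind(1, x), y, weights)
  rss <- sum(weights * fit$residuals^2)
  tss <- sum(weights * (y - stats::weighted.mean(y, weights))^2)
  structure(list(intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 aicc = aicc_from_rss(n, rss, 3L, small_sample),
                 n = n),
            class = "linear_fit")
}

#' Compare linear and sigmoid fits by AICc
#'
#' The preferred model is the one with the lower AICc; its probability of
#' correctness is the two-model Akaike weight
#' \eqn{1 / (1 + e^{-\Delta/2})} with \eqn{\Delta} the absolute AICc
#' difference. The two model probabilities sum to one.
#'
#' @param linear A [fit_linear()] result.
#' @param sigmoid A [fit_sigmoid()] result.
#' @return List with `preferred` (`"linear"` or `"sigmoid"`), `delta_aicc`,
#'   `prob_correct` (of the preferred model) and the two model
#'   probabilities.
#' @export
compare_models_aicc <- function(linear, sigmoid) {
  stopifnot(inherits(linear, "linear_fit"), inherits(sigmoid, "sigmoid_fit"))
  if (!isTRUE(sigmoid$converged))
    stop("sigmoid fit did not converge", call. = FALSE)
  if (linear$n != sigmoid$n)
    stop("fits are not on identical data (point counts differ)",
         call. = FALSE)
  delta <- abs(linear$aicc - sigmoid$aicc)
  preferred <- if (sigmoid$aicc <= linear$aicc) "sigmoid" else "linear"
  p_pref <- 1 / (1 + exp(-delta / 2))
  probs <- c(sigmoid = NA_real_, linear = NA_real_)
  probs[preferred] <- p_pref
  probs[setdiff(names(probs), preferred)] <- 1 - p_pref
  list(preferred = preferred, delta_aicc = delta,
       prob_correct = p_pref, model_probabilities = probs)
}

#' Read the imminent-decline threshold off a sigmoid fit
#'
#' The threshold is the fitted inflection location `c` with its asymptotic
#' 95% confidence interval. When `c` falls outside the observed biomarker
#' range the estimate is an extrapolation and flagged as such.
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @return List with `threshold`, `ci95`, `extrapolated`.
#' @export
estimate_threshold <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged))
    stop("cannot estimate a threshold from a non-converged fit",
         call. = FALSE)
  list(threshold = fit$c,
       ci95 = fit$c_ci95,
       extrapolated = fit$c < fit$x_range[1] || fit$c > fit$x_range[2])
}
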