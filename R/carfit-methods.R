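#' @export
print.carfit <- function(x, ...) {
  cat(sprintf("Bayesian %s CAR model, %d areas, %d retained draws\n",
              toupper(x$model), length(x$y), nrow(x$draws$s)))
  cat("call: "); print(x$call)
  cat("posterior mean coefficients:\n")
  print(round(colMeans(x$draws$beta), 4))
  if (x$model == "leroux")
    cat(sprintf("posterior mean rho = %.3f, sigma_s^2 = %.4f\n",
                mean(x$draws$rho), mean(x$draws$sigma_s2)))
  else
    cat(sprintf("posterior mean sigma_s^2 = %.4f, sigma_u^2 = %.4f\n",
                mean(x$draws$sigma_s2), mean(x$draws$sigma_u2)))
  invisible(x)
}

#' Summarise a CAR model fit
#'
#' Posterior means, standard deviations and central 95% credible intervals
#' for the regression coefficients and variance parameters, plus sampler
#' acceptance rates and effective sample sizes (lag-autocorrelation
#' estimator) for the scalar parameters.
#'
#' @param object a [fit_car()] object.
#' @param ... unused.
#' @return a `summary.carfit` list with a coefficient table and diagnostics.
#' @export
summary.carfit <- function(object, ...) {
  d <- object$draws
  pars <- cbind(d$beta, sigma_s2 = d$sigma_s2)
  if (object$model == "leroux") pars <- cbind(pars, rho = d$rho)
  else pars <- cbind(pars, sigma_u2 = d$sigma_u2)
  tab <- t(apply(pars, 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      `2.5%` = unname(stats::quantile(v, 0.025)),
      `97.5%` = unname(stats::quantile(v, 0.975)),
      n_eff = ess(v))
  }))
  out <- list(model = object$model, coefficients = tab,
              accept = object$accept, n = length(object$y),
              draws = nrow(d$s))
  class(out) <- "summary.carfit"
  out
}

#' @export
print.summary.carfit <- function(x, ...) {
  cat(sprintf("Bayesian %s CAR model: %d areas, %d retained draws\n\n",
              toupper(x$model), x$n, x$draws))
  print(round(x$coefficients, 4))
  cat("\nacceptance rates:\n")
  print(round(x$accept[!is.na(x$accept)], 3))
  invisible(x)
}

# effective sample size via initial positive sequence of autocorrelations
ess <- function(v) {
  M <- length(v)
  if (stats::sd(v) == 0) return(NA_real_)
  ac <- stats::acf(v, lag.max = min(M - 1L, 100L), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  L <- if (length(pos)) pos[1] - 1L else length(ac)
  M / (1 + 2 * sum(ac[seq_len(L)]))
}

#' @export
coef.carfit <- function(object, ...) colMeans(object$draws$beta)

#' @export
fitted.carfit <- function(object, ...) {
  out <- object$E * colMeans(exp(object$draws$mu))
  names(out) <- object$graph$ids
  out
}

#' Posterior-median model residuals
#'
#' \eqn{\epsilon_i = E_i e^{\mu_i} - y_i} for the Leroux model and
#' \eqn{E_i e^{\mu_i - u_i} - y_i} for BYM, summarised by the per-area
#' posterior median (the convention used by the fraction-of-spatial-variation
#' statistic and the residual Moran's I test).
#'
#' @param object a [fit_car()] object.
#' @param ... unused.
#' @return named numeric vector of residuals.
#' @export
residuals.carfit <- function(object, ...) {
  out <- apply(residual_draws(object), 2, stats::median)
  names(out) <- object$graph$ids
  out
}

#' Simulate counts from the posterior predictive distribution
#'
#' Each replicate draws one retained posterior iterate \eqn{\mu^{(m)}} and
#' simulates \eqn{\tilde y_i \sim \mathrm{Pois}(E_i e^{\mu_i^{(m)}})}.
#'
#' @param object a [fit_car()] object.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return N x `nsim` integer matrix of predictive counts.
#' @export
simulate.carfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(object$draws$mu)
  n <- length(object$y)
  idx <- sample.int(M, nsim, replace = TRUE)
  out <- vapply(idx, function(m) {
    stats::rpois(n, object$E * exp(object$draws$mu[m, ]))
  }, integer(n))
  rownames(out) <- object$graph$ids
  out
}

#' Diagnostic plots for a CAR fit
#'
#' Panel 1: observed vs fitted counts. Panel 2: raw SIR vs posterior SIR
#' (shrinkage view). Panel 3: trace of \eqn{\sigma_s^2}.
#'
#' @param x a [fit_car()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.carfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$y, fitted(x), xlab = "observed count", ylab = "fitted count", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$y / x$E, colMeans(exp(x$draws$mu)),
                 xlab = "raw SIR", ylab = "posterior SIR", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::plot(x$draws$sigma_s2, type = "l", xlab = "retained draw",
                 ylab = expression(sigma[s]^2))
  invisible(x)
}
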