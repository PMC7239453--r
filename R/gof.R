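#' Deviance information criterion
#'
#' \deqn{DIC = 2 p_D - 2 \log p(y \mid \bar\theta)} with effective
#' dimension \eqn{p_D = \bar D - D(\bar\theta)}, the mean posterior
#' deviance minus the deviance at the plug-in. The plug-in is taken on the
#' linear predictor: \eqn{\bar\theta} is the posterior mean of
#' \eqn{\mu_i} (DIC is only defined up to this parameterisation choice).
#'
#' @param loglik M x N matrix of pointwise log-likelihoods
#'   ([loglik_matrix()]).
#' @param loglik_hat length-N log-likelihood at the posterior mean of the
#'   parameters.
#' @return list with `dic` and `p_d`.
#' @export
dic <- function(loglik, loglik_hat) {
  stopifnot(is.matrix(loglik), ncol(loglik) == length(loglik_hat))
  dbar <- mean(-2 * rowSums(loglik))
  dhat <- -2 * sum(loglik_hat)
  p_d <- dbar - dhat
  list(dic = dhat + 2 * p_d, p_d = p_d)
}

#' Widely applicable information criterion
#'
#' \deqn{WAIC = 2\sum_i \{ \mathrm{var}_m[\log p(y_i\mid\theta_i^{(m)})]
#'   - \log \tfrac1M \sum_m p(y_i\mid\theta_i^{(m)}) \}}
#' with penalty \eqn{p_W = \sum_i \mathrm{var}_m[\log p]}. The
#' log-mean-exp is computed with a max shift for stability.
#'
#' @param loglik M x N matrix of pointwise log-likelihoods.
#' @return list with `waic` and `p_w`.
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2)
  p_w <- sum(apply(loglik, 2, stats::var))
  lppd <- sum(apply(loglik, 2, log_mean_exp))
  list(waic = 2 * (p_w - lppd), p_w = p_w)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Conditional predictive ordinates
#'
#' Leave-one-out predictive density of each observation, estimated from the
#' posterior sample by the harmonic-mean identity
#' \deqn{CPO_i = \left[\frac1M \sum_m \frac1{p(y_i\mid\theta^{(m)})}
#'   \right]^{-1}.}
#' The summary score is \eqn{-\sum_i \log CPO_i} (smaller is better).
#' Scaled CPOs (divided by the maximum) below 0.01 flag areas the model
#' fits poorly. Areas with a zero-likelihood draw (infinite harmonic term)
#' are excluded from the sum with a warning — the harmonic-mean estimator
#' is known to be unstable in the tails.
#'
#' @param loglik M x N matrix of pointwise log-likelihoods.
#' @return list with `cpo` (per-area), `neg_sum_log_cpo`, `scaled`,
#'   `flags` (scaled < 0.01) and `excluded` (areas dropped from the sum).
#' @export
cpo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2)
  log_cpo <- -apply(-loglik, 2, log_mean_exp)
  excluded <- !is.finite(log_cpo)
  if (any(excluded))
    warning(sum(excluded), " area(s) with zero-likelihood draws excluded from the CPO sum")
  cpo_i <- exp(log_cpo)
  scaled <- cpo_i / max(cpo_i[!excluded])
  list(cpo = cpo_i,
       neg_sum_log_cpo = -sum(log_cpo[!excluded]),
       scaled = scaled,
       flags = !excluded & scaled < 0.01,
       excluded = excluded)
}

#' Moran's I with the normal-approximation test
#'
#' \deqn{I = \frac{N}{S_0} \frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar
#'   x)}{\sum_i (x_i - \bar x)^2}, \qquad S_0 = \sum_{ij} w_{ij}.}
#' The two-sided p-value uses the null moments under normality,
#' \eqn{E[I] = -1/(N-1)} and the standard variance formula. Applied to
#' posterior-median model residuals it checks the iid-residual assumption:
#' residual autocorrelation signals under-smoothing of the spatial signal.
#'
#' @param x numeric per-area vector (typically [residuals.carfit()]).
#' @param graph an [area_graph()].
#' @return list with `i`, `expected`, `sd`, `p_value`.
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n
  if (length(x) != n) stop("x must have one value per area")
  if (stats::sd(x) == 0) stop("constant input: Moran's I undefined")
  W <- graph$w
  s0 <- sum(W)
  if (s0 == 0) stop("graph has no edges")
  xc <- x - mean(x)
  i_obs <- (n / s0) * sum(W * outer(xc, xc)) / sum(xc^2)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  z <- (i_obs - e_i) / sqrt(var_i)
  list(i = i_obs, expected = e_i, sd = sqrt(var_i),
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Goodness-of-fit summary for one fitted model
#'
#' DIC, WAIC, the negative sum of log CPOs, and Moran's I on the
#' posterior-median residuals, bundled for [compare_models()].
#'
#' @param fit a [fit_car()] object.
#' @return object of class `gof_result`.
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  ll <- loglik_matrix(fit)
  mu_hat <- colMeans(fit$draws$mu)
  ll_hat <- stats::dpois(fit$y, fit$E * exp(mu_hat), log = TRUE)
  d <- dic(ll, ll_hat)
  w <- waic(ll)
  cp <- cpo(ll)
  mi <- morans_i(residuals(fit), fit$graph)
  structure(list(dic = d$dic, p_d = d$p_d, waic = w$waic, p_w = w$p_w,
                 neg_sum_log_cpo = cp$neg_sum_log_cpo,
                 cpo_flags = cp$flags, morans_i = mi$i,
                 morans_p = mi$p_value),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("goodness-of-fit statistics\n")
  cat(sprintf("  DIC  : %.2f (p_D = %.1f)\n", x$dic, x$p_d))
  cat(sprintf("  WAIC : %.2f (p_W = %.1f)\n", x$waic, x$p_w))
  cat(sprintf("  -sum log CPO : %.2f (%d poorly fit area(s))\n",
              x$neg_sum_log_cpo, sum(x$cpo_flags)))
  cat(sprintf("  Moran's I on residuals: %.3f (p = %.3f)\n",
              x$morans_i, x$morans_p))
  invisible(x)
}

#' Compare model variants on goodness-of-fit
#'
#' Flags the variant minimising each criterion and bands DIC and WAIC by
#' the common rules of thumb: a variant within 2 units of the minimum has
#' essentially equivalent support, within 7 units reasonable support.
#' Small Moran's I p-values (residual autocorrelation) are highlighted.
#'
#' @param results named list of [gof()] results.
#' @param moran_threshold p-value below which residual autocorrelation is
#'   flagged.
#' @return data frame with one row per variant: the criteria, `dic_band` /
#'   `waic_band` (`"best"`, `"within2"`, `"within7"`, `"worse"`), best
#'   flags, and `moran_flag`.
#' @export
compare_models <- function(results, moran_threshold = 0.05) {
  stopifnot(length(results) >= 1)
  lab <- names(results) %||% paste0("V", seq_along(results))
  dics <- vapply(results, `[[`, 1.0, "dic")
  waics <- vapply(results, `[[`, 1.0, "waic")
  cpos <- vapply(results, `[[`, 1.0, "neg_sum_log_cpo")
  morp <- vapply(results, `[[`, 1.0, "morans_p")
  band <- function(v) {
    dd <- v - min(v)
    ifelse(dd == 0, "best",
           ifelse(dd <= 2, "within2", ifelse(dd <= 7, "within7", "worse")))
  }
  data.frame(variant = lab, dic = dics, waic = waics,
             neg_sum_log_cpo = cpos, morans_p = morp,
             dic_band = band(dics), waic_band = band(waics),
             dic_best = dics == min(dics), waic_best = waics == min(waics),
             cpo_best = cpos == min(cpos),
             moran_flag = morp < moran_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
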