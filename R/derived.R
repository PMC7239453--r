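#' Derived incidence-ratio surfaces
#'
#' The quantities the smoothing diagnostics operate on:
#' \describe{
#'   \item{raw SIR}{`y/E`, the observed standardised incidence ratio.}
#'   \item{SIR}{the model relative risk \eqn{e^{\mu_i}} ("posterior SIR").}
#'   \item{CASIR}{covariate-adjusted SIR,
#'     \eqn{\exp(\mu_i - \beta^T x_i)} = \eqn{\exp(s_i)}; for the BYM model
#'     the unstructured effect is also removed, so CASIR is \eqn{\exp(s_i)}
#'     in both models. The CASIR surface reflects the degree of smoothing
#'     directly, which the SIR need not.}
#'   \item{CARSIR}{covariate-adjusted raw SIR,
#'     \eqn{(y_i/E_i)\exp(-\beta^T x_i)}; zero where \eqn{y_i = 0}.}
#'   \item{residuals}{\eqn{\epsilon_i = E_i e^{\mu_i} - y_i} (Leroux) or
#'     \eqn{\epsilon_i = E_i e^{\mu_i - u_i} - y_i} (BYM, so the
#'     unstructured noise does not enter the systematic part).}
#' }
#'
#' `casir()`, `carsir()`, `sir()` and `residual_draws()` return per-draw
#' M x N matrices; `derived_surfaces()` collects posterior summaries
#' (mean for the ratio surfaces, median for the residuals, matching the
#' conventions of the fraction-of-spatial-variation statistic).
#'
#' @param fit a [fit_car()] object.
#' @return for the per-draw functions, an M x N matrix; for
#'   `derived_surfaces()`, a data frame keyed by area id with columns
#'   `raw_sir`, `sir`, `casir`, `carsir`, `resid`.
#' @export
casir <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  exp(fit$draws$s)
}

#' @rdname casir
#' @param point_beta if `TRUE`, evaluate the covariate adjustment at the
#'   posterior mean of `beta` instead of draw by draw (sensitivity option;
#'   the default adjusts with each draw's own coefficients).
#' @export
carsir <- function(fit, point_beta = FALSE) {
  stopifnot(inherits(fit, "carfit"))
  raw <- fit$y / fit$E
  if (point_beta) {
    bx <- as.vector(fit$X %*% colMeans(fit$draws$beta))
    out <- matrix(raw * exp(-bx), nrow = nrow(fit$draws$beta),
                  ncol = length(raw), byrow = TRUE)
  } else {
    bx <- fit$draws$beta %*% t(fit$X)  # M x N
    out <- sweep(exp(-bx), 2, raw, `*`)
  }
  out
}

#' @rdname casir
#' @export
sir <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  exp(fit$draws$mu)
}

#' @rdname casir
#' @export
residual_draws <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  mu <- fit$draws$mu
  if (fit$model == "bym") mu <- mu - fit$draws$u
  sweep(exp(mu), 2, fit$E, `*`) - matrix(fit$y, nrow(mu), ncol(mu), byrow = TRUE)
}

#' @rdname casir
#' @param summary `"mean"` or `"median"` for the ratio surfaces (residuals
#'   are always summarised by the posterior median).
#' @export
derived_surfaces <- function(fit, summary = c("mean", "median"),
                             point_beta = FALSE) {
  summary <- match.arg(summary)
  fun <- if (summary == "mean") colMeans else function(m) apply(m, 2, stats::median)
  data.frame(
    id = fit$graph$ids,
    raw_sir = fit$y / fit$E,
    sir = fun(sir(fit)),
    casir = fun(casir(fit)),
    carsir = fun(carsir(fit, point_beta = point_beta)),
    resid = apply(residual_draws(fit), 2, stats::median),
    stringsAsFactors = FALSE
  )
}
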