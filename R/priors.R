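#' Hyperpriors for the structured-effect variance
#'
#' The degree of spatial smoothing exerted by the Leroux and BYM models is
#' driven largely by the hyperprior placed on the structured random-effect
#' variance \eqn{\sigma_s^2}. Two families are supported: inverse-gamma
#' IG(shape `alpha`, rate `eta`), and the left-truncated Normal
#' LTN = N(`mean`, `var`)+ truncated at zero, parameterised by mean and
#' variance of the untruncated Normal. A concentrated prior near zero forces
#' \eqn{s \approx 0} (over-smoothing); a diffuse prior lets the field chase
#' the raw incidence ratios (under-smoothing).
#'
#' @param alpha,eta IG shape and rate, both positive.
#' @return a `hyperprior` list with elements `family` and the parameters.
#' @examples
#' hyperprior_ig(1, 0.01)   # weakly informative default
#' hyperprior_ltn(0, 10)    # half-Normal-like prior on the variance
#' @export
hyperprior_ig <- function(alpha, eta) {
  stopifnot(alpha > 0, eta > 0)
  structure(list(family = "ig", alpha = alpha, eta = eta), class = "hyperprior")
}

#' @rdname hyperprior_ig
#' @param mean,var mean and variance (positive) of the untruncated Normal.
#' @export
hyperprior_ltn <- function(mean, var) {
  stopifnot(var > 0)
  structure(list(family = "ltn", mean = mean, var = var), class = "hyperprior")
}

#' @export
print.hyperprior <- function(x, ...) {
  if (x$family == "ig") {
    cat(sprintf("sigma_s^2 ~ IG(shape = %g, rate = %g)\n", x$alpha, x$eta))
  } else {
    cat(sprintf("sigma_s^2 ~ N(%g, %g) truncated at 0\n", x$mean, x$var))
  }
  invisible(x)
}

# log prior density up to a constant (hyperparameters fixed)
hyperprior_logd <- function(hp, x) {
  if (x <= 0) return(-Inf)
  if (hp$family == "ig") {
    (-hp$alpha - 1) * log(x) - hp$eta / x
  } else {
    -(x - hp$mean)^2 / (2 * hp$var)
  }
}

#' Hyperprior grid spanning strong to weak smoothing
#'
#' Twelve hyperprior settings labelled A through L, approximately ordered
#' in descending order of smoothing intensity: variant A concentrates
#' \eqn{\sigma_s^2} near zero (structured effects shrunk flat), variant L is
#' diffuse (structured effects free to track the raw incidence ratios).
#' Pairing the grid with the two models and two families gives the
#' "model variants" scored by [run_comparison()].
#'
#' For the IG family the grid fixes the prior mean of \eqn{\sigma_s^2} at
#' `1e-4, 5e-4, 0.001, 0.005, 0.01, 0.05, 0.1, 0.25` with tight shapes, then
#' relaxes into heavy-tailed members; for the LTN family the mean and
#' variance both grow.
#'
#' @param family `"ig"` or `"ltn"`.
#' @return named list of 12 [hyperprior_ig()]/[hyperprior_ltn()] objects,
#'   labels `"A"`..`"L"`.
#' @export
hyperprior_grid <- function(family = c("ig", "ltn")) {
  family <- match.arg(family)
  labels <- LETTERS[1:12]
  if (family == "ig") {
    shapes <- c(50, 50, 50, 50, 20, 20, 10, 5, 3, 2, 1, 0.5)
    rates  <- c(50 * c(1e-4, 5e-4, 1e-3, 5e-3) - c(1e-4, 5e-4, 1e-3, 5e-3),
                19 * c(1e-2, 5e-2), 9 * 0.1, 4 * 0.25, 2 * 0.5, 1,
                0.5,   # IG(1, 0.5): heavy tail, mode 0.25
                0.5)   # IG(0.5, 0.5): very diffuse, scaled-chi-square-like
    grid <- Map(hyperprior_ig, shapes, rates)
  } else {
    mus <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 0.1, 0.25, 0.5, 1, 2, 5)
    vars <- c(1e-8, 2.5e-7, 1e-6, 2.5e-5, 1e-4, 2.5e-3, 0.01, 0.05, 0.25, 1, 4, 25)
    grid <- Map(hyperprior_ltn, mus, vars)
  }
  names(grid) <- labels
  grid
}

#' MCMC settings
#'
#' @param n_iter total iterations including burn-in.
#' @param burnin iterations discarded; step sizes adapt only in this window.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; seeded runs are bit-reproducible.
#' @param target_accept Robbins-Monro target acceptance for single-site
#'   updates.
#' @param step_s,step_beta,step_rho,step_sigma,step_u initial random-walk
#'   standard deviations (adapted during burn-in).
#' @return a `mcmc_control` list.
#' @export
mcmc_control <- function(n_iter = 20000, burnin = 10000, thin = 10, seed = 1,
                         target_accept = 0.4, step_s = 0.3, step_beta = 0.05,
                         step_rho = 0.5, step_sigma = 0.5, step_u = 0.3) {
  stopifnot(n_iter > burnin, burnin >= 0, thin >= 1)
  kept <- floor((n_iter - burnin) / thin)
  if (kept < 100)
    warning("fewer than 100 retained draws; downstream statistics will be noisy")
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 target_accept = target_accept, step_s = step_s,
                 step_beta = step_beta, step_rho = step_rho,
                 step_sigma = step_sigma, step_u = step_u),
            class = "mcmc_control")
}
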