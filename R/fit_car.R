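#' Fit a Bayesian CAR disease-mapping model
#'
#' Fits the Leroux or BYM Poisson model for areal counts by
#' Metropolis-within-Gibbs MCMC. The likelihood is
#' \deqn{y_i \sim \mathrm{Pois}(E_i e^{\mu_i})}
#' with log relative risk \eqn{\mu_i = \beta^T x_i + s_i} (Leroux) or
#' \eqn{\mu_i = \beta^T x_i + s_i + u_i} (BYM). The structured effects `s`
#' carry a CAR prior with binary first-order adjacency weights: the Leroux
#' full conditional has mean
#' \eqn{\rho\sum_j w_{ij}s_j / (\rho\sum_j w_{ij} + 1 - \rho)} and variance
#' \eqn{\sigma_s^2/(\rho\sum_j w_{ij} + 1 - \rho)} with
#' \eqn{\rho \sim \mathrm{Unif}(0,1)}; the BYM structured effect is intrinsic
#' CAR (neighbour-average conditional mean, variance
#' \eqn{\sigma_s^2/\sum_j w_{ij}}) plus iid unstructured effects
#' \eqn{u_i \sim N(0, \sigma_u^2)}, \eqn{\sigma_u^2 \sim N(0,10)+}.
#' Regression coefficients have independent N(0, 100) priors.
#'
#' Sampler details: single-site random-walk Metropolis for each \eqn{s_i},
#' vectorised over colour classes of the adjacency graph (areas within a
#' class are conditionally independent, so joint acceptance within a class
#' is exact); vectorised Metropolis for `u`; a random-walk block update for
#' `beta`; Gibbs for \eqn{\sigma_s^2} under the conjugate IG hyperprior and
#' log-scale Metropolis under the LTN hyperprior; Metropolis on
#' \eqn{\mathrm{logit}(\rho)} using precomputed eigenvalues of the Laplacian
#' for the determinant term. Step sizes adapt by Robbins-Monro toward the
#' target acceptance rate during burn-in only. The intrinsic CAR field is
#' re-centred to sum to zero every iteration, with the compensating shift
#' absorbed into the intercept.
#'
#' @param formula model formula for the covariates, e.g. `y ~ x`. The
#'   response must be the observed counts.
#' @param data an [area_data()] object or data frame containing the response,
#'   covariates, and (unless `expected` is given) a column `E` of expected
#'   counts.
#' @param graph an [area_graph()] with one node per row of `data`, in the
#'   same order.
#' @param expected expected counts \eqn{E_i}; defaults to `data$E`.
#' @param model `"leroux"` or `"bym"`.
#' @param hyperprior a [hyperprior_ig()] or [hyperprior_ltn()] object for
#'   \eqn{\sigma_s^2}.
#' @param mcmc an [mcmc_control()] object.
#' @param u_prior_var parameters (mean, variance) of the left-truncated
#'   Normal prior for \eqn{\sigma_u^2} in the BYM model.
#' @param beta_prior_var prior variance of the regression coefficients.
#' @return An object of class `carfit` with posterior draws in `$draws`
#'   (`beta`, `s`, `u` (BYM), `rho` (Leroux), `sigma_s2`, `sigma_u2` (BYM),
#'   `mu`), acceptance rates in `$accept`, and the call, data, graph and
#'   design matrix. Methods: [print.carfit()], [summary.carfit()],
#'   [coef.carfit()], [fitted.carfit()], [residuals.carfit()],
#'   [simulate.carfit()], [plot.carfit()].
#' @examples
#' g <- make_lattice(5, 5)
#' set.seed(1)
#' d <- simulate_counts(g, s = simulate_leroux_field(g, 0.7, 0.3, seed = 1),
#'                      beta = 0, E = rep(20, 25), seed = 2)
#' fit <- fit_car(y ~ 1, d, g, mcmc = mcmc_control(2000, 1000, 1, seed = 3))
#' fit
#' @export
fit_car <- function(formula, data, graph, expected = NULL,
                    model = c("leroux", "bym"),
                    hyperprior = hyperprior_ig(1, 0.01),
                    mcmc = mcmc_control(),
                    u_prior_var = c(0, 10),
                    beta_prior_var = 100) {
  model <- match.arg(model)
  stopifnot(inherits(graph, "area_graph"), inherits(hyperprior, "hyperprior"))
  cl <- match.call()

  mf <- stats::model.frame(formula, as.data.frame(data))
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (n != graph$n) stop("data and graph disagree on the number of areas")
  if (is.null(expected)) {
    if (!"E" %in% names(data)) stop("supply `expected` or a column E in data")
    expected <- data$E
  }
  E <- as.numeric(expected)
  if (any(E <= 0)) stop("expected counts must be positive")
  if (any(y < 0)) stop("counts must be non-negative")
  p <- ncol(X)

  deg <- area_degree(graph)
  if (model == "bym" && any(deg == 0L))
    stop("BYM requires every area to have at least one neighbour (ICAR update)")

  draws <- car_mcmc(y = y, E = E, X = X, graph = graph, model = model,
                    hyperprior = hyperprior, mcmc = mcmc,
                    u_prior_var = u_prior_var, beta_prior_var = beta_prior_var)

  structure(list(call = cl, model = model, hyperprior = hyperprior,
                 mcmc = mcmc, formula = formula, y = y, E = E, X = X,
                 graph = graph, data = data,
                 draws = draws$draws, accept = draws$accept),
            class = "carfit")
}

# The Metropolis-within-Gibbs engine shared by both models.
car_mcmc <- function(y, E, X, graph, model, hyperprior, mcmc,
                     u_prior_var, beta_prior_var) {
  set.seed(mcmc$seed)
  n <- length(y)
  p <- ncol(X)
  W <- graph$w
  deg <- area_degree(graph)
  colr <- graph_coloring(graph)
  classes <- split(seq_len(n), colr)
  leroux <- model == "leroux"

  # eigenvalues of the graph Laplacian D - W, for the Leroux log-determinant
  lam <- if (leroux) eigen(diag(deg) - W, symmetric = TRUE, only.values = TRUE)$values

  # initial values: Poisson GLM for beta, flat field
  beta <- tryCatch(
    stats::glm.fit(X, y, family = stats::poisson(), offset = log(E))$coefficients,
    error = function(e) rep(0, p))
  beta[!is.finite(beta)] <- 0
  s <- rep(0, n)
  u <- rep(0, n)
  rho <- 0.5
  sigma_s2 <- 0.1
  sigma_u2 <- 0.1

  # adaptive step sizes
  st_s <- mcmc$step_s; st_b <- mcmc$step_beta; st_r <- mcmc$step_rho
  st_g <- mcmc$step_sigma; st_u <- mcmc$step_u
  tgt1 <- mcmc$target_accept  # single-site target
  tgtb <- 0.3                 # block/scalar targets
  acc <- c(s = 0, beta = 0, rho = 0, u = 0, sigma = 0)
  cnt <- c(s = 0, beta = 0, rho = 0, u = 0, sigma = 0)

  keep <- floor((mcmc$n_iter - mcmc$burnin) / mcmc$thin)
  out_beta <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X)))
  out_s <- matrix(NA_real_, keep, n)
  out_u <- if (!leroux) matrix(NA_real_, keep, n)
  out_rho <- if (leroux) numeric(keep)
  out_ss <- numeric(keep)
  out_su <- if (!leroux) numeric(keep)
  k <- 0L

  eta_fixed <- as.vector(X %*% beta)
  qf_icar <- function(s) sum(deg * s^2) - sum(s * as.vector(W %*% s))

  for (it in seq_len(mcmc$n_iter)) {
    adapting <- it <= mcmc$burnin
    gam <- 1 / sqrt(it)

    ## --- structured field s, colourwise single-site Metropolis ---
    off <- E * exp(eta_fixed + if (leroux) 0 else u)
    n_acc_s <- 0L
    for (cls in classes) {
      Ws <- as.vector(W %*% s)
      if (leroux) {
        prec <- (rho * deg[cls] + 1 - rho) / sigma_s2
        m <- rho * Ws[cls] / (rho * deg[cls] + 1 - rho)
      } else {
        prec <- deg[cls] / sigma_s2
        m <- Ws[cls] / deg[cls]
      }
      cur <- s[cls]
      prop <- cur + stats::rnorm(length(cls), 0, st_s)
      la <- y[cls] * (prop - cur) - off[cls] * (exp(prop) - exp(cur)) -
        0.5 * prec * ((prop - m)^2 - (cur - m)^2)
      ok <- log(stats::runif(length(cls))) < la
      s[cls[ok]] <- prop[ok]
      n_acc_s <- n_acc_s + sum(ok)
    }
    rate_s <- n_acc_s / n
    acc["s"] <- acc["s"] + n_acc_s; cnt["s"] <- cnt["s"] + n
    if (adapting) st_s <- exp(log(st_s) + gam * (rate_s - tgt1))

    ## --- BYM: recentre s (ICAR impropriety), shift into intercept ---
    if (!leroux) {
      mbar <- mean(s)
      s <- s - mbar
      beta[1] <- beta[1] + mbar
      eta_fixed <- as.vector(X %*% beta)

      ## --- unstructured field u, vectorised Metropolis ---
      offu <- E * exp(eta_fixed + s)
      prop <- u + stats::rnorm(n, 0, st_u)
      la <- y * (prop - u) - offu * (exp(prop) - exp(u)) -
        (prop^2 - u^2) / (2 * sigma_u2)
      ok <- log(stats::runif(n)) < la
      u[ok] <- prop[ok]
      acc["u"] <- acc["u"] + sum(ok); cnt["u"] <- cnt["u"] + n
      if (adapting) st_u <- exp(log(st_u) + gam * (mean(ok) - tgt1))
    }

    ## --- regression block beta ---
    re <- s + if (leroux) 0 else u
    offb <- E * exp(re)
    propb <- beta + stats::rnorm(p, 0, st_b)
    eta_prop <- as.vector(X %*% propb)
    la <- sum(y * (eta_prop - eta_fixed) - offb * (exp(eta_prop) - exp(eta_fixed))) -
      (sum(propb^2) - sum(beta^2)) / (2 * beta_prior_var)
    aprob <- if (is.finite(la)) min(1, exp(la)) else 0
    if (aprob > stats::runif(1)) {
      beta <- propb
      eta_fixed <- eta_prop
      acc["beta"] <- acc["beta"] + 1
    }
    cnt["beta"] <- cnt["beta"] + 1
    if (adapting) st_b <- exp(log(st_b) + gam * (aprob - tgtb))

    ## --- rho (Leroux mixing parameter), Metropolis on logit scale ---
    if (leroux) {
      z <- stats::qlogis(rho)
      zp <- z + stats::rnorm(1, 0, st_r)
      rp <- stats::plogis(zp)
      qf <- function(r) r * qf_icar(s) + (1 - r) * sum(s^2)
      logtarget <- function(r) {
        0.5 * sum(log(r * lam + 1 - r)) - qf(r) / (2 * sigma_s2) +
          log(r) + log(1 - r)  # Jacobian of logit; Unif(0,1) prior
      }
      la <- logtarget(rp) - logtarget(rho)
      aprob <- if (is.finite(la)) min(1, exp(la)) else 0
      if (aprob > stats::runif(1)) {
        rho <- rp
        acc["rho"] <- acc["rho"] + 1
      }
      cnt["rho"] <- cnt["rho"] + 1
      if (adapting) st_r <- exp(log(st_r) + gam * (aprob - tgtb))
    }

    ## --- sigma_s2 ---
    qf_s <- if (leroux) rho * qf_icar(s) + (1 - rho) * sum(s^2) else qf_icar(s)
    rank_q <- if (leroux) n else n - 1L
    if (hyperprior$family == "ig") {
      # conjugate inverse-gamma Gibbs step
      sigma_s2 <- 1 / stats::rgamma(1, shape = hyperprior$alpha + rank_q / 2,
                                    rate = hyperprior$eta + qf_s / 2)
    } else {
      lp <- function(v) -rank_q / 2 * log(v) - qf_s / (2 * v) +
        hyperprior_logd(hyperprior, v) + log(v)  # + log Jacobian
      vp <- exp(log(sigma_s2) + stats::rnorm(1, 0, st_g))
      la <- lp(vp) - lp(sigma_s2)
      aprob <- if (is.finite(la)) min(1, exp(la)) else 0
      if (aprob > stats::runif(1)) {
        sigma_s2 <- vp
        acc["sigma"] <- acc["sigma"] + 1
      }
      cnt["sigma"] <- cnt["sigma"] + 1
      if (adapting) st_g <- exp(log(st_g) + gam * (aprob - tgtb))
    }

    ## --- sigma_u2 (BYM), log-scale Metropolis under N(0,10)+ ---
    if (!leroux) {
      lpu <- function(v) -n / 2 * log(v) - sum(u^2) / (2 * v) -
        (v - u_prior_var[1])^2 / (2 * u_prior_var[2]) + log(v)
      vp <- exp(log(sigma_u2) + stats::rnorm(1, 0, st_g))
      la <- lpu(vp) - lpu(sigma_u2)
      if (is.finite(la) && la > log(stats::runif(1))) sigma_u2 <- vp
    }

    ## --- store ---
    if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0L) {
      k <- k + 1L
      out_beta[k, ] <- beta
      out_s[k, ] <- s
      out_ss[k] <- sigma_s2
      if (leroux) out_rho[k] <- rho else {
        out_u[k, ] <- u
        out_su[k] <- sigma_u2
      }
    }
  }

  mu <- out_s + out_beta %*% t(X)
  if (!leroux) mu <- mu + out_u
  dimnames(mu) <- NULL
  draws <- list(beta = out_beta, s = out_s, sigma_s2 = out_ss, mu = mu)
  if (leroux) draws$rho <- out_rho else {
    draws$u <- out_u
    draws$sigma_u2 <- out_su
  }
  list(draws = draws, accept = ifelse(cnt > 0, acc / cnt, NA))
}

#' Matrix of pointwise log-likelihoods
#'
#' Entry (m, i) is the Poisson log-pmf
#' \eqn{\log p(y_i \mid \theta_i^{(m)})} evaluated at mean
#' \eqn{E_i e^{\mu_i^{(m)}}} for retained draw m. This matrix feeds
#' [dic()], [waic()] and [cpo()].
#'
#' @param fit a [fit_car()] object.
#' @return M x N numeric matrix.
#' @export
loglik_matrix <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  mu <- fit$draws$mu
  M <- nrow(mu)
  t(vapply(seq_len(M), function(m) {
    stats::dpois(fit$y, fit$E * exp(mu[m, ]), log = TRUE)
  }, numeric(length(fit$y))))
}

#' Reallocate BYM structured/unstructured effects for identifiability
#'
#' The BYM decomposition of the spatial effect into structured (`s`) and
#' unstructured (`u`) parts is not identifiable from a single realisation.
#' This post-hoc rescaling reallocates, draw by draw, the total effect
#' `s + u` between the two parts in proportion to the standard-deviation
#' ratio \eqn{r = \mathrm{sd}(s) / (\mathrm{sd}(s) + \mathrm{sd}(u))}:
#' the new structured part is \eqn{r (s + u)}, the new unstructured part
#' \eqn{(1 - r)(s + u)}. The sum, and hence \eqn{\mu} and the likelihood,
#' are unchanged.
#'
#' @param fit a BYM [fit_car()] object.
#' @return the fit with reallocated `s` and `u` draws; flag
#'   `$identifiability_rescaled` set.
#' @export
rescale_bym <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  if (fit$model != "bym") stop("identifiability rescaling applies to BYM fits only")
  s <- fit$draws$s
  u <- fit$draws$u
  for (m in seq_len(nrow(s))) {
    sds <- stats::sd(s[m, ]); sdu <- stats::sd(u[m, ])
    if (sds + sdu == 0) stop("draw ", m, " has zero total spatial variation")
    r <- sds / (sds + sdu)
    tot <- s[m, ] + u[m, ]
    s[m, ] <- r * tot
    u[m, ] <- (1 - r) * tot
  }
  fit$draws$s <- s
  fit$draws$u <- u
  fit$identifiability_rescaled <- TRUE
  fit
}
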