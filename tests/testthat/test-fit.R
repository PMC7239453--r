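# Short chains are used throughout: these tests check correctness properties
# (reproducibility, constraints, algebraic identities, gross calibration),
# not publication-grade posterior accuracy.

fit_quick <- function(data, graph, model = "leroux", seed = 1, n = 2000,
                      burn = 1000, ...) {
  fit_car(y ~ 1, data, graph, model = model,
          mcmc = mcmc_control(n, burn, 1, seed = seed), ...)
}

test_that("seeded runs are bit-reproducible", {
  g <- make_lattice(4, 4)
  d <- simulate_counts(g, s = simulate_leroux_field(g, 0.5, 0.3, 1),
                       beta = 0.1, seed = 2)
  f1 <- fit_quick(d, g, seed = 42, n = 600, burn = 300)
  f2 <- fit_quick(d, g, seed = 42, n = 600, burn = 300)
  expect_identical(f1$draws, f2$draws)
  b1 <- fit_quick(d, g, model = "bym", seed = 42, n = 600, burn = 300)
  b2 <- fit_quick(d, g, model = "bym", seed = 42, n = 600, burn = 300)
  expect_identical(b1$draws, b2$draws)
})

test_that("with y = E and intercept only, the intercept posterior sits at zero", {
  g <- make_lattice(6, 6)
  d <- area_data(y = rep(20L, 36), E = rep(20, 36), ids = g$ids)
  fit <- fit_quick(d, g, seed = 3, n = 3000, burn = 1500)
  b0 <- fit$draws$beta[, 1]
  expect_lt(abs(mean(b0)), 0.1)
  expect_true(stats::quantile(b0, 0.025) < 0 && stats::quantile(b0, 0.975) > 0)
})

test_that("BYM structured effects are recentred to zero at every retained draw", {
  g <- make_lattice(5, 5)
  d <- simulate_counts(g, s = simulate_icar_field(g, 0.4, 5), beta = 0, seed = 6)
  fit <- fit_quick(d, g, model = "bym", seed = 7, n = 800, burn = 400)
  expect_true(all(abs(rowSums(fit$draws$s)) < 1e-10))
  expect_true(all(fit$draws$sigma_s2 > 0))
  expect_true(all(fit$draws$sigma_u2 > 0))
})

test_that("Leroux rho draws stay in (0,1) and sigma draws positive", {
  g <- make_lattice(5, 5)
  d <- simulate_counts(g, s = simulate_leroux_field(g, 0.7, 0.4, 8),
                       beta = 0, seed = 9)
  fit <- fit_quick(d, g, seed = 10, n = 800, burn = 400)
  expect_true(all(fit$draws$rho > 0 & fit$draws$rho < 1))
  expect_true(all(fit$draws$sigma_s2 > 0))
  expect_equal(dim(fit$draws$s), c(400, 25))
})

test_that("log-likelihood matrix matches a hand-written Poisson pmf oracle", {
  g <- make_lattice(3, 3)
  d <- simulate_counts(g, beta = 0.2, seed = 11)
  fit <- fit_quick(d, g, seed = 12, n = 400, burn = 200)
  ll <- loglik_matrix(fit)
  # mu = 0, E = y = 1 gives exactly -1
  fake <- fake_carfit(matrix(0, 2, 2), matrix(0, 2, 1), y = c(1L, 1L),
                      E = c(1, 1), X = matrix(1, 2, 1),
                      graph = suppressWarnings(area_graph(matrix(0, 2, 2))))
  expect_equal(loglik_matrix(fake), matrix(-1, 2, 2))
  # hand pmf: y log(lam) - lam - log(y!)
  for (m in c(1, 50)) {
    lam <- fit$E * exp(fit$draws$mu[m, ])
    hand <- fit$y * log(lam) - lam - lfactorial(fit$y)
    expect_equal(ll[m, ], hand, tolerance = 1e-12)
  }
  expect_true(all(ll <= 0))   # Poisson pmf never exceeds 1 for these data
})

test_that("stronger smoothing priors shrink the CASIR range", {
  fx <- smoothing_gradient_fixture(21)
  f_tight <- fit_car(y ~ x, fx$data, fx$graph, hyperprior = fx$hyperpriors$over,
                     mcmc = mcmc_control(2000, 1000, 1, seed = 1))
  f_diffuse <- fit_car(y ~ x, fx$data, fx$graph, hyperprior = fx$hyperpriors$under,
                       mcmc = mcmc_control(2000, 1000, 1, seed = 1))
  r_tight <- diff(range(colMeans(casir(f_tight))))
  r_diffuse <- diff(range(colMeans(casir(f_diffuse))))
  expect_lt(r_tight, r_diffuse / 5)
  expect_lt(abs(r_tight), 0.05)   # CASIR pinned near 1 under the tight prior
})

test_that("covariate coefficients concentrate near zero when truth has no effect", {
  make_case <- function(nrow, ncol, seed) {
    g <- make_lattice(nrow, ncol)
    x <- simulate_leroux_field(g, 0.8, 1, seed)
    d <- simulate_counts(g, s = simulate_leroux_field(g, 0.6, 0.3, seed + 1),
                         beta = c(0, 0), X = data.frame(x = x), seed = seed + 2)
    fit_car(y ~ x, d, g, mcmc = mcmc_control(2500, 1200, 1, seed = seed + 3))
  }
  f25 <- make_case(5, 5, 31)
  f100 <- make_case(10, 10, 41)
  sd25 <- sd(f25$draws$beta[, 2])
  sd100 <- sd(f100$draws$beta[, 2])
  expect_lt(sd100, sd25)                       # information grows with N
  expect_lt(abs(mean(f100$draws$beta[, 2])), 3 * sd100)
})

test_that("BYM identifiability rescaling conserves the total effect", {
  g <- make_lattice(5, 5)
  d <- simulate_counts(g, s = simulate_icar_field(g, 0.4, 51), beta = 0,
                       seed = 52, u_sigma = 0.2)
  fit <- fit_quick(d, g, model = "bym", seed = 53, n = 800, burn = 400)
  rs <- rescale_bym(fit)
  expect_equal(rs$draws$s + rs$draws$u, fit$draws$s + fit$draws$u,
               tolerance = 1e-12)
  expect_identical(rs$draws$mu, fit$draws$mu)
  # a draw with u = 0 is unchanged; a draw with s = 0 moves everything to u
  f2 <- fit
  f2$draws$s <- rbind(c(1, rep(0, 23), -1), rep(0, 25))
  f2$draws$u <- rbind(rep(0, 25), c(2, rep(0, 23), -2))
  f2$draws$mu <- f2$draws$mu[1:2, ]
  f2$draws$beta <- f2$draws$beta[1:2, , drop = FALSE]
  r2 <- rescale_bym(f2)
  expect_equal(r2$draws$s[1, ], f2$draws$s[1, ])
  expect_equal(r2$draws$s[2, ], rep(0, 25))
  expect_equal(r2$draws$u[2, ], f2$draws$u[2, ])
  # degenerate draw errors
  f3 <- f2
  f3$draws$s[1, ] <- 0; f3$draws$u[1, ] <- 0
  expect_error(rescale_bym(f3), "zero total")
  expect_error(rescale_bym(fit_quick(d, g, seed = 1, n = 400, burn = 200)), "BYM")
})

test_that("BYM psi responds to whether the truth is structured or unstructured", {
  g <- make_lattice(6, 6)
  d_unstr <- simulate_counts(g, beta = 0, seed = 61, u_sigma = 0.5, E = 30)
  s_str <- simulate_icar_field(g, 1.2, 62)
  d_str <- simulate_counts(g, s = s_str, beta = 0, seed = 63, E = 30)
  f_u <- fit_quick(d_unstr, g, model = "bym", seed = 64, n = 2500, burn = 1200)
  f_s <- fit_quick(d_str, g, model = "bym", seed = 65, n = 2500, burn = 1200)
  expect_lt(fraction_spatial_variation(f_u), fraction_spatial_variation(f_s))
})

test_that("carfit methods expose coherent summaries", {
  g <- make_lattice(4, 4)
  d <- simulate_counts(g, s = simulate_leroux_field(g, 0.5, 0.3, 71),
                       beta = 0.2, seed = 72)
  fit <- fit_quick(d, g, seed = 73, n = 1000, burn = 500)
  expect_length(coef(fit), 1)
  expect_length(fitted(fit), 16)
  expect_length(residuals(fit), 16)
  med_mu <- apply(sweep(exp(fit$draws$mu), 2, fit$E, `*`), 2, median)
  expect_equal(unname(residuals(fit)), unname(med_mu - fit$y), tolerance = 1e-12)
  sm <- summary(fit)
  expect_true(all(c("mean", "sd", "2.5%", "97.5%", "n_eff") %in%
                    colnames(sm$coefficients)))
  ys <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(ys), c(16, 3))
  expect_true(all(ys >= 0))
  expect_output(print(fit), "LEROUX")
})

test_that("fit_car validates its inputs", {
  g <- make_lattice(4, 4)
  d <- simulate_counts(g, beta = 0, seed = 81)
  expect_error(fit_car(y ~ 1, d, make_lattice(3, 3)), "disagree")
  gi <- suppressWarnings(graph_from_edges(cbind(g$ids[1], g$ids[2]), ids = g$ids))
  expect_error(fit_car(y ~ 1, d, gi, model = "bym"), "neighbour")
  d2 <- as.data.frame(d); d2$E <- NULL
  expect_error(fit_car(y ~ 1, d2, g), "expected")
})
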