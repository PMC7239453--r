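#' Simulate a Leroux Gaussian Markov random field
#'
#' One draw from the zero-mean GMRF whose precision is
#' \eqn{Q = (\rho(D - W) + (1-\rho)I)/\sigma_s^2}, the joint distribution
#' implied by the Leroux conditionals. At \eqn{\rho = 0} this is iid
#' \eqn{N(0, \sigma_s^2)}; as \eqn{\rho \to 1} it approaches the intrinsic
#' CAR.
#'
#' @param graph an [area_graph()].
#' @param rho spatial mixing parameter in `[0, 1)`; request
#'   [simulate_icar_field()] for the intrinsic limit.
#' @param sigma_s marginal conditional scale (standard deviation).
#' @param seed RNG seed.
#' @return numeric field of length `graph$n`.
#' @export
simulate_leroux_field <- function(graph, rho, sigma_s, seed) {
  stopifnot(inherits(graph, "area_graph"), sigma_s > 0)
  if (rho >= 1) stop("rho = 1 is the intrinsic CAR; use simulate_icar_field()")
  if (rho < 0) stop("rho must be in [0, 1)")
  set.seed(seed)
  n <- graph$n
  Q <- (rho * (diag(area_degree(graph)) - graph$w) + (1 - rho) * diag(n)) / sigma_s^2
  R <- chol(Q)
  backsolve(R, stats::rnorm(n))
}

#' Simulate an intrinsic CAR field
#'
#' Draws from the intrinsic CAR distribution (conditional mean equal to the
#' neighbour average, conditional variance \eqn{\sigma_s^2/\sum_j w_{ij}})
#' via the eigendecomposition of the graph Laplacian, constrained to sum to
#' zero. Requires a connected graph.
#'
#' @param graph a connected [area_graph()].
#' @param sigma_s conditional scale.
#' @param seed RNG seed.
#' @return numeric field of length `graph$n` summing to zero.
#' @export
simulate_icar_field <- function(graph, sigma_s, seed) {
  stopifnot(inherits(graph, "area_graph"), sigma_s > 0)
  n <- graph$n
  d <- boundary_distances(graph)
  if (any(is.infinite(d))) stop("graph is disconnected; the intrinsic CAR is undefined")
  set.seed(seed)
  Q <- (diag(area_degree(graph)) - graph$w) / sigma_s^2
  eg <- eigen(Q, symmetric = TRUE)
  # drop the null eigenvector (constant); sample in the orthogonal complement
  keep <- seq_len(n - 1L)
  z <- stats::rnorm(n - 1L) / sqrt(eg$values[keep])
  x <- as.vector(eg$vectors[, keep, drop = FALSE] %*% z)
  x - mean(x)
}

#' Simulate Poisson areal counts with known truth
#'
#' \eqn{y_i \sim \mathrm{Pois}(E_i \exp(\beta^T x_i + s_i + u_i))}, with
#' the generating field(s), coefficients and seed recorded in the
#' `"truth"` attribute so parameter-recovery and smoothing experiments can
#' compare against ground truth.
#'
#' @param graph an [area_graph()].
#' @param s structured field (length N); default zero.
#' @param beta coefficient vector matching `cbind(1, X)`; a scalar is the
#'   intercept of a covariate-free model.
#' @param X optional matrix/data frame of covariates (without intercept).
#' @param E expected counts; default drawn log-uniform on `[5, 50]`,
#'   mimicking small-area disease counts.
#' @param seed RNG seed.
#' @param u_sigma optional standard deviation of additional iid unstructured
#'   effects.
#' @return an [area_data()] with attribute `truth` (list with `s`, `u`,
#'   `beta`, `seed`).
#' @export
simulate_counts <- function(graph, s = NULL, beta = 0, X = NULL, E = NULL,
                            seed, u_sigma = NULL) {
  stopifnot(inherits(graph, "area_graph"))
  set.seed(seed)
  n <- graph$n
  if (is.null(s)) s <- rep(0, n)
  if (length(s) != n) stop("s must have one value per area")
  if (is.null(E)) E <- exp(stats::runif(n, log(5), log(50)))
  if (length(E) == 1L) E <- rep(E, n)
  Xm <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  if (ncol(Xm) != length(beta)) stop("beta length must match intercept + covariates")
  u <- if (is.null(u_sigma)) rep(0, n) else stats::rnorm(n, 0, u_sigma)
  mu <- as.vector(Xm %*% beta) + s + u
  if (any(abs(mu) > 30)) stop("log relative risk too extreme; Poisson mean overflows")
  y <- stats::rpois(n, E * exp(mu))
  cov_df <- if (is.null(X)) NULL else as.data.frame(X)
  out <- area_data(y, E, covariates = cov_df, ids = graph$ids)
  attr(out, "truth") <- list(s = s, u = u, beta = beta, seed = seed)
  out
}

#' Write/read the ground-truth sidecar of a synthetic dataset
#'
#' @param data a dataset from [simulate_counts()].
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   truth list.
#' @export
write_truth <- function(data, path) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("no truth metadata attached to this dataset")
  jsonlite::write_json(tr, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr
}

#' Smoothing-gradient test bed
#'
#' One synthetic county-map-scale dataset (56 areas on a 7 x 8 rook lattice,
#' one spatially autocorrelated covariate, expected counts log-uniform on
#' `[5, 50]`) together with three hyperprior settings for \eqn{\sigma_s^2}
#' of strictly increasing prior diffuseness, deliberately chosen to induce
#' over-, moderate and under-smoothing when the Leroux model is fit with
#' each in turn. The covariate is itself a Leroux field with \eqn{\rho=0.9},
#' so the SIR surface can look rough even under heavy smoothing while the
#' CASIR surface flattens (the smoothing paradox).
#'
#' Generating values: structured field \eqn{\rho = 0.8},
#' \eqn{\sigma_s = 0.4}; \eqn{\beta = (0.1, 0.3)}.
#'
#' @param seed master seed for all randomness in the bundle.
#' @return list with `graph`, `data` (an [area_data()] with truth attached),
#'   and `hyperpriors` (named list `over`, `moderate`, `under`).
#' @export
smoothing_gradient_fixture <- function(seed) {
  graph <- make_lattice(7, 8)
  covar <- simulate_leroux_field(graph, rho = 0.9, sigma_s = 1, seed = seed + 1L)
  s <- simulate_leroux_field(graph, rho = 0.8, sigma_s = 0.4, seed = seed + 2L)
  data <- simulate_counts(graph, s = s, beta = c(0.1, 0.3),
                          X = data.frame(x = covar), seed = seed + 3L)
  attr(data, "truth")$rho <- 0.8
  attr(data, "truth")$sigma_s <- 0.4
  list(
    graph = graph,
    data = data,
    hyperpriors = list(
      over = hyperprior_ig(100, 0.001),   # sigma_s^2 pinned near 1e-5
      moderate = hyperprior_ig(3, 0.32),  # prior mean 0.16 = truth
      under = hyperprior_ig(2.1, 5)       # diffuse, favours large sigma_s^2
    )
  )
}
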