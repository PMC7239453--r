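# Brute-force re-implementations used as independent oracles. These are
# deliberately naive (double loops, direct formulas) and share no code with
# the package internals.

oracle_shortest_paths <- function(w) {
  n <- nrow(w)
  d <- ifelse(w == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_variogram_mean <- function(z, d, H) {
  n <- length(z)
  sapply(seq_len(H), function(h) {
    g <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      js <- which(d[i, ] <= h & seq_len(n) != i & is.finite(d[i, ]))
      if (length(js)) g[i] <- sum((z[i] - z[js])^2) / (2 * length(js))
    }
    mean(g, na.rm = TRUE)
  })
}

oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  K <- length(lev)
  cm <- matrix(0, K, K)
  for (i in seq_along(a))
    cm[match(a[i], lev), match(b[i], lev)] <- cm[match(a[i], lev), match(b[i], lev)] + 1
  N <- length(a)
  po <- sum(diag(cm)) / N
  pe <- 0
  for (k in seq_len(K)) pe <- pe + sum(cm[k, ]) * sum(cm[, k]) / N^2
  (po - pe) / (1 - pe)
}

oracle_psi <- function(s, e) {
  vs <- sum((s - mean(s))^2) / (length(s) - 1)
  ve <- sum((e - mean(e))^2) / (length(e) - 1)
  vs / (vs + ve)
}

oracle_dic <- function(ll, ll_hat) {
  M <- nrow(ll)
  devs <- numeric(M)
  for (m in seq_len(M)) devs[m] <- -2 * sum(ll[m, ])
  dbar <- mean(devs)
  dhat <- -2 * sum(ll_hat)
  list(dic = 2 * (dbar - dhat) + dhat, p_d = dbar - dhat)
}

oracle_waic <- function(ll) {
  M <- nrow(ll); N <- ncol(ll)
  total <- 0; pw <- 0
  for (i in seq_len(N)) {
    v <- sum((ll[, i] - mean(ll[, i]))^2) / (M - 1)
    lme <- log(mean(exp(ll[, i])))
    total <- total + v - lme
    pw <- pw + v
  }
  list(waic = 2 * total, p_w = pw)
}

oracle_cpo <- function(ll) {
  N <- ncol(ll)
  out <- numeric(N)
  for (i in seq_len(N)) out[i] <- 1 / mean(1 / exp(ll[, i]))
  out
}

oracle_morans <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  s0 <- sum(w)
  i_obs <- (n / s0) * num / sum((x - xb)^2)
  e_i <- -1 / (n - 1)
  s1 <- 0; for (i in seq_len(n)) for (j in seq_len(n)) s1 <- s1 + (w[i, j] + w[j, i])^2
  s1 <- s1 / 2
  s2 <- 0; for (i in seq_len(n)) s2 <- s2 + (sum(w[i, ]) + sum(w[, i]))^2
  v <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  z <- (i_obs - e_i) / sqrt(v)
  list(i = i_obs, p = 2 * pnorm(-abs(z)))
}

# random connected-ish graph for property tests
random_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1  # spine keeps it connected
  extra <- matrix(runif(n * n) < p, n, n)
  extra[lower.tri(extra, diag = TRUE)] <- FALSE
  w[extra] <- 1
  w <- pmax(w, t(w))
  diag(w) <- 0
  suppressWarnings(area_graph(w))
}

# minimal hand-built carfit for exact algebraic checks of derived surfaces
fake_carfit <- function(s_draws, beta_draws, y, E, X, graph,
                        model = "leroux", u_draws = NULL) {
  mu <- s_draws + beta_draws %*% t(X)
  if (!is.null(u_draws)) mu <- mu + u_draws
  draws <- list(s = s_draws, beta = beta_draws, mu = mu,
                sigma_s2 = rep(0.1, nrow(s_draws)))
  if (!is.null(u_draws)) draws$u <- u_draws
  structure(list(model = model, draws = draws, y = y, E = E, X = X,
                 graph = graph), class = "carfit")
}
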