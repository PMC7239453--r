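test_that("areal variogram reproduces hand-computed values", {
  # two adjacent areas, z = (0, 2)
  g2 <- graph_from_edges(cbind("A", "B"))
  d2 <- boundary_distances(g2)
  v2 <- areal_variogram(c(0, 2), d2, H = 1)
  expect_equal(unname(v2$gamma_area[, 1]), c(2, 2))
  expect_equal(v2$gamma_mean, 2)
  # path A-B-C, z = (0, 1, 2): gamma_A(2) = (1 + 4)/(2*2)
  g3 <- graph_from_edges(rbind(c("A", "B"), c("B", "C")))
  v3 <- areal_variogram(c(0, 1, 2), boundary_distances(g3), H = 2)
  expect_equal(v3$gamma_area[1, 2], 1.25)
  # constant surface: flat variogram
  vc <- areal_variogram(rep(3, 3), boundary_distances(g3), H = 2)
  expect_equal(vc$gamma_mean, c(0, 0))
})

test_that("variogram agrees with the brute-force oracle on random graphs", {
  for (seed in 1:5) {
    g <- random_graph(sample(8:25, 1), p = 0.2, seed = seed)
    d <- boundary_distances(g)
    z <- rnorm(g$n)
    H <- 3
    expect_equal(areal_variogram(z, d, H)$gamma_mean,
                 oracle_variogram_mean(z, unclass(d), H), tolerance = 1e-12)
  }
})

test_that("variogram counts are monotone in the lag", {
  g <- random_graph(20, seed = 9)
  v <- areal_variogram(rnorm(20), boundary_distances(g), H = 4)
  expect_true(all(apply(v$counts, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(v$gamma_area >= 0, na.rm = TRUE))
})

test_that("variogram ratio: identity, flatness, and exact affine scaling", {
  g <- make_lattice(4, 5)
  d <- boundary_distances(g)
  z <- rnorm(20)
  expect_equal(variogram_ratio(z, z, d), 1)
  # a flat smoothed surface signals total over-smoothing
  expect_equal(variogram_ratio(rep(1, 20), z, d), 0)
  # affine surfaces scale the ratio by b^2, exactly
  for (b in c(0.5, 0.3, 2)) {
    expect_equal(variogram_ratio(1.7 + b * z, z, d), b^2, tolerance = 1e-12)
  }
  # degenerate raw surface errors
  expect_error(variogram_ratio(z, rep(2, 20), d), "zero")
})

test_that("spatial excess kurtosis matches its limiting cases", {
  g <- make_lattice(6, 6)
  # checkerboard: deviations form a symmetric two-point set -> -2
  cb <- ifelse((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2 == 0, 1, -1)
  z <- as.vector(t(cb))
  expect_equal(spatial_excess_kurtosis(z, g), -2)
  # large-N Gaussian deviations: excess kurtosis near 0
  gl <- make_lattice(40, 40)
  set.seed(42)
  expect_equal(spatial_excess_kurtosis(rnorm(1600), gl), 0, tolerance = 0.35)
  # one extreme deviation among near-zero ones dominates
  spike <- c(rep(0, 35), 10)
  expect_gt(spatial_excess_kurtosis(spike, g), 5)
  expect_error(spatial_excess_kurtosis(rep(1, 36), g), "constant")
})

test_that("roughness: zero for constants, homogeneous of degree 1, checkerboard value", {
  g <- make_lattice(6, 6)
  expect_equal(roughness(rep(2.2, 36), g), 0)
  z <- rnorm(36)
  expect_equal(roughness(3 * z, g), 3 * roughness(z, g))
  cb <- as.vector(t(ifelse((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2 == 0, 1, -1)))
  expect_equal(roughness(cb, g), 2, tolerance = 0.02)  # deviations are exactly +/-2
})

test_that("quantile categorisation follows the half-open interval rule", {
  z <- 1:100
  cat3 <- quantile_categorize(z, c(0.25, 0.75))
  expect_equal(unname(table(cat3)), c(25, 50, 25), ignore_attr = TRUE)
  expect_warning(catc <- quantile_categorize(rep(1, 10), c(0.25, 0.75)), "degenerate")
  expect_true(all(catc == 1))
  # heavy ties at a cut point: compare against explicit half-open counting
  zt <- c(rep(1, 6), rep(2, 8), rep(3, 6))
  q <- quantile(zt, c(0.25, 0.75), type = 7, names = FALSE)
  brute <- vapply(zt, function(v) 1L + sum(v >= q), 1L)
  expect_equal(quantile_categorize(zt, c(0.25, 0.75)), brute)
})

test_that("Cohen's kappa: analytic cases and oracle agreement", {
  a <- rep(1:2, each = 9)
  expect_equal(cohens_kappa(a, a), 1)              # perfect agreement
  expect_equal(cohens_kappa(a, 3 - a), -1)         # balanced perfect disagreement
  # confusion matrix [[2,1],[1,2]] -> 1/3
  x <- c(1, 1, 1, 2, 2, 2); y <- c(1, 1, 2, 1, 2, 2)
  expect_equal(cohens_kappa(x, y), 1 / 3)
  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)), "undefined")
  # random categorisations against the double-loop oracle
  for (seed in 1:6) {
    set.seed(seed)
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(cohens_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-12)
  }
  # invariance to consistent relabelling
  set.seed(9)
  a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_equal(cohens_kappa(4 - a, 4 - b), cohens_kappa(a, b))
})

test_that("kappa smoothing statistic: rank invariance and flatness behaviour", {
  set.seed(11)
  carsir <- exp(rnorm(60))
  expect_equal(kappa_gos(carsir, carsir, 3), 1)
  expect_equal(kappa_gos(carsir, carsir, 5), 1)
  # strictly monotone transform preserves ranks hence kappa = 1
  expect_equal(kappa_gos(carsir^0.3, carsir, 3), 1)
  expect_equal(kappa_gos(log(carsir + 2), carsir, 5), 1)
  # a constant smoothed surface gives a single category: no agreement structure
  expect_warning(k <- kappa_gos(rep(1, 60), carsir, 3))
  expect_lt(abs(k), 0.2)
})

test_that("fraction of spatial variation: limits, example, invariance", {
  expect_equal(psi_fraction(c(0, 1, 2), rep(5, 3)), 1)
  expect_equal(psi_fraction(rep(1, 3), c(0, 1, 4)), 0)
  expect_equal(psi_fraction(c(0, 1, 2), c(0, 2, 4)), 0.2)
  set.seed(3)
  s <- rnorm(20); e <- rnorm(20)
  expect_equal(psi_fraction(s, e), oracle_psi(s, e), tolerance = 1e-12)
  expect_equal(psi_fraction(s + 7, e - 2), psi_fraction(s, e))
  expect_true(psi_fraction(s, e) >= 0 && psi_fraction(s, e) <= 1)
  expect_error(psi_fraction(rep(1, 4), rep(2, 4)), "undefined")
})

test_that("relative position of CASIR hits its endpoints and midpoint", {
  g <- graph_from_edges(rbind(c("A", "B"), c("B", "C")))
  # constant-over-draws surfaces so posterior means equal the constructed values
  casir_v <- c(1.2, 1.0, sqrt(0.9))
  y <- c(12, 15, 9); E <- rep(10, 3)       # carsir (beta = 0): 1.2, 1.5, 0.9
  fit <- fake_carfit(s_draws = rbind(log(casir_v), log(casir_v)),
                     beta_draws = matrix(0, 2, 1), y = y, E = E,
                     X = matrix(1, 3, 1), graph = g)
  rp <- relative_position_casir(fit)
  expect_equal(rp$rel_pos[1], 0)   # CASIR = CARSIR: no shrinkage
  # area C: m_C = casir_B = 1.0, casir_C at the log midpoint of (0.9, 1.0)
  expect_equal(rp$rel_pos[3], 0.5)
  # area B by direct interpolation: m_B = mean(casir_A, casir_C)
  m_b <- mean(casir_v[c(1, 3)])
  expect_equal(rp$rel_pos[2],
               (log(casir_v[2]) - log(1.5)) / (log(m_b) - log(1.5)))
  expect_false(any(rp$excluded))
})

test_that("relative position exclusion rules are local and reasoned", {
  g <- make_lattice(2, 3)
  casir_v <- c(1.3, 1.1, 0.9, 1.0, 1.05, 0.95)
  y <- c(13, 0, 9, 10, 11, 9); E <- rep(10, 6)   # area 2 has a zero count
  fit <- fake_carfit(rbind(log(casir_v), log(casir_v)), matrix(0, 2, 1),
                     y, E, matrix(1, 6, 1), g)
  rp <- relative_position_casir(fit)
  expect_true(rp$excluded[2])
  expect_equal(rp$reason[2], "zero_count")
  # tightening the range threshold excludes more areas but leaves others' values
  rp2 <- relative_position_casir(fit, min_log_range = 0.2)
  keep <- !rp2$excluded
  expect_true(sum(rp2$excluded) >= sum(rp$excluded))
  expect_equal(rp2$rel_pos[keep], rp$rel_pos[keep])
  # capping is for reporting only
  expect_true(all(rp$capped >= -0.2 & rp$capped <= 1.2, na.rm = TRUE))
})

test_that("cut-off profiles encode the published bounds and drive PASS/FAIL", {
  pu <- cutoff_profile("pu")
  expect_equal(pu$variogram, c(0.1, 0.4))
  expect_equal(pu$kappa, c(0.05, 0.7))
  expect_equal(pu$rel_pos_range, c(0.2, 0.98))
  expect_true(is.na(pu$kurtosis_tol))
  u <- cutoff_profile("u")
  expect_equal(u$variogram, c(0.2, 0.8))
  expect_equal(u$kurtosis_tol, 0.3)

  mk <- function(vr, kap, rel, rough = 1, ks = 1, kr = 0) {
    structure(list(variogram_ratio = vr,
                   kurtosis = list(kurtosis_smoothed = ks, kurtosis_raw = kr,
                                   roughness = rough),
                   kappa3 = kap, kappa5 = kap, psi = 0.5,
                   rel_pos = data.frame(rel_pos = rel,
                                        excluded = rep(FALSE, length(rel)),
                                        reason = NA_character_)),
              class = "gos_result")
  }
  r <- mk(0.5, 0.97, rep(0.5, 20))
  fl_u <- suppressWarnings(apply_cutoffs(r, u))
  expect_true(fl_u[["variogram"]])        # 0.5 in (0.2, 0.8)
  expect_false(fl_u[["kappa"]])           # 0.97 > 0.95: under-smoothing side
  expect_true(fl_u[["rel_pos"]])
  # rel-pos: 90% of areas inside (0.2, 0.98) passes the 75% (pu) requirement
  rel <- c(rep(0.5, 18), 1.1, -0.1)
  expect_true(apply_cutoffs(mk(0.2, 0.3, rel), pu)[["rel_pos"]])
  # kurtosis criterion needs the comparison set's minimum roughness
  set <- list(mk(0.5, 0.5, 0.5, rough = 0.10), mk(0.5, 0.5, 0.5, rough = 0.12),
              mk(0.5, 0.5, 0.5, rough = 0.20))
  fl <- apply_cutoffs(set[[2]], u, comparison_set = set)
  expect_true(fl[["kurtosis"]])           # 0.12 < 0.10 * 1.3 and kurtosis preserved
  fl3 <- apply_cutoffs(set[[3]], u, comparison_set = set)
  expect_false(fl3[["kurtosis"]])         # 0.20 > 0.13
  expect_warning(apply_cutoffs(set[[1]], u, comparison_set = set[1]), "singleton")
})

test_that("consensus counts passes over the three penalised criteria", {
  fl <- list(
    A = c(variogram = FALSE, kurtosis = NA, kappa = TRUE, rel_pos = FALSE),
    B = c(variogram = TRUE, kurtosis = NA, kappa = TRUE, rel_pos = TRUE),
    C = c(variogram = TRUE, kurtosis = NA, kappa = FALSE, rel_pos = TRUE))
  cs <- consensus(fl)
  expect_equal(cs$n_pass, c(1L, 3L, 2L))
  expect_equal(cs$consensus, c(FALSE, TRUE, TRUE))
})
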