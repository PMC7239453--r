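#' Areal variogram on boundary-crossing distance
#'
#' The classical variogram adapted to areal data: for area i at lag h,
#' \deqn{\gamma_i(h) = \frac{1}{2 N_i(h)} \sum_{j \sim i} (z_i - z_j)^2}
#' where the sum runs over areas j no more distant than h boundary
#' crossings from i (\eqn{0 < d_{ij} \le h}) and \eqn{N_i(h)} counts them.
#' The area-averaged variogram \eqn{\gamma(h)} is the mean of
#' \eqn{\gamma_i(h)} over areas with \eqn{N_i(h) > 0}.
#'
#' @param z numeric per-area vector.
#' @param d a [boundary_distances()] matrix.
#' @param H maximum lag; defaults to the largest finite distance in `d`.
#' @return object of class `areal_variogram`: list with `lags`,
#'   `gamma_area` (N x H, `NA` where \eqn{N_i(h) = 0}), `gamma_mean`
#'   (length H) and `counts`.
#' @examples
#' g <- make_lattice(4, 4)
#' v <- areal_variogram(rnorm(16), boundary_distances(g))
#' v$gamma_mean
#' @export
areal_variogram <- function(z, d, H = NULL) {
  stopifnot(is.matrix(d), all(is.finite(z)))
  n <- length(z)
  if (nrow(d) != n) stop("z and d disagree on the number of areas")
  finite <- d[is.finite(d) & d > 0]
  if (is.null(H)) H <- if (length(finite)) max(finite) else 1
  H <- as.integer(H)
  if (H < 1) stop("H must be at least 1")
  D2 <- outer(z, z, `-`)^2
  gamma_area <- matrix(NA_real_, n, H)
  counts <- matrix(0L, n, H)
  for (h in seq_len(H)) {
    A <- is.finite(d) & d > 0 & d <= h
    cnt <- rowSums(A)
    ss <- rowSums(D2 * A)
    counts[, h] <- cnt
    gamma_area[, h] <- ifelse(cnt > 0, ss / (2 * cnt), NA_real_)
  }
  gamma_mean <- apply(gamma_area, 2, function(col) {
    if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
  })
  structure(list(lags = seq_len(H), gamma_area = gamma_area,
                 gamma_mean = gamma_mean, counts = counts),
            class = "areal_variogram")
}

#' @export
print.areal_variogram <- function(x, ...) {
  cat("areal variogram, lags 1..", max(x$lags), "\n", sep = "")
  print(round(stats::setNames(x$gamma_mean, paste0("h=", x$lags)), 4))
  invisible(x)
}

#' Plot area-averaged variograms
#' @param x an [areal_variogram()].
#' @param add add to an existing plot.
#' @param ... passed to [graphics::lines()]/[graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.areal_variogram <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$lags, x$gamma_mean, ...)
  else graphics::plot(x$lags, x$gamma_mean, type = "b", xlab = "lag h",
                      ylab = expression(gamma(h)), ...)
  invisible(x)
}

#' Variogram-ratio smoothing statistic
#'
#' The ratio of the area-averaged variograms of the smoothed surface
#' (CASIR) to its raw counterpart (CARSIR), averaged over lags
#' \eqn{1, \dots, H}. A flat smoothed variogram (ratio near 0) indicates
#' over-smoothing; a ratio near 1 says the smoothed surface is as rough as
#' the raw one, i.e. under-smoothing.
#'
#' @param casir,carsir per-area posterior point estimates of CASIR and
#'   CARSIR, on the same graph.
#' @param d a [boundary_distances()] matrix.
#' @param H maximum lag (see [areal_variogram()]).
#' @return the mean over lags of \eqn{\gamma_{CASIR}(h)/\gamma_{CARSIR}(h)};
#'   lags with a zero raw variogram are dropped with a warning.
#' @export
variogram_ratio <- function(casir, carsir, d, H = NULL) {
  vs <- areal_variogram(casir, d, H)
  vr <- areal_variogram(carsir, d, H)
  num <- vs$gamma_mean
  den <- vr$gamma_mean
  bad <- is.na(den) | den == 0
  if (all(bad)) stop("raw-surface variogram is zero or undefined at every lag")
  if (any(bad)) warning(sum(bad), " lag(s) with zero raw variogram excluded")
  mean(num[!bad] / den[!bad])
}

#' Spatial excess kurtosis and roughness
#'
#' Both statistics are built from the first-order neighbourhood deviations
#' \eqn{e_i = z_i - \bar z(w_i)}, the areal analogue of a first-difference
#' series. The excess kurtosis,
#' \eqn{\mathrm{Kurt}(z) = \mathrm{E}[e^4]/\mathrm{E}[e^2]^2 - 3} with
#' moments taken as averages over areas, is large when variation is
#' dominated by infrequent extreme deviations. The roughness is the sample
#' standard deviation of the \eqn{e_i}. A good smoother minimises roughness
#' while preserving the kurtosis of the unsmoothed surface.
#'
#' @param z numeric per-area vector.
#' @param graph an [area_graph()]; isolated areas are excluded from the
#'   deviation set with a warning.
#' @return a single numeric value.
#' @export
spatial_excess_kurtosis <- function(z, graph) {
  e <- neighborhood_deviations(z, graph)
  if (length(e) < 3) stop("need at least 3 areas with neighbours")
  if (all(e == 0)) stop("constant field: spatial kurtosis undefined")
  mean(e^4) / mean(e^2)^2 - 3
}

#' @rdname spatial_excess_kurtosis
#' @export
roughness <- function(z, graph) {
  e <- neighborhood_deviations(z, graph)
  stats::sd(e)
}

neighborhood_deviations <- function(z, graph) {
  nm <- suppressWarnings(neighbor_mean(graph, z))
  e <- z - nm
  if (anyNA(e)) {
    warning("isolated area(s) excluded from neighbourhood deviations")
    e <- e[!is.na(e)]
  }
  e
}

#' Kurtosis-preservation summary for one model
#'
#' Computes the spatial excess kurtosis of the smoothed and raw surfaces
#' and the roughness of the smoothed surface. The SIR-based version is the
#' more stable in practice, so the default surfaces are the posterior SIR
#' and the raw SIR (a flag in [gos()] switches to CASIR/CARSIR). The PASS criterion — kurtosis preserved and
#' roughness within a tolerance of the minimum across a comparison set of
#' model variants — is evaluated by [apply_cutoffs()], which knows the
#' comparison set.
#'
#' @param smoothed,raw per-area surfaces on the same graph.
#' @param graph an [area_graph()].
#' @return list with `kurtosis_smoothed`, `kurtosis_raw`, `roughness`.
#' @export
kurtosis_preservation <- function(smoothed, raw, graph) {
  list(kurtosis_smoothed = spatial_excess_kurtosis(smoothed, graph),
       kurtosis_raw = spatial_excess_kurtosis(raw, graph),
       roughness = roughness(smoothed, graph))
}

#' Categorise a surface by its own empirical quantiles
#'
#' Cuts `z` at its type-7 empirical quantiles at probabilities `probs`,
#' assigning category k to values in the half-open interval
#' \eqn{[q_{k-1}, q_k)} (the last category is closed above).
#'
#' @param z numeric vector.
#' @param probs strictly increasing cut probabilities in (0, 1).
#' @return integer vector of categories in `1..(length(probs) + 1)`.
#' @export
quantile_categorize <- function(z, probs) {
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1))
    stop("probs must be strictly increasing within (0, 1)")
  if (length(unique(z)) == 1L) {
    warning("degenerate surface: all values equal, single category")
    return(rep(1L, length(z)))
  }
  q <- stats::quantile(z, probs, type = 7, names = FALSE)
  findInterval(z, q) + 1L
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical surfaces,
#' \deqn{\kappa = \frac{\Pr(A_o) - \Pr(A_e)}{1 - \Pr(A_e)}}
#' with observed agreement \eqn{\Pr(A_o) = \frac{1}{N}\sum_i c_{ii}} and
#' expected agreement \eqn{\Pr(A_e)} from the products of the row and
#' column marginals of the confusion matrix \eqn{\{c_{ij}\}}.
#'
#' @param a,b equal-length category vectors over a shared category
#'   universe.
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(rep(1:2, 9), rep(1:2, 9))  # perfect agreement: 1
#' cohens_kappa(rep(1:2, 9), rep(2:1, 9))  # balanced disagreement: -1
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("categorised surfaces must have equal length")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev)
  fb <- factor(b, levels = lev)
  cm <- table(fa, fb)
  N <- sum(cm)
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe == 1) stop("both surfaces constant in the same category: kappa undefined")
  (po - pe) / (1 - pe)
}

#' Kappa smoothing statistic
#'
#' Categorises CASIR and CARSIR each by their own empirical quantiles
#' (3 categories with cuts 0.25/0.75, or 5 with cuts 0.1/0.3/0.7/0.9) and
#' computes Cohen's kappa, treating CARSIR as the baseline. Smaller kappa
#' indicates greater smoothing; kappa near 1 indicates under-smoothing.
#'
#' @param casir,carsir per-area posterior point estimates.
#' @param n_categories 3 or 5.
#' @return kappa value.
#' @export
kappa_gos <- function(casir, carsir, n_categories = 3) {
  probs <- switch(as.character(n_categories),
                  "3" = c(0.25, 0.75),
                  "5" = c(0.1, 0.3, 0.7, 0.9),
                  stop("n_categories must be 3 or 5"))
  cohens_kappa(quantile_categorize(casir, probs),
               quantile_categorize(carsir, probs))
}

#' Fraction of spatial variation
#'
#' \deqn{\psi = \frac{\mathrm{Var}(s^*)}{\mathrm{Var}(s^*) +
#'   \mathrm{Var}(\epsilon^*)}}
#' where \eqn{s^*_i} and \eqn{\epsilon^*_i} are per-area posterior medians
#' of the structured effect and the model residuals, and the variances are
#' sample variances over areas (divisor N - 1). This generalises the
#' classic BYM structured/unstructured variance ratio to any model with one
#' structured effect.
#'
#' @param s_star,eps_star per-area posterior medians.
#' @return psi in `[0, 1]`.
#' @export
psi_fraction <- function(s_star, eps_star) {
  vs <- stats::var(s_star)
  ve <- stats::var(eps_star)
  if (vs + ve == 0) stop("both fields constant: psi undefined")
  vs / (vs + ve)
}

#' @rdname psi_fraction
#' @param fit a [fit_car()] object; medians are taken over its retained
#'   draws.
#' @export
fraction_spatial_variation <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  s_star <- apply(fit$draws$s, 2, stats::median)
  eps_star <- apply(residual_draws(fit), 2, stats::median)
  psi_fraction(s_star, eps_star)
}

#' Relative position of CASIR
#'
#' Under no smoothing the CASIR estimate of an area coincides with its raw
#' counterpart CARSIR; under maximal smoothing it is pulled to the
#' posterior mean of its neighbours' CASIR. Denoting these two extremes 0
#' and 1, the relative position
#' \deqn{r_i = \frac{\log CASIR_i - \log CARSIR_i}
#'   {\log m_i - \log CARSIR_i}}
#' (with \eqn{m_i} the neighbour mean of the posterior-mean CASIR)
#' quantifies the shrinkage experienced by each area. Computed on the log
#' scale; areas are excluded when the log-range of potential values is
#' narrower than `min_log_range` (the position is then dominated by
#' Monte-Carlo noise), when \eqn{y_i = 0} (CARSIR undefined on the log
#' scale), or when the area is isolated. Values are capped for reporting;
#' the PASS criterion uses the uncapped values of non-excluded areas.
#'
#' @param fit a [fit_car()] object.
#' @param min_log_range exclusion threshold on \eqn{|\log m_i - \log
#'   CARSIR_i|}.
#' @param cap reporting caps, default `c(-0.2, 1.2)`.
#' @param log_scale compute positions on the log scale (default); linear
#'   scale available for sensitivity checks.
#' @return data frame of class `rel_pos`: `id`, `rel_pos` (uncapped, `NA`
#'   when excluded), `capped`, `excluded`, `reason`.
#' @export
relative_position_casir <- function(fit, min_log_range = 0.03,
                                    cap = c(-0.2, 1.2), log_scale = TRUE) {
  stopifnot(inherits(fit, "carfit"))
  graph <- fit$graph
  casir_hat <- colMeans(casir(fit))
  carsir_hat <- colMeans(carsir(fit))
  m_hat <- suppressWarnings(neighbor_mean(graph, casir_hat))

  n <- graph$n
  reason <- rep(NA_character_, n)
  reason[fit$y == 0] <- "zero_count"
  reason[is.na(m_hat)] <- "isolated"
  tr <- if (log_scale) log else identity
  num <- den <- rep(NA_real_, n)
  ok0 <- is.na(reason)
  num[ok0] <- tr(casir_hat[ok0]) - tr(carsir_hat[ok0])
  den[ok0] <- tr(m_hat[ok0]) - tr(carsir_hat[ok0])
  range_log <- abs(log(m_hat) - log(carsir_hat))
  narrow <- ok0 & range_log < min_log_range
  reason[narrow] <- "narrow_range"
  r <- ifelse(is.na(reason), num / den, NA_real_)
  out <- data.frame(
    id = graph$ids,
    rel_pos = r,
    capped = pmin(pmax(r, cap[1]), cap[2]),
    excluded = !is.na(reason),
    reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rel_pos", "data.frame")
  out
}

#' Cut-off profiles for the GoS criteria
#'
#' Three named profiles translate each smoothing statistic into a PASS/FAIL
#' verdict: `"u"` (unbiased), `"c"` (conservative, less likely to choose an
#' under- or over-smoothed model) and `"pu"` (penalise under-smoothing more
#' heavily than over-smoothing). The kurtosis-preservation criterion has no
#' `"pu"` form. All bounds can be overridden.
#'
#' @param name `"u"`, `"c"` or `"pu"`.
#' @param variogram length-2 bounds on the variogram ratio.
#' @param kurtosis_tol roughness tolerance above the comparison-set minimum
#'   (0.3 = +30%); `NA` disables the criterion.
#' @param kappa length-2 bounds on kappa.
#' @param rel_pos_prop,rel_pos_range required proportion of areas and the
#'   admissible range of relative positions.
#' @return a `cutoff_profile` list.
#' @export
cutoff_profile <- function(name = c("u", "c", "pu"), variogram = NULL,
                           kurtosis_tol = NULL, kappa = NULL,
                           rel_pos_prop = NULL, rel_pos_range = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    u = list(variogram = c(0.2, 0.8), kurtosis_tol = 0.30,
             kappa = c(0.05, 0.95), rel_pos_prop = 0.75,
             rel_pos_range = c(0.01, 0.99)),
    c = list(variogram = c(0.25, 0.75), kurtosis_tol = 0.10,
             kappa = c(0.1, 0.9), rel_pos_prop = 0.85,
             rel_pos_range = c(0.02, 0.98)),
    pu = list(variogram = c(0.1, 0.4), kurtosis_tol = NA_real_,
              kappa = c(0.05, 0.7), rel_pos_prop = 0.75,
              rel_pos_range = c(0.2, 0.98)))
  if (!is.null(variogram)) def$variogram <- variogram
  if (!is.null(kurtosis_tol)) def$kurtosis_tol <- kurtosis_tol
  if (!is.null(kappa)) def$kappa <- kappa
  if (!is.null(rel_pos_prop)) def$rel_pos_prop <- rel_pos_prop
  if (!is.null(rel_pos_range)) def$rel_pos_range <- rel_pos_range
  structure(c(list(name = name), def), class = "cutoff_profile")
}

#' Goodness-of-smoothing statistics for one fitted model
#'
#' Computes all five smoothing statistics from a fit: the variogram ratio
#' of CASIR to CARSIR, the kurtosis-preservation pair with roughness, kappa
#' with 3 and 5 categories, the fraction of spatial variation, and the
#' per-area relative position of CASIR. PASS/FAIL verdicts are attached
#' later by [apply_cutoffs()], which needs the comparison set of competing
#' variants for the roughness criterion.
#'
#' @param fit a [fit_car()] object.
#' @param H maximum variogram lag (default: resolved from the graph).
#' @param kurtosis_surface `"sir"` (default: posterior SIR vs raw SIR) or
#'   `"casir"` (CASIR vs CARSIR) for the kurtosis/roughness inputs.
#' @param min_log_range,cap passed to [relative_position_casir()].
#' @return object of class `gos_result`: list with elements
#'   `variogram_ratio`, `kurtosis` (list), `kappa3`, `kappa5`, `psi`,
#'   `rel_pos` (data frame), plus the surfaces used.
#' @export
gos <- function(fit, H = NULL, kurtosis_surface = c("sir", "casir"),
                min_log_range = 0.03, cap = c(-0.2, 1.2)) {
  stopifnot(inherits(fit, "carfit"))
  kurtosis_surface <- match.arg(kurtosis_surface)
  graph <- fit$graph
  d <- boundary_distances(graph)
  surf <- derived_surfaces(fit)
  ksmooth <- if (kurtosis_surface == "sir") surf$sir else surf$casir
  kraw <- if (kurtosis_surface == "sir") surf$raw_sir else surf$carsir
  structure(list(
    variogram_ratio = variogram_ratio(surf$casir, surf$carsir, d, H),
    kurtosis = kurtosis_preservation(ksmooth, kraw, graph),
    kappa3 = kappa_gos(surf$casir, surf$carsir, 3),
    kappa5 = kappa_gos(surf$casir, surf$carsir, 5),
    psi = fraction_spatial_variation(fit),
    rel_pos = relative_position_casir(fit, min_log_range, cap),
    surfaces = surf,
    model = fit$model
  ), class = "gos_result")
}

#' @export
print.gos_result <- function(x, ...) {
  rp <- x$rel_pos$rel_pos[!x$rel_pos$excluded]
  cat("goodness-of-smoothing statistics\n")
  cat(sprintf("  variogram ratio : %.3f\n", x$variogram_ratio))
  cat(sprintf("  kurtosis        : smoothed %.2f vs raw %.2f (roughness %.4f)\n",
              x$kurtosis$kurtosis_smoothed, x$kurtosis$kurtosis_raw,
              x$kurtosis$roughness))
  cat(sprintf("  kappa (3/5 cat) : %.3f / %.3f\n", x$kappa3, x$kappa5))
  cat(sprintf("  psi             : %.3f\n", x$psi))
  cat(sprintf("  rel. position   : median %.3f (%d of %d areas evaluated)\n",
              stats::median(rp), length(rp), nrow(x$rel_pos)))
  invisible(x)
}

#' PASS/FAIL verdicts under a cut-off profile
#'
#' Applies a [cutoff_profile()] to one model's [gos()] result. The
#' kurtosis criterion (kurtosis preserved AND roughness below the
#' comparison-set minimum plus its tolerance) needs the competing variants'
#' results; with a singleton comparison set the roughness part degenerates
#' to PASS and a warning is raised.
#'
#' @param result a [gos()] result.
#' @param profile a [cutoff_profile()].
#' @param comparison_set list of [gos()] results across the variants being
#'   compared (including `result` itself); used only by the kurtosis
#'   criterion.
#' @param kappa_categories use the 3- or 5-category kappa.
#' @return named logical vector over criteria `variogram`, `kurtosis`
#'   (`NA` when the profile disables it), `kappa`, `rel_pos`.
#' @export
apply_cutoffs <- function(result, profile = cutoff_profile("u"),
                          comparison_set = list(result),
                          kappa_categories = 3) {
  stopifnot(inherits(result, "gos_result"), inherits(profile, "cutoff_profile"))
  vr <- result$variogram_ratio
  pass_v <- vr >= profile$variogram[1] && vr <= profile$variogram[2]

  if (is.na(profile$kurtosis_tol)) {
    pass_k <- NA
  } else {
    if (length(comparison_set) < 2)
      warning("singleton comparison set: roughness criterion degenerates to PASS")
    rmin <- min(vapply(comparison_set, function(r) r$kurtosis$roughness, 1.0))
    pass_k <- (result$kurtosis$kurtosis_smoothed >= result$kurtosis$kurtosis_raw) &&
      (result$kurtosis$roughness < rmin * (1 + profile$kurtosis_tol))
  }

  kap <- if (kappa_categories == 3) result$kappa3 else result$kappa5
  pass_kap <- kap >= profile$kappa[1] && kap <= profile$kappa[2]

  rp <- result$rel_pos$rel_pos[!result$rel_pos$excluded]
  prop_in <- mean(rp >= profile$rel_pos_range[1] & rp <= profile$rel_pos_range[2])
  pass_rp <- prop_in >= profile$rel_pos_prop

  c(variogram = pass_v, kurtosis = pass_k, kappa = pass_kap, rel_pos = pass_rp)
}

#' Consensus count over the penalise-under-smoothing criteria
#'
#' Counts, per model variant, how many of the three consensus criteria
#' (variogram ratio, kappa, relative position, all under the `"pu"`
#' profile) PASS. A variant with 2 or 3 passes is in consensus: it is
#' judged neither clearly under- nor over-smoothing by a majority of the
#' statistics.
#'
#' @param flags named list (one element per variant) of logical vectors as
#'   returned by [apply_cutoffs()], or a matrix with those criteria as
#'   columns.
#' @return data frame with `variant`, `n_pass` (0-3) and `consensus`
#'   (`n_pass >= 2`).
#' @export
consensus <- function(flags) {
  if (is.matrix(flags)) flags <- split(flags, row(flags, as.factor = TRUE))
  crit <- c("variogram", "kappa", "rel_pos")
  n_pass <- vapply(flags, function(f) sum(f[crit], na.rm = TRUE), 1L)
  data.frame(variant = names(flags) %||% seq_along(flags),
             n_pass = as.integer(n_pass),
             consensus = n_pass >= 2L,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
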