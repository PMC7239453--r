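#' Run a full model-comparison workflow
#'
#' Fits every configured model variant to one areal dataset, computes the
#' goodness-of-smoothing and goodness-of-fit statistics for each, applies
#' the requested cut-off profiles, and forms the consensus over the three
#' penalise-under-smoothing criteria (variogram ratio, kappa, relative
#' position, profile `"pu"`). Per-variant seeds are derived by hashing the
#' master seed with the variant label, so adding a variant does not perturb
#' the others. A variant whose sampler fails is recorded and skipped.
#'
#' @param config either a path to a YAML file or a list with elements:
#'   \describe{
#'     \item{data}{an [area_data()] or a CSV path for [read_area_data()].}
#'     \item{graph}{an [area_graph()] or a GAL path for [read_gal()].}
#'     \item{variants}{named list; each element a list with `model`
#'       (`"leroux"`/`"bym"`), `family` (`"ig"`/`"ltn"`) and the
#'       hyperparameters (`alpha`/`eta` or `mean`/`var`), or directly a
#'       `hyperprior` object plus `model`.}
#'     \item{mcmc}{arguments for [mcmc_control()] (seed is overridden per
#'       variant).}
#'     \item{profiles}{character vector of profile names, default
#'       `c("u", "c", "pu")`.}
#'     \item{seed}{master seed.}
#'   }
#' @return object of class `comparison_bundle`: per-variant `gos` and
#'   `gof` results, flags (variant x criterion x profile), the GoF
#'   comparison table, the consensus table, and any per-variant errors.
#' @export
run_comparison <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  data <- config$data
  if (is.character(data)) data <- read_area_data(data)
  graph <- config$graph
  if (is.character(graph)) graph <- read_gal(graph)
  profiles <- config$profiles %||% c("u", "c", "pu")
  seed <- as.integer(config$seed %||% 1L)
  mcmc_args <- config$mcmc %||% list()
  variants <- config$variants
  if (is.null(names(variants)) || any(names(variants) == ""))
    stop("variants must be a named list with unique labels")
  if (anyDuplicated(names(variants))) stop("variant labels must be unique")

  formula <- stats::as.formula(config$formula %||% default_formula(data))

  gos_list <- list()
  gof_list <- list()
  errors <- list()
  for (lab in names(variants)) {
    v <- variants[[lab]]
    hp <- if (inherits(v$hyperprior, "hyperprior")) v$hyperprior
          else if ((v$family %||% "ig") == "ig") hyperprior_ig(v$alpha, v$eta)
          else hyperprior_ltn(v$mean, v$var)
    mc <- do.call(mcmc_control,
                  utils::modifyList(mcmc_args, list(seed = variant_seed(seed, lab))))
    res <- tryCatch({
      fit <- fit_car(formula, data, graph, model = v$model %||% "leroux",
                     hyperprior = hp, mcmc = mc)
      list(gos = gos(fit), gof = gof(fit))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[lab]] <- conditionMessage(res)
    } else {
      gos_list[[lab]] <- res$gos
      gof_list[[lab]] <- res$gof
    }
  }
  if (!length(gos_list)) stop("all variants failed: ",
                              paste(unlist(errors), collapse = "; "))

  flags <- array(NA, dim = c(length(gos_list), 4L, length(profiles)),
                 dimnames = list(names(gos_list),
                                 c("variogram", "kurtosis", "kappa", "rel_pos"),
                                 profiles))
  for (pr in profiles) {
    prof <- cutoff_profile(pr)
    for (lab in names(gos_list)) {
      flags[lab, , pr] <- suppressWarnings(
        apply_cutoffs(gos_list[[lab]], prof, comparison_set = gos_list))
    }
  }
  cons <- if ("pu" %in% profiles) {
    consensus(lapply(names(gos_list), function(l) flags[l, , "pu"]) |>
                stats::setNames(names(gos_list)))
  }
  structure(list(variants = names(gos_list), gos = gos_list, gof = gof_list,
                 flags = flags, profiles = profiles,
                 gof_table = compare_models(gof_list),
                 consensus = cons, errors = errors, seed = seed),
            class = "comparison_bundle")
}

default_formula <- function(data) {
  covs <- setdiff(names(data), c("id", "y", "E"))
  if (length(covs)) paste("y ~", paste(covs, collapse = " + ")) else "y ~ 1"
}

# deterministic per-variant seed below 2^31
variant_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 94906249
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647) + 1L
}

#' @export
print.comparison_bundle <- function(x, ...) {
  cat(sprintf("model comparison over %d variant(s), master seed %d\n",
              length(x$variants), x$seed))
  if (!is.null(x$consensus)) {
    cat("\nconsensus over the penalise-under-smoothing criteria:\n")
    print(x$consensus)
  }
  if (length(x$errors)) {
    cat("\nfailed variants:\n")
    for (l in names(x$errors)) cat(" ", l, ":", x$errors[[l]], "\n")
  }
  invisible(x)
}

#' Render comparison tables (and optionally write them)
#'
#' Produces tidy tables from a [run_comparison()] bundle: one row per
#' (variant, statistic) for the GoS values, one row per (variant,
#' criterion, profile) for the PASS/FAIL flags, the GoF comparison table
#' and the consensus counts. When `dir` is given the tables are written as
#' CSV plus a combined JSON report.
#'
#' @param bundle a [run_comparison()] result.
#' @param dir optional output directory.
#' @return list of data frames `gos`, `flags`, `gof`, `consensus`,
#'   invisibly when writing.
#' @export
render_report <- function(bundle, dir = NULL) {
  stopifnot(inherits(bundle, "comparison_bundle"))
  gs <- do.call(rbind, lapply(names(bundle$gos), function(lab) {
    g <- bundle$gos[[lab]]
    rp <- g$rel_pos$rel_pos[!g$rel_pos$excluded]
    data.frame(variant = lab,
               statistic = c("variogram_ratio", "kurtosis_smoothed",
                             "kurtosis_raw", "roughness", "kappa3", "kappa5",
                             "psi", "rel_pos_median"),
               value = c(g$variogram_ratio, g$kurtosis$kurtosis_smoothed,
                         g$kurtosis$kurtosis_raw, g$kurtosis$roughness,
                         g$kappa3, g$kappa5, g$psi,
                         if (length(rp)) stats::median(rp) else NA_real_),
               stringsAsFactors = FALSE)
  }))
  fl <- expand.grid(variant = dimnames(bundle$flags)[[1]],
                    criterion = dimnames(bundle$flags)[[2]],
                    profile = dimnames(bundle$flags)[[3]],
                    stringsAsFactors = FALSE)
  fl$pass <- mapply(function(v, c, p) bundle$flags[v, c, p],
                    fl$variant, fl$criterion, fl$profile)
  out <- list(gos = gs, flags = fl, gof = bundle$gof_table,
              consensus = bundle$consensus)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(gs, file.path(dir, "gos_statistics.csv"), row.names = FALSE)
    utils::write.csv(fl, file.path(dir, "gos_flags.csv"), row.names = FALSE)
    utils::write.csv(bundle$gof_table, file.path(dir, "gof_comparison.csv"),
                     row.names = FALSE)
    if (!is.null(bundle$consensus))
      utils::write.csv(bundle$consensus, file.path(dir, "consensus.csv"),
                       row.names = FALSE)
    jsonlite::write_json(out, file.path(dir, "report.json"),
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}
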