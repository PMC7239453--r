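#' Areal count data
#'
#' Container for small-area disease counts: observed counts `y`, expected
#' counts `E` (from indirect standardisation), and any covariates. The raw
#' standardised incidence ratio is `y/E`.
#'
#' @param y non-negative integer observed counts.
#' @param E strictly positive expected counts.
#' @param covariates optional data frame of per-area covariates.
#' @param ids area labels; default `"A1"..."An"`. Must match the graph the
#'   data are modelled on.
#' @return object of class `area_data`: a data frame with columns `id`,
#'   `y`, `E` and the covariates, in input order.
#' @export
area_data <- function(y, E, covariates = NULL, ids = NULL) {
  n <- length(y)
  if (length(E) != n) stop("y and E must have the same length")
  if (anyNA(y) || anyNA(E)) stop("missing values in y or E are not allowed")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(E <= 0)) stop("expected counts E must be strictly positive")
  if (is.null(ids)) ids <- paste0("A", seq_len(n))
  df <- data.frame(id = as.character(ids), y = as.integer(y), E = as.numeric(E),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per area")
    if (any(names(covariates) %in% names(df)))
      stop("covariate names clash with id/y/E")
    df <- cbind(df, covariates)
  }
  class(df) <- c("area_data", "data.frame")
  df
}

#' @export
print.area_data <- function(x, ...) {
  cat(sprintf("area_data: %d areas, %d covariate(s); total y = %d, total E = %.1f\n",
              nrow(x), ncol(x) - 3L, sum(x$y), sum(x$E)))
  NextMethod()
}

#' Read areal count data from CSV
#'
#' Expects columns `id`, `y`, `E`; any further columns are kept as
#' covariates.
#'
#' @param path CSV file path.
#' @return an [area_data()] object.
#' @export
read_area_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "y", "E")
  if (!all(need %in% names(df))) stop("CSV must contain columns id, y, E")
  extra <- setdiff(names(df), need)
  area_data(df$y, df$E,
            covariates = if (length(extra)) df[extra] else NULL,
            ids = df$id)
}

#' Write areal count data to CSV
#' @param data an [area_data()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_area_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
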