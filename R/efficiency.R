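#' Construct a dilution series
#'
#' Holds replicate Ct values measured over a serial dilution of template,
#' the input to standard-curve efficiency estimation.
#'
#' @param levels relative template concentrations (unitless, strictly
#'   positive, at least 3 distinct values), e.g. `5^-(1:5)` for a 5-fold
#'   series.
#' @param ct_values numeric matrix of Ct values, one row per level, one
#'   column per replicate (`NA` allowed for dropped wells), or a vector of
#'   one Ct per level.
#' @return an object of class `dilution_series`.
#' @export
dilution_series <- function(levels, ct_values) {
  levels <- as.numeric(levels)
  if (length(unique(levels)) < 3L) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(levels <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (!is.matrix(ct_values)) ct_values <- matrix(ct_values, ncol = 1L)
  if (nrow(ct_values) != length(levels)) {
    stop("ct_values must have one row per dilution level", call. = FALSE)
  }
  if (any(rowSums(!is.na(ct_values)) == 0L)) {
    stop("every level needs at least one non-missing Ct", call. = FALSE)
  }
  structure(list(levels = levels, ct_values = ct_values),
            class = "dilution_series")
}

#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least squares of the mean Ct per dilution level against
#' log10(relative concentration). The amplification efficiency follows from
#' the slope as \deqn{E = 10^{-1/slope} - 1} (100\% = perfect doubling per
#' cycle, slope -3.3219). R-squared is reported from the level-means
#' regression, matching how instrument software reports it. A result is
#' flagged acceptable when `E_percent` falls within `e_band` and R-squared
#' is at least `r2_min`.
#'
#' @param d a [dilution_series()].
#' @param e_band acceptance band for `E_percent` (default `c(90, 110)`).
#' @param r2_min minimum acceptable R-squared (default 0.98).
#' @return an object of class `efficiency_result`: list with `slope`
#'   (cycles per log10 concentration), `intercept` (cycles), `E_percent`,
#'   `R2`, `acceptable`, `n_levels`.
#' @export
fit_standard_curve <- function(d, e_band = c(90, 110), r2_min = 0.98) {
  stopifnot(inherits(d, "dilution_series"))
  mean_ct <- rowMeans(d$ct_values, na.rm = TRUE)
  lx <- log10(d$levels)
  fit <- stats::lm(mean_ct ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0) {
    stop("non-amplifying series: standard-curve slope is not negative",
         call. = FALSE)
  }
  e_pct <- (10^(-1 / slope) - 1) * 100
  # squared Pearson correlation of the fitted line with the level means
  # (identical to the regression R2, but quiet on exact fits)
  r2 <- stats::cor(stats::fitted(fit), mean_ct)^2
  structure(list(slope = slope, intercept = intercept, E_percent = e_pct,
                 R2 = r2,
                 acceptable = e_pct >= e_band[1L] && e_pct <= e_band[2L] &&
                   r2 >= r2_min,
                 n_levels = length(d$levels)),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf(
    "standard curve: slope %.4f, E = %.3f%%, R2 = %.4f (%s)\n",
    x$slope, x$E_percent, x$R2,
    if (x$acceptable) "acceptable" else "outside acceptance band"))
  invisible(x)
}

#' Fit standard curves for several genes
#'
#' @param series named list of [dilution_series()], one per gene.
#' @param ... passed to [fit_standard_curve()].
#' @return data.frame with one row per gene: `gene_id`, `slope`,
#'   `intercept`, `E_percent`, `R2`, `acceptable`.
#' @export
fit_standard_curves <- function(series, ...) {
  stopifnot(is.list(series), !is.null(names(series)))
  rows <- lapply(names(series), function(g) {
    r <- fit_standard_curve(series[[g]], ...)
    data.frame(gene_id = g, slope = r$slope, intercept = r$intercept,
               E_percent = r$E_percent, R2 = r$R2, acceptable = r$acceptable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
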