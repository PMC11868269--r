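#' Per-sample normalization factor from a reference set
#'
#' The normalization factor for sample s is the geometric mean of the
#' selected reference genes' relative quantities:
#' `NF_s = (prod_r Q_rs)^(1/|refs|)`. With a single reference it equals
#' that gene's Q row.
#'
#' @param q a [relative_quantities()] result.
#' @param refs nonempty character vector of reference gene ids present in
#'   `q`.
#' @return named numeric vector of per-sample factors (> 0), with attribute
#'   `"refs"`.
#' @export
normalization_factor <- function(q, refs) {
  stopifnot(inherits(q, "qmatrix"))
  if (!length(refs)) stop("`refs` must be nonempty", call. = FALSE)
  unknown <- setdiff(refs, rownames(q$q))
  if (length(unknown)) {
    stop("unknown reference gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nf <- exp(colMeans(log(q$q[refs, , drop = FALSE])))
  names(nf) <- q$samples$sample_id
  attr(nf, "refs") <- refs
  nf
}

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, `dCt = Ct_target - mean(Ct_refs)` (the arithmetic mean
#' of reference Ct values, equivalent to normalizing by the geometric mean
#' of reference quantities), `ddCt = dCt - dCt_calibrator`, and the fold
#' change is `2^-ddCt` (or `(1 + efficiency)^-ddCt` when an efficiency is
#' supplied). The calibrator sample's value is exactly 1.
#'
#' @param m a collapsed, complete [ct_matrix()] containing the target and
#'   reference genes.
#' @param target target gene id (must not appear among `refs`).
#' @param refs nonempty character vector of reference gene ids.
#' @param calibrator sample id of the calibrator.
#' @param efficiency optional common amplification efficiency as a fraction;
#'   default 1 (i.e. base 2).
#' @return a data.frame of class `relative_expression` (`sample_id`,
#'   `fold_change`) with attributes `target`, `refs`, `calibrator`.
#' @export
ddct_relative_expression <- function(m, target, refs, calibrator,
                                     efficiency = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!m$collapsed) {
    stop("collapse technical replicates first", call. = FALSE)
  }
  if (target %in% refs) {
    stop("target gene must not appear among the references", call. = FALSE)
  }
  genes <- c(target, refs)
  unknown <- setdiff(genes, rownames(m$ct))
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- m$samples$sample_id
  if (!calibrator %in% ids) {
    stop("calibrator sample '", calibrator, "' not found", call. = FALSE)
  }
  x <- m$ct[genes, , drop = FALSE]
  if (anyNA(x)) stop("missing Ct among target/reference genes", call. = FALSE)
  base <- 1 + (efficiency %||% 1)
  if (base <= 1) stop("efficiency must be > 0", call. = FALSE)
  dct <- x[target, ] - colMeans(x[refs, , drop = FALSE])
  ddct <- dct - dct[match(calibrator, ids)]
  out <- data.frame(sample_id = ids, fold_change = unname(base^(-ddct)),
                    stringsAsFactors = FALSE)
  structure(out, target = target, refs = refs, calibrator = calibrator,
            class = c("relative_expression", "data.frame"))
}

#' Quantify divergence between two normalizations of the same target
#'
#' Compares the fold-change profile of one target gene computed with two
#' different reference sets: the per-sample fold ratio a/b, the maximum
#' absolute log2 ratio, the Spearman correlation of the two profiles, and
#' whether the peak (argmax) sample agrees -- the qualitative criterion for
#' whether an unstable normalizer distorts the expression pattern.
#'
#' @param a,b [ddct_relative_expression()] results for the same target,
#'   samples and calibrator.
#' @return list of class `normalization_comparison`: `ratio` (data.frame
#'   `sample_id`, `ratio`), `max_abs_log2_ratio`, `spearman`,
#'   `peak_agreement`, `peak_a`, `peak_b`.
#' @export
compare_normalizations <- function(a, b) {
  stopifnot(inherits(a, "relative_expression"),
            inherits(b, "relative_expression"))
  if (!identical(attr(a, "target"), attr(b, "target"))) {
    stop("profiles normalize different targets", call. = FALSE)
  }
  if (!identical(a$sample_id, b$sample_id)) {
    stop("profiles cover different samples", call. = FALSE)
  }
  if (!identical(attr(a, "calibrator"), attr(b, "calibrator"))) {
    stop("profiles use different calibrators", call. = FALSE)
  }
  ratio <- a$fold_change / b$fold_change
  peak_a <- a$sample_id[which.max(a$fold_change)]
  peak_b <- b$sample_id[which.max(b$fold_change)]
  structure(list(
    ratio = data.frame(sample_id = a$sample_id, ratio = ratio,
                       stringsAsFactors = FALSE),
    max_abs_log2_ratio = max(abs(log2(ratio))),
    spearman = stats::cor(a$fold_change, b$fold_change, method = "spearman"),
    peak_agreement = identical(peak_a, peak_b),
    peak_a = peak_a, peak_b = peak_b),
    class = "normalization_comparison")
}
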