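#' Convert stability scores to ranks
#'
#' Ascending scores map to ranks 1..G (1 = most stable); exact ties receive
#' the average of the tied positions, so the rank sum is always
#' `G(G+1)/2`.
#'
#' @param s a `stability_scores` data.frame (from any of the four methods)
#'   or a named numeric vector of scores.
#' @return a data.frame of class `rank_vector` (`gene_id`, `rank`) with a
#'   `method` attribute.
#' @export
rank_genes <- function(s) {
  if (inherits(s, "stability_scores")) {
    method <- attr(s, "method")
    scores <- stats::setNames(s$score, s$gene_id)
  } else if (is.numeric(s) && !is.null(names(s))) {
    method <- "scores"
    scores <- s
  } else {
    stop("`s` must be stability scores or a named numeric vector",
         call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  structure(data.frame(gene_id = names(scores),
                       rank = rank(unname(scores), ties.method = "average"),
                       stringsAsFactors = FALSE),
            method = method, class = c("rank_vector", "data.frame"))
}

# rank_vector from an explicit total order (used for geNorm's stepwise
# ranking, which is an order rather than a score).
rank_from_order <- function(ordering, method) {
  structure(data.frame(gene_id = ordering,
                       rank = seq_along(ordering),
                       stringsAsFactors = FALSE),
            method = method, class = c("rank_vector", "data.frame"))
}

#' Aggregate per-method ranks by geometric mean
#'
#' The comprehensive ranking: each gene's per-method ranks are combined as
#' `(prod ranks)^(1/M)`, and genes are ordered by ascending geometric mean.
#' Ties are broken by the delta-Ct rank (when present) and then by gene id,
#' so the final order is deterministic.
#'
#' @param ranks named list of [rank_genes()] results (at least 2), all over
#'   the same gene set; names are method labels.
#' @return a data.frame of class `comprehensive_ranking`, ordered most to
#'   least stable: `gene_id`, one `<method>_rank` column per method,
#'   `geom_mean_rank`, `final_rank`.
#' @export
geometric_mean_ranking <- function(ranks) {
  stopifnot(is.list(ranks), length(ranks) >= 2L, !is.null(names(ranks)))
  genes <- sort(ranks[[1L]]$gene_id)
  mat <- vapply(ranks, function(rv) {
    if (!setequal(rv$gene_id, genes)) {
      stop("rank vectors cover different gene sets", call. = FALSE)
    }
    rv$rank[match(genes, rv$gene_id)]
  }, numeric(length(genes)))
  gm <- exp(rowMeans(log(mat)))
  tie1 <- if ("delta_ct" %in% names(ranks)) {
    mat[, "delta_ct"]
  } else {
    rep(0, length(genes))
  }
  ord <- order(gm, tie1, genes)
  out <- data.frame(gene_id = genes, mat, geom_mean_rank = gm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1L + seq_along(ranks)] <- paste0(names(ranks), "_rank")
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("comprehensive_ranking", "data.frame")
  out
}

#' Recommend a reference-gene set
#'
#' Takes the top genes of the comprehensive ranking, with the set size given
#' by the geNorm pairwise-variation analysis (`optimal_n`). When the geNorm
#' trace found no V below its threshold, the size minimizing V is used and
#' the flag is propagated on the result.
#'
#' @param cr a [geometric_mean_ranking()] result.
#' @param trace a [genorm_ranking()] trace from the same subset.
#' @return character vector of recommended gene ids (comprehensive order),
#'   with attributes `optimal_n` and `no_n_below_threshold`.
#' @export
recommend_reference_set <- function(cr, trace) {
  stopifnot(inherits(cr, "comprehensive_ranking"),
            inherits(trace, "genorm_trace"))
  n <- trace$optimal_n
  if (n > nrow(cr)) {
    stop("optimal_n (", n, ") exceeds the gene count (", nrow(cr), ")",
         call. = FALSE)
  }
  structure(cr$gene_id[seq_len(n)], optimal_n = n,
            no_n_below_threshold = trace$no_n_below_threshold)
}

# Run the four methods plus aggregation on one already-subset matrix.
.analyze_subset <- function(sub, v_threshold, aggregation,
                            bestkeeper_sd_threshold = 1.0) {
  grouping_key <- attr(sub, "grouping")
  grouping <- if (is.null(grouping_key)) NULL else sub$samples[[grouping_key]]
  q <- relative_quantities(sub)
  dct <- delta_ct_stability(sub)
  trace <- genorm_ranking(q, v_threshold = v_threshold)
  nf <- normfinder_stability(q, grouping = grouping)
  bk <- bestkeeper_stats(sub, sd_threshold = bestkeeper_sd_threshold)
  scores <- list(delta_ct = dct,
                 genorm = genorm_m_values(q),
                 normfinder = nf$scores,
                 bestkeeper = bestkeeper_scores(bk))
  ranks <- list(delta_ct = rank_genes(dct),
                genorm = rank_from_order(trace$ranking, "genorm"),
                normfinder = rank_genes(nf$scores),
                bestkeeper = rank_genes(bestkeeper_scores(bk)))
  cr <- geometric_mean_ranking(ranks)
  if (aggregation == "scores") {
    # sensitivity variant: order by the geometric mean of the raw scores
    # (floored at machine epsilon since a perfectly stable gene scores 0)
    gene_order <- sort(cr$gene_id)
    gm_scores <- Reduce(`+`, lapply(scores, function(s) {
      log(pmax(stats::setNames(s$score, s$gene_id)[gene_order],
               .Machine$double.eps))
    })) / length(scores)
    gm_scores <- exp(gm_scores)
    cr <- cr[match(gene_order, cr$gene_id), , drop = FALSE]
    cr$geom_mean_rank <- NULL
    cr$geom_mean_score <- unname(gm_scores)
    cr <- cr[order(gm_scores, cr$delta_ct_rank, cr$gene_id), , drop = FALSE]
    cr$final_rank <- seq_len(nrow(cr))
    rownames(cr) <- NULL
    class(cr) <- c("comprehensive_ranking", "data.frame")
  }
  list(scores = scores, ranks = ranks, comprehensive = cr, trace = trace,
       bestkeeper = bk, normfinder_detail = nf$detail,
       recommended = recommend_reference_set(cr, trace))
}

#' Run the full stability battery over condition sets
#'
#' For every configured condition set the battery subsets the matrix,
#' computes relative quantities, runs all four stability methods, aggregates
#' the per-method ranks by geometric mean, runs the geNorm
#' pairwise-variation analysis and derives the recommended reference set.
#' The per-set comprehensive orders are assembled into a wide table (rows =
#' rank position, columns = condition sets).
#'
#' @param m a collapsed [ct_matrix()].
#' @param sets list of [condition_set()] objects (default:
#'   [default_condition_sets()]).
#' @param v_threshold geNorm pairwise-variation threshold (default 0.15).
#' @param aggregation `"ranks"` (geometric mean of per-method ranks, the
#'   default) or `"scores"` (geometric mean of raw scores, for sensitivity
#'   analysis).
#' @param on_missing passed to [subset_samples()].
#' @param bestkeeper_sd_threshold BestKeeper stability cutoff (cycles).
#' @return an object of class `condition_battery`: list with `results` (one
#'   entry per set: `scores`, `ranks`, `comprehensive`, `trace`,
#'   `bestkeeper`, `normfinder_detail`, `recommended`), `table` (the wide
#'   comprehensive-ranking data.frame), `v_threshold`, `aggregation`.
#' @export
run_condition_battery <- function(m, sets = default_condition_sets(),
                                  v_threshold = 0.15,
                                  aggregation = c("ranks", "scores"),
                                  on_missing = c("error", "drop_samples"),
                                  bestkeeper_sd_threshold = 1.0) {
  stopifnot(inherits(m, "ct_matrix"))
  aggregation <- match.arg(aggregation)
  on_missing <- match.arg(on_missing)
  if (!m$collapsed) {
    stop("collapse technical replicates before running the battery",
         call. = FALSE)
  }
  if (is.null(names(sets))) {
    names(sets) <- vapply(sets, `[[`, "", "name")
  }
  results <- lapply(sets, function(cs) {
    tryCatch({
      sub <- subset_samples(m, cs, on_missing = on_missing)
      .analyze_subset(sub, v_threshold, aggregation,
                      bestkeeper_sd_threshold)
    }, error = function(e) {
      stop("condition set '", cs$name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  tab <- data.frame(rank = seq_len(nrow(results[[1L]]$comprehensive)))
  for (nm in names(results)) {
    tab[[nm]] <- results[[nm]]$comprehensive$gene_id
  }
  structure(list(results = results, table = tab, v_threshold = v_threshold,
                 aggregation = aggregation),
            class = "condition_battery")
}

#' @export
print.condition_battery <- function(x, ...) {
  cat(sprintf("condition battery: %d sets, %d genes\n",
              length(x$results), nrow(x$table)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-12s recommended: %s%s\n", nm,
                paste(r$recommended, collapse = " + "),
                if (attr(r$recommended, "no_n_below_threshold")) {
                  " [no V below threshold]"
                } else ""))
  }
  invisible(x)
}
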