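#' Convert Ct values to relative quantities (2^-dCt)
#'
#' For each gene, delta-Ct is the Ct minus the gene's minimum Ct within the
#' analyzed sample set, and the relative quantity is
#' `Q = (1 + E)^(-dCt)` with efficiency `E = 1` (perfect doubling) by
#' default. Every gene therefore has `max(Q) = 1`, attained at its most
#' abundant sample. Because the reference Ct is per gene, adding a constant
#' to all of a gene's Ct values leaves its Q row unchanged.
#'
#' @param m a collapsed, complete [ct_matrix()].
#' @param efficiencies optional per-gene efficiencies as fractions (named
#'   vector or single value recycled); default 1 for every gene.
#' @return an object of class `qmatrix`: list with `q` (genes x samples
#'   matrix of quantities in (0, 1]), `ref_ct` (per-gene minimum Ct used),
#'   `efficiency` (per-gene E), `genes`, `samples`.
#' @export
relative_quantities <- function(m, efficiencies = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!m$collapsed) {
    stop("collapse technical replicates before computing quantities",
         call. = FALSE)
  }
  if (anyNA(m$ct)) {
    idx <- which(is.na(m$ct), arr.ind = TRUE)
    abort_cells("missing Ct; subset or drop samples first",
                sprintf("%s@%s", rownames(m$ct)[idx[, 1]],
                        m$samples$sample_id[idx[, 2]]))
  }
  G <- n_genes(m)
  eff <- rep(1, G)
  names(eff) <- rownames(m$ct)
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies))) {
      eff[] <- efficiencies
    } else {
      unknown <- setdiff(names(efficiencies), names(eff))
      if (length(unknown)) {
        stop("efficiencies for unknown genes: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      eff[names(efficiencies)] <- efficiencies
    }
  }
  if (any(eff <= 0)) stop("efficiencies must be > 0", call. = FALSE)
  ref_ct <- apply(m$ct, 1L, min)
  dct <- m$ct - ref_ct
  q <- (1 + eff)^(-dct)
  structure(list(q = q, ref_ct = ref_ct, efficiency = eff, genes = m$genes,
                 samples = m$samples),
            class = "qmatrix")
}

# log2 quantities of candidate-reference genes from a qmatrix
.candidate_log2q <- function(q) {
  stopifnot(inherits(q, "qmatrix"))
  keep <- q$genes$role == "candidate_reference"
  log2(q$q[keep, , drop = FALSE])
}

.check_stability_input <- function(x, min_genes = 2L, min_samples = 3L,
                                   what = "stability analysis") {
  if (nrow(x) < min_genes) {
    stop(what, " requires at least ", min_genes, " candidate genes",
         call. = FALSE)
  }
  if (ncol(x) < min_samples) {
    stop(what, " requires at least ", min_samples, " samples", call. = FALSE)
  }
}

# Mean over partner genes of the sample SD of pairwise row differences.
# Shared arithmetic core of the delta-Ct score and the geNorm M value
# (which applies it to log2 quantities).
.pairwise_sd_mean <- function(x) {
  G <- nrow(x)
  sds <- matrix(0, G, G)
  for (i in seq_len(G - 1L)) {
    for (k in (i + 1L):G) {
      s <- sample_sd(x[i, ] - x[k, ])
      sds[i, k] <- s
      sds[k, i] <- s
    }
  }
  out <- rowSums(sds) / (G - 1L)
  names(out) <- rownames(x)
  out
}

new_stability_scores <- function(scores, method) {
  structure(data.frame(gene_id = names(scores), score = unname(scores),
                       stringsAsFactors = FALSE),
            method = method, class = c("stability_scores", "data.frame"))
}

#' Comparative delta-Ct stability scores
#'
#' For every gene pair the sample standard deviation of the Ct difference is
#' computed across samples; a gene's score is the mean of these SDs over all
#' partner genes (the "average STDEV" of the comparative delta-Ct method,
#' in cycles). A gene that keeps a constant offset from every other gene
#' scores 0; lower is more stable.
#'
#' @param m a collapsed, complete [ct_matrix()] with at least 2 candidate
#'   genes and 3 samples.
#' @return a `stability_scores` data.frame (`gene_id`, `score`) with
#'   attribute `method = "delta_ct"`.
#' @export
delta_ct_stability <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (anyNA(m$ct)) stop("missing Ct; subset first", call. = FALSE)
  x <- candidate_ct(m)
  .check_stability_input(x, what = "delta-Ct analysis")
  new_stability_scores(.pairwise_sd_mean(x), "delta_ct")
}

#' geNorm M values
#'
#' The geNorm expression-stability measure: for gene g, `M_g` is the mean
#' over all other genes k of the sample standard deviation of
#' `log2(Q_g / Q_k)` (unitless, log2 scale). With the default efficiency of
#' 1, `log2 Q = -dCt`, so M equals the delta-Ct score on the same matrix.
#'
#' @param q a [relative_quantities()] result with at least 2 candidate
#'   genes.
#' @return a `stability_scores` data.frame with attribute
#'   `method = "genorm"`.
#' @export
genorm_m_values <- function(q) {
  y <- .candidate_log2q(q)
  .check_stability_input(y, what = "geNorm analysis")
  new_stability_scores(.pairwise_sd_mean(y), "genorm")
}

#' geNorm stepwise ranking and pairwise variation
#'
#' Implements the full geNorm procedure: M values are computed, the gene
#' with the highest M is excluded, and M is recomputed on the remainder
#' until two genes are left. The final two genes cannot be separated by the
#' algorithm and share the top of the ranking; to emit a total order they
#' are sorted by their M in the preceding 3-gene iteration. Ties in the
#' exclusion step are broken by removing the lexicographically last gene id.
#'
#' Pairwise variation `V(n/n+1)` is the sample SD over samples of
#' `log2(NF_n / NF_{n+1})`, where `NF_n` is the per-sample geometric mean of
#' the quantities of the n top-ranked genes. The optimal number of
#' references is the smallest n with `V < v_threshold`; when no V falls
#' below the threshold the n minimizing V is reported and flagged.
#'
#' @param q a [relative_quantities()] result with at least 3 candidate
#'   genes.
#' @param v_threshold pairwise-variation threshold (default 0.15).
#' @return an object of class `genorm_trace`: list with `initial_m` (named
#'   vector), `exclusion` (data.frame `iteration`, `gene_id`, `m_value`),
#'   `final_pair`, `ranking` (best to worst), `scores` (per-gene M at
#'   exclusion, the stepwise geNorm chart values), `v` (data.frame `n`,
#'   `v`), `optimal_n`, `no_n_below_threshold`, `v_threshold`.
#' @export
genorm_ranking <- function(q, v_threshold = 0.15) {
  y <- .candidate_log2q(q)
  .check_stability_input(y, min_genes = 3L, what = "geNorm ranking")
  G <- nrow(y)
  genes <- rownames(y)
  initial_m <- .pairwise_sd_mean(y)
  remaining <- genes
  excl <- data.frame(iteration = integer(), gene_id = character(),
                     m_value = numeric(), stringsAsFactors = FALSE)
  last3_m <- NULL
  it <- 0L
  while (length(remaining) > 2L) {
    it <- it + 1L
    M <- .pairwise_sd_mean(y[remaining, , drop = FALSE])
    if (length(remaining) == 3L) last3_m <- M
    worst <- names(M)[order(-M, -rank(names(M)))][1L]
    excl <- rbind(excl, data.frame(iteration = it, gene_id = worst,
                                   m_value = unname(M[worst]),
                                   stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- remaining[order(last3_m[remaining])]
  ranking <- c(final_pair, rev(excl$gene_id))
  scores <- c(last3_m[final_pair], rev(excl$m_value))
  names(scores) <- ranking
  nf <- vapply(seq_len(G), function(n) {
    colMeans(y[ranking[seq_len(n)], , drop = FALSE])
  }, numeric(ncol(y)))  # samples x n matrix of log2 NF_n
  v <- vapply(2:(G - 1L), function(n) {
    sample_sd(nf[, n] - nf[, n + 1L])
  }, 0)
  vdf <- data.frame(n = 2:(G - 1L), v = v)
  below <- vdf$n[vdf$v < v_threshold]
  no_n <- length(below) == 0L
  optimal_n <- if (no_n) vdf$n[which.min(vdf$v)] else min(below)
  structure(list(initial_m = initial_m, exclusion = excl,
                 final_pair = final_pair, ranking = ranking, scores = scores,
                 v = vdf, optimal_n = optimal_n,
                 no_n_below_threshold = no_n, v_threshold = v_threshold),
            class = "genorm_trace")
}

#' @export
print.genorm_trace <- function(x, ...) {
  cat("geNorm ranking (most to least stable):\n  ",
      paste(x$ranking, collapse = " > "), "\n")
  cat(sprintf("optimal n = %d%s (V threshold %.2f)\n", x$optimal_n,
              if (x$no_n_below_threshold) " [no V below threshold]" else "",
              x$v_threshold))
  invisible(x)
}

#' NormFinder stability values
#'
#' Model-based stability assessment on log2 quantities. Samples are first
#' centered (each sample's mean over genes is subtracted), removing the
#' sample-size effect. Within each group the per-gene intragroup variance is
#' estimated with a bias correction, \deqn{\hat\sigma^2_{ig} = \max(0,
#' (s^2_{ig} - S_g / (I(I-1))) \cdot I/(I-2))} where `s2` is the sample
#' variance of the centered values, `S_g` their sum over genes and `I` the
#' gene count. With a single group the stability value is
#' `rho = sqrt(sigma2)`. With two or more groups the intergroup deviations
#' `d_ig` (group mean minus size-weighted overall mean, summing to zero over
#' genes within each group) are shrunk towards zero using the
#' between-group variance estimate `gamma2`, and
#' \deqn{\rho_i = mean_g(|\tilde d_{ig}| + \sqrt{(\hat\sigma^2_{ig}/n_g)
#' \gamma^2 / (\gamma^2 + \hat\sigma^2_{ig}/n_g)})} combines both error
#' sources. When `gamma2` collapses to zero the one-group formula is applied
#' to the pooled samples and the result is flagged.
#'
#' @param q a [relative_quantities()] result with at least 3 candidate
#'   genes.
#' @param grouping `NULL` for a single group, or a factor/vector with one
#'   group label per sample (each group needs at least 2 samples).
#' @return list with `scores` (a `stability_scores` data.frame, method
#'   `"normfinder"`) and `detail` (class `normfinder_detail`: matrices `d`,
#'   `d_shrunk`, `sigma2` (genes x groups), `gamma2`, `rho`,
#'   `group_sizes`, `pooled_fallback`).
#' @export
normfinder_stability <- function(q, grouping = NULL) {
  y <- .candidate_log2q(q)
  if (nrow(y) < 3L) {
    stop("NormFinder requires at least 3 candidate genes (the variance ",
         "correction factor I/(I-2) is undefined otherwise)", call. = FALSE)
  }
  S <- ncol(y)
  grouping <- grouping %||% rep("all", S)
  if (length(grouping) != S) {
    stop("grouping must have one label per sample", call. = FALSE)
  }
  grp <- factor(grouping)
  n_g <- table(grp)
  if (any(n_g < 2L)) {
    stop("every NormFinder group needs at least 2 samples; too small: ",
         paste(names(n_g)[n_g < 2L], collapse = ", "), call. = FALSE)
  }
  I <- nrow(y)
  Gg <- nlevels(grp)
  z <- sweep(y, 2L, colMeans(y))  # sample-centering
  zbar <- vapply(levels(grp), function(g) {
    rowMeans(z[, grp == g, drop = FALSE])
  }, numeric(I))
  s2 <- vapply(levels(grp), function(g) {
    apply(z[, grp == g, drop = FALSE], 1L, stats::var)
  }, numeric(I))
  S_g <- colSums(s2)
  sigma2 <- pmax(sweep(s2, 2L, S_g / (I * (I - 1L))) * I / (I - 2L), 0)
  ng <- as.numeric(n_g[levels(grp)])
  if (Gg == 1L) {
    rho <- sqrt(sigma2[, 1L])
    d <- matrix(0, I, 1L, dimnames = dimnames(sigma2))
    detail <- list(d = d, d_shrunk = d, sigma2 = sigma2, gamma2 = NA_real_,
                   rho = rho, group_sizes = ng, pooled_fallback = FALSE)
  } else {
    overall <- as.vector(zbar %*% ng) / sum(ng)
    d <- zbar - overall
    sig_over_n <- sweep(sigma2, 2L, ng, `/`)
    gamma2 <- max(0, sum(d^2) / ((Gg - 1L) * (I - 1L)) - mean(sig_over_n))
    if (gamma2 == 0) {
      # no detectable intergroup variance: pool and fall back
      pooled_s2 <- apply(z, 1L, stats::var)
      pooled_sig2 <- pmax(0, (pooled_s2 - sum(pooled_s2) / (I * (I - 1L))) *
                            I / (I - 2L))
      rho <- sqrt(pooled_sig2)
      names(rho) <- rownames(y)
      detail <- list(d = d, d_shrunk = d * 0, sigma2 = sigma2, gamma2 = 0,
                     rho = rho, group_sizes = ng, pooled_fallback = TRUE)
    } else {
      shrink <- gamma2 / (gamma2 + sig_over_n)
      d_shrunk <- d * shrink
      rho <- rowMeans(abs(d_shrunk) + sqrt(sig_over_n * shrink))
      names(rho) <- rownames(y)
      detail <- list(d = d, d_shrunk = d_shrunk, sigma2 = sigma2,
                     gamma2 = gamma2, rho = rho, group_sizes = ng,
                     pooled_fallback = FALSE)
    }
  }
  class(detail) <- "normfinder_detail"
  list(scores = new_stability_scores(detail$rho, "normfinder"),
       detail = detail)
}

#' BestKeeper descriptive stability statistics
#'
#' Operates on raw Ct values: per gene the sample standard deviation (SD,
#' cycles) and percent coefficient of variation (CV = SD / mean x 100), plus
#' the Pearson correlation of each gene's Ct with the BestKeeper index (the
#' per-sample geometric mean of all candidate genes' Ct). Genes are ordered
#' by ascending SD with ties broken by ascending CV; SD below `sd_threshold`
#' (conventionally 1 cycle) flags stable expression.
#'
#' @param m a collapsed, complete [ct_matrix()] with at least 3 samples.
#' @param sd_threshold stability cutoff on SD, cycles (default 1.0).
#' @return a data.frame of class `bestkeeper_result` ordered by stability:
#'   `gene_id`, `sd_ct`, `cv_pct`, `r_index`, `stable`; the index vector is
#'   attached as attribute `"index"`.
#' @export
bestkeeper_stats <- function(m, sd_threshold = 1.0) {
  stopifnot(inherits(m, "ct_matrix"))
  if (anyNA(m$ct)) stop("missing Ct; subset first", call. = FALSE)
  x <- candidate_ct(m)
  .check_stability_input(x, what = "BestKeeper analysis")
  mu <- rowMeans(x)
  if (any(mu <= 0)) stop("CV undefined: mean Ct <= 0", call. = FALSE)
  sds <- apply(x, 1L, sample_sd)
  cv <- sds / mu * 100
  index <- exp(colMeans(log(x)))
  # r is undefined (NA) for a constant gene or constant index
  r <- apply(x, 1L, function(row) {
    if (sample_sd(row) == 0 || sample_sd(index) == 0) NA_real_
    else stats::cor(row, index)
  })
  out <- data.frame(gene_id = rownames(x), sd_ct = sds, cv_pct = cv,
                    r_index = r, stable = sds < sd_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$sd_ct, out$cv_pct, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index") <- index
  attr(out, "sd_threshold") <- sd_threshold
  class(out) <- c("bestkeeper_result", "data.frame")
  out
}

#' Extract per-gene scores from a BestKeeper result
#'
#' The SD of raw Ct is the BestKeeper quantity used for cross-method rank
#' aggregation (lower = more stable).
#'
#' @param bk a [bestkeeper_stats()] result.
#' @return a `stability_scores` data.frame, method `"bestkeeper"`.
#' @export
bestkeeper_scores <- function(bk) {
  stopifnot(inherits(bk, "bestkeeper_result"))
  scores <- stats::setNames(bk$sd_ct, bk$gene_id)
  new_stability_scores(scores, "bestkeeper")
}
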