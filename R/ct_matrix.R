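#' Construct a replicated Ct matrix
#'
#' A `ct_matrix` holds quantification-cycle (Ct) values for a set of genes
#' measured across annotated samples (wells). Rows are genes, columns are
#' wells; each well carries sample metadata (condition, timepoint, biological
#' and technical replicate). Missing wells ("Undetermined" on the cycler) are
#' stored as `NA`.
#'
#' @param ct numeric matrix of Ct values (cycles), genes in rows (rownames =
#'   gene identifiers), wells in columns. `NA` marks undetermined wells; all
#'   non-missing values must lie in `[5, 45]`.
#' @param samples data.frame with one row per column of `ct`, columns
#'   `sample_id`, `condition`, `timepoint`, `bio_rep`, `tech_rep`.
#'   `(sample_id, tech_rep)` must be unique; `sample_id` identifies the
#'   biological sample.
#' @param roles character vector, one per gene, either
#'   `"candidate_reference"` or `"target"`. Defaults to all candidates.
#' @param collapsed logical; `TRUE` once technical replicates have been
#'   averaged (at most one well per biological sample).
#' @return an object of class `ct_matrix`.
#' @seealso [read_ct_table()], [collapse_technical_replicates()]
#' @export
ct_matrix <- function(ct, samples, roles = NULL, collapsed = FALSE) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix (genes x wells)", call. = FALSE)
  }
  if (is.null(rownames(ct)) || anyNA(rownames(ct)) || any(rownames(ct) == "")) {
    stop("`ct` must have gene identifiers as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(ct))) {
    stop("gene identifiers must be unique; duplicated: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "),
         call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "timepoint", "bio_rep", "tech_rep")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("`samples` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) != ncol(ct)) {
    stop("`samples` must have one row per column of `ct`", call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$timepoint <- as.character(samples$timepoint)
  samples$bio_rep <- as.integer(samples$bio_rep)
  samples$tech_rep <- as.integer(samples$tech_rep)
  if (any(samples$bio_rep < 1L) || any(samples$tech_rep < 1L)) {
    stop("bio_rep and tech_rep must be >= 1", call. = FALSE)
  }
  key <- paste(samples$sample_id, samples$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- samples[duplicated(key), , drop = FALSE]
    abort_cells("duplicate (sample_id, tech_rep) pairs",
                paste0("(", dup$sample_id, ", tech_rep ", dup$tech_rep, ")"))
  }
  roles <- roles %||% rep("candidate_reference", nrow(ct))
  if (length(roles) != nrow(ct) ||
      !all(roles %in% c("candidate_reference", "target"))) {
    stop("`roles` must be 'candidate_reference' or 'target', one per gene",
         call. = FALSE)
  }
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct < 5 | ct > 45), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_cells(
      "Ct values outside [5, 45]",
      sprintf("%s@%s=%g", rownames(ct)[bad[, 1]],
              samples$sample_id[bad[, 2]], ct[bad]))
  }
  colnames(ct) <- make.unique(paste(samples$sample_id, samples$tech_rep,
                                    sep = "."))
  structure(
    list(ct = ct,
         genes = data.frame(gene_id = rownames(ct), role = roles,
                            stringsAsFactors = FALSE),
         samples = samples,
         collapsed = isTRUE(collapsed)),
    class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d genes x %d wells (%s), %d missing\n",
              nrow(x$ct), ncol(x$ct),
              if (x$collapsed) "collapsed" else "raw technical replicates",
              sum(is.na(x$ct))))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

n_genes <- function(m) nrow(m$ct)
n_samples <- function(m) ncol(m$ct)

candidate_genes <- function(m) {
  m$genes$gene_id[m$genes$role == "candidate_reference"]
}

# Ct submatrix restricted to candidate reference genes.
candidate_ct <- function(m) {
  m$ct[m$genes$role == "candidate_reference", , drop = FALSE]
}

sentinel_missing <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | toupper(x) == "NA" | tolower(x) == "undetermined"
}

parse_ct_cells <- function(chr, gene, well) {
  vals <- rep(NA_real_, length(chr))
  miss <- sentinel_missing(chr)
  num <- suppressWarnings(as.numeric(chr[!miss]))
  bad <- which(!miss)[is.na(num)]
  if (length(bad)) {
    abort_cells("non-numeric Ct values",
                sprintf("%s@%s='%s'", gene[bad], well[bad], chr[bad]))
  }
  vals[!miss] <- num
  vals
}

#' Read a replicated Ct table from delimited text
#'
#' Two layouts are supported. `"long"` expects columns `sample_id`,
#' `condition`, `timepoint`, `bio_rep`, `tech_rep`, `gene_id`, `ct` (and an
#' optional `role` column). `"wide"` expects the first column to hold gene
#' identifiers and the remaining columns one well each, keyed to a sample
#' metadata sheet. Cells reading `"Undetermined"`, `"NA"` or empty become
#' missing values; any other non-numeric cell is an error naming its
#' coordinates, as is any Ct outside `[5, 45]`.
#'
#' @param path path to a UTF-8 CSV (comma) or TSV (tab) file; the delimiter
#'   is inferred from the extension (`.csv` = comma, otherwise tab) unless
#'   `sep` is given.
#' @param layout `"wide"` or `"long"`.
#' @param meta for `layout = "wide"`: sample metadata, either a data.frame or
#'   a path to a delimited file, with columns `sample_id`, `condition`,
#'   `timepoint`, `bio_rep`, `tech_rep` and optionally `well` matching the Ct
#'   table's column names (when absent, `sample_id` is used as the well key).
#' @param roles optional role vector for `layout = "wide"` (see
#'   [ct_matrix()]).
#' @param sep field separator override.
#' @return a validated [ct_matrix()].
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), meta = NULL,
                          roles = NULL, sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", quote = "\"",
                           stringsAsFactors = FALSE)
  if (layout == "long") {
    req <- c("sample_id", "condition", "timepoint", "bio_rep", "tech_rep",
             "gene_id", "ct")
    missing_cols <- setdiff(req, names(raw))
    if (length(missing_cols)) {
      stop("long layout is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    trip <- paste(raw$gene_id, raw$sample_id, raw$tech_rep, sep = "\r")
    if (anyDuplicated(trip)) {
      d <- raw[duplicated(trip), , drop = FALSE]
      abort_cells("duplicate (gene, sample, tech_rep) triples",
                  sprintf("(%s, %s, tech_rep %s)", d$gene_id, d$sample_id,
                          d$tech_rep))
    }
    vals <- parse_ct_cells(raw$ct, raw$gene_id, raw$sample_id)
    genes <- unique(raw$gene_id)
    wkey <- paste(raw$sample_id, raw$tech_rep, sep = "\r")
    wells <- !duplicated(wkey)
    samples <- data.frame(sample_id = raw$sample_id[wells],
                          condition = raw$condition[wells],
                          timepoint = raw$timepoint[wells],
                          bio_rep = as.integer(raw$bio_rep[wells]),
                          tech_rep = as.integer(raw$tech_rep[wells]),
                          stringsAsFactors = FALSE)
    ct <- matrix(NA_real_, length(genes), nrow(samples),
                 dimnames = list(genes, NULL))
    ct[cbind(match(raw$gene_id, genes), match(wkey, wkey[wells]))] <- vals
    gene_roles <- if ("role" %in% names(raw)) {
      raw$role[match(genes, raw$gene_id)]
    } else roles
    ct_matrix(ct, samples, roles = gene_roles,
              collapsed = !anyDuplicated(samples$sample_id))
  } else {
    if (is.null(meta)) {
      stop("wide layout requires a sample metadata sheet (`meta`)",
           call. = FALSE)
    }
    if (is.character(meta)) {
      msep <- if (grepl("\\.csv$", meta, ignore.case = TRUE)) "," else "\t"
      meta <- utils::read.table(meta, header = TRUE, sep = msep,
                                colClasses = "character", comment.char = "#",
                                stringsAsFactors = FALSE)
    }
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    gene_ids <- raw[[1]]
    well_ids <- names(raw)[-1]
    if (anyDuplicated(gene_ids)) {
      abort_cells("duplicate gene rows in wide table",
                  unique(gene_ids[duplicated(gene_ids)]))
    }
    key_col <- if ("well" %in% names(meta)) "well" else "sample_id"
    idx <- match(well_ids, meta[[key_col]])
    if (anyNA(idx)) {
      abort_cells("Ct columns missing from the metadata sheet",
                  well_ids[is.na(idx)])
    }
    samples <- meta[idx, c("sample_id", "condition", "timepoint", "bio_rep",
                           "tech_rep"), drop = FALSE]
    chr <- as.matrix(raw[, -1, drop = FALSE])
    vals <- parse_ct_cells(as.vector(chr),
                           rep(gene_ids, times = length(well_ids)),
                           rep(well_ids, each = length(gene_ids)))
    ct <- matrix(vals, nrow = length(gene_ids),
                 dimnames = list(gene_ids, NULL))
    ct_matrix(ct, samples, roles = roles,
              collapsed = !anyDuplicated(samples$sample_id))
  }
}

#' Write a Ct matrix to delimited text
#'
#' Writes the long layout read by [read_ct_table()]. Values are serialized at
#' full double precision so that a write-then-read round trip is bit-exact;
#' missing wells are written as `NA`.
#'
#' @param m a [ct_matrix()].
#' @param path output path; `.csv` writes comma-separated, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path) {
  stopifnot(inherits(m, "ct_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  G <- n_genes(m)
  S <- n_samples(m)
  long <- data.frame(
    sample_id = rep(m$samples$sample_id, each = G),
    condition = rep(m$samples$condition, each = G),
    timepoint = rep(m$samples$timepoint, each = G),
    bio_rep = rep(m$samples$bio_rep, each = G),
    tech_rep = rep(m$samples$tech_rep, each = G),
    gene_id = rep(rownames(m$ct), times = S),
    role = rep(m$genes$role, times = S),
    ct = ifelse(is.na(as.vector(m$ct)), "NA",
                sprintf("%.17g", as.vector(m$ct))),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse technical replicates to one Ct per biological sample
#'
#' Technical replicates of each biological sample are averaged
#' (arithmetic mean of non-missing Ct). Any replicate group whose sample
#' standard deviation exceeds `qc_sd_warn` cycles is recorded in a QC log
#' (attribute `"qc_log"` of the result) and reported once as a warning; the
#' data are never altered by QC. A biological sample's value is missing only
#' when all of its technical replicates are missing.
#'
#' @param m a [ct_matrix()].
#' @param qc_sd_warn QC threshold, cycles, for the SD of a technical
#'   replicate group (default 0.5).
#' @return a collapsed [ct_matrix()] with one column per biological sample
#'   and a `"qc_log"` attribute (data.frame `gene_id`, `sample_id`, `n_reps`,
#'   `sd_ct`).
#' @export
collapse_technical_replicates <- function(m, qc_sd_warn = 0.5) {
  stopifnot(inherits(m, "ct_matrix"))
  ids <- unique(m$samples$sample_id)
  G <- n_genes(m)
  out <- matrix(NA_real_, G, length(ids),
                dimnames = list(rownames(m$ct), NULL))
  qc <- list()
  for (j in seq_along(ids)) {
    cols <- which(m$samples$sample_id == ids[j])
    block <- m$ct[, cols, drop = FALSE]
    out[, j] <- rowMeans(block, na.rm = TRUE)
    out[rowSums(!is.na(block)) == 0L, j] <- NA_real_
    if (length(cols) > 1L) {
      sds <- apply(block, 1L, function(x) sample_sd(x[!is.na(x)]))
      hit <- which(!is.na(sds) & sds > qc_sd_warn)
      for (i in hit) {
        qc[[length(qc) + 1L]] <- data.frame(
          gene_id = rownames(m$ct)[i], sample_id = ids[j],
          n_reps = sum(!is.na(block[i, ])), sd_ct = sds[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  first <- match(ids, m$samples$sample_id)
  samples <- data.frame(sample_id = ids,
                        condition = m$samples$condition[first],
                        timepoint = m$samples$timepoint[first],
                        bio_rep = m$samples$bio_rep[first],
                        tech_rep = 1L, stringsAsFactors = FALSE)
  res <- ct_matrix(out, samples, roles = m$genes$role, collapsed = TRUE)
  qc_log <- if (length(qc)) do.call(rbind, qc) else
    data.frame(gene_id = character(), sample_id = character(),
               n_reps = integer(), sd_ct = numeric(),
               stringsAsFactors = FALSE)
  attr(res, "qc_log") <- qc_log
  if (nrow(qc_log)) {
    warning(sprintf(
      "%d technical replicate group(s) exceed SD %.2f cycles (worst: %s@%s, SD %.3f)",
      nrow(qc_log), qc_sd_warn,
      qc_log$gene_id[which.max(qc_log$sd_ct)],
      qc_log$sample_id[which.max(qc_log$sd_ct)],
      max(qc_log$sd_ct)), call. = FALSE)
  }
  res
}

#' Define a condition subset of an experiment
#'
#' A condition set names the samples that enter one stability analysis:
#' either a list of condition labels (e.g. `"cold"`, or the union
#' `c("cold", "salt", "drought")` for pooled abiotic stress), explicit sample
#' ids, or both (union). `grouping` optionally names a sample-metadata column
#' (`"condition"` or `"timepoint"`) used to partition the member samples into
#' NormFinder groups; the default is a single group.
#'
#' @param name label for the set (used in reports).
#' @param conditions character vector of condition labels.
#' @param sample_ids character vector of explicit sample ids.
#' @param grouping `NULL` (single group) or a metadata column name.
#' @return an object of class `condition_set`.
#' @export
condition_set <- function(name, conditions = character(),
                          sample_ids = character(), grouping = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(grouping) &&
      !grouping %in% c("condition", "timepoint", "bio_rep")) {
    stop("grouping must be NULL or one of 'condition', 'timepoint', 'bio_rep'",
         call. = FALSE)
  }
  structure(list(name = name, conditions = as.character(conditions),
                 sample_ids = as.character(sample_ids), grouping = grouping),
            class = "condition_set")
}

#' Read condition-set definitions from a YAML or JSON config
#'
#' The config maps set names to entries with fields `conditions` (list of
#' condition labels), optional `sample_ids`, and optional `grouping`. An
#' entry with no `conditions` and no `sample_ids` selects all samples.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a named list of [condition_set()] objects.
#' @export
read_condition_sets <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sets <- lapply(names(cfg), function(nm) {
    e <- cfg[[nm]]
    condition_set(nm,
                  conditions = unlist(e$conditions) %||% character(),
                  sample_ids = unlist(e$sample_ids) %||% character(),
                  grouping = e$grouping)
  })
  names(sets) <- names(cfg)
  sets
}

#' Subset a Ct matrix to the members of a condition set
#'
#' Keeps only the samples selected by `cs`. Under `on_missing = "error"` any
#' missing candidate-reference Ct among the members is an error listing the
#' offending cells; under `"drop_samples"` any member sample missing at least
#' one candidate-reference Ct is removed (and listed in the
#' `"dropped_samples"` attribute), so the result is complete over candidate
#' references. Fewer than 4 resulting samples is an error.
#'
#' @param m a collapsed [ct_matrix()].
#' @param cs a [condition_set()].
#' @param on_missing `"error"` or `"drop_samples"`.
#' @return a [ct_matrix()] containing only member samples, with attributes
#'   `"condition_set"` (the set name) and `"grouping"`.
#' @export
subset_samples <- function(m, cs, on_missing = c("error", "drop_samples")) {
  stopifnot(inherits(m, "ct_matrix"), inherits(cs, "condition_set"))
  on_missing <- match.arg(on_missing)
  keep <- if (!length(cs$conditions) && !length(cs$sample_ids)) {
    rep(TRUE, n_samples(m))
  } else {
    m$samples$condition %in% cs$conditions |
      m$samples$sample_id %in% cs$sample_ids
  }
  if (!any(keep)) {
    stop("condition set '", cs$name, "' matches no samples", call. = FALSE)
  }
  ct <- m$ct[, keep, drop = FALSE]
  samples <- m$samples[keep, , drop = FALSE]
  cand <- m$genes$role == "candidate_reference"
  miss <- is.na(ct[cand, , drop = FALSE])
  dropped <- character()
  if (any(miss)) {
    if (on_missing == "error") {
      idx <- which(miss, arr.ind = TRUE)
      abort_cells(
        sprintf("condition set '%s': missing candidate-reference Ct", cs$name),
        sprintf("%s@%s", rownames(ct)[cand][idx[, 1]],
                samples$sample_id[idx[, 2]]))
    }
    bad_cols <- colSums(miss) > 0L
    dropped <- unique(samples$sample_id[bad_cols])
    ct <- ct[, !bad_cols, drop = FALSE]
    samples <- samples[!bad_cols, , drop = FALSE]
  }
  if (ncol(ct) < 4L) {
    stop("condition set '", cs$name, "' resolves to ", ncol(ct),
         " samples; at least 4 are required", call. = FALSE)
  }
  res <- ct_matrix(ct, samples, roles = m$genes$role, collapsed = m$collapsed)
  attr(res, "condition_set") <- cs$name
  attr(res, "grouping") <- cs$grouping
  attr(res, "dropped_samples") <- dropped
  res
}

#' Per-gene descriptive statistics of Ct values
#'
#' For each gene: mean, minimum, maximum and range (max minus min) of Ct over
#' samples, in cycles. The range is the usual screening statistic for how
#' much a candidate reference varies across an experiment.
#'
#' @param m a collapsed, complete [ct_matrix()].
#' @return a data.frame of class `ct_summary` with columns `gene_id`,
#'   `mean_ct`, `min_ct`, `max_ct`, `range_ct`.
#' @export
ct_summary <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (n_genes(m) == 0L || n_samples(m) == 0L) {
    stop("empty Ct matrix", call. = FALSE)
  }
  if (anyNA(m$ct)) {
    idx <- which(is.na(m$ct), arr.ind = TRUE)
    abort_cells("ct_summary requires a complete matrix; missing",
                sprintf("%s@%s", rownames(m$ct)[idx[, 1]],
                        m$samples$sample_id[idx[, 2]]))
  }
  out <- data.frame(
    gene_id = rownames(m$ct),
    mean_ct = rowMeans(m$ct),
    min_ct = apply(m$ct, 1L, min),
    max_ct = apply(m$ct, 1L, max),
    stringsAsFactors = FALSE)
  out$range_ct <- out$max_ct - out$min_ct
  rownames(out) <- NULL
  class(out) <- c("ct_summary", "data.frame")
  out
}

#' Pre-select candidate reference genes from an expression table
#'
#' Screens an expression table (e.g. normalized small RNA-seq abundances) for
#' genes that are both well expressed and flat: retained genes have mean
#' expression at or above `min_expr` and a max/min expression ratio across
#' samples below `max_fc`. The result is ordered by descending mean
#' expression.
#'
#' @param expr numeric matrix of strictly positive expression values, genes
#'   in rows (rownames = gene ids), samples in columns.
#' @param min_expr abundance threshold on the per-gene mean.
#' @param max_fc fold-change bound on the per-gene max/min ratio
#'   (default 1.4).
#' @return character vector of retained gene ids, most abundant first.
#' @export
select_candidate_references <- function(expr, min_expr, max_fc = 1.4) {
  if (!is.matrix(expr) || !is.numeric(expr) || is.null(rownames(expr))) {
    stop("`expr` must be a numeric matrix with gene rownames", call. = FALSE)
  }
  if (any(!is.finite(expr)) || any(expr <= 0)) {
    stop("expression values must be strictly positive and finite",
         call. = FALSE)
  }
  mu <- rowMeans(expr)
  fc <- apply(expr, 1L, max) / apply(expr, 1L, min)
  keep <- mu >= min_expr & fc < max_fc
  rownames(expr)[keep][order(mu[keep], decreasing = TRUE)]
}
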