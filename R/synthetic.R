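#' Specify a synthetic Ct experiment with known ground truth
#'
#' The generator models each well's Ct as the sum of a gene baseline, an
#' optional fixed per-condition offset, and three Gaussian variance
#' components on the Ct (log-quantity) scale:
#' \deqn{Ct = B_g + \delta_{g,c} + u_{g,c,t} + v_{g,c,t,b} + w_{g,c,t,b,r}}
#' where \eqn{u \sim N(0, \tau_g^2)} is drawn once per condition-by-timepoint
#' cell (treatment-driven fluctuation -- what makes a reference unstable),
#' \eqn{v \sim N(0, \sigma_{bio,g}^2)} once per biological replicate and
#' \eqn{w \sim N(0, \sigma_{tech,g}^2)} once per well. Because Ct is already
#' logarithmic in template, additive Gaussian effects correspond to
#' log-normal expression, the structure the stability algorithms assume.
#'
#' @param genes data.frame with columns `gene_id`, `base_ct` (cycles, in
#'   `[10, 35]`), `tau` (condition-effect SD, cycles), `sigma_bio`
#'   (biological-replicate SD), `sigma_tech` (technical-replicate SD), and
#'   optionally `designation` (`"stable"`/`"unstable"`; defaults to
#'   `"stable"` when `tau <= 0.1`).
#' @param cells data.frame with columns `condition`, `timepoint`: one row per
#'   condition-by-timepoint cell of the design.
#' @param n_bio,n_tech biological and technical replicates per cell (>= 1).
#' @param offsets optional numeric matrix of fixed per-condition offsets
#'   (cycles): genes in rows, condition labels in columns.
#' @param rng_seed default seed used by [simulate_ct_experiment()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genes, cells, n_bio = 3L, n_tech = 3L,
                           offsets = NULL, rng_seed = 1L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "base_ct", "tau", "sigma_bio", "sigma_tech")
  if (length(setdiff(req, names(genes)))) {
    stop("`genes` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id", call. = FALSE)
  sds <- as.matrix(genes[, c("tau", "sigma_bio", "sigma_tech")])
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all SDs must be finite and >= 0", call. = FALSE)
  }
  if (any(genes$base_ct < 10 | genes$base_ct > 35)) {
    stop("base_ct must lie in [10, 35]", call. = FALSE)
  }
  if (!is_count(n_bio) || !is_count(n_tech)) {
    stop("n_bio and n_tech must be positive integers", call. = FALSE)
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!all(c("condition", "timepoint") %in% names(cells)) || !nrow(cells)) {
    stop("`cells` needs >= 1 row with columns condition, timepoint",
         call. = FALSE)
  }
  cells$condition <- as.character(cells$condition)
  cells$timepoint <- as.character(cells$timepoint)
  if (anyDuplicated(paste(cells$condition, cells$timepoint, sep = "\r"))) {
    stop("duplicate condition x timepoint cells", call. = FALSE)
  }
  if (!is.null(offsets)) {
    if (!is.matrix(offsets) || is.null(rownames(offsets)) ||
        is.null(colnames(offsets))) {
      stop("`offsets` must be a matrix with gene rownames and condition colnames",
           call. = FALSE)
    }
    unknown <- setdiff(rownames(offsets), genes$gene_id)
    if (length(unknown)) {
      stop("offsets for unknown genes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!"designation" %in% names(genes)) {
    genes$designation <- ifelse(genes$tau <= 0.1, "stable", "unstable")
  }
  structure(list(genes = genes, cells = cells, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), offsets = offsets,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d genes; %d condition x timepoint cells; %d bio x %d tech reps\n",
    nrow(x$genes), nrow(x$cells), x$n_bio, x$n_tech))
  invisible(x)
}

#' Simulate a replicated Ct experiment
#'
#' Draws a full well-level Ct table from a [synthetic_spec()] together with
#' the truth labels of the generating process. The same seed always yields a
#' bit-identical matrix; no global RNG state is consumed. Draws falling
#' outside the valid Ct window `[5, 45]` are an error (the generator never
#' clips), which signals that the spec's baselines and SDs are inconsistent
#' with plausible cycler output.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed; defaults to the spec's.
#' @return list with elements `ct` (an uncollapsed [ct_matrix()]) and `truth`
#'   (data.frame `gene_id`, `designation`, `tau`, `sigma_bio`, `sigma_tech`).
#' @export
simulate_ct_experiment <- function(spec, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  G <- nrow(spec$genes)
  C <- nrow(spec$cells)
  nb <- spec$n_bio
  nt <- spec$n_tech
  cell_of_sample <- rep(seq_len(C), each = nb)
  bio_of_sample <- rep(seq_len(nb), times = C)
  S <- length(cell_of_sample)
  well_sample <- rep(seq_len(S), each = nt)
  ct <- matrix(NA_real_, G, S * nt,
               dimnames = list(spec$genes$gene_id, NULL))
  with_rng_seed(rng_seed, {
    for (i in seq_len(G)) {
      g <- spec$genes[i, ]
      delta <- numeric(C)
      if (!is.null(spec$offsets) && g$gene_id %in% rownames(spec$offsets)) {
        hit <- match(spec$cells$condition, colnames(spec$offsets))
        delta[!is.na(hit)] <- spec$offsets[g$gene_id, hit[!is.na(hit)]]
      }
      u <- stats::rnorm(C, 0, g$tau)
      v <- stats::rnorm(S, 0, g$sigma_bio)
      w <- stats::rnorm(S * nt, 0, g$sigma_tech)
      ct[i, ] <- g$base_ct + delta[cell_of_sample[well_sample]] +
        u[cell_of_sample[well_sample]] + v[well_sample] + w
    }
  })
  if (any(ct < 5 | ct > 45)) {
    idx <- which(ct < 5 | ct > 45, arr.ind = TRUE)
    abort_cells(
      "simulated Ct outside [5, 45]; baselines/SDs inconsistent with a real cycler",
      sprintf("%s (well %d) = %.2f", rownames(ct)[idx[, 1]], idx[, 2],
              ct[idx]))
  }
  sid <- sprintf("%s_%s_b%d",
                 gsub("[^A-Za-z0-9]+", ".", spec$cells$condition)[cell_of_sample],
                 gsub("[^A-Za-z0-9]+", ".", spec$cells$timepoint)[cell_of_sample],
                 bio_of_sample)
  samples <- data.frame(
    sample_id = rep(sid, each = nt),
    condition = rep(spec$cells$condition[cell_of_sample], each = nt),
    timepoint = rep(spec$cells$timepoint[cell_of_sample], each = nt),
    bio_rep = rep(bio_of_sample, each = nt),
    tech_rep = rep(seq_len(nt), times = S),
    stringsAsFactors = FALSE)
  truth <- spec$genes[, c("gene_id", "designation", "tau", "sigma_bio",
                          "sigma_tech")]
  rownames(truth) <- NULL
  list(ct = ct_matrix(ct, samples, collapsed = nt == 1L), truth = truth)
}

#' Simulate a standard-curve dilution series
#'
#' For relative template concentration `x`, the expected Ct is
#' `base_ct - log10(x) / log10(1 + E_true)`: one cycle earlier for every
#' factor of `(1 + E)` more template. Replicate noise is Gaussian with SD
#' `rep_sd` cycles.
#'
#' @param E_true true amplification efficiency as a fraction (1 = perfect
#'   doubling); must satisfy `0 < E_true <= 1.5`.
#' @param base_ct expected Ct at concentration 1 (cycles).
#' @param dilution_factors strictly positive, distinct relative
#'   concentrations (at least 3), e.g. `5^-(1:5)`.
#' @param rep_sd replicate SD in cycles (0 = noiseless).
#' @param n_reps replicates per level.
#' @param rng_seed integer seed.
#' @return a [dilution_series()].
#' @export
simulate_dilution_series <- function(E_true, base_ct, dilution_factors,
                                     rep_sd = 0, n_reps = 3L, rng_seed = 1L) {
  if (!is.numeric(E_true) || length(E_true) != 1L || E_true <= 0 ||
      E_true > 1.5) {
    stop("E_true must be a fraction in (0, 1.5]", call. = FALSE)
  }
  x <- as.numeric(dilution_factors)
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  if (any(x <= 0) || anyDuplicated(x)) {
    stop("dilution factors must be strictly positive and distinct",
         call. = FALSE)
  }
  stopifnot(is_count(n_reps), rep_sd >= 0)
  mu <- base_ct - log10(x) / log10(1 + E_true)
  ct <- with_rng_seed(rng_seed, {
    matrix(rep(mu, each = n_reps) +
             stats::rnorm(length(x) * n_reps, 0, rep_sd),
           nrow = length(x), byrow = TRUE)
  })
  dilution_series(levels = x, ct_values = ct)
}

# Fixed, documented per-condition offsets for the preset: each gene's
# condition-level fixed effect is N(0, tau_g^2) drawn once under a constant
# design seed, so tissue/stage/treatment regulation is a reproducible
# property of the preset rather than of the run seed.
.preset_offsets <- function(genes, conditions, design_seed = 20240401L) {
  with_rng_seed(design_seed, {
    off <- matrix(stats::rnorm(nrow(genes) * length(conditions)),
                  nrow = nrow(genes),
                  dimnames = list(genes$gene_id, conditions))
    off * genes$tau
  })
}

#' Default study-design preset for the simulator
#'
#' Emulates a full reference-miRNA screening design: 14 candidate genes
#' (9 miRNAs and 5 conventional reference genes) profiled under 9 stress
#' treatments (cold, salt, drought; ABA, MeJA, ethephon; Al3+, Cu2+, Fe2+)
#' at 6 timepoints (0, 3, 6, 12, 24, 72 h), across 6 flowering stages
#' (S1-S6) and 4 tissues (root, leaf, seed, flower), with 3 biological and 3
#' technical replicates throughout.
#'
#' Three genes are designated stable (`tau` = 0.05 cycles: miR159b-3p,
#' novel3, novel2), three unstable (UBQ4 `tau` = 1.5, ACT11 1.8, TUA5 3.0 --
#' TUA5 is the designated least-stable gene), and the remaining eight
#' intermediate (`tau` = 0.8). All genes share `sigma_bio` = 0.2 and
#' `sigma_tech` = 0.1 cycles. Each gene additionally carries fixed
#' per-condition offsets with SD proportional to its `tau`, modelling
#' systematic tissue-, stage- and treatment-level regulation on top of the
#' random condition-by-timepoint fluctuations.
#'
#' @param rng_seed default simulation seed stored in the spec.
#' @return a [synthetic_spec()].
#' @seealso [default_condition_sets()] for the matching analysis battery.
#' @export
study_design_preset <- function(rng_seed = 1L) {
  genes <- data.frame(
    gene_id = c("miR159b-3p", "novel3", "novel2",
                "novel8", "novel33", "miR395e", "miR403-3p", "miR168b-5p",
                "miR171a-3p", "U6", "18S",
                "UBQ4", "ACT11", "TUA5"),
    base_ct = c(15.5, 18.0, 17.0,
                16.5, 19.0, 20.0, 21.0, 21.5,
                22.0, 23.0, 24.0,
                27.0, 26.0, 25.0),
    tau = c(0.05, 0.05, 0.05,
            0.8, 0.8, 0.8, 0.8, 0.8,
            0.8, 0.8, 0.8,
            1.5, 1.8, 3.0),
    sigma_bio = 0.2,
    sigma_tech = 0.1,
    designation = c(rep("stable", 3L), rep("intermediate", 8L),
                    rep("unstable", 3L)),
    stringsAsFactors = FALSE)
  treatments <- c("cold", "salt", "drought", "ABA", "MeJA", "ethephon",
                  "Al3+", "Cu2+", "Fe2+")
  cells <- rbind(
    expand.grid(condition = treatments,
                timepoint = c("0", "3", "6", "12", "24", "72"),
                stringsAsFactors = FALSE),
    data.frame(condition = paste0("S", 1:6), timepoint = "stage",
               stringsAsFactors = FALSE),
    data.frame(condition = c("root", "leaf", "seed", "flower"),
               timepoint = "tissue", stringsAsFactors = FALSE))
  offsets <- .preset_offsets(genes, unique(cells$condition))
  synthetic_spec(genes, cells, n_bio = 3L, n_tech = 3L, offsets = offsets,
                 rng_seed = rng_seed)
}

#' Condition sets matching the study-design preset
#'
#' The 15 analysis subsets of the preset design: each of the nine
#' treatments, the three pooled families (abiotic = cold + salt + drought,
#' hormone = ABA + MeJA + ethephon, metal ion = Al3+ + Cu2+ + Fe2+),
#' flowering stages, tissues, and all samples.
#'
#' @return a named list of [condition_set()] objects.
#' @export
default_condition_sets <- function() {
  sets <- list(
    condition_set("cold", "cold"),
    condition_set("salt", "salt"),
    condition_set("drought", "drought"),
    condition_set("abiotic", c("cold", "salt", "drought")),
    condition_set("ABA", "ABA"),
    condition_set("MeJA", "MeJA"),
    condition_set("ethephon", "ethephon"),
    condition_set("hormone", c("ABA", "MeJA", "ethephon")),
    condition_set("Al3+", "Al3+"),
    condition_set("Cu2+", "Cu2+"),
    condition_set("Fe2+", "Fe2+"),
    condition_set("metal_ion", c("Al3+", "Cu2+", "Fe2+")),
    condition_set("flowering", paste0("S", 1:6)),
    condition_set("tissues", c("root", "leaf", "seed", "flower")),
    condition_set("all_samples"))
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}
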