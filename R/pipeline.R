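# End-to-end pipeline: read (or simulate) -> collapse -> battery ->
# recommend, with a deterministic on-disk report bundle.

# Round only at serialization; write a schema comment line first.
write_report_tsv <- function(df, path, precision = 4L) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- round(out[[j]], precision)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(out), collapse = ", ")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

canonical_config_hash <- function(cfg) {
  norm <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, norm)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(norm(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

default_pipeline_config <- function() {
  list(v_threshold = 0.15, bestkeeper_sd_threshold = 1.0,
       aggregation = "ranks", rng_seed = 1L, precision = 4L,
       qc_sd_warn = 0.5)
}

#' Run the full reference-gene stability pipeline
#'
#' Executes read (or simulate) -> technical-replicate collapse -> condition
#' battery -> recommendation, and writes a report bundle to the configured
#' output directory: `ct_summary.tsv`, `comprehensive_ranking.tsv` (wide,
#' rows = rank position, columns = condition sets), one
#' `scores_<method>.tsv` per stability method, `genorm_pairwise_variation.tsv`,
#' a machine-readable `summary.json` and a `run_log.txt` recording the
#' package version, config hash and seed. All computation is finished before
#' any file is written, so a failing stage leaves no partial outputs; reruns
#' with an identical config produce byte-identical bundles.
#'
#' @param config a list, or path to a YAML/JSON file, with fields:
#'   `out_dir` (required); either `input` (list with `ct` path, optional
#'   `layout` and `meta`) or `simulate` (list with optional `seed`; the
#'   study-design preset is simulated); optional `condition_sets` (path to a
#'   [read_condition_sets()] config; default the preset battery);
#'   `v_threshold` (0.15), `bestkeeper_sd_threshold` (1.0), `aggregation`
#'   (`"ranks"`), `rng_seed` (1), `precision` (4 decimals at serialization),
#'   `qc_sd_warn` (0.5 cycles).
#' @return invisibly, a list with `battery`, `summary` and `paths`.
#' @export
run_pipeline <- function(config) {
  stage <- "config"
  fail <- function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    if (is.character(config)) {
      if (!file.exists(config)) stop("config file not found: ", config)
      config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
        jsonlite::read_json(config, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(config)
      }
    }
    cfg <- utils::modifyList(default_pipeline_config(), config)
    if (is.null(cfg$out_dir)) stop("config needs `out_dir`")
    if (cfg$v_threshold <= 0 || cfg$bestkeeper_sd_threshold <= 0) {
      stop("thresholds must be positive")
    }
    # hash covers the analysis-relevant config; the output location is not
    # part of the result's identity
    cfg_hash <- canonical_config_hash(cfg[setdiff(names(cfg), "out_dir")])

    stage <- "read"
    truth <- NULL
    if (!is.null(cfg$input)) {
      if (!file.exists(cfg$input$ct)) {
        stop("input Ct table not found: ", cfg$input$ct)
      }
      m <- read_ct_table(cfg$input$ct,
                         layout = cfg$input$layout %||% "long",
                         meta = cfg$input$meta)
    } else {
      seed <- cfg$simulate$seed %||% cfg$rng_seed
      sim <- simulate_ct_experiment(study_design_preset(), rng_seed = seed)
      m <- sim$ct
      truth <- sim$truth
    }
    sets <- if (is.null(cfg$condition_sets)) {
      default_condition_sets()
    } else {
      read_condition_sets(cfg$condition_sets)
    }

    stage <- "collapse"
    collapsed <- if (m$collapsed) m else {
      suppressWarnings(collapse_technical_replicates(
        m, qc_sd_warn = cfg$qc_sd_warn))
    }
    qc_log <- attr(collapsed, "qc_log") %||%
      data.frame(gene_id = character(), sample_id = character(),
                 n_reps = integer(), sd_ct = numeric())

    stage <- "battery"
    battery <- run_condition_battery(
      collapsed, sets, v_threshold = cfg$v_threshold,
      aggregation = cfg$aggregation,
      bestkeeper_sd_threshold = cfg$bestkeeper_sd_threshold)
    summ <- ct_summary(collapsed)

    stage <- "summary"
    set_summaries <- lapply(names(battery$results), function(nm) {
      r <- battery$results[[nm]]
      list(final_order = r$comprehensive$gene_id,
           geom_mean_rank = round(r$comprehensive[[
             if (battery$aggregation == "ranks") "geom_mean_rank"
             else "geom_mean_score"]], cfg$precision),
           optimal_n = attr(r$recommended, "optimal_n"),
           no_n_below_threshold = attr(r$recommended,
                                       "no_n_below_threshold"),
           recommended = as.character(r$recommended),
           normfinder_pooled_fallback = r$normfinder_detail$pooled_fallback)
    })
    names(set_summaries) <- names(battery$results)
    summary_obj <- list(
      package = "refstab",
      version = as.character(utils::packageVersion("refstab")),
      config_hash = cfg_hash,
      rng_seed = cfg$rng_seed,
      aggregation = battery$aggregation,
      v_threshold = battery$v_threshold,
      n_genes = nrow(battery$table),
      n_samples = n_samples(collapsed),
      condition_sets = set_summaries)

    stage <- "write"
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    p <- file.path(cfg$out_dir, "ct_summary.tsv")
    write_report_tsv(summ, p, cfg$precision)
    paths$ct_summary <- p
    p <- file.path(cfg$out_dir, "comprehensive_ranking.tsv")
    write_report_tsv(battery$table, p, cfg$precision)
    paths$comprehensive_ranking <- p
    for (method in c("delta_ct", "genorm", "normfinder", "bestkeeper")) {
      rows <- lapply(names(battery$results), function(nm) {
        r <- battery$results[[nm]]
        s <- r$scores[[method]]
        rk <- r$ranks[[method]]
        data.frame(condition_set = nm, gene_id = s$gene_id, score = s$score,
                   rank = rk$rank[match(s$gene_id, rk$gene_id)],
                   stringsAsFactors = FALSE)
      })
      p <- file.path(cfg$out_dir, sprintf("scores_%s.tsv", method))
      write_report_tsv(do.call(rbind, rows), p, cfg$precision)
      paths[[paste0("scores_", method)]] <- p
    }
    vrows <- lapply(names(battery$results), function(nm) {
      v <- battery$results[[nm]]$trace$v
      data.frame(condition_set = nm, n = v$n, v = v$v,
                 below_threshold = v$v < battery$v_threshold,
                 stringsAsFactors = FALSE)
    })
    p <- file.path(cfg$out_dir, "genorm_pairwise_variation.tsv")
    write_report_tsv(do.call(rbind, vrows), p, cfg$precision)
    paths$genorm_v <- p
    if (nrow(qc_log)) {
      p <- file.path(cfg$out_dir, "qc_log.tsv")
      write_report_tsv(qc_log, p, cfg$precision)
      paths$qc_log <- p
    }
    if (!is.null(truth)) {
      p <- file.path(cfg$out_dir, "simulation_truth.tsv")
      write_report_tsv(truth, p, cfg$precision)
      paths$truth <- p
    }
    p <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(summary_obj, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths$summary <- p
    p <- file.path(cfg$out_dir, "run_log.txt")
    writeLines(c(
      sprintf("refstab %s", summary_obj$version),
      sprintf("config_hash: %s", cfg_hash),
      sprintf("rng_seed: %s", cfg$rng_seed),
      sprintf("input: %s",
              if (is.null(cfg$input)) "simulated (study design preset)"
              else cfg$input$ct),
      sprintf("condition_sets: %s", paste(names(sets), collapse = ", ")),
      sprintf("stages: config, read, collapse, battery, summary, write"),
      sprintf("qc_flags: %d", nrow(qc_log))), p)
    paths$log <- p
    invisible(list(battery = battery, summary = summary_obj, paths = paths))
  }, error = fail)
}
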