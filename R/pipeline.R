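# Configuration-driven end-to-end pipeline: feature table -> DAM calls and
# summaries -> model enhancement and gap-filling -> growth simulation and
# capability screen -> subsystem overlays, with a structured run log.

#' Read a pipeline configuration
#'
#' YAML with a versioned schema (`fluxprint-pipeline/1`). Defaults follow the
#' conventional analysis parameters: |log2 FC| threshold 0.5, alpha 0.05,
#' production threshold 1e-10 mmol/gDW/h, glucose uptake 25 mmol/gDW/h,
#' growth floor 1 h^-1.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_pipeline_config(cfg, dir = dirname(path))
}

#' @rdname read_pipeline_config
#' @param config Raw named list (e.g. from [yaml::read_yaml()]).
#' @param dir Base directory against which relative paths resolve.
#' @export
as_pipeline_config <- function(config, dir = ".") {
  defaults <- list(
    schema = "fluxprint-pipeline/1",
    lfc_threshold = 0.5, alpha = 0.05,
    production_threshold = 1e-10,
    uptake_rate = 25, growth_floor = 1,
    growth_unit = "per_hour",
    normalization = "median-scale",
    seed = 1,
    comparisons = list(), carbon_sources = list(), gapfill_targets = list(),
    capability_targets = list()
  )
  cfg <- defaults
  for (k in names(config)) cfg[[k]] <- config[[k]]
  for (p in c("feature_table", "design", "features", "template_model", "universe", "deg_table")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      candidate <- file.path(dir, cfg[[p]])
      if (file.exists(candidate)) cfg[[p]] <- candidate
    }
  }
  num <- c("lfc_threshold", "alpha", "production_threshold", "uptake_rate", "growth_floor")
  bad <- num[vapply(num, function(k) !is.numeric(cfg[[k]]) || cfg[[k]] < 0, logical(1))]
  if (length(bad)) stop("config thresholds must be non-negative numbers: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

read_feature_table_files <- function(table_path, design_path, features_path = NULL) {
  tab <- readr::read_tsv(table_path, col_types = readr::cols(
    feature = "c", .default = "d"
  ))
  x <- as.matrix(tab[setdiff(names(tab), "feature")])
  rownames(x) <- tab$feature
  design <- readr::read_tsv(design_path, col_types = readr::cols(
    sample = "c", condition = "c", replicate = "i"
  ))
  features <- if (!is.null(features_path)) {
    readr::read_tsv(features_path, col_types = readr::cols(
      feature = "c", mz = "d", rt = "d", name = "c", class = "c"
    ))
  } else {
    NULL
  }
  feature_table(x, design, features)
}

write_feature_table_files <- function(ft, dir, prefix = "feature") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as_tibble(ft$intensities, rownames = "feature")
  readr::write_tsv(tab, file.path(dir, paste0(prefix, "_intensities.tsv")))
  readr::write_tsv(ft$design, file.path(dir, paste0(prefix, "_design.tsv")))
  readr::write_tsv(ft$features, file.path(dir, paste0(prefix, "_metadata.tsv")))
  invisible(dir)
}

#' Run the full footprint-integration pipeline
#'
#' Stage order: normalise intensities; pairwise DAM tests for every
#' configured comparison; significance calls; DAM summaries, set comparison,
#' clustering, PCA and volcano coordinates; footprint incorporation into the
#' template model; gap-filling of configured targets; model statistics and
#' diff against the template; growth simulation per carbon source;
#' biosynthetic capability screen; subsystem overlays. Any stage error
#' aborts with the stage name; outputs of completed stages are preserved in
#' the returned (partial) report.
#'
#' The run is a pure function of (inputs, config, seed) up to timestamps.
#'
#' @param config A `pipeline_config` (or named list coercible to one).
#' @param inputs Optional in-memory inputs overriding the config paths:
#'   `feature_table`, `model`, `universe`, `degs`, `footprints`.
#' @param out_dir Optional directory for TSV/JSON artefacts.
#' @return A `pipeline_report` list with per-stage results and `log`
#'   (tibble stage/status/detail).
#' @export
run_pipeline <- function(config, inputs = list(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- as_pipeline_config(config)
  report <- list(config = config)
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1L]] <<- tibble(stage = stage, status = status, detail = detail)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note(name, "error", conditionMessage(e))
      report$log <- bind_rows(log)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ft <- inputs$feature_table %||% stage(
    "load-feature-table",
    read_feature_table_files(config$feature_table, config$design, config$features)
  )
  ft <- stage("normalize", normalize_intensities(ft, method = config$normalization))
  note("normalize", "ok", paste("method:", config$normalization))

  comparisons <- config$comparisons
  if (!length(comparisons)) {
    conds <- unique(ft$design$condition)
    comparisons <- utils::combn(conds, 2, simplify = FALSE)
  }
  dams <- stage("pairwise-dam-tests", bind_rows(lapply(comparisons, function(pr) {
    pairwise_dam_test(ft, pr[[1]], pr[[2]])
  })))
  dams <- stage("call-significant", call_significant(
    dams,
    lfc_threshold = config$lfc_threshold, alpha = config$alpha
  ))
  report$dams <- dams
  note("call-significant", "ok", sprintf(
    "lfc>=%.3g (paper-stated), alpha<=%.3g (paper-stated)",
    config$lfc_threshold, config$alpha
  ))

  report$dam_summary <- stage("summarize", summarize_dams(dams))
  sig <- filter(dams, .data$significant)
  sets <- split(sig, sig$comparison)
  if (length(sets) >= 2L) {
    report$dam_overlap <- stage("compare-sets", compare_dam_sets(sets))
  }
  if (nrow(sig) >= 2L) {
    lfc_mat <- sig %>%
      select("feature", "comparison", "log2_fold_change") %>%
      tidyr::pivot_wider(names_from = "comparison", values_from = "log2_fold_change", values_fill = 0)
    m <- as.matrix(lfc_mat[-1])
    rownames(m) <- lfc_mat$feature
    report$dam_cluster <- stage("cluster", hierarchical_cluster(m))
  }
  report$pca <- stage("pca", pca_scores(ft))
  report$volcano <- stage("volcano", volcano_data(dams))
  note("summaries", "ok")

  model <- inputs$model %||% (if (!is.null(config$template_model)) {
    stage("load-model", load_model(config$template_model))
  })
  if (!is.null(model)) {
    template <- model
    footprints <- inputs$footprints %||% (if (!is.null(config$footprints)) {
      readr::read_tsv(config$footprints, col_types = readr::cols(.default = "c"))
    })
    if (!is.null(footprints)) {
      inc <- stage("incorporate-footprints", incorporate_footprint_metabolites(model, footprints))
      model <- inc$model
      report$footprint_matches <- inc$matches
      note("incorporate-footprints", "ok", sprintf("%d records, %d matched", nrow(inc$matches), sum(inc$matches$matched)))
    }
    universe <- inputs$universe %||% (if (!is.null(config$universe)) {
      stage("load-universe", load_model(config$universe, check = FALSE))
    })
    if (!is.null(universe) && length(config$gapfill_targets)) {
      gf_results <- list()
      for (tg in unlist(config$gapfill_targets)) {
        res <- stage(paste0("gap-fill:", tg), gap_fill(model, universe, tg))
        gf_results[[tg]] <- res
        if (res$status == "filled") model <- res$model
        note(paste0("gap-fill:", tg), res$status, paste(res$added, collapse = ";"))
      }
      report$gap_fill <- gf_results
    }
    report$model <- model
    report$model_stats <- stage("model-stats", compute_model_stats(model))
    report$model_diff <- stage("model-diff", diff_models(template, model))

    if (length(config$carbon_sources)) {
      report$growth <- stage("growth", bind_rows(lapply(config$carbon_sources, function(cs) {
        simulate_growth(
          model, medium_spec(cs, uptake_rate = config$uptake_rate),
          unit = config$growth_unit
        )
      })))
      note("growth", "ok")
    }
    if (length(config$capability_targets)) {
      report$capability <- stage("capability", screen_biosynthetic_capability(
        model, unlist(config$capability_targets),
        medium = medium_spec(
          config$carbon_sources[[1]] %||% "glc_e",
          uptake_rate = config$uptake_rate
        ),
        growth_floor = config$growth_floor
      ))
      note("capability", "ok")
    }
    if (!is.null(config$subsystems)) {
      degs <- inputs$degs %||% (if (!is.null(config$deg_table)) {
        readr::read_tsv(config$deg_table, col_types = readr::cols(
          gene = "c", log2_fold_change = "d", comparison = "c", .default = "c"
        ))
      })
      overlays <- list()
      for (sub in unlist(config$subsystems)) {
        subnet <- stage(paste0("subsystem:", sub), extract_subsystem(model, sub))
        comps <- unique(dams$comparison[dams$significant])
        views <- lapply(comps, function(cc) {
          overlay_omics(subnet, dams, degs %||% tibble(
            gene = character(), log2_fold_change = numeric(), comparison = character()
          ), cc)
        })
        overlays[[sub]] <- list(
          subnetwork = subnet,
          views = views,
          report = report_pathway_response(views, lfc_threshold = config$lfc_threshold)
        )
      }
      report$pathways <- overlays
      note("overlays", "ok")
    }
  }

  report$log <- bind_rows(log)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' Write pipeline artefacts to disk
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(report$dams, file.path(out_dir, "dam_records.tsv"))
  readr::write_tsv(report$dam_summary$comparisons, file.path(out_dir, "dam_summary.tsv"))
  readr::write_tsv(report$dam_summary$classes, file.path(out_dir, "dam_classes.tsv"))
  if (!is.null(report$growth)) readr::write_tsv(report$growth, file.path(out_dir, "growth.tsv"))
  if (!is.null(report$capability)) {
    readr::write_tsv(as_tibble(report$capability), file.path(out_dir, "capability.tsv"))
  }
  if (!is.null(report$model_stats)) {
    readr::write_tsv(tidy(report$model_stats), file.path(out_dir, "model_stats.tsv"))
  }
  if (!is.null(report$model_diff)) {
    readr::write_tsv(tidy(report$model_diff), file.path(out_dir, "model_diff.tsv"))
  }
  if (!is.null(report$model)) save_model(report$model, file.path(out_dir, "enhanced_model.json"))
  if (!is.null(report$pathways)) {
    for (nm in names(report$pathways)) {
      fn <- paste0("pathway_", gsub("[^A-Za-z0-9]+", "_", tolower(nm)), ".tsv")
      readr::write_tsv(report$pathways[[nm]]$report, file.path(out_dir, fn))
    }
  }
  readr::write_tsv(report$log, file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$log)
  invisible(x)
}
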