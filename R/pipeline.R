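#' Pipeline configuration
#'
#' Collects every tunable constant of the workflow with its conventional
#' default: pseudobulking (min 25 cells), gene QC (100 counts in a single
#' sample, detection in 25% of samples), highly variable gene selection
#' (normalized variance > 1.5 or biological variance > 0), cell-type
#' markers (log fold change > 1, FDR < 0.01), state markers (lfc >= 0.5,
#' FDR < 0.05), six factors, loading threshold 0.1, spot proportion
#' threshold 0.1, activation score threshold 2, permutation counts
#' (1000 functional, 100 spatial/bulk), top 21 spatial interactions.
#' Stage seeds are derived deterministically from the global seed.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_cells = 25, min_count = 100, min_detection = 0.25,
              hvg_method = "biovar", hvg_threshold = NULL,
              marker_lfc_min = 1, marker_fdr_max = 0.01,
              state_lfc_min = 0.5, state_fdr_max = 0.05,
              K = 6, loading_threshold = 0.1,
              prop_threshold = 0.1, score_threshold = 2,
              n_perm_functional = 1000, n_perm_spatial = 100,
              n_perm_bulk = 100, top_n_interactions = 21,
              alpha_bh = 0.05, alpha_state_anova = 0.01,
              max_iter = 1000, tol = 1e-6, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_seed <- function(config, stage) {
  offsets <- c(fit = 0L, functional = 1L, spatial = 2L, bulk = 3L,
               simulate = 4L)
  config$seed + unname(offsets[stage])
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  res
}

#' Run the end-to-end multicellular factor analysis pipeline
#'
#' Composes the workflow: pseudobulk views (QC, TMM, HVG, background
#' exclusion, assembly) -> factor model fit -> postprocessing ->
#' factor-covariate association -> signature extraction, with optional
#' spatial scoring and bulk transfer stages. All outputs are plain CSV /
#' TSV / JSON files under `out_dir`; a JSON-lines run log records seeds
#' and per-stage record counts. Identical config and inputs reproduce
#' identical outputs.
#'
#' @param cells a [cell_profiles] object.
#' @param config a [pipeline_config].
#' @param out_dir artifact directory (created).
#' @param covariates optional data.frame of sample covariates; defaults
#'   to the condition recorded in the cell metadata.
#' @param slides optional list of [spatial_slide] for the spatial stage.
#' @param bulk optional `bulk_study` for the transfer stage.
#' @return list with the fitted `model`, `views`, `associations`,
#'   `signatures`, optional `areas` and `bulk_scores`, and `out_dir`.
#' @export
run_pipeline <- function(cells, config = pipeline_config(), out_dir,
                         covariates = NULL, slides = NULL, bulk = NULL) {
  stopifnot(inherits(cells, "cell_profiles"),
            inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.jsonl")
  unlink(logf)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  log_stage("config", config = unclass(config))

  views <- run_stage("makeviews", logf, {
    raw <- build_pseudobulk(cells, min_cells = config$min_cells)
    if (!length(raw)) stop("no views: every profile was discarded")
    pb <- lapply(raw, qc_filter_genes, min_count = config$min_count,
                 min_detection = config$min_detection)
    pb <- lapply(pb, tmm_normalize)
    hvg <- lapply(pb, select_hvg, method = config$hvg_method,
                  threshold = config$hvg_threshold)
    ## markers are contrasted on the unfiltered pseudobulks: per-view gene
    ## QC removes other cell types' markers from a view, which would blind
    ## the cross-type contrast
    markers <- detect_markers(lapply(raw, tmm_normalize),
                              level = "celltype_pseudobulk",
                              lfc_min = config$marker_lfc_min,
                              fdr_max = config$marker_fdr_max)
    final <- exclude_background(hvg, markers)
    empty <- vapply(final, length, 0L) == 0
    if (any(empty)) {
      warning("views with empty gene sets omitted: ",
              paste(names(final)[empty], collapse = ", "))
      final <- final[!empty]; pb <- pb[!empty]
    }
    if (!length(pb)) stop("no views: all gene sets empty")
    group_id <- NULL
    if ("group_id" %in% names(cells$cell_meta)) {
      gm <- unique(cells$cell_meta[c("sample_id", "group_id")])
      group_id <- setNames(gm$group_id, gm$sample_id)
    }
    ds <- assemble_views(pb, gene_sets = final, group_id = group_id)
    log_stage("makeviews", n_views = length(ds$views),
              n_samples = length(ds$sample_ids),
              genes_per_view = vapply(ds$views, ncol, 0L),
              background_removed = vapply(attr(final, "removed") %||%
                                            list(), length, 0L))
    list(dataset = ds, pseudobulk = pb, markers = markers, final = final)
  })

  model <- run_stage("fit", logf, {
    if (!length(views$dataset$views)) stop("no views")
    hp <- gfa_hyperparams(K = config$K, max_iter = config$max_iter,
                          tol = config$tol,
                          seed = stage_seed(config, "fit"))
    m <- postprocess_factors(fit_gfa(views$dataset, hp))
    log_stage("fit", iterations = length(m$elbo_trace),
              converged = m$converged,
              total_r2 = m$r2$overall_total)
    m
  })

  assoc <- run_stage("associate", logf, {
    if (is.null(covariates)) {
      meta <- unique(cells$cell_meta[c("sample_id", "condition")])
      covariates <- data.frame(condition = meta$condition,
                               row.names = meta$sample_id)
    }
    Z <- do.call(rbind, model$Z)
    a <- associate_factors(Z, covariates)
    write.csv(a, file.path(out_dir, "associations.csv"), row.names = FALSE)
    log_stage("associate", n_tests = nrow(a))
    a
  })

  sigs <- run_stage("signatures", logf, {
    cond <- assoc[assoc$covariate == assoc$covariate[1], ]
    top <- cond$factor[which.min(cond$padj)]
    s <- extract_signatures(model, top,
                            threshold = config$loading_threshold)
    write_signatures(s, file.path(out_dir, "signatures"))
    log_stage("signatures", top_factor = top, n_signatures = length(s),
              genes = vapply(s, function(x) length(x$weights), 0L))
    s
  })

  areas <- NULL
  if (!is.null(slides)) {
    areas <- run_stage("spatial", logf, {
      ar <- do.call(rbind, lapply(slides, function(sl) {
        sc <- score_spots(sl, sigs, prop_threshold = config$prop_threshold,
                          n_perm = config$n_perm_spatial,
                          seed = stage_seed(config, "spatial"))
        relative_activation_area(sc, sl$props,
                                 score_threshold = config$score_threshold,
                                 prop_threshold = config$prop_threshold)
      }))
      write.csv(ar, file.path(out_dir, "activation_areas.csv"),
                row.names = FALSE)
      log_stage("spatial", n_slides = length(slides), n_rows = nrow(ar))
      ar
    })
  }

  bulk_scores <- NULL
  if (!is.null(bulk)) {
    bulk_scores <- run_stage("bulk", logf, {
      bs <- score_bulk_signatures(bulk, sigs,
                                  n_perm = config$n_perm_bulk,
                                  seed = stage_seed(config, "bulk"))
      write.csv(bs$z, file.path(out_dir, "bulk_scores.csv"))
      log_stage("bulk", n_samples = nrow(bs$z), n_signatures = ncol(bs$z))
      bs
    })
  }

  save_model(model, file.path(out_dir, "model"))
  Z <- do.call(rbind, model$Z)
  write.csv(data.frame(sample_id = rownames(Z), Z),
            file.path(out_dir, "factor_scores.csv"), row.names = FALSE)
  list(model = model, views = views, associations = assoc,
       signatures = sigs, areas = areas, bulk_scores = bulk_scores,
       out_dir = out_dir)
}
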