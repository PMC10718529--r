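#' Load annotated single-cell counts from disk
#'
#' Supported formats: `"mtx_dir"` — a directory with `matrix.mtx`
#' (genes x cells triplet), `features.tsv`, `barcodes.tsv` and a
#' cell-metadata CSV/TSV keyed by barcode; `"csv"` — a dense gene x cell
#' count table whose first column holds gene ids, plus the same metadata
#' table. Duplicate gene ids are summed; cells with missing required
#' metadata are dropped (and counted in attribute `dropped_cells`);
#' rows/columns are ordered lexicographically.
#'
#' @param path matrix directory or CSV file.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param meta metadata file path; defaults to `metadata.csv` inside an
#'   mtx directory.
#' @param column_map named vector mapping required names (`sample_id`,
#'   `cell_type`, optionally `cell_state`, `condition`, `group_id`,
#'   `batch`, `barcode`) to the columns of the metadata table.
#' @return a [cell_profiles].
#' @export
load_cell_data <- function(path, format = c("mtx_dir", "csv"),
                           meta = NULL, column_map = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mfile <- file.path(path, "matrix.mtx")
    for (f in c(mfile, file.path(path, "features.tsv"),
                file.path(path, "barcodes.tsv")))
      if (!file.exists(f)) stop("missing file: ", f)
    if (file.size(mfile) == 0) stop("empty file: ", mfile)
    m <- as.matrix(Matrix::readMM(mfile))            # genes x cells
    feats <- read.delim(file.path(path, "features.tsv"), header = FALSE)[[1]]
    bcs <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE)[[1]]
    stopifnot(nrow(m) == length(feats), ncol(m) == length(bcs))
    counts <- t(m)
    dimnames(counts) <- list(bcs, feats)
    meta <- meta %||% file.path(path, "metadata.csv")
  } else {
    if (!file.exists(path) || file.size(path) == 0)
      stop("empty or missing file: ", path)
    tab <- read.csv(path, check.names = FALSE)
    genes <- as.character(tab[[1]])
    counts <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(counts) <- genes
    assert_that(!is.null(meta), "csv format requires a metadata file")
  }
  mt <- read.csv(meta, check.names = FALSE)
  cm <- column_map %||% c()
  pick <- function(key) {
    col <- unname(cm[key]) %||% key
    if (is.na(col)) col <- key
    if (col %in% names(mt)) mt[[col]] else NULL
  }
  bc <- pick("barcode") %||% mt[[1]]
  md <- data.frame(row.names = as.character(bc))
  for (key in c("sample_id", "cell_type", "cell_state", "condition",
                "group_id", "batch")) {
    v <- pick(key)
    if (!is.null(v)) md[[key]] <- as.character(v)
  }
  assert_that(all(c("sample_id", "cell_type") %in% names(md)),
              "metadata must provide sample_id and cell_type")
  common <- intersect(rownames(counts), rownames(md))
  if (length(common) != nrow(counts) || length(common) != nrow(md))
    if (length(common) == 0)
      stop(sprintf("dimension mismatch: %d cells in matrix, %d in metadata, 0 shared",
                   nrow(counts), nrow(md)))
  counts <- counts[common, , drop = FALSE]
  md <- md[common, , drop = FALSE]
  ok <- !is.na(md$sample_id) & !is.na(md$cell_type) &
        md$sample_id != "" & md$cell_type != ""
  dropped <- sum(!ok)
  counts <- counts[ok, , drop = FALSE]
  md <- md[ok, , drop = FALSE]
  ord <- order(rownames(counts))
  storage.mode(counts) <- "integer"
  out <- cell_profiles(counts[ord, , drop = FALSE], md[ord, , drop = FALSE])
  attr(out, "dropped_cells") <- dropped
  out
}

fmt17 <- function(x) sprintf("%.17g", x)

write_matrix_exact <- function(m, path) {
  df <- as.data.frame(apply(m, 2, fmt17), stringsAsFactors = FALSE)
  if (nrow(m) == 1) df <- as.data.frame(t(vapply(m[1, ], fmt17, "")))
  colnames(df) <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  df <- cbind(id = rownames(m) %||% as.character(seq_len(nrow(m))), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_exact <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

MODEL_FORMAT_VERSION <- "mcfa-model-1"

#' Persist a fitted model as a plain-text bundle
#'
#' Writes a directory of full-precision CSV matrices (weights, scores,
#' posterior variances, precisions, explained variance, ELBO trace) plus
#' a JSON config; [load_model] restores it exactly, and saving the
#' loaded model again reproduces the files byte for byte.
#'
#' @param model a `gfa_model`.
#' @param path target directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gfa_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(version = MODEL_FORMAT_VERSION, K = model$K,
              view_names = model$view_names,
              group_names = model$group_names,
              view_kind = as.list(model$view_kind),
              groups = as.list(model$groups),
              hp = unclass(model$hp), converged = model$converged,
              active = as.list(model$active %||% logical(0)))
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (v in model$view_names) {
    write_matrix_exact(model$W[[v]], file.path(path, paste0("W_", v, ".csv")))
    write_matrix_exact(model$W_var[[v]],
                       file.path(path, paste0("Wvar_", v, ".csv")))
    write_matrix_exact(rbind(alpha = model$alpha[[v]]),
                       file.path(path, paste0("alpha_", v, ".csv")))
    for (g in model$group_names)
      write_matrix_exact(rbind(tau = model$tau[[v]][[g]]),
                         file.path(path, paste0("tau_", v, "_", g, ".csv")))
  }
  for (g in model$group_names) {
    write_matrix_exact(model$Z[[g]], file.path(path, paste0("Z_", g, ".csv")))
    write_matrix_exact(model$Z_var[[g]],
                       file.path(path, paste0("Zvar_", g, ".csv")))
    write_matrix_exact(rbind(beta = model$beta[[g]]),
                       file.path(path, paste0("beta_", g, ".csv")))
  }
  write_matrix_exact(rbind(elbo = model$elbo_trace),
                     file.path(path, "elbo.csv"))
  ## r2 tensor flattened view x group rows
  r2flat <- do.call(rbind, lapply(model$view_names, function(v)
    do.call(rbind, lapply(model$group_names, function(g) {
      row <- c(model$r2$per_factor[v, g, ], total = model$r2$total[v, g])
      m <- rbind(row); rownames(m) <- paste(v, g, sep = "|"); m
    }))))
  write_matrix_exact(r2flat, file.path(path, "r2.csv"))
  write_matrix_exact(rbind(factor_total = c(model$r2$factor_total,
                                            overall = model$r2$overall_total)),
                     file.path(path, "r2_totals.csv"))
  for (v in names(model$transform)) for (g in names(model$transform[[v]])) {
    tr <- model$transform[[v]][[g]]
    rows <- rbind(center = tr$center)
    if (!is.null(tr$scale)) rows <- rbind(rows, scale = tr$scale)
    write_matrix_exact(rows, file.path(path,
                                       paste0("transform_", v, "_", g, ".csv")))
  }
  invisible(path)
}

#' Load a model bundle written by [save_model]
#' @param path bundle directory.
#' @return the restored `gfa_model`.
#' @export
load_model <- function(path) {
  cfgf <- file.path(path, "config.json")
  if (!file.exists(cfgf)) stop("missing group: config.json")
  cfg <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
  if (!identical(cfg$version, MODEL_FORMAT_VERSION))
    stop(sprintf("model format version mismatch: found '%s', expected '%s'",
                 cfg$version %||% "<none>", MODEL_FORMAT_VERSION))
  need <- c(paste0("W_", cfg$view_names, ".csv"),
            paste0("Z_", cfg$group_names, ".csv"), "elbo.csv", "r2.csv")
  for (f in need)
    if (!file.exists(file.path(path, f))) stop("missing group: ", f)
  K <- cfg$K
  vnames <- cfg$view_names; gnames <- cfg$group_names
  rd <- function(f) read_matrix_exact(file.path(path, f))
  model <- list(
    W = setNames(lapply(vnames, function(v) rd(paste0("W_", v, ".csv"))), vnames),
    W_var = setNames(lapply(vnames, function(v) rd(paste0("Wvar_", v, ".csv"))), vnames),
    Z = setNames(lapply(gnames, function(g) rd(paste0("Z_", g, ".csv"))), gnames),
    Z_var = setNames(lapply(gnames, function(g) rd(paste0("Zvar_", g, ".csv"))), gnames),
    alpha = setNames(lapply(vnames, function(v)
      rd(paste0("alpha_", v, ".csv"))[1, ]), vnames),
    beta = setNames(lapply(gnames, function(g)
      rd(paste0("beta_", g, ".csv"))[1, ]), gnames),
    tau = setNames(lapply(vnames, function(v)
      setNames(lapply(gnames, function(g)
        rd(paste0("tau_", v, "_", g, ".csv"))[1, ]), gnames)), vnames),
    elbo_trace = unname(rd("elbo.csv")[1, ]),
    K = K, view_names = vnames, group_names = gnames,
    view_kind = setNames(unlist(cfg$view_kind), names(cfg$view_kind)),
    transform = setNames(lapply(vnames, function(v)
      setNames(lapply(gnames, function(g) {
        f <- file.path(path, paste0("transform_", v, "_", g, ".csv"))
        if (!file.exists(f)) return(NULL)
        m <- read_matrix_exact(f)
        list(center = m["center", ],
             scale = if ("scale" %in% rownames(m)) m["scale", ] else NULL)
      }), gnames)), vnames),
    groups = setNames(unlist(cfg$groups), names(cfg$groups)),
    hp = do.call(gfa_hyperparams, cfg$hp[c("K", "a0", "b0", "c0", "d0",
                                           "e0", "f0", "max_iter", "tol",
                                           "seed")]),
    converged = cfg$converged)
  r2flat <- rd("r2.csv")
  per <- array(NA_real_, c(length(vnames), length(gnames), K),
               dimnames = list(vnames, gnames, paste0("Factor", seq_len(K))))
  tot <- matrix(NA_real_, length(vnames), length(gnames),
                dimnames = list(vnames, gnames))
  for (v in vnames) for (g in gnames) {
    row <- r2flat[paste(v, g, sep = "|"), ]
    per[v, g, ] <- row[seq_len(K)]
    tot[v, g] <- row[K + 1]
  }
  totals <- rd("r2_totals.csv")[1, ]
  model$r2 <- list(per_factor = per, total = tot,
                   factor_total = totals[seq_len(K)],
                   overall_total = unname(totals[K + 1]))
  if (length(cfg$active)) model$active <- unlist(cfg$active)
  class(model) <- "gfa_model"
  model
}

#' Export factor signatures as two-column TSV files
#'
#' One `(gene, weight)` TSV per (cell type, factor, sign), named
#' `<cell_type>_factor<k>_<sign>.tsv`.
#'
#' @param sigs output of [extract_signatures].
#' @param dir target directory.
#' @return written paths, invisibly.
#' @export
write_signatures <- function(sigs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sigs, function(s) {
    p <- file.path(dir, sprintf("%s_factor%d_%s.tsv", s$cell_type,
                                s$factor, s$sign))
    write.table(data.frame(gene = names(s$weights), weight = s$weights),
                p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Export gene sets in GMT format
#' @param sets named list of gene id vectors.
#' @param path output file.
#' @export
export_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "mcfa", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
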