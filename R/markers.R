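#' Detect cell-type or cell-state marker genes
#'
#' One-vs-rest differential expression with Welch t-tests and
#' Benjamini-Hochberg adjustment within each contrast.
#'
#' At level `"celltype_pseudobulk"` the input is a named list of
#' normalized `pseudobulk_view`s; each cell type's log-CPM profiles are
#' contrasted against the pooled profiles of all other cell types over the
#' genes common to all views, and markers must satisfy
#' `lfc > lfc_min` (default 1) and adjusted p `< fdr_max` (default 0.01).
#'
#' At level `"cellstate_cells"` the input is a [cell_profiles] object;
#' cells are log-normalized (log1p of counts per 10k) and, within each
#' cell type, each cell state is contrasted against the remaining cells of
#' that type; markers must satisfy `lfc >= lfc_min` (default 0.5) and
#' adjusted p `< fdr_max` (default 0.05).
#'
#' @param data list of pseudobulk views or a `cell_profiles` object.
#' @param level `"celltype_pseudobulk"` or `"cellstate_cells"`.
#' @param lfc_min,fdr_max marker thresholds; `NULL` picks the level default.
#' @return a `marker_table` data.frame with columns `class`, `cell_type`,
#'   `gene`, `lfc`, `p`, `padj`.
#' @export
detect_markers <- function(data,
                           level = c("celltype_pseudobulk", "cellstate_cells"),
                           lfc_min = NULL, fdr_max = NULL) {
  level <- match.arg(level)
  if (level == "celltype_pseudobulk") {
    lfc_min <- lfc_min %||% 1
    fdr_max <- fdr_max %||% 0.01
    detect_markers_celltype(data, lfc_min, fdr_max)
  } else {
    lfc_min <- lfc_min %||% 0.5
    fdr_max <- fdr_max %||% 0.05
    detect_markers_cellstate(data, lfc_min, fdr_max)
  }
}

detect_markers_celltype <- function(views, lfc_min, fdr_max) {
  stopifnot(is.list(views), length(views) >= 2)
  for (v in views) assert_that(!is.null(v$logexpr), "views must be normalized first")
  genes <- Reduce(intersect, lapply(views, function(v) colnames(v$logexpr)))
  assert_that(length(genes) > 0, "no genes shared across views")
  mats <- lapply(views, function(v) v$logexpr[, genes, drop = FALSE])
  x <- do.call(rbind, mats)
  lab <- rep(names(views), vapply(mats, nrow, 0L))
  res <- list()
  for (ct in names(views)) {
    in_g <- lab == ct
    if (sum(in_g) < 2 || sum(!in_g) < 2) {
      warning(sprintf("cell type '%s' has <2 replicates; skipped", ct))
      next
    }
    w <- welch_by_column(x, in_g)
    padj <- p.adjust(w$p, method = "BH")
    keep <- w$lfc > lfc_min & padj < fdr_max
    keep[is.na(keep)] <- FALSE
    if (any(keep))
      res[[ct]] <- data.frame(class = ct, cell_type = ct, gene = genes[keep],
                              lfc = w$lfc[keep], p = w$p[keep],
                              padj = padj[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(class = character(0), cell_type = character(0),
               gene = character(0), lfc = numeric(0), p = numeric(0),
               padj = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("marker_table", class(out))
  attr(out, "level") <- "celltype_pseudobulk"
  out
}

detect_markers_cellstate <- function(cells, lfc_min, fdr_max) {
  stopifnot(inherits(cells, "cell_profiles"))
  meta <- cells$cell_meta
  assert_that("cell_state" %in% names(meta), "cell_meta lacks cell_state")
  depth <- rowSums(cells$counts)
  logn <- log1p(sweep(cells$counts, 1, pmax(depth, 1), "/") * 1e4)
  res <- list()
  for (ct in unique(meta$cell_type)) {
    in_ct <- meta$cell_type == ct
    xs <- logn[in_ct, , drop = FALSE]
    states <- meta$cell_state[in_ct]
    for (st in unique(states)) {
      in_st <- states == st
      if (sum(in_st) < 3 || sum(!in_st) < 3) {
        warning(sprintf("state '%s' of '%s' has <3 cells; skipped", st, ct))
        next
      }
      w <- welch_by_column(xs, in_st)
      padj <- p.adjust(w$p, method = "BH")
      keep <- w$lfc >= lfc_min & padj < fdr_max
      keep[is.na(keep)] <- FALSE
      if (any(keep))
        res[[paste(ct, st)]] <- data.frame(
          class = st, cell_type = ct, gene = colnames(xs)[keep],
          lfc = w$lfc[keep], p = w$p[keep], padj = padj[keep],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(class = character(0), cell_type = character(0),
               gene = character(0), lfc = numeric(0), p = numeric(0),
               padj = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("marker_table", class(out))
  attr(out, "level") <- "cellstate_cells"
  out
}

#' Exclude ambient background genes from highly variable gene sets
#'
#' Droplet data carries cell-free mRNA, so highly expressed markers of one
#' cell type leak into every other cell type's pseudobulk profile. For each
#' cell type the highly variable genes that are markers of *any other* cell
#' type are removed, except those that are also markers of the cell type
#' itself.
#'
#' @param hvg_by_type named list of gene-id character vectors.
#' @param markers a `marker_table` at cell-type level.
#' @return named list of cleaned gene sets; removed genes per type in
#'   attribute `removed`.
#' @export
exclude_background <- function(hvg_by_type, markers) {
  stopifnot(is.list(hvg_by_type))
  msets <- split(markers$gene, markers$class)
  removed <- list()
  out <- list()
  for (ct in names(hvg_by_type)) {
    if (!ct %in% names(msets))
      warning(sprintf("no markers recorded for '%s'; treating as empty", ct))
    own <- msets[[ct]] %||% character(0)
    others <- unlist(msets[setdiff(names(msets), ct)], use.names = FALSE)
    bad <- setdiff(others, own)
    out[[ct]] <- setdiff(hvg_by_type[[ct]], bad)
    removed[[ct]] <- intersect(hvg_by_type[[ct]], bad)
  }
  attr(out, "removed") <- removed
  out
}
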