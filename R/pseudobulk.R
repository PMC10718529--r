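#' Annotated single-cell count container
#'
#' Holds a raw UMI count matrix (cells in rows, genes in columns) together
#' with per-cell metadata. Duplicate gene identifiers are summed at
#' construction; gene ids are case-sensitive strings.
#'
#' @param counts non-negative integer matrix, cells x genes, with gene ids
#'   as column names.
#' @param cell_meta data.frame with one row per cell; must contain
#'   `sample_id` and `cell_type`, optionally `cell_state`, `condition`,
#'   `group_id`, `batch`.
#' @return an object of class `cell_profiles`.
#' @export
cell_profiles <- function(counts, cell_meta) {
  counts <- as.matrix(counts)
  assert_that(!is.null(colnames(counts)), "counts must have gene ids as column names")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(max(abs(counts - round(counts))) == 0, "counts must be integers")
  assert_that(nrow(counts) == nrow(cell_meta),
              sprintf("counts has %d cells but cell_meta has %d rows",
                      nrow(counts), nrow(cell_meta)))
  assert_that(all(c("sample_id", "cell_type") %in% names(cell_meta)),
              "cell_meta must contain sample_id and cell_type")
  assert_that(!anyNA(cell_meta$sample_id) && !anyNA(cell_meta$cell_type),
              "sample_id and cell_type must be non-missing for every cell")
  if (anyDuplicated(colnames(counts))) {
    counts <- t(rowsum(t(counts), group = colnames(counts)))
  }
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 gene_ids = colnames(counts),
                 cell_meta = cell_meta),
            class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat(sprintf("cell_profiles: %d cells x %d genes; %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$cell_type))))
  invisible(x)
}

new_pseudobulk_view <- function(cell_type, counts, n_cells, sample_meta) {
  structure(list(cell_type = cell_type,
                 counts = counts,
                 n_cells = n_cells,
                 size_factors = NULL,
                 logexpr = NULL,
                 hvg = NULL,
                 sample_meta = sample_meta),
            class = "pseudobulk_view")
}

#' @export
print.pseudobulk_view <- function(x, ...) {
  cat(sprintf("pseudobulk_view '%s': %d samples x %d genes%s%s\n",
              x$cell_type, nrow(x$counts), ncol(x$counts),
              if (is.null(x$logexpr)) "" else " (normalized)",
              if (is.null(x$hvg)) "" else sprintf(", %d HVGs", length(x$hvg))))
  invisible(x)
}

#' Build per-cell-type pseudobulk expression profiles
#'
#' Sums the UMI counts of all cells of each cell type within each sample.
#' Profiles aggregated from fewer than `min_cells` cells are discarded
#' (they mostly carry ambient signal and unstable library sizes).
#'
#' @param cells a [cell_profiles] object.
#' @param min_cells minimum number of cells per (sample, cell type) profile
#'   (default 25).
#' @param ontology optional named character vector mapping raw cell-type
#'   labels to a harmonized ontology; unknown labels raise an error.
#' @return named list of `pseudobulk_view`, one per cell type. Dropped
#'   profiles are recorded in each view's `dropped` attribute.
#' @export
build_pseudobulk <- function(cells, min_cells = 25, ontology = NULL) {
  stopifnot(inherits(cells, "cell_profiles"), min_cells >= 1)
  meta <- cells$cell_meta
  ctype <- as.character(meta$cell_type)
  if (!is.null(ontology)) {
    unknown <- setdiff(unique(ctype), names(ontology))
    if (length(unknown))
      stop("unknown cell types in ontology map: ", paste(unknown, collapse = ", "))
    ctype <- unname(ontology[ctype])
  }
  samp <- as.character(meta$sample_id)
  key <- paste(ctype, samp, sep = "\r")
  agg <- rowsum(cells$counts, group = key)
  ncell <- as.vector(table(key)[rownames(agg)])
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  agg_type <- vapply(parts, `[`, "", 1L)
  agg_samp <- vapply(parts, `[`, "", 2L)

  meta_cols <- intersect(c("condition", "group_id", "batch"), names(meta))
  smeta <- unique(data.frame(sample_id = samp, meta[meta_cols],
                             stringsAsFactors = FALSE))
  rownames(smeta) <- smeta$sample_id

  out <- list()
  for (ct in sort(unique(agg_type))) {
    sel <- agg_type == ct
    keep <- sel & ncell >= min_cells
    dropped <- data.frame(sample_id = agg_samp[sel & !keep],
                          n_cells = ncell[sel & !keep])
    if (!any(keep)) {
      warning(sprintf("cell type '%s': no profile reaches min_cells=%d; view omitted",
                      ct, min_cells))
      next
    }
    cnt <- agg[keep, , drop = FALSE]
    rownames(cnt) <- agg_samp[keep]
    cnt <- cnt[order(rownames(cnt)), , drop = FALSE]
    v <- new_pseudobulk_view(ct, cnt,
                             setNames(ncell[keep][order(agg_samp[keep])], rownames(cnt)),
                             smeta[rownames(cnt), , drop = FALSE])
    attr(v, "dropped") <- dropped
    out[[ct]] <- v
  }
  out
}

#' Filter lowly expressed genes from a pseudobulk view
#'
#' A gene is kept iff its maximum count across samples is at least
#' `min_count` AND it is detected (count > 0) in at least a `min_detection`
#' fraction of the samples (ties at exactly the fraction are kept).
#'
#' @param view a `pseudobulk_view`.
#' @param min_count minimum count required in at least one sample (default 100).
#' @param min_detection minimum detection fraction across samples (default 0.25).
#' @return the filtered view; discarded gene ids in attribute `discarded`.
#' @export
qc_filter_genes <- function(view, min_count = 100, min_detection = 0.25) {
  stopifnot(inherits(view, "pseudobulk_view"))
  if (nrow(view$counts) < 2) stop("qc_filter_genes needs at least 2 samples")
  maxc <- apply(view$counts, 2, max)
  det <- colMeans(view$counts > 0)
  keep <- maxc >= min_count & det >= min_detection
  out <- view
  out$counts <- view$counts[, keep, drop = FALSE]
  if (!is.null(out$logexpr)) out$logexpr <- out$logexpr[, keep, drop = FALSE]
  attr(out, "discarded") <- colnames(view$counts)[!keep]
  out
}

## Direct implementation of trimmed-mean-of-M-values scaling
## (Robinson & Oshlack): reference column by the 75th-percentile rule,
## 30% two-sided trim on M, 5% on A, inverse delta-method-variance weights.
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample with zero library size")
  f75 <- apply(sweep(counts, 2, libsize, "/"), 2, quantile, probs = 0.75)
  ref <- if (min(f75) == 0) which.max(colSums(sqrt(counts)))
         else which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]; nr <- libsize[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    yj <- counts[, j]; nj <- libsize[j]
    logR <- log2((yj / nj) / (yr / nr))
    absE <- (log2(yj / nj) + log2(yr / nr)) / 2
    v <- (nj - yj) / (nj * yj) + (nr - yr) / (nr * yr)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
            rank(absE) >= loS & rank(absE) <= hiS
    fj <- sum(logR[keep] / v[keep], na.rm = TRUE) /
          sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(fj)) fj <- 0
    2^fj
  }, 0)
  f / geometric_mean(f)
}

#' TMM normalization and log-CPM transform of a pseudobulk view
#'
#' Computes trimmed-mean-of-M-values size factors (rescaled to geometric
#' mean 1) and the log2 counts-per-million matrix
#' `log2(1e6 * y / (libsize * factor) + prior_count)`.
#'
#' @param view a `pseudobulk_view`, ideally after [qc_filter_genes].
#' @param prior_count pseudo-count added inside the log (default 1).
#' @return the view with `size_factors` and `logexpr` filled in.
#' @export
tmm_normalize <- function(view, prior_count = 1) {
  stopifnot(inherits(view, "pseudobulk_view"), prior_count > 0)
  if (nrow(view$counts) < 2) stop("tmm_normalize needs at least 2 samples")
  counts <- t(view$counts)           # genes x samples for the factor code
  f <- tmm_factors(counts)
  libsize <- colSums(counts)
  cpm <- sweep(counts, 2, libsize * f, "/") * 1e6
  out <- view
  out$size_factors <- setNames(f, rownames(view$counts))
  out$logexpr <- t(log2(cpm + prior_count))
  out
}

#' Select highly variable genes from normalized pseudobulk profiles
#'
#' Fits a smooth mean-variance trend to the per-gene variance of `logexpr`
#' (loess with span 0.3, or a quadratic polynomial when fewer than 30
#' genes are available) and selects genes exceeding it.
#'
#' @param view a normalized `pseudobulk_view`.
#' @param method `"normvar"` keeps genes with variance / trend(mean) >
#'   `threshold` (default threshold 1.5); `"biovar"` keeps genes with
#'   variance - trend(mean) > `threshold` (default threshold 0).
#' @param threshold selection threshold; defaults depend on `method`.
#' @return character vector of selected gene ids (also stored in the view
#'   when assigned back by the caller).
#' @export
select_hvg <- function(view, method = c("normvar", "biovar"), threshold = NULL) {
  stopifnot(inherits(view, "pseudobulk_view"))
  assert_that(!is.null(view$logexpr), "run tmm_normalize first")
  method <- match.arg(method)
  if (is.null(threshold)) threshold <- if (method == "normvar") 1.5 else 0
  x <- view$logexpr
  if (nrow(x) < 5)
    warning("fewer than 5 samples; variance estimates are unstable")
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  if (all(v < 1e-12)) {
    warning("all genes constant; empty HVG set")
    return(character(0))
  }
  trend <- fit_variance_trend(mu, v)
  sel <- if (method == "normvar") (v / pmax(trend, 1e-12)) > threshold
         else (v - trend) > threshold
  sel[is.na(sel)] <- FALSE
  colnames(x)[sel]
}

fit_variance_trend <- function(mu, v) {
  if (length(mu) >= 30) {
    fit <- suppressWarnings(loess(v ~ mu, span = 0.3, degree = 2,
                                  control = loess.control(surface = "direct")))
    tr <- predict(fit, mu)
  } else {
    fit <- lm(v ~ mu + I(mu^2))
    tr <- predict(fit, data.frame(mu = mu))
  }
  pmax(tr, 0)
}
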