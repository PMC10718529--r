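#' Project new samples into a reference factor space
#'
#' Concatenates the reference weight matrices across views, restricts
#' them and the new multi-view data to the shared (view, feature) pairs,
#' and computes `Z_new = (W^+ Y)^T` with the Moore-Penrose pseudoinverse
#' `W^+`. When W has full column rank this is the least-squares solution
#' of `min || Y - W Z^T ||`; a rank-deficient W still yields the
#' minimal-norm solution and sets the `rank_deficient` flag.
#'
#' New-cohort data must be processed with the same pipeline and centered
#' within the new study (its own feature means, not the reference's).
#'
#' @param reference_W named list of view weight matrices (features x
#'   factors), e.g. `model$W` of a fitted `gfa_model`.
#' @param new_data a `multiview_dataset` for the new cohort (or a named
#'   list of samples x feature matrices).
#' @return a `projection_result`: `scores` (samples x factors),
#'   `features_used` and `coverage` per view, `rank_deficient`.
#' @export
project_samples <- function(reference_W, new_data) {
  views <- if (inherits(new_data, "multiview_dataset")) new_data$views
           else new_data
  shared <- list()
  cover <- feats <- c()
  for (v in names(reference_W)) {
    ref_feats <- rownames(reference_W[[v]])
    new_feats <- if (v %in% names(views)) colnames(views[[v]]) else character(0)
    sh <- intersect(ref_feats, new_feats)
    cover[v] <- length(sh) / length(ref_feats)
    feats[v] <- length(sh)
    if (length(sh)) shared[[v]] <- sh
    if (cover[v] < 0.5)
      warning(sprintf("view '%s': only %.0f%% of reference features found",
                      v, 100 * cover[v]))
  }
  if (!length(shared)) stop("zero shared features in every view")
  W <- do.call(rbind, lapply(names(shared), function(v)
    reference_W[[v]][shared[[v]], , drop = FALSE]))
  samples <- Reduce(union, lapply(views[names(shared)], rownames))
  Y <- do.call(rbind, lapply(names(shared), function(v) {
    m <- matrix(NA_real_, length(shared[[v]]), length(samples),
                dimnames = list(NULL, samples))
    pres <- intersect(rownames(views[[v]]), samples)
    m[, pres] <- t(views[[v]][pres, shared[[v]], drop = FALSE])
    m
  }))
  ## missing entries contribute nothing: zero-fill after centering
  Y[is.na(Y)] <- 0
  rk <- qr(W)$rank
  Winv <- MASS::ginv(W)
  Z <- t(Winv %*% Y)
  colnames(Z) <- colnames(reference_W[[1]])
  structure(list(scores = Z, features_used = feats, coverage = cover,
                 rank_deficient = rk < ncol(W)),
            class = "projection_result")
}

#' Score factor signatures on a bulk transcriptomics study
#'
#' Within the study, each gene is z-scored across samples (zero-variance
#' genes dropped); signatures are then scored per sample with the
#' permutation-normalized weighted mean. Studies are never pooled before
#' scaling. Signatures with fewer than 10% of their genes measured in
#' the study are skipped with a warning.
#'
#' @param study a `bulk_study` (fields `expr` gene x sample, `condition`,
#'   `study_id`) or a gene x sample matrix.
#' @param sigs a `factor_signature` or named list of them.
#' @param n_perm permutations (default 100).
#' @param seed RNG seed.
#' @return an `enrichment_result` (see [score_wmean]).
#' @export
score_bulk_signatures <- function(study, sigs, n_perm = 100, seed = 1) {
  expr <- if (inherits(study, "bulk_study")) study$expr else as.matrix(study)
  assert_that(!anyDuplicated(rownames(expr)), "duplicate gene ids")
  assert_that(ncol(expr) >= 2, "need at least 2 samples")
  sdv <- apply(expr, 1, sd)
  x <- t(scale(t(expr[sdv > 0, , drop = FALSE])))
  X <- t(x)                                    # samples x genes
  sigl <- as_signature_list(sigs)
  keep <- vapply(sigl, function(w)
    mean(names(w) %in% colnames(X)) >= 0.1, TRUE)
  if (!all(keep))
    warning(sprintf("%d signature(s) with <10%% measured genes skipped",
                    sum(!keep)))
  sigl <- sigl[keep]
  assert_that(length(sigl) > 0, "no signature has enough measured genes")
  score_wmean(X, sigl, n_perm = n_perm, seed = seed)
}

#' Silhouette widths of samples relative to a labeling
#'
#' Standard silhouette on Euclidean distances:
#' `s(i) = (b - a) / max(a, b)` with `a` the mean within-label distance
#' and `b` the smallest mean distance to another label. Samples in
#' singleton labels, and the degenerate case a = b = 0, get width 0.
#'
#' @param X samples x feature matrix.
#' @param labels label per sample (>= 2 distinct).
#' @return numeric vector of widths in [-1, 1], named by sample.
#' @export
silhouette_by_label <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  assert_that(length(unique(labels)) >= 2, "need at least two labels")
  d <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(X)
  s
}

#' Wilcoxon rank-sum comparison of two groups, BH-adjusted in a family
#'
#' Two-sided rank-sum test with tie correction; when `values` is a named
#' list, every element is tested and BH adjustment runs across the list
#' (the family). A constant pooled sample yields p = 1.
#'
#' @param values numeric vector, or named list of numeric vectors.
#' @param labels two-level grouping aligned with each vector.
#' @return data.frame with `name`, `statistic`, `p`, `padj`.
#' @export
compare_groups_wilcoxon <- function(values, labels) {
  if (!is.list(values)) values <- list(value = values)
  if (!is.list(labels)) labels <- rep(list(labels), length(values))
  res <- lapply(seq_along(values), function(i) {
    v <- values[[i]]; l <- as.character(labels[[i]])
    lev <- unique(l)
    assert_that(length(lev) == 2, "labels must have exactly two levels")
    assert_that(min(table(l)) >= 2, "need >= 2 samples per group")
    wt <- rank_sum_test(v[l == lev[1]], v[l == lev[2]])
    data.frame(name = names(values)[i] %||% paste0("v", i),
               statistic = wt$statistic, p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
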