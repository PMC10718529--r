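#' Assemble centered multi-view data for factor analysis
#'
#' Aligns per-cell-type pseudobulk views (restricted to their final gene
#' sets) on the union of sample ids, centers every feature per group and,
#' for multi-group data, scales each feature to unit variance per group.
#' Samples absent from a view are recorded as missing (NA rows), never
#' zero-filled.
#'
#' @param views named list of normalized `pseudobulk_view`s.
#' @param gene_sets optional named list restricting each view to a final
#'   gene set (e.g. the output of [exclude_background]).
#' @param group_id named character vector mapping sample id to group/study;
#'   `NULL` puts all samples in one group `"all"`.
#' @param scale_per_group divide each feature by its per-group standard
#'   deviation; default `TRUE` when there is more than one group. Features
#'   with zero variance within a group are masked (NA) for that group and
#'   flagged.
#' @param extra_views optional structural views from
#'   [make_structural_views]; they are centered (and scaled) like
#'   expression views but keep their own `view_kind`.
#' @return a `multiview_dataset`.
#' @export
assemble_views <- function(views, gene_sets = NULL, group_id = NULL,
                           scale_per_group = NULL, extra_views = NULL) {
  mats <- list()
  kind <- character(0)
  for (ct in names(views)) {
    v <- views[[ct]]
    assert_that(!is.null(v$logexpr), sprintf("view '%s' is not normalized", ct))
    m <- v$logexpr
    if (!is.null(gene_sets)) {
      gs <- intersect(gene_sets[[ct]] %||% colnames(m), colnames(m))
      m <- m[, gs, drop = FALSE]
    }
    if (anyDuplicated(rownames(m)))
      stop(sprintf("duplicated sample_ids within view '%s'", ct))
    mats[[ct]] <- m
    kind[ct] <- "expression"
  }
  if (!is.null(extra_views)) {
    for (nm in names(extra_views$views)) {
      m <- extra_views$views[[nm]]
      if (anyDuplicated(rownames(m)))
        stop(sprintf("duplicated sample_ids within view '%s'", nm))
      mats[[nm]] <- m
      kind[nm] <- extra_views$view_kind[[nm]]
    }
  }
  assert_that(length(mats) > 0, "no views supplied")
  samples <- sort(unique(unlist(lapply(mats, rownames))))
  if (is.null(group_id)) {
    groups <- setNames(rep("all", length(samples)), samples)
  } else {
    assert_that(all(samples %in% names(group_id)),
                "every sample needs a group_id")
    groups <- setNames(as.character(group_id[samples]), samples)
  }
  if (is.null(scale_per_group)) scale_per_group <- length(unique(groups)) > 1

  transform <- list()
  dropped <- list()
  out <- list()
  for (nm in names(mats)) {
    m <- mats[[nm]]
    full <- matrix(NA_real_, length(samples), ncol(m),
                   dimnames = list(samples, colnames(m)))
    full[rownames(m), ] <- m
    tr <- list()
    for (g in unique(groups)) {
      rows <- names(groups)[groups == g]
      obs <- rows[rowSums(!is.na(full[rows, , drop = FALSE])) > 0]
      if (!length(obs)) next
      mu <- colMeans(full[obs, , drop = FALSE])
      full[obs, ] <- sweep(full[obs, , drop = FALSE], 2, mu, "-")
      sdv <- NULL
      if (scale_per_group) {
        sdv <- apply(full[obs, , drop = FALSE], 2, sd)
        zero <- !is.na(sdv) & sdv < 1e-12
        if (any(zero)) {
          dropped[[nm]] <- c(dropped[[nm]],
                             setNames(rep(g, sum(zero)), colnames(full)[zero]))
          full[obs, zero] <- NA_real_
          sdv[zero] <- NA_real_
        }
        full[obs, !zero] <- sweep(full[obs, !zero, drop = FALSE], 2,
                                  sdv[!zero], "/")
      }
      tr[[g]] <- list(center = mu, scale = sdv)
    }
    transform[[nm]] <- tr
    out[[nm]] <- full
  }
  structure(list(views = out,
                 sample_ids = samples,
                 groups = groups,
                 view_kind = kind,
                 transform = transform,
                 dropped_features = dropped,
                 scaled = scale_per_group),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("multiview_dataset: %d samples, %d groups, %d views\n",
              length(x$sample_ids), length(unique(x$groups)),
              length(x$views)))
  for (nm in names(x$views)) {
    miss <- sum(apply(is.na(x$views[[nm]]), 1, all))
    cat(sprintf("  %s [%s]: %d features, %d missing samples\n", nm,
                x$view_kind[[nm]], ncol(x$views[[nm]]), miss))
  }
  invisible(x)
}

#' Centered log-ratio transform of a composition matrix
#'
#' Rows are closed to sum 1; zeros are replaced multiplicatively by half
#' the smallest positive part of the row before re-closure.
#'
#' @param comp samples x parts matrix of non-negative fractions.
#' @return matrix of the same shape whose rows sum to 0.
#' @export
clr_transform <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp < 0)) stop("negative compositions")
  t(apply(comp, 1, function(x) {
    x <- x / sum(x)
    if (any(x == 0)) {
      delta <- 0.5 * min(x[x > 0])
      x[x == 0] <- delta
      x <- x / sum(x)
    }
    log(x) - mean(log(x))
  }))
}

#' Build structural (composition and spatial-dependency) views
#'
#' The composition view is the centered log-ratio transform of per-sample
#' cell-type fractions. Each spatial-dependency context (e.g.
#' colocalization, local or extended neighborhood importances from a
#' spatially contextualized model) becomes one view holding the `top_n`
#' interactions with the highest variance of standardized importances.
#'
#' @param compositions samples x cell-type fraction matrix (rows closed to 1).
#' @param importances optional named list: context -> samples x interaction
#'   matrix of standardized importances, columns named "predictor->target".
#' @param top_n number of interactions kept per context (default 21).
#' @return list with `views` (named matrices) and `view_kind`.
#' @export
make_structural_views <- function(compositions, importances = NULL,
                                  top_n = 21) {
  views <- list(composition = clr_transform(compositions))
  kind <- c(composition = "composition")
  for (ctx in names(importances)) {
    m <- as.matrix(importances[[ctx]])
    if (top_n > ncol(m)) {
      warning(sprintf("context '%s': top_n=%d exceeds %d interactions; using all",
                      ctx, top_n, ncol(m)))
      keep <- seq_len(ncol(m))
    } else {
      keep <- order(apply(m, 2, var), decreasing = TRUE)[seq_len(top_n)]
      keep <- sort(keep)
    }
    views[[ctx]] <- m[, keep, drop = FALSE]
    kind[ctx] <- "spatial_dependency"
  }
  list(views = views, view_kind = kind)
}
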