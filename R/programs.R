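#' Associate factor scores with sample covariates
#'
#' Categorical covariates are tested with tie-corrected Kruskal-Wallis
#' tests (chi-square p, df = levels - 1); continuous covariates with the
#' F-test of a simple linear regression of the score on the covariate.
#' p-values are Benjamini-Hochberg adjusted across factors, separately
#' for each covariate.
#'
#' @param scores samples x factors matrix (rownames = sample ids).
#' @param covariates data.frame of covariates, rownames = sample ids.
#' @param kinds optional named vector with values `"categorical"` or
#'   `"continuous"`; inferred from the column class otherwise.
#' @return an `association_table` data.frame with columns `factor`,
#'   `covariate`, `kind`, `statistic`, `p`, `padj`.
#' @export
associate_factors <- function(scores, covariates, kinds = NULL) {
  scores <- as.matrix(scores)
  assert_that(!is.null(rownames(scores)), "scores needs sample ids as rownames")
  common <- intersect(rownames(scores), rownames(covariates))
  assert_that(length(common) >= 4, "fewer than 4 samples shared")
  scores <- scores[common, , drop = FALSE]
  covariates <- covariates[common, , drop = FALSE]
  res <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    kind <- if (!is.null(kinds) && cv %in% names(kinds)) kinds[[cv]]
            else if (is.numeric(x)) "continuous" else "categorical"
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      warning(sprintf("covariate '%s' is constant; skipped", cv))
      next
    }
    if (kind == "categorical") {
      tab <- table(x[ok])
      if (sum(tab >= 2) < 2) {
        warning(sprintf("covariate '%s' lacks 2 levels with 2 samples; skipped", cv))
        next
      }
    }
    stat <- p <- numeric(ncol(scores))
    for (k in seq_len(ncol(scores))) {
      y <- scores[ok, k]
      if (kind == "categorical") {
        kw <- kruskal.test(y, factor(x[ok]))
        stat[k] <- unname(kw$statistic); p[k] <- kw$p.value
      } else {
        fit <- summary(lm(y ~ x[ok]))
        fs <- fit$fstatistic
        stat[k] <- unname(fs[1])
        p[k] <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
      }
    }
    res[[cv]] <- data.frame(factor = colnames(scores) %||%
                              paste0("Factor", seq_len(ncol(scores))),
                            covariate = cv, kind = kind, statistic = stat,
                            p = p, padj = p.adjust(p, "BH"),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(factor = character(0), covariate = character(0),
               kind = character(0), statistic = numeric(0),
               p = numeric(0), padj = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("association_table", class(out))
  out
}

#' Extract cell-type-specific factor signatures
#'
#' For each expression view, loadings of the chosen factor with absolute
#' value below `threshold` are zeroed; the surviving positive weights form
#' the positive signature and the negative weights the negative signature.
#' The biological reading of the two signs follows the direction of the
#' factor's association with the covariate of interest and is left to the
#' caller.
#'
#' @param model a `gfa_model`.
#' @param factor factor index (or `"FactorK"` name).
#' @param threshold absolute-loading threshold (default 0.1).
#' @return a named list (`"<cell type>.positive"` / `".negative"`) of
#'   `factor_signature` objects: `cell_type`, `factor`, `sign`, `weights`
#'   (named numeric), `threshold`. Empty signatures are omitted.
#' @export
extract_signatures <- function(model, factor, threshold = 0.1) {
  stopifnot(inherits(model, "gfa_model"))
  if (is.character(factor)) factor <- match(factor, colnames(model$W[[1]]))
  if (is.na(factor) || factor < 1 || factor > model$K)
    stop("factor out of range")
  out <- list()
  expr_views <- model$view_names[
    model$view_kind[model$view_names] == "expression"]
  for (v in expr_views) {
    w <- model$W[[v]][, factor]
    w[abs(w) < threshold] <- 0
    for (sg in c("positive", "negative")) {
      ww <- if (sg == "positive") w[w > 0] else w[w < 0]
      if (!length(ww)) next
      out[[paste(v, sg, sep = ".")]] <- structure(
        list(cell_type = v, factor = factor, sign = sg,
             weights = ww, threshold = threshold),
        class = "factor_signature")
    }
  }
  out
}

#' @export
print.factor_signature <- function(x, ...) {
  cat(sprintf("factor_signature: %s, factor %d, %s, %d genes\n",
              x$cell_type, x$factor, x$sign, length(x$weights)))
  invisible(x)
}

#' Permutation-normalized weighted-mean signature scores
#'
#' The raw score of a sample is the weighted mean
#' \eqn{s = \sum_g x_g w_g / \sum_g |w_g|} over the signature genes.
#' The null reassigns the signature's weights (in fixed order) to genes
#' drawn uniformly without replacement from the measured universe; the
#' normalized score is \eqn{z = (s - \mu_{null}) / \sigma_{null}} per
#' sample. A degenerate null (sd 0) yields z = 0 and a flag.
#'
#' @param X samples x genes expression matrix.
#' @param sig a `factor_signature`, a named weight vector, or a named
#'   list of either (scored in order under one seeded stream).
#' @param n_perm number of permutations (default 1000; spatial and bulk
#'   scoring conventionally use 100).
#' @param seed RNG seed.
#' @return an `enrichment_result`: `raw` and `z` (samples x signatures
#'   matrices), `degenerate` logical matrix, `n_perm`, `seed`.
#' @export
score_wmean <- function(X, sig, n_perm = 1000, seed = 1) {
  X <- as.matrix(X)
  assert_that(!is.null(colnames(X)), "X needs gene ids as colnames")
  sigs <- as_signature_list(sig)
  raw <- z <- matrix(NA_real_, nrow(X), length(sigs),
                     dimnames = list(rownames(X), names(sigs)))
  degen <- matrix(FALSE, nrow(X), length(sigs),
                  dimnames = dimnames(raw))
  with_seed(seed, {
    for (j in seq_along(sigs)) {
      w <- sigs[[j]]
      found <- names(w) %in% colnames(X)
      if (!all(found))
        warning(sprintf("signature '%s': %d genes absent from X dropped",
                        names(sigs)[j], sum(!found)))
      w <- w[found]
      if (!length(w)) stop("empty effective signature: ", names(sigs)[j])
      denom <- sum(abs(w))
      raw[, j] <- as.vector(X[, names(w), drop = FALSE] %*% w) / denom
      null <- matrix(NA_real_, nrow(X), n_perm)
      for (p in seq_len(n_perm)) {
        idx <- sample.int(ncol(X), length(w))
        null[, p] <- as.vector(X[, idx, drop = FALSE] %*% w) / denom
      }
      mu <- rowMeans(null)
      sdv <- apply(null, 1, sd)
      zj <- (raw[, j] - mu) / sdv
      bad <- !is.finite(zj)
      zj[bad] <- 0
      degen[, j] <- sdv == 0
      z[, j] <- zj
    }
  })
  structure(list(raw = raw, z = z, degenerate = degen,
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

as_signature_list <- function(sig) {
  if (inherits(sig, "factor_signature"))
    return(setNames(list(sig$weights),
                    paste(sig$cell_type, sig$sign, sep = ".")))
  if (is.numeric(sig)) return(list(signature = sig))
  stopifnot(is.list(sig))
  out <- lapply(sig, function(s)
    if (inherits(s, "factor_signature")) s$weights else s)
  if (is.null(names(out))) names(out) <- paste0("sig", seq_along(out))
  out
}

#' Hypergeometric enrichment of marker sets in signature genes
#'
#' Upper-tail test of the overlap k between signature genes (the draw)
#' and each marker set within the universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n). BH adjustment across
#' marker sets.
#'
#' @param sig_genes character vector of signature genes (subset of
#'   universe).
#' @param marker_sets named list of gene sets (intersected with the
#'   universe).
#' @param universe character vector of all measured genes.
#' @return data.frame with `set`, `overlap`, `set_size`, `p`, `padj`.
#' @export
enrich_hypergeometric <- function(sig_genes, marker_sets, universe) {
  assert_that(length(universe) > 0, "empty universe")
  sig_genes <- intersect(sig_genes, universe)
  n <- length(sig_genes); N <- length(universe)
  res <- lapply(names(marker_sets), function(st) {
    mk <- intersect(marker_sets[[st]], universe)
    k <- length(intersect(sig_genes, mk))
    data.frame(set = st, overlap = k, set_size = length(mk),
               p = phyper(k - 1, length(mk), N - length(mk), n,
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

## vectorized one-way ANOVA per column: eta^2 = SSB/SST, F p-value
eta_squared_by_column <- function(x, g) {
  g <- factor(g)
  n <- nrow(x); k <- nlevels(g)
  gm <- colMeans(x)
  ssb <- rep(0, ncol(x))
  for (lev in levels(g)) {
    rows <- g == lev
    ssb <- ssb + sum(rows) * (colMeans(x[rows, , drop = FALSE]) - gm)^2
  }
  sst <- colSums(sweep(x, 2, gm, "-")^2)
  eta2 <- ifelse(sst > 0, ssb / sst, NA_real_)
  ssw <- sst - ssb
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  p[!is.finite(fstat)] <- ifelse(ssb[!is.finite(fstat)] > 0, 0, 1)
  list(eta2 = eta2, f = fstat, p = p, sst = sst)
}

#' Partition signature-gene variance between condition and cell state
#'
#' For each signature gene, one-way ANOVAs quantify how much expression
#' variance is explained by the sample condition (on sample pseudobulks)
#' versus by the cell state (on per-state pseudobulks); eta-squared is
#' SS_between / SS_total. The log2 ratio r = log2(eta2_condition /
#' eta2_state) measures cell-state independence (r > 0: condition
#' explains more). A one-sample t-test of r against 0 summarizes the
#' cell type, with a Shapiro-Wilk normality check.
#'
#' @param cond_pb list with `expr` (samples x genes) and `label`
#'   (condition per sample).
#' @param state_pb list with `expr` (state-pseudobulk profiles x genes,
#'   profiles from >= 25 cells) and `label` (cell state per profile).
#' @param genes signature genes to analyze.
#' @param alpha BH-adjusted significance level stored per gene (default 0.01).
#' @return a `state_variance_result`: per-gene table (`eta2_condition`,
#'   `eta2_state`, adjusted p per grouping, `log2_ratio`) and a summary
#'   (`t`, `p`, `shapiro_p`, `n_genes`, `n_excluded`).
#' @export
variance_partition_states <- function(cond_pb, state_pb, genes,
                                      alpha = 0.01) {
  for (pb in list(cond_pb, state_pb)) {
    tab <- table(pb$label)
    assert_that(sum(tab >= 2) >= 2,
                "need >= 2 groups with >= 2 profiles each per grouping")
  }
  genes <- Reduce(intersect, list(genes, colnames(cond_pb$expr),
                                  colnames(state_pb$expr)))
  xc <- cond_pb$expr[, genes, drop = FALSE]
  xs <- state_pb$expr[, genes, drop = FALSE]
  ac <- eta_squared_by_column(xc, cond_pb$label)
  as_ <- eta_squared_by_column(xs, state_pb$label)
  keep <- !is.na(ac$eta2) & !is.na(as_$eta2)   # zero-total-variance genes out
  tab <- data.frame(gene = genes,
                    eta2_condition = ac$eta2, p_condition = ac$p,
                    padj_condition = p.adjust(ac$p, "BH"),
                    eta2_state = as_$eta2, p_state = as_$p,
                    padj_state = p.adjust(as_$p, "BH"),
                    stringsAsFactors = FALSE)[keep, ]
  defined <- tab$eta2_condition > 0 & tab$eta2_state > 0
  tab$log2_ratio <- ifelse(defined,
                           log2(tab$eta2_condition / tab$eta2_state),
                           NA_real_)
  r <- tab$log2_ratio[defined]
  summ <- list(n_genes = nrow(tab), n_excluded = sum(!defined),
               alpha = alpha, t = NA_real_, p = NA_real_,
               shapiro_p = NA_real_)
  if (length(r) >= 3) {
    tt <- t.test(r, mu = 0)
    summ$t <- unname(tt$statistic); summ$p <- tt$p.value
    if (length(r) >= 3 && length(unique(r)) > 1)
      summ$shapiro_p <- shapiro.test(r)$p.value
  }
  structure(list(genes = tab, summary = summ),
            class = "state_variance_result")
}

#' Pairwise Jaccard index between gene sets
#'
#' @param sets named list of gene sets.
#' @return symmetric matrix J(A,B) = |A∩B| / |A∪B| with unit diagonal;
#'   NA when both sets are empty.
#' @export
signature_jaccard <- function(sets) {
  n <- length(sets)
  out <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- length(union(sets[[i]], sets[[j]]))
    out[i, j] <- if (u == 0) NA_real_ else
      length(intersect(sets[[i]], sets[[j]])) / u
    if (i == j && u > 0) out[i, j] <- 1
  }
  out
}
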