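#' Spatial slide container
#'
#' @param expr spot x gene log-normalized expression matrix.
#' @param props spot x cell-type proportion matrix (entries in [0, 1]).
#' @param coords spot x 2 coordinate matrix.
#' @param condition slide-level condition label.
#' @param slide_id slide identifier.
#' @return a `spatial_slide`.
#' @export
spatial_slide <- function(expr, props, coords, condition, slide_id) {
  expr <- as.matrix(expr); props <- as.matrix(props)
  coords <- as.matrix(coords)
  assert_that(nrow(expr) == nrow(props) && nrow(expr) == nrow(coords),
              "spots must align across expr/props/coords")
  assert_that(all(props >= 0 & props <= 1), "proportions must be in [0,1]")
  structure(list(slide_id = slide_id, expr = expr, props = props,
                 coords = coords, condition = condition),
            class = "spatial_slide")
}

#' Score factor signatures on the spots of a slide
#'
#' Applies the permutation-normalized weighted mean ([score_wmean], using
#' the slide's own measured gene universe) to every spot, then masks the
#' spots where the signature's cell type falls below `prop_threshold`
#' (score undefined, reported NA — never zero).
#'
#' @param slide a [spatial_slide].
#' @param sigs a `factor_signature` or named list of them.
#' @param prop_threshold minimum cell-type proportion (default 0.1).
#' @param n_perm permutations for the null (default 100).
#' @param seed RNG seed.
#' @return `spot_scores`: `z` (masked spot x signature matrix), `raw`,
#'   `degenerate`, `sig_meta` (cell type and sign per column),
#'   `slide_id`, `condition`.
#' @export
score_spots <- function(slide, sigs, prop_threshold = 0.1, n_perm = 100,
                        seed = 1) {
  stopifnot(inherits(slide, "spatial_slide"))
  if (inherits(sigs, "factor_signature")) sigs <- list(sigs)
  if (is.null(names(sigs)))
    names(sigs) <- vapply(sigs, function(s)
      paste(s$cell_type, s$sign, sep = "."), "")
  for (s in sigs)
    if (!s$cell_type %in% colnames(slide$props))
      stop(sprintf("cell type '%s' absent from slide proportions", s$cell_type))
  res <- score_wmean(slide$expr, sigs, n_perm = n_perm, seed = seed)
  z <- res$z
  meta <- data.frame(signature = names(sigs),
                     cell_type = vapply(sigs, `[[`, "", "cell_type"),
                     sign = vapply(sigs, `[[`, "", "sign"),
                     stringsAsFactors = FALSE)
  for (j in seq_along(sigs))
    z[slide$props[, meta$cell_type[j]] < prop_threshold, j] <- NA_real_
  structure(list(z = z, raw = res$raw, degenerate = res$degenerate,
                 sig_meta = meta, prop_threshold = prop_threshold,
                 slide_id = slide$slide_id, condition = slide$condition,
                 n_perm = n_perm, seed = seed),
            class = "spot_scores")
}

#' Relative activation area of signatures on a slide
#'
#' The effective area of a signature is the number of spots where its
#' cell type is present (proportion >= `prop_threshold`); a spot is
#' active when the normalized score strictly exceeds `score_threshold`
#' (boundary spots at exactly the threshold count as inactive). The
#' relative area is active / effective, undefined (NA) when the
#' effective area is zero.
#'
#' @param scores `spot_scores` from [score_spots].
#' @param props spot x cell-type proportion matrix of the same slide.
#' @param score_threshold activation threshold on z (default 2).
#' @param prop_threshold presence threshold (default 0.1).
#' @return an `area_summary` data.frame: `slide_id`, `condition`,
#'   `signature`, `cell_type`, `sign`, `effective_spots`, `active_spots`,
#'   `relative_area`.
#' @export
relative_activation_area <- function(scores, props, score_threshold = 2,
                                     prop_threshold = 0.1) {
  stopifnot(inherits(scores, "spot_scores"))
  meta <- scores$sig_meta
  out <- lapply(seq_len(nrow(meta)), function(j) {
    present <- props[, meta$cell_type[j]] >= prop_threshold
    eff <- sum(present)
    act <- sum(scores$z[present, j] > score_threshold, na.rm = TRUE)
    data.frame(slide_id = scores$slide_id, condition = scores$condition,
               signature = meta$signature[j], cell_type = meta$cell_type[j],
               sign = meta$sign[j], effective_spots = eff,
               active_spots = act,
               relative_area = if (eff > 0) act / eff else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("area_summary", class(out))
  out
}

#' Compare relative activation areas between slide conditions
#'
#' Two-sided Wilcoxon rank-sum tests (with tie handling) on slide-level
#' relative areas, per (cell type, sign) and condition pair; BH
#' adjustment across (cell type, sign) within each pair.
#'
#' @param areas an `area_summary` (rows over slides), or any data.frame
#'   with `slide_id`, `condition`, `cell_type`, `sign`, `relative_area`.
#' @return data.frame with one row per (cell_type, sign, condition pair):
#'   `statistic`, `p`, `padj`, group sizes.
#' @export
compare_area_by_condition <- function(areas) {
  conds <- unique(areas$condition)
  assert_that(length(conds) >= 2, "need at least two conditions")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  res <- list()
  for (pr in pairs) {
    fam <- list()
    for (key in unique(paste(areas$cell_type, areas$sign, sep = "."))) {
      sub <- areas[paste(areas$cell_type, areas$sign, sep = ".") == key, ]
      a <- sub$relative_area[sub$condition == pr[1]]
      b <- sub$relative_area[sub$condition == pr[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        warning(sprintf("'%s' (%s vs %s): fewer than 2 slides; skipped",
                        key, pr[1], pr[2]))
        next
      }
      wt <- rank_sum_test(a, b)
      fam[[key]] <- data.frame(cell_type = sub$cell_type[1],
                               sign = sub$sign[1],
                               condition_a = pr[1], condition_b = pr[2],
                               n_a = length(a), n_b = length(b),
                               statistic = wt$statistic, p = wt$p.value,
                               stringsAsFactors = FALSE)
    }
    if (length(fam)) {
      fam <- do.call(rbind, fam)
      fam$padj <- p.adjust(fam$p, "BH")
      res[[paste(pr, collapse = "_vs_")]] <- fam
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
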