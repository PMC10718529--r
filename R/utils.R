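#' @importFrom stats cor sd var quantile pt pf pchisq phyper p.adjust
#'   kruskal.test wilcox.test shapiro.test t.test rnorm runif rgamma rlnorm
#'   rmultinom loess loess.control predict lm median dist setNames
#'   complete.cases
#' @importFrom utils head read.csv write.csv read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' All randomized operations in the package route their seed through this
#' helper so the caller's RNG state is never disturbed.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Optimal one-to-one factor matching by absolute correlation
#'
#' Matches each column of `truth` to a distinct column of `fitted` so that
#' the sum of absolute Pearson correlations is maximal (exact assignment by
#' dynamic programming over used-column bitmasks; intended for small factor
#' counts, K <= 12).
#'
#' @param truth numeric matrix, samples x true factors.
#' @param fitted numeric matrix, samples x fitted factors (at least as many
#'   columns as `truth`).
#' @param use complete.cases restriction is applied to rows jointly.
#' @return list with `assignment` (fitted column index per true factor),
#'   `abs_cor` (matched absolute correlations) and `cor_matrix`.
#' @export
match_factors <- function(truth, fitted) {
  truth <- as.matrix(truth); fitted <- as.matrix(fitted)
  stopifnot(nrow(truth) == nrow(fitted), ncol(fitted) >= ncol(truth))
  ok <- complete.cases(truth) & complete.cases(fitted)
  ## collapsed (all-zero) fitted factors have no correlation: score 0
  cm <- suppressWarnings(abs(cor(truth[ok, , drop = FALSE],
                                 fitted[ok, , drop = FALSE])))
  cm[!is.finite(cm)] <- 0
  kt <- ncol(truth); kf <- ncol(fitted)
  if (kf > 20) stop("match_factors: too many fitted factors for exact assignment")
  ## DP over bitmask of used fitted columns
  nmask <- bitwShiftL(1L, kf)
  best <- matrix(-Inf, kt + 1L, nmask)
  choice <- matrix(NA_integer_, kt + 1L, nmask)
  best[1L, 1L] <- 0
  for (i in seq_len(kt)) {
    prev <- which(is.finite(best[i, ])) - 1L
    for (m in prev) {
      for (j in seq_len(kf)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(m, bit) == 0L) {
          nm <- bitwOr(m, bit)
          v <- best[i, m + 1L] + cm[i, j]
          if (v > best[i + 1L, nm + 1L]) {
            best[i + 1L, nm + 1L] <- v
            choice[i + 1L, nm + 1L] <- j
          }
        }
      }
    }
  }
  final <- which.max(best[kt + 1L, ])
  mask <- final - 1L
  assign <- integer(kt)
  for (i in rev(seq_len(kt))) {
    j <- choice[i + 1L, mask + 1L]
    assign[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  list(assignment = assign,
       abs_cor = cm[cbind(seq_len(kt), assign)],
       cor_matrix = cm)
}

#' Principal angles between two column subspaces
#'
#' @param a,b matrices with the same number of rows; angles are computed
#'   between their column spans via orthonormal bases.
#' @return numeric vector of angles in radians, increasing.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

## Rank-sum (Mann-Whitney) two-sided test shared by the spatial and
## transfer modules; exact when base R's wilcox.test would be exact.
rank_sum_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = min(1, wt$p.value))
}

## Vectorized Welch two-sample t-test on columns of a matrix split by a
## logical index; returns lfc (mean in - mean out), t, df, p.
welch_by_column <- function(x, in_group) {
  x1 <- x[in_group, , drop = FALSE]
  x2 <- x[!in_group, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, var); v2 <- apply(x2, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  ## constant-in-both-groups genes: zero variance, undefined t -> lfc decides
  degen <- !is.finite(tstat)
  p[degen] <- ifelse(abs(m1 - m2)[degen] > 0, 0, 1)
  list(lfc = m1 - m2, t = tstat, df = df, p = p)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
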