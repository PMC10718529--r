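test_that("Kruskal-Wallis association matches the hand-computed H", {
  scores <- matrix(c(1, 2, 3, 4), 4, 1,
                   dimnames = list(paste0("s", 1:4), "Factor1"))
  cov <- data.frame(grp = c("a", "a", "b", "b"),
                    row.names = paste0("s", 1:4))
  a <- associate_factors(scores, cov)
  expect_equal(a$statistic, 2.4, tolerance = 1e-12)
  expect_equal(a$kind, "categorical")
})

test_that("rank-based association is invariant to monotone transforms", {
  withr::with_seed(31, {
    scores <- matrix(rnorm(60), 20, 3,
                     dimnames = list(sprintf("s%02d", 1:20),
                                     paste0("Factor", 1:3)))
    cov <- data.frame(grp = rep(c("a", "b"), 10),
                      row.names = rownames(scores))
    a1 <- associate_factors(scores, cov)
    a2 <- associate_factors(exp(scores), cov)
    expect_equal(a1$statistic, a2$statistic, tolerance = 1e-12)
  })
})

test_that("null factor scores give uniform association p-values", {
  withr::with_seed(37, {
    p <- replicate(1000, {
      y <- rnorm(16)
      g <- sample(rep(c("a", "b"), 8))
      kruskal.test(y, factor(g))$p.value
    })
    expect_gt(mean(p < 0.05), 0.03)
    expect_lt(mean(p < 0.05), 0.07)
  })
})

test_that("BH adjustment follows the step-up rule and family boundaries", {
  scores <- matrix(rnorm(80), 20, 4,
                   dimnames = list(sprintf("s%02d", 1:20),
                                   paste0("Factor", 1:4)))
  # direct check of the step-up rule on the documented example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  withr::with_seed(41, {
    cov <- data.frame(grp = rep(c("a", "b"), 10),
                      age = rnorm(20), row.names = rownames(scores))
    a <- associate_factors(scores, cov)
    for (cv in unique(a$covariate)) {
      sub <- a[a$covariate == cv, ]
      expect_equal(sub$padj, p.adjust(sub$p, "BH"))
      expect_true(all(sub$padj >= sub$p))
    }
    expect_equal(unique(a$kind[a$covariate == "age"]), "continuous")
  })
})

test_that("signature extraction thresholds and partitions by sign", {
  m <- list(W = list(CT1 = matrix(c(0.05, 0.5, -0.3), 3, 1,
                                  dimnames = list(c("g1", "g2", "g3"),
                                                  "Factor1"))),
            K = 1L, view_names = "CT1",
            view_kind = c(CT1 = "expression"))
  class(m) <- "gfa_model"
  sigs <- extract_signatures(m, 1, threshold = 0.1)
  expect_equal(sigs$CT1.positive$weights, c(g2 = 0.5))
  expect_equal(sigs$CT1.negative$weights, c(g3 = -0.3))
  # counting: |pos| + |neg| equals weights above threshold
  n_surv <- sum(abs(m$W$CT1[, 1]) >= 0.1)
  expect_equal(length(sigs$CT1.positive$weights) +
                 length(sigs$CT1.negative$weights), n_surv)
  # threshold 0 assigns every nonzero weight to exactly one sign
  s0 <- extract_signatures(m, 1, threshold = 0)
  all_genes <- c(names(s0$CT1.positive$weights), names(s0$CT1.negative$weights))
  expect_setequal(all_genes, c("g1", "g2", "g3"))
  expect_equal(anyDuplicated(all_genes), 0)
  expect_error(extract_signatures(m, 5), "out of range")
})

test_that("weighted-mean scores match the closed form", {
  X <- matrix(c(3, 1), 1, 2, dimnames = list("s1", c("g1", "g2")))
  r <- score_wmean(X, c(g1 = 2, g2 = -1), n_perm = 10, seed = 1)
  expect_equal(unname(r$raw[1, 1]), 5 / 3, tolerance = 1e-12)
  # equal weights reduce to the arithmetic mean
  X2 <- matrix(rnorm(30), 3, 10,
               dimnames = list(paste0("s", 1:3), paste0("g", 1:10)))
  w <- setNames(rep(2, 4), paste0("g", 1:4))
  r2 <- score_wmean(X2, w, n_perm = 10, seed = 1)
  expect_equal(unname(r2$raw[, 1]), unname(rowMeans(X2[, 1:4])),
               tolerance = 1e-12)
})

test_that("normalized scores are invariant to positive weight rescaling", {
  withr::with_seed(43, {
    X <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(sprintf("s%02d", 1:50),
                                sprintf("g%03d", 1:100)))
    w <- setNames(rnorm(20), sprintf("g%03d", 1:20))
    za <- score_wmean(X, w, n_perm = 50, seed = 9)$z
    zb <- score_wmean(X, 7.3 * w, n_perm = 50, seed = 9)$z
    expect_equal(za, zb, tolerance = 1e-12)
  })
})

test_that("degenerate permutation nulls yield flagged zero scores", {
  X <- matrix(0, 2, 30, dimnames = list(c("s1", "s2"), sprintf("g%02d", 1:30)))
  r <- score_wmean(X, setNames(c(1, -2), c("g01", "g02")),
                   n_perm = 20, seed = 3)
  expect_true(all(r$z == 0))
  expect_true(all(r$degenerate))
})

test_that("hypergeometric enrichment equals exact enumeration", {
  # worked case: N=10, K=5, n=4, k=4 -> 5/210
  uni <- paste0("g", 1:10)
  sig <- paste0("g", 1:4)
  res <- enrich_hypergeometric(sig, list(st = paste0("g", 1:5)), uni)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  # zero overlap -> p = 1
  res0 <- enrich_hypergeometric(sig, list(st = paste0("g", 6:8)), uni)
  expect_equal(res0$p, 1)
  # full enumeration oracle for small universes
  withr::with_seed(47, {
    for (rep in 1:5) {
      N <- sample(8:20, 1)
      uni <- paste0("g", seq_len(N))
      mk <- sample(uni, sample(2:(N - 2), 1))
      sig <- sample(uni, sample(2:(N - 2), 1))
      k <- length(intersect(sig, mk))
      draws <- combn(N, length(sig))
      p_enum <- mean(apply(draws, 2, function(ix)
        length(intersect(uni[ix], mk)) >= k))
      p_pkg <- enrich_hypergeometric(sig, list(m = mk), uni)$p
      expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
  })
})

test_that("eta-squared matches hand-computed sums of squares", {
  x <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "g"))
  res <- mcfa:::eta_squared_by_column(x, c("A", "A", "B", "B"))
  expect_equal(unname(res$eta2), 0.8, tolerance = 1e-12)
  # equal group means -> eta2 = 0
  x2 <- matrix(c(1, 3, 2, 2), 4, 1, dimnames = list(NULL, "g"))
  res2 <- mcfa:::eta_squared_by_column(x2, c("A", "A", "B", "B"))
  expect_equal(unname(res2$eta2), 0, tolerance = 1e-12)
  expect_equal(log2(0.8 / 0.2), 2)
})

test_that("variance partition separates condition- from state-driven genes", {
  withr::with_seed(53, {
    genes <- sprintf("g%02d", 1:20)
    cond <- rep(c("a", "b"), each = 6)
    state <- rep(c("s1", "s2"), 8)
    xc <- matrix(rnorm(12 * 20, 0, 0.2), 12, 20,
                 dimnames = list(NULL, genes))
    xs <- matrix(rnorm(16 * 20, 0, 0.2), 16, 20,
                 dimnames = list(NULL, genes))
    xc[cond == "b", 1:10] <- xc[cond == "b", 1:10] + 3  # condition genes
    xs[state == "s2", 11:20] <- xs[state == "s2", 11:20] + 3
    res <- variance_partition_states(list(expr = xc, label = cond),
                                     list(expr = xs, label = state), genes)
    tab <- res$genes
    expect_true(all(tab$eta2_condition >= 0 & tab$eta2_condition <= 1))
    expect_true(all(tab$log2_ratio[match(genes[1:10], tab$gene)] > 0,
                    na.rm = TRUE))
    expect_true(all(tab$log2_ratio[match(genes[11:20], tab$gene)] < 0,
                    na.rm = TRUE))
    expect_true(is.finite(res$summary$t))
  })
})

test_that("Jaccard indices follow the set formula", {
  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"),
               c = c("p", "q"))
  J <- signature_jaccard(sets)
  expect_equal(J["a", "b"], 0.5)
  expect_equal(J["a", "a"], 1)
  expect_equal(J["a", "c"], 0)
  expect_true(isSymmetric(J))
})
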