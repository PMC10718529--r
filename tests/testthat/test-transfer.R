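test_that("projection matches hand and least-squares oracles", {
  # orthonormal columns: third feature annihilated
  W <- list(v = matrix(c(1, 0, 0, 0, 1, 0), 3, 2,
                       dimnames = list(c("f1", "f2", "f3"),
                                       c("Factor1", "Factor2"))))
  Y <- matrix(c(3, 4, 5), 1, 3, dimnames = list("s1", c("f1", "f2", "f3")))
  pr <- project_samples(W, list(v = Y))
  expect_equal(unname(pr$scores[1, ]), c(3, 4), tolerance = 1e-12)
  withr::with_seed(59, {
    # exact span: recovered Z equals truth
    Wb <- matrix(rnorm(200 * 6), 200, 6,
                 dimnames = list(sprintf("f%03d", 1:200),
                                 paste0("Factor", 1:6)))
    Zt <- matrix(rnorm(15 * 6), 15, 6)
    Yb <- Zt %*% t(Wb)
    dimnames(Yb) <- list(sprintf("s%02d", 1:15), rownames(Wb))
    pr2 <- project_samples(list(v = Wb), list(v = Yb))
    expect_lt(max(abs(pr2$scores - Zt)), 1e-8)
    # noisy case: agrees with the normal-equations solution
    Yn <- Yb + matrix(rnorm(length(Yb)), nrow(Yb), ncol(Yb))
    pr3 <- project_samples(list(v = Wb), list(v = Yn))
    ls <- t(solve(crossprod(Wb), t(Yn %*% Wb)))
    expect_lt(max(abs(pr3$scores - ls)), 1e-8)
    expect_false(pr3$rank_deficient)
  })
})

test_that("projection restricts to shared features and reports coverage", {
  withr::with_seed(61, {
    W <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(sprintf("f%02d", 1:60),
                                paste0("Factor", 1:3)))
    Z <- matrix(rnorm(8 * 3), 8, 3)
    Y <- Z %*% t(W)
    dimnames(Y) <- list(sprintf("s%d", 1:8), rownames(W))
    keep <- sample(60, 45)
    expect_warning(
      pr <- project_samples(list(v = W), list(v = Y[, keep])),
      NA)
    expect_equal(unname(pr$coverage["v"]), 45 / 60)
    expect_lt(max(abs(pr$scores - Z)), 1e-6)
    expect_error(
      suppressWarnings(project_samples(
        list(v = W),
        list(v = matrix(0, 2, 2,
                        dimnames = list(c("a", "b"), c("x", "y")))))),
      "zero shared")
  })
})

test_that("projecting the reference reconstruction recovers its scores", {
  sim <- simulate_multiview(n_samples = c(g1 = 30), views = c(v1 = 80, v2 = 60),
                            K_true = 3, noise_sd = 0.2, seed = 67)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 3, max_iter = 200, seed = 1))
  rec <- list(v1 = reconstruct(m, "v1", "g1"), v2 = reconstruct(m, "v2", "g1"))
  for (v in names(rec)) rownames(rec[[v]]) <- rownames(m$Z$g1)
  pr <- project_samples(m$W, rec)
  expect_lt(max(abs(pr$scores - m$Z$g1)), 1e-6)
})

test_that("bulk scoring is invariant to constant genes and gene order", {
  withr::with_seed(71, {
    expr <- matrix(rlnorm(80 * 10, 3, 1), 80, 10,
                   dimnames = list(sprintf("g%02d", 1:80),
                                   sprintf("s%02d", 1:10)))
    sig <- setNames(rnorm(15), sprintf("g%02d", 1:15))
    base <- score_bulk_signatures(expr, sig, n_perm = 40, seed = 3)
    # appending a constant gene changes nothing
    expr2 <- rbind(expr, gX = 5)
    with_const <- score_bulk_signatures(expr2, sig, n_perm = 40, seed = 3)
    expect_equal(base$z, with_const$z)
    # permuting gene rows changes nothing
    expr3 <- expr[sample(nrow(expr)), ]
    perm <- score_bulk_signatures(expr3, sig, n_perm = 40, seed = 3)
    expect_equal(base$raw, perm$raw)
  })
})

test_that("two mirror-image samples score antisymmetrically", {
  withr::with_seed(73, {
    x <- rnorm(40)
    expr <- cbind(s1 = x, s2 = -x) + 10
    rownames(expr) <- sprintf("g%02d", 1:40)
    sig <- setNames(abs(rnorm(10)) + 0.5, sprintf("g%02d", 1:10))
    r <- score_bulk_signatures(expr, sig, n_perm = 30, seed = 5)
    expect_equal(unname(r$raw[1, 1]), -unname(r$raw[2, 1]), tolerance = 1e-10)
  })
})

test_that("bulk scores equal score_wmean on the scaled matrix, bitwise", {
  withr::with_seed(79, {
    expr <- matrix(rlnorm(50 * 8, 3, 1), 50, 8,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:8)))
    sig <- setNames(rnorm(12), sprintf("g%02d", 1:12))
    r1 <- score_bulk_signatures(expr, sig, n_perm = 25, seed = 7)
    scaled <- t(scale(t(expr)))
    r2 <- score_wmean(t(scaled), list(signature = sig), n_perm = 25, seed = 7)
    expect_identical(unname(r1$z), unname(r2$z))
  })
})

test_that("silhouette widths match the hand case and stay in [-1, 1]", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  s <- silhouette_by_label(X, c("A", "A", "B", "B"))
  expect_equal(unname(s[1]), (10.5 - 1) / 10.5, tolerance = 1e-12)
  # identical points: a = b = 0 -> 0 by convention
  s0 <- silhouette_by_label(matrix(1, 4, 2), c("A", "A", "B", "B"))
  expect_true(all(s0 == 0))
  # singletons get 0
  s1 <- silhouette_by_label(matrix(c(0, 5, 9), 3, 1), c("A", "B", "B"))
  expect_equal(unname(s1[1]), 0)
  withr::with_seed(83, {
    for (i in 1:20) {
      X <- matrix(rnorm(30 * 3), 30, 3)
      lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
      if (length(unique(lab)) < 2) next
      s <- silhouette_by_label(X, lab)
      expect_true(all(s >= -1 & s <= 1))
    }
  })
  expect_error(silhouette_by_label(matrix(0, 3, 1), c("A", "A", "A")),
               "two labels")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  withr::with_seed(89, {
    X <- matrix(rnorm(40 * 4), 40, 4)
    lab <- sample(c("a", "b", "c"), 40, replace = TRUE)
    mine <- silhouette_by_label(X, lab)
    ref <- cluster::silhouette(as.integer(factor(lab)), dist(X))[, "sil_width"]
    expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
  })
})

test_that("group comparisons share one rank-sum kernel", {
  v <- c(1, 2, 3, 10, 20, 30)
  l <- rep(c("a", "b"), each = 3)
  r <- compare_groups_wilcoxon(v, l)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  rid <- compare_groups_wilcoxon(c(1, 2, 3, 1, 2, 3), l)
  expect_equal(rid$p, 1)
  # identical to the spatial module's test on the same numbers
  ar <- data.frame(slide_id = paste0("s", 1:6), condition = l,
                   cell_type = "CT1", sign = "positive", relative_area = v)
  expect_equal(compare_area_by_condition(ar)$p, r$p, tolerance = 1e-12)
  # constant pooled values -> p = 1
  expect_equal(compare_groups_wilcoxon(rep(2, 6), l)$p, 1)
})
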