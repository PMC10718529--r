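test_that("ARD isolates a noiseless rank-1 signal in one factor", {
  sim <- simulate_multiview(n_samples = c(g1 = 50), views = c(v1 = 100),
                            K_true = 1, noise_sd = 0, seed = 3)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 2, max_iter = 300, seed = 1))
  ft <- sort(m$r2$factor_total, decreasing = TRUE)
  expect_gt(ft[1], 0.999)
  expect_lt(ft[2], 0.001)
  expect_gt(m$r2$overall_total, 0.999)
})

test_that("identical seed and data give identical ELBO traces", {
  sim <- simulate_multiview(n_samples = c(g1 = 20), views = c(v1 = 30),
                            K_true = 2, noise_sd = 0.4, seed = 5)
  m1 <- fit_gfa(sim$data, gfa_hyperparams(K = 3, max_iter = 40, seed = 7))
  m2 <- fit_gfa(sim$data, gfa_hyperparams(K = 3, max_iter = 40, seed = 7))
  expect_identical(m1$elbo_trace, m2$elbo_trace)
  expect_identical(m1$W, m2$W)
})

test_that("two identical groups recover matching score matrices", {
  base <- simulate_multiview(n_samples = c(g1 = 30), views = c(v1 = 80, v2 = 60),
                             K_true = 2, noise_sd = 0.2, seed = 11)
  # duplicate the group: same observations under two group labels
  v <- lapply(base$data$views, function(m) {
    m2 <- rbind(m, m)
    rownames(m2) <- c(paste0("a_", rownames(m)), paste0("b_", rownames(m)))
    m2
  })
  groups <- setNames(rep(c("a", "b"), each = 30), rownames(v[[1]]))
  tr <- lapply(base$data$transform, function(x)
    list(a = x$g1, b = x$g1))
  ds <- structure(list(views = v, sample_ids = rownames(v[[1]]),
                       groups = groups,
                       view_kind = base$data$view_kind,
                       transform = tr, dropped_features = list(),
                       scaled = FALSE), class = "multiview_dataset")
  m <- fit_gfa(ds, gfa_hyperparams(K = 3, max_iter = 400, seed = 2))
  active <- which(m$r2$factor_total > 0.005)
  expect_length(active, 2)          # ARD prunes the surplus factor
  mt <- match_factors(m$Z$a[, active], m$Z$b[, active])
  expect_true(all(mt$abs_cor >= 0.99))
})

test_that("explained variance matches a brute-force residual oracle", {
  sim <- simulate_multiview(n_samples = c(g1 = 15, g2 = 12),
                            views = c(v1 = 20, v2 = 25), K_true = 2,
                            noise_sd = 0.5, missing_frac = 0.2, seed = 13)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 3, max_iter = 30, seed = 1))
  r2 <- m$r2
  for (v in c("v1", "v2")) for (g in c("g1", "g2")) {
    rows <- names(sim$data$groups)[sim$data$groups == g]
    y <- sim$data$views[[v]][rows, ]
    ob <- !is.na(y)
    for (k in 1:3) {
      rec <- m$Z[[g]][, k] %o% m$W[[v]][, k]
      oracle <- 1 - sum((y - rec)[ob]^2) / sum(y[ob]^2)
      expect_equal(unname(r2$per_factor[v, g, k]), oracle, tolerance = 1e-10)
    }
    full <- m$Z[[g]] %*% t(m$W[[v]])
    expect_equal(unname(r2$total[v, g]),
                 1 - sum((y - full)[ob]^2) / sum(y[ob]^2),
                 tolerance = 1e-10)
  }
  # a factor with all-zero weights explains nothing
  m0 <- m; m0$W$v1[, 2] <- 0
  ev <- explained_variance(m0, sim$data)
  expect_equal(unname(ev$per_factor["v1", "g1", 2]), 0, tolerance = 1e-12)
})

test_that("postprocessing sorts, sign-fixes and preserves the fit", {
  sim <- simulate_multiview(n_samples = c(g1 = 25), views = c(v1 = 40, v2 = 30),
                            K_true = 3, noise_sd = 0.3, seed = 17)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 4, max_iter = 150, seed = 4))
  pp <- postprocess_factors(m)
  expect_true(all(diff(pp$r2$factor_total) <= 1e-12))
  # reconstruction invariant under reordering + sign flips
  for (v in c("v1", "v2")) {
    expect_lt(max(abs(reconstruct(m, v, "g1") - reconstruct(pp, v, "g1"))),
              1e-10)
  }
  # sign convention: positive cubed-weight sum in the top view
  for (k in seq_len(pp$K)) {
    vtot <- apply(pp$r2$per_factor[, , k, drop = FALSE], 1, sum, na.rm = TRUE)
    expect_gte(sum(pp$W[[names(which.max(vtot))]][, k]^3), 0)
  }
  expect_identical(postprocess_factors(pp), postprocess_factors(pp))
  pp2 <- postprocess_factors(pp)
  expect_equal(pp2$W, pp$W)
})

test_that("reconstruct equals the factor-by-factor accumulation", {
  sim <- simulate_multiview(n_samples = c(g1 = 10), views = c(v1 = 15),
                            K_true = 2, noise_sd = 0.2, seed = 19)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 2, max_iter = 20, seed = 1))
  acc <- matrix(0, 10, 15)
  for (k in 1:2) acc <- acc + m$Z$g1[, k] %o% m$W$v1[, k]
  expect_lt(max(abs(reconstruct(m, "v1", "g1") - acc)), 1e-12)
  mz <- m; mz$W$v1[] <- 0
  expect_true(all(reconstruct(mz, "v1", "g1") == 0))
  expect_error(reconstruct(m, "nope", "g1"), "unknown view")
  expect_error(reconstruct(m, "v1", "nope"), "unknown group")
})

test_that("flat-prior single-view fit spans the principal subspace", {
  sim <- simulate_multiview(n_samples = c(g1 = 60), views = c(v1 = 80),
                            K_true = 3, noise_sd = 0.1, seed = 23)
  m <- fit_gfa(sim$data, gfa_hyperparams(K = 3, max_iter = 500, seed = 2))
  y <- sim$data$views$v1
  sv <- svd(y)
  ang <- principal_angles(m$W$v1, sv$v[, 1:3])
  expect_lt(max(ang), 0.05)
})

test_that("uncentered data is rejected with a pointer to assemble_views", {
  sim <- simulate_multiview(n_samples = c(g1 = 10), views = c(v1 = 12),
                            K_true = 1, noise_sd = 0.1, seed = 29)
  sim$data$views$v1[, 1] <- sim$data$views$v1[, 1] + 1
  expect_error(fit_gfa(sim$data, gfa_hyperparams(K = 1, max_iter = 5)),
               "assemble_views")
})
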