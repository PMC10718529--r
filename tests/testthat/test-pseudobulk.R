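test_that("pseudobulk profiles are exact per-(sample, type) count sums", {
  pb <- build_pseudobulk(tiny_cells(), min_cells = 1)
  expect_equal(unname(pb$T$counts["S", ]), c(4, 6, 1))
  expect_equal(unname(pb$U$counts["S", ]), c(5, 1, 3))
  expect_equal(unname(pb$T$n_cells), c(2, 2))

  # brute-force group-by-sum oracle on simulated data
  sim <- simulate_single_cell(n_samples_per_condition = 2, n_cells = 20,
                              seed = 1)
  pb2 <- build_pseudobulk(sim$cells, min_cells = 1)
  meta <- sim$cells$cell_meta
  for (ct in names(pb2)) {
    for (s in rownames(pb2[[ct]]$counts)) {
      rows <- meta$cell_type == ct & meta$sample_id == s
      expect_equal(unname(pb2[[ct]]$counts[s, ]),
                   unname(colSums(sim$cells$counts[rows, , drop = FALSE])))
    }
  }
  # count conservation: retained + dropped cells account for every count
  total <- sum(sim$cells$counts)
  expect_equal(sum(vapply(pb2, function(v) sum(v$counts), 0)), total)
})

test_that("profiles below min_cells are discarded", {
  pb <- suppressWarnings(build_pseudobulk(tiny_cells(), min_cells = 3))
  expect_null(pb$T)  # all T profiles have 2 cells
  counts <- matrix(1L, 24, 2, dimnames = list(NULL, c("g1", "g2")))
  meta <- data.frame(sample_id = "S", cell_type = "T")[rep(1, 24), ]
  expect_warning(pb <- build_pseudobulk(cell_profiles(counts, meta),
                                        min_cells = 25), "omitted")
  expect_length(pb, 0)
})

test_that("duplicate gene ids are summed at load", {
  counts <- matrix(c(3, 4), 1, 2, dimnames = list(NULL, c("gX", "gX")))
  cp <- cell_profiles(counts, data.frame(sample_id = "S", cell_type = "T"))
  expect_equal(unname(cp$counts[1, "gX"]), 7)
})

test_that("gene QC applies the max-count and detection rules", {
  mk <- function(x) mcfa:::new_pseudobulk_view(
    "T", matrix(x, 4, 1, dimnames = list(paste0("s", 1:4), "g")),
    setNames(rep(30L, 4), paste0("s", 1:4)),
    data.frame(sample_id = paste0("s", 1:4)))
  expect_equal(ncol(qc_filter_genes(mk(c(99, 50, 10, 0)))$counts), 0)
  # boundary: max >= 100 and detection exactly 25% is kept
  expect_equal(ncol(qc_filter_genes(mk(c(120, 0, 0, 0)))$counts), 1)
  expect_equal(ncol(qc_filter_genes(mk(c(0, 0, 0, 0)))$counts), 0)
  one <- mcfa:::new_pseudobulk_view(
    "T", matrix(500, 1, 1, dimnames = list("s1", "g")),
    c(s1 = 30L), data.frame(sample_id = "s1"))
  expect_error(qc_filter_genes(one), "2 samples")
})

test_that("gene QC is idempotent", {
  v <- mcfa:::new_pseudobulk_view(
    "T", random_counts(80, 6, seed = 4),
    setNames(rep(50L, 6), sprintf("s%d", 1:6)),
    data.frame(sample_id = sprintf("s%d", 1:6)))
  once <- qc_filter_genes(v)
  twice <- qc_filter_genes(once)
  expect_identical(once$counts, twice$counts)
})

test_that("TMM factors are 1 for identical and depth-scaled libraries", {
  x <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(mcfa:::tmm_factors(x), rep(1, 3))
  y <- cbind(c(10, 20, 30, 40), 2 * c(10, 20, 30, 40))
  expect_equal(mcfa:::tmm_factors(y), rep(1, 2))
})

test_that("TMM matches the edgeR implementation to 1e-10", {
  skip_if_not_installed("edgeR")
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- matrix(rpois(50 * 4, rgamma(50, 2, 0.02)), 50, 4)
      mine <- mcfa:::tmm_factors(x)
      ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = x))$samples$norm.factors
      expect_lt(max(abs(mine - ref)), 1e-10)
    }
  })
})

test_that("TMM size factors have geometric mean 1 and log-CPM is correct", {
  v <- mcfa:::new_pseudobulk_view(
    "T", random_counts(60, 5, seed = 7),
    setNames(rep(50L, 5), sprintf("s%d", 1:5)),
    data.frame(sample_id = sprintf("s%d", 1:5)))
  nv <- tmm_normalize(v)
  expect_lt(abs(exp(mean(log(nv$size_factors))) - 1), 1e-9)
  libsize <- rowSums(v$counts)
  expected <- log2(1e6 * v$counts[2, 5] /
                     (libsize[2] * nv$size_factors[2]) + 1)
  expect_equal(unname(nv$logexpr[2, 5]), unname(expected))
  zero <- v; zero$counts[1, ] <- 0L
  expect_error(tmm_normalize(zero), "zero library")
})

test_that("HVG selection recovers planted high-dispersion genes", {
  withr::with_seed(3, {
    n_g <- 500; n_s <- 40
    mu <- runif(n_g, 2, 10)
    x <- matrix(rnorm(n_s * n_g, rep(mu, each = n_s), 0.3), n_s, n_g)
    planted <- sample(n_g, 20)
    x[, planted] <- matrix(rnorm(n_s * 20, rep(mu[planted], each = n_s), 2),
                           n_s, 20)
    colnames(x) <- sprintf("g%03d", seq_len(n_g))
    rownames(x) <- sprintf("s%02d", seq_len(n_s))
    v <- mcfa:::new_pseudobulk_view("T", round(2^x),
                                    setNames(rep(50L, n_s), rownames(x)),
                                    data.frame(sample_id = rownames(x)))
    v$logexpr <- x
    hits <- select_hvg(v, method = "biovar", threshold = 0)
    expect_gte(sum(colnames(x)[planted] %in% hits), 18)
  })
})

test_that("HVG selection is empty for flat data and infinite thresholds", {
  x <- matrix(rnorm(200, 5, 1), 20, 10,
              dimnames = list(sprintf("s%d", 1:20), sprintf("g%d", 1:10)))
  v <- mcfa:::new_pseudobulk_view("T", round(2^x),
                                  setNames(rep(50L, 20), rownames(x)),
                                  data.frame(sample_id = rownames(x)))
  v$logexpr <- x
  expect_length(select_hvg(v, "normvar", threshold = Inf), 0)
  vc <- v; vc$logexpr <- matrix(5, 20, 10, dimnames = dimnames(x))
  expect_warning(res <- select_hvg(vc, "biovar"), "constant")
  expect_length(res, 0)
})
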