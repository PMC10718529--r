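# Small fixtures shared across test files; everything is built in code.

# Two-type, two-sample count matrix with hand-checkable sums.
tiny_cells <- function() {
  counts <- rbind(
    c(1, 2, 0), c(3, 4, 1),          # type T, sample S
    c(5, 0, 2), c(0, 1, 1),          # type U, sample S
    c(2, 2, 2), c(1, 1, 1))          # type T, sample S2
  colnames(counts) <- c("gA", "gB", "gC")
  meta <- data.frame(
    sample_id = c("S", "S", "S", "S", "S2", "S2"),
    cell_type = c("T", "T", "U", "U", "T", "T"),
    condition = "ctrl")
  cell_profiles(counts, meta)
}

# Normalized pseudobulk view wrapper around a raw count matrix.
as_norm_view <- function(counts, cell_type = "T") {
  v <- mcfa:::new_pseudobulk_view(
    cell_type, counts,
    setNames(rep(100L, nrow(counts)), rownames(counts)),
    data.frame(sample_id = rownames(counts), row.names = rownames(counts)))
  tmm_normalize(v)
}

random_counts <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    mu <- rgamma(n_genes, 2, 0.02)
    matrix(rpois(n_genes * n_samples, mu), n_samples, n_genes,
           byrow = TRUE,
           dimnames = list(sprintf("s%d", seq_len(n_samples)),
                           sprintf("g%03d", seq_len(n_genes))))
  })
}

make_signature <- function(weights, cell_type = "CT1", sign = "positive",
                           factor = 1L) {
  structure(list(cell_type = cell_type, factor = factor, sign = sign,
                 weights = weights, threshold = 0.1),
            class = "factor_signature")
}
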