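# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's computation paths: naive matrix DP for local alignment,
# grid search for pI, transitive closure for single-linkage.

# Naive quadratic-space affine-gap Smith-Waterman (R matrices, no
# traceback). Gap of length k costs open + k * ext, as documented.
naive_sw_score <- function(a, b, sub = blosum62(), open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B); NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# Exhaustive 0.001-pH-step grid-search pI oracle.
grid_pi <- function(seq, pka_table = "EMBOSS") {
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(charge_at_ph(seq, grid, pka_table)))]
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet(), len, replace = TRUE), collapse = ""), "")
}

# Minimal feature-table constructor for pairing tests.
feat <- function(gene_id, start, end, strand, contig = "chr1",
                 protein = "ACDEFGHIKLMNPQRSTVWY") {
  data.frame(gene_id = gene_id, contig = contig, start = start, end = end,
             strand = strand, protein = protein, stringsAsFactors = FALSE)
}

asg <- function(gene_id, family, role) {
  data.frame(gene_id = gene_id, family = family, role = role,
             stringsAsFactors = FALSE)
}

demo_refs <- function() read_ta_references(demo_reference_path())

demo_clusters <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cluster_references(demo_refs())
    cache
  }
})

# Pair-recovery metrics of a screen against a simulation's ground truth.
screen_metrics <- function(sim, clusters) {
  sc <- tascreen:::screen_features(sim$features, clusters)
  called <- paste(sc$pairs$toxin, sc$pairs$antitoxin)
  truth <- paste(sim$truth$pairs$toxin, sim$truth$pairs$antitoxin)
  list(recall = if (length(truth)) mean(truth %in% called) else NA_real_,
       precision = if (length(called)) mean(called %in% truth)
                   else NA_real_,
       n_called = length(called), pairs = sc$pairs,
       assignments = sc$assignments)
}
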