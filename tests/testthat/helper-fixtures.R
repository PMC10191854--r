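# Shared fixtures: small simulation configs and an independent generator of
# conflict-free genotype matrices with a known shared-mutation structure.

small_config <- function(...) {
  args <- list(n_clones = 8, ageing_mut_mean = 300, late_gens_per_branch = 8,
               n_sources = 12, panel_size = 40)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# Generates a random conflict-free binary genotype matrix by building a
# random rooted tree bottom-up (agglomerative random merges) and dropping
# mutations on its branches. Independent of the package's simulator and
# reconstruction code; returns the matrix plus the truth needed for the
# shared-mutation oracle.
random_perfect_matrix <- function(m_samples, n_mut = 60) {
  samples <- LETTERS[seq_len(m_samples)]
  clusters <- as.list(samples)
  subsets <- as.list(samples)
  while (length(clusters) > 1L) {
    pick <- sample.int(length(clusters), 2)
    merged <- sort(unlist(clusters[pick]))
    clusters <- c(clusters[-pick], list(merged))
    if (length(merged) < m_samples) subsets <- c(subsets, list(merged))
  }
  rows <- lapply(seq_len(n_mut), function(i) {
    carry <- subsets[[sample.int(length(subsets), 1)]]
    as.integer(samples %in% carry)
  })
  M <- do.call(rbind, rows)
  colnames(M) <- samples
  M
}

key_samples_for_test <- function(key) strsplit(key, "+", fixed = TRUE)[[1]]

# Independent oracle: in a perfect phylogeny the molecular time of the MRCA
# of samples i and j equals the number of mutations carried by both.
shared_mutation_matrix <- function(M) {
  m <- ncol(M)
  out <- matrix(NA_real_, m, m, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) out[i, j] <- sum(M[, i] == 1 & M[, j] == 1)
  }
  out
}
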