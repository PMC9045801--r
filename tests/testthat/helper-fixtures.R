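# In-code fixtures shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# wide count tibble from a taxa-by-samples matrix given as rows
toy_counts <- function(..., taxa = NULL, samples = NULL) {
  m <- rbind(...)
  rownames(m) <- taxa %||% paste0("t", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  counts_tibble(m)
}

# minimal metadata for a vector of sample ids
toy_metadata <- function(sample_id,
                         tree = rep("beech", length(sample_id)),
                         canopy = rep("closed", length(sample_id)),
                         year = rep(1L, length(sample_id))) {
  tibble::tibble(sample_id = sample_id, tree = tree, canopy = canopy,
                 block = 1L, plot = "p", mixture = FALSE,
                 year = as.integer(year))
}

# a small simulated dataset reused by several files
small_simulation <- function(seed = 42, n_taxa = 40, depth = 1000) {
  design <- generate_design(2, 3)
  taxa <- generate_taxa(n_taxa, seed = seed)
  sim <- generate_community_counts(design, taxa, depth = depth, seed = seed)
  list(design = design, taxa = taxa, counts = sim$counts)
}
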