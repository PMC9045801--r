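# Shared helpers: wide count tibbles <-> matrices, seed splitting, validation.

#' Convert a wide count/abundance tibble to a taxa-by-sample matrix
#'
#' Count and abundance tables travel through the package as wide tibbles with
#' an `otu_id` first column and one column per sample. This helper extracts
#' the numeric matrix with taxa as rownames.
#'
#' @param tbl A data frame with an `otu_id` column and numeric sample columns.
#' @return A numeric matrix (taxa x samples) with dimnames.
#' @export
counts_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (!"otu_id" %in% names(tbl)) {
    abort("count table must have an `otu_id` column")
  }
  ids <- as.character(tbl$otu_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "otu_id")])
  if (anyDuplicated(colnames(m))) {
    abort("duplicate sample ids in count table")
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a taxa-by-sample matrix back to a wide tibble
#'
#' @param m A numeric matrix with taxon rownames and sample colnames.
#' @return A tibble with `otu_id` plus one column per sample.
#' @export
counts_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "otu_id")
}

# Derive a per-operation RNG seed from a master seed so modules can be
# re-run independently; kept below 2^31 - 1.
split_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 1009L
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_proportion <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1]", name))
  }
  as.numeric(x)
}

# p-value convention for all permutation tests: the observed statistic counts
# as one of the permutations, so p >= 1/(n_perm + 1) always.
perm_pvalue <- function(perm_stats, observed) {
  (sum(perm_stats >= observed - 1e-12) + 1) / (length(perm_stats) + 1)
}
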