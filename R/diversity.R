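# Per-sample diversity estimates on rarefied counts.

#' Diversity indices for one count vector
#'
#' Computes OTU richness S (number of taxa with positive counts), the
#' bias-corrected Chao1 richness estimate
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} (F1 = singletons, F2 =
#' doubletons), the Shannon-Wiener index \eqn{H = -\sum p \ln p} in nats,
#' and Pielou evenness \eqn{J = H / \ln S} (defined as 1 when S = 1).
#' The classic (uncorrected) Chao1 \eqn{S + F_1^2 / (2 F_2)} is available
#' via `chao1_bias_corrected = FALSE`; it is undefined (NaN) when F2 = 0
#' and F1 > 0.
#'
#' @param x Vector of non-negative integer counts, at least one positive.
#' @param chao1_bias_corrected Use the bias-corrected Chao1 form (default).
#' @return A one-row tibble with `richness`, `chao1`, `shannon`, `evenness`.
#' @examples
#' diversity_indices(rep(200, 10))  # S = 10, H = ln 10, J = 1, Chao1 = 10
#' @export
diversity_indices <- function(x, chao1_bias_corrected = TRUE) {
  if (any(x < 0) || any(x != floor(x))) {
    abort("counts must be non-negative integers")
  }
  if (sum(x) <= 0) abort("all-zero count vector")
  pos <- x[x > 0]
  s <- length(pos)
  p <- pos / sum(pos)
  h <- -sum(p * log(p))
  j <- if (s == 1) 1 else h / log(s)
  f1 <- sum(pos == 1)
  f2 <- sum(pos == 2)
  chao1 <- if (chao1_bias_corrected) {
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 == 0) {
    s
  } else {
    s + f1^2 / (2 * f2)
  }
  tibble::tibble(richness = s, chao1 = chao1, shannon = h, evenness = j)
}

#' Diversity table for every sample of a count table
#'
#' @param counts Wide count tibble, typically rarefied to common depth.
#' @inheritParams diversity_indices
#' @return A tibble with one row per sample: `sample_id`, `richness`,
#'   `chao1`, `shannon`, `evenness`.
#' @export
diversity_table <- function(counts, chao1_bias_corrected = TRUE) {
  m <- counts_matrix(counts)
  purrr::map_dfr(colnames(m), function(s) {
    dplyr::bind_cols(tibble::tibble(sample_id = s),
                     diversity_indices(m[, s], chao1_bias_corrected))
  })
}
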