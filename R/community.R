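# Dirichlet-multinomial community counts from design + taxon archetypes.

#' Generate OTU count tables with recoverable ground truth
#'
#' Builds the expected relative abundance of every taxon in every sample from
#' the taxon archetypes, perturbs each sample's composition with a Dirichlet
#' draw, and draws multinomial read counts at a fixed sequencing depth.
#'
#' The expected (unnormalised) abundance of taxon *t* in sample *s* is
#' \deqn{base_t \cdot w_{tree} \cdot w_{canopy} \cdot
#'       \exp(-(year_s - \mu_t)^2 / (2 \sigma_t^2))}
#' where \eqn{w_{tree} = \pi_{tree}} for beech samples and
#' \eqn{1 - \pi_{tree}} for fir samples, and analogously
#' \eqn{w_{canopy} = \pi_{canopy}} for closed-canopy samples. A hard
#' specialist (\eqn{\pi_{tree} = 1}) therefore never produces reads on the
#' other tree species.
#'
#' Overdispersion enters through the Dirichlet concentration: each sample's
#' composition is drawn from Dirichlet(expected proportions / overdispersion),
#' so the total concentration is 1/overdispersion and smaller values give
#' compositions closer to their expectation.
#'
#' @param design Sample metadata tibble from [generate_design()].
#' @param taxa Taxon archetypes from [generate_taxa()].
#' @param depth Reads per sample; every column of the output sums to this.
#' @param overdispersion Positive Dirichlet overdispersion (default 0.05).
#' @param seed Integer seed.
#' @return A list with `counts` (wide tibble: `otu_id` + one integer column
#'   per sample) and `truth` (the archetype tibble, the recoverable truth).
#' @examples
#' d <- generate_design(1, 2)
#' tx <- generate_taxa(20, seed = 3)
#' out <- generate_community_counts(d, tx, depth = 500, seed = 3)
#' all(colSums(counts_matrix(out$counts)) == 500)
#' @export
generate_community_counts <- function(design, taxa, depth = 2000,
                                      overdispersion = 0.05, seed = 1) {
  depth <- check_count(depth, "depth")
  if (!is.data.frame(taxa) || nrow(taxa) == 0) {
    abort("`taxa` must be a non-empty archetype table")
  }
  if (!is.data.frame(design) || nrow(design) == 0) {
    abort("`design` must be a non-empty sample metadata table")
  }
  if (length(overdispersion) != 1 || overdispersion <= 0) {
    abort("`overdispersion` must be a single positive number")
  }

  # expected abundance matrix: taxa x samples
  expected <- vapply(seq_len(nrow(design)), function(s) {
    wt <- if (design$tree[s] == "beech") taxa$pi_tree else 1 - taxa$pi_tree
    wc <- if (design$canopy[s] == "closed") taxa$pi_canopy else 1 - taxa$pi_canopy
    taxa$base * wt * wc *
      exp(-(design$year[s] - taxa$mu)^2 / (2 * taxa$sigma^2))
  }, numeric(nrow(taxa)))
  dimnames(expected) <- list(taxa$taxon_id, design$sample_id)

  zero_cols <- colSums(expected) <= 0
  if (any(zero_cols)) {
    abort(paste0("all-zero expected composition for sample(s): ",
                 paste(design$sample_id[zero_cols], collapse = ", ")))
  }

  counts <- withr::with_seed(split_seed(seed, 3L), {
    apply_cols <- vapply(seq_len(ncol(expected)), function(s) {
      p <- expected[, s] / sum(expected[, s])
      conc <- p / overdispersion
      # Dirichlet draw via independent gammas; conc = 0 stays exactly 0
      g <- numeric(length(conc))
      pos <- conc > 0
      g[pos] <- rgamma(sum(pos), shape = conc[pos], rate = 1)
      if (sum(g) <= 0) g[pos] <- p[pos] # degenerate gamma underflow guard
      drop(rmultinom(1, size = depth, prob = g / sum(g)))
    }, numeric(nrow(expected)))
    dimnames(apply_cols) <- dimnames(expected)
    apply_cols
  })

  list(counts = counts_tibble(counts), truth = taxa)
}
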