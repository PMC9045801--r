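# Taxon archetypes: the generator's per-taxon ground truth.

GUILD_LEVELS <- c("white_rot", "brown_rot", "soft_rot", "saprotroph",
                  "plant_pathogen", "ectomycorrhiza", "yeast", "endophyte",
                  "lichen", "unclassified", "other")

#' Generate taxon archetypes with known affinities and temporal niches
#'
#' Each simulated taxon carries the ground truth the downstream estimators
#' try to recover: a tree affinity `pi_tree` (1 = occurs on beech only,
#' 0 = fir only), a canopy affinity `pi_canopy` (1 = closed canopy only),
#' a temporal occupancy window (Gaussian peak `mu` in years, width `sigma`),
#' a base relative-abundance scale and an ecological guild.
#'
#' A fraction `specialist_fraction` of taxa are hard specialists
#' (`pi_tree` drawn from \{0, 1\} with equal probability, independently for
#' canopy); the rest draw affinities from a Beta distribution with shape
#' `affinity_shape`, so `affinity_shape = c(2, 2)` gives symmetric
#' generalists centred on 0.5.
#'
#' @param n_taxa Number of taxa (>= 0).
#' @param specialist_fraction Proportion of hard specialists in \[0, 1\].
#' @param affinity_shape Length-2 positive shape of the generalist Beta law.
#' @param temporal_range Length-2 year interval for the uniform draw of `mu`.
#' @param sigma_range Length-2 positive interval for the uniform draw of the
#'   temporal width `sigma` (years).
#' @param seed Integer seed; output is reproducible given all arguments.
#' @return A tibble with columns `taxon_id`, `pi_tree`, `pi_canopy`, `mu`,
#'   `sigma`, `base`, `guild`.
#' @examples
#' taxa <- generate_taxa(10, specialist_fraction = 1, seed = 1)
#' all(taxa$pi_tree %in% c(0, 1))
#' @export
generate_taxa <- function(n_taxa,
                          specialist_fraction = 0.3,
                          affinity_shape = c(2, 2),
                          temporal_range = c(1, 6),
                          sigma_range = c(0.25, 1.5),
                          seed = 1) {
  n_taxa <- check_count(n_taxa, "n_taxa", min = 0L)
  specialist_fraction <- check_proportion(specialist_fraction,
                                          "specialist_fraction")
  if (length(affinity_shape) != 2 || any(affinity_shape <= 0)) {
    abort("`affinity_shape` must be two positive Beta shape parameters")
  }
  if (length(temporal_range) != 2 || temporal_range[2] < temporal_range[1]) {
    abort("`temporal_range` must be an increasing year interval")
  }
  if (length(sigma_range) != 2 || any(sigma_range <= 0)) {
    abort("`sigma_range` must be a positive interval")
  }

  if (n_taxa == 0L) {
    return(tibble::tibble(
      taxon_id = character(), pi_tree = numeric(), pi_canopy = numeric(),
      mu = numeric(), sigma = numeric(), base = numeric(), guild = character()
    ))
  }

  withr::with_seed(split_seed(seed, 2L), {
    specialist <- runif(n_taxa) < specialist_fraction
    draw_affinity <- function() {
      p <- rbeta(n_taxa, affinity_shape[1], affinity_shape[2])
      p[specialist] <- as.numeric(runif(sum(specialist)) < 0.5)
      p
    }
    tibble::tibble(
      taxon_id = sprintf("OTU%04d", seq_len(n_taxa)),
      pi_tree = draw_affinity(),
      pi_canopy = draw_affinity(),
      mu = runif(n_taxa, temporal_range[1], temporal_range[2]),
      sigma = runif(n_taxa, sigma_range[1], sigma_range[2]),
      base = stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1),
      guild = sample(GUILD_LEVELS, n_taxa, replace = TRUE)
    )
  })
}
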