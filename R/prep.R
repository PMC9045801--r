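# Analysis-ready matrices: rarefied counts, species tables, relative
# abundances, Hellinger coordinates, abundance filters, guild profiles.

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's reads to a common `depth` without replacement
#' (random selection of individual reads), removing sequencing-depth bias
#' before diversity estimation. Samples with fewer than `depth` total reads
#' are dropped with a warning; their ids are recorded in the
#' `dropped_samples` attribute for audit.
#'
#' @param counts Wide count tibble (`otu_id` + sample columns).
#' @param depth Target reads per sample (default 2000).
#' @param seed Integer seed.
#' @return A rarefied wide count tibble; every retained column sums to
#'   `depth`. Attribute `dropped_samples` lists removed sample ids.
#' @export
rarefy_counts <- function(counts, depth = 2000, seed = 1) {
  depth <- check_count(depth, "depth")
  m <- counts_matrix(counts)
  totals <- colSums(m)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(colnames(m)[drop], collapse = ", ")),
            call. = FALSE)
  }
  m <- m[, !drop, drop = FALSE]
  if (ncol(m) == 0) {
    out <- counts_tibble(m)
    attr(out, "dropped_samples") <- colnames(counts_matrix(counts))
    return(out)
  }
  storage.mode(m) <- "integer"
  rare <- withr::with_seed(split_seed(seed, 6L), {
    # vegan::rrarefy works on sample-by-taxa rows, without replacement;
    # silence its smallest-count heuristic, which misfires on tables
    # without singletons
    withCallingHandlers(
      t(vegan::rrarefy(t(m), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  })
  storage.mode(rare) <- "double"
  out <- counts_tibble(rare)
  attr(out, "dropped_samples") <- colnames(counts_matrix(counts))[drop]
  out
}

#' Relative abundances per sample
#'
#' @param counts Wide count (or non-negative abundance) tibble.
#' @return A wide tibble of proportions; every sample column sums to 1.
#' @export
relative_abundance <- function(counts) {
  m <- counts_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  counts_tibble(sweep(m, 2, totals, "/"))
}

#' Hellinger transformation
#'
#' Square root of relative abundances: gives each sample unit Euclidean
#' norm, so Euclidean distances between transformed samples are ecologically
#' meaningful for species data (no double-zero inflation).
#'
#' @param counts Wide count or relative-abundance tibble.
#' @return A wide tibble of Hellinger coordinates.
#' @export
hellinger <- function(counts) {
  rel <- relative_abundance(counts)
  m <- counts_matrix(rel)
  counts_tibble(sqrt(m))
}

#' Aggregate OTUs to species-level taxa
#'
#' OTUs whose best hit reaches both the identity and the coverage threshold
#' are merged under the binomial of the best hit; all other OTUs are merged
#' under "<genus> sp.". OTUs flagged as host plant or otherwise non-fungal
#' are discarded before merging. Counts are summed within each merged taxon.
#'
#' @param counts Wide count tibble.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param identity_threshold Identity %% for a species-level hit (default 97).
#' @param coverage_threshold Coverage %% for a species-level hit (default 95).
#' @return A wide count tibble keyed by species/genus-sp. name, in order of
#'   first appearance.
#' @export
aggregate_to_species <- function(counts, taxonomy, identity_threshold = 97,
                                 coverage_threshold = 95) {
  m <- counts_matrix(counts)
  idx <- match(rownames(m), taxonomy$otu_id)
  if (anyNA(idx)) {
    abort(paste0("no taxonomy record for OTU(s): ",
                 paste(rownames(m)[is.na(idx)], collapse = ", ")))
  }
  tax <- taxonomy[idx, ]
  keep <- tax$kingdom_flag == "fungal"
  m <- m[keep, , drop = FALSE]
  tax <- tax[keep, ]
  species_hit <- !is.na(tax$species) & tax$species != "" &
    tax$identity_pct >= identity_threshold &
    tax$coverage_pct >= coverage_threshold
  name <- ifelse(species_hit, tax$species, paste(tax$genus, "sp."))
  agg <- rowsum(m, group = name, reorder = FALSE)
  counts_tibble(agg)
}

FILTER_PRESETS <- c("ordination", "succession", "specificity")

#' Abundance filters for taxon subsets
#'
#' Three named presets select the taxa entering ordination, successional
#' and specificity displays:
#' \describe{
#'   \item{ordination}{relative abundance > 0.5% in at least 3 samples.}
#'   \item{succession}{mean within-year ("yearly observation", computed per
#'     tree x canopy treatment) relative abundance > 1% in at least 3
#'     treatment-years, or maximum yearly abundance > 2%.}
#'   \item{specificity}{the ordination rule AND relative abundance > 1% in
#'     at least one sample.}
#' }
#' All comparisons are strict ("over" the threshold). The specificity
#' subset is therefore always contained in the ordination subset.
#'
#' @param rel Wide relative-abundance tibble.
#' @param preset One of `"ordination"`, `"succession"`, `"specificity"`.
#' @param metadata Sample metadata (required for the succession preset's
#'   yearly observations).
#' @return Character vector of retained taxon ids.
#' @export
apply_abundance_filter <- function(rel, preset, metadata = NULL) {
  if (length(preset) != 1 || !preset %in% FILTER_PRESETS) {
    abort(paste0("unknown filter preset; use one of: ",
                 paste(FILTER_PRESETS, collapse = ", ")))
  }
  m <- counts_matrix(rel)
  if (nrow(m) == 0) return(character())

  prevalent <- rowSums(m > 0.005) >= 3
  if (preset == "ordination") {
    return(rownames(m)[prevalent])
  }
  if (preset == "specificity") {
    return(rownames(m)[prevalent & rowSums(m > 0.01) >= 1])
  }
  # succession preset: yearly observation = mean relative abundance per
  # year within a tree x canopy treatment
  if (is.null(metadata)) {
    abort("the succession preset needs sample metadata with `year`")
  }
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")
  group <- interaction(meta$tree, meta$canopy, meta$year, drop = TRUE)
  yearly <- t(rowsum(t(m), group = group) / as.vector(table(group)))
  keep <- rowSums(yearly > 0.01) >= 3 | apply(yearly, 1, max) > 0.02
  rownames(m)[keep]
}

#' Guild composition per sample group
#'
#' Maps each taxon to its ecological guild (white rot, brown rot,
#' saprotroph, ...; unmapped genera become "unclassified") and sums relative
#' abundances per guild within groups defined by metadata factors.
#'
#' @param rel Wide relative-abundance tibble.
#' @param taxonomy Taxonomy tibble giving each taxon's genus.
#' @param guild_map Tibble with columns `genus`, `guild`.
#' @param metadata Sample metadata tibble.
#' @param grouping Character vector of metadata column names to group by
#'   (e.g. `c("tree", "canopy", "year")`).
#' @return A tibble with the grouping columns, `guild` and `share`; shares
#'   sum to 1 within each group.
#' @export
guild_profile <- function(rel, taxonomy, guild_map, metadata,
                          grouping = c("tree", "year")) {
  if (length(grouping) == 0) abort("`grouping` must name >= 1 factor")
  missing <- setdiff(grouping, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks grouping column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- counts_matrix(rel)
  idx <- match(rownames(m), taxonomy$otu_id)
  genus <- taxonomy$genus[idx]
  # species-aggregated tables key rows by name, not otu_id; fall back to
  # the leading word of the taxon name as its genus
  genus[is.na(genus)] <- sub(" .*$", "", rownames(m)[is.na(genus)])
  guild <- guild_lookup(genus, guild_map)

  by_guild <- rowsum(m, group = guild, reorder = TRUE)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  long <- tibble::as_tibble(as.data.frame(t(by_guild))) |>
    dplyr::mutate(sample_id = colnames(by_guild)) |>
    tidyr::pivot_longer(-dplyr::all_of("sample_id"),
                        names_to = "guild", values_to = "abundance") |>
    dplyr::left_join(meta, by = "sample_id")

  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "guild")))) |>
    dplyr::summarise(share = sum(.data$abundance), .groups = "drop_last") |>
    dplyr::mutate(total = sum(.data$share)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) abort("empty group in guild profile")
  out |>
    dplyr::mutate(share = .data$share / .data$total) |>
    dplyr::select(-"total")
}
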