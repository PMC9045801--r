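# TSV readers/writers for every tabular artifact, with strict validation.
# All files are UTF-8, tab-separated, header row, `NA` for missing values.

TREE_LEVELS <- c("beech", "fir")
CANOPY_LEVELS <- c("open", "closed")
KINGDOM_FLAGS <- c("fungal", "host_plant", "other")

write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Read an OTU-by-sample count table
#'
#' Expects a TSV whose first column is `otu_id` and whose remaining columns
#' are integer read counts, one column per sample. Round-trips exactly with
#' [write_count_table()]; row and column order are preserved.
#'
#' @param path Path to a TSV file.
#' @return A wide count tibble (`otu_id` + one integer column per sample).
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "otu_id") {
    abort("first column of a count table must be `otu_id`")
  }
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed count table: %s at line %d",
                  probs$expected[1], probs$row[1] + 1L))
  }
  ids <- tbl$otu_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(tbl))) abort("duplicate sample ids")
  for (j in setdiff(names(tbl), "otu_id")) {
    v <- tbl[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("non-numeric count in column `%s` at line %d",
                    j, bad + 1L))
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "negative, missing or non-integer count in column `%s` at line %d",
        j, bad[1] + 1L))
    }
  }
  tbl
}

#' @rdname read_count_table
#' @param table A wide count tibble.
#' @export
write_count_table <- function(table, path) {
  stopifnot("otu_id" %in% names(table))
  write_tsv_na(table, path)
}

#' Read sample metadata
#'
#' Validates factor levels (`tree` in beech/fir, `canopy` in open/closed)
#' and requires integral `year >= 1`.
#'
#' @param path Path to a TSV with columns sample_id, tree, canopy, block,
#'   plot, mixture, year.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  required <- c("sample_id", "tree", "canopy", "block", "plot",
                "mixture", "year")
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$sample_id)) abort("duplicate sample ids in metadata")
  bad_tree <- setdiff(unique(tbl$tree), TREE_LEVELS)
  if (length(bad_tree) > 0) {
    abort(paste0("unknown tree level(s): ", paste(bad_tree, collapse = ", ")))
  }
  bad_canopy <- setdiff(unique(tbl$canopy), CANOPY_LEVELS)
  if (length(bad_canopy) > 0) {
    abort(paste0("unknown canopy level(s): ",
                 paste(bad_canopy, collapse = ", ")))
  }
  if (any(is.na(tbl$year)) || any(tbl$year < 1) ||
      any(tbl$year != floor(tbl$year))) {
    abort("`year` must be an integer >= 1 for every sample")
  }
  tbl$year <- as.integer(tbl$year)
  tbl$mixture <- as.logical(tbl$mixture)
  if (is.numeric(tbl$block)) tbl$block <- as.integer(tbl$block)
  tbl
}

#' @rdname read_metadata
#' @param metadata A metadata tibble.
#' @export
write_metadata <- function(metadata, path) write_tsv_na(metadata, path)

#' Read a taxonomy table
#'
#' One row per OTU with the best BLAST hit: `species` (empty/NA when only a
#' genus-level hit exists), `genus`, `identity_pct`, `coverage_pct`, and an
#' optional `kingdom_flag` (fungal / host_plant / other; defaults to fungal).
#'
#' @param path Path to a TSV file.
#' @return A taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("otu_id", "species", "genus", "identity_pct", "coverage_pct")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("taxonomy is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"kingdom_flag" %in% names(tbl)) tbl$kingdom_flag <- "fungal"
  bad_flag <- setdiff(unique(tbl$kingdom_flag), KINGDOM_FLAGS)
  if (length(bad_flag) > 0) {
    abort(paste0("unknown kingdom_flag: ", paste(bad_flag, collapse = ", ")))
  }
  for (col in c("identity_pct", "coverage_pct")) {
    v <- tbl[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v > 100)) {
      abort(sprintf("`%s` must lie in [0, 100]", col))
    }
  }
  tbl
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) write_tsv_na(taxonomy, path)

#' Read a genus-to-guild map
#'
#' Returns a lookup function-friendly tibble; [guild_lookup()] resolves any
#' genus absent from the map to `"unclassified"`.
#'
#' @param path Path to a TSV with columns `genus`, `guild`.
#' @return A tibble with columns `genus`, `guild`.
#' @export
read_guild_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("genus", "guild") %in% names(tbl))) {
    abort("guild map needs columns `genus` and `guild`")
  }
  bad <- setdiff(unique(tbl$guild), GUILD_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown guild(s): ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' @rdname read_guild_map
#' @param guild_map A tibble with columns `genus`, `guild`.
#' @export
write_guild_map <- function(guild_map, path) write_tsv_na(guild_map, path)

#' Resolve genera to guilds, defaulting to "unclassified"
#'
#' @param genus Character vector of genus names.
#' @param guild_map Tibble from [read_guild_map()] (may have zero rows).
#' @return Character vector of guilds, `"unclassified"` for absent genera.
#' @export
guild_lookup <- function(genus, guild_map) {
  idx <- match(genus, guild_map$genus)
  out <- guild_map$guild[idx]
  out[is.na(out)] <- "unclassified"
  out
}

#' @rdname read_metadata
#' @export
read_chemistry <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "pH", "ergosterol", "C", "N", "moisture")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("chemistry is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}

#' @rdname read_metadata
#' @param chemistry A chemistry tibble.
#' @export
write_chemistry <- function(chemistry, path) write_tsv_na(chemistry, path)

#' Invent a taxonomy table for simulated OTUs
#'
#' Assigns each archetype a binomial name within a synthetic genus pool and
#' draws BLAST-like identity/coverage so that a tunable fraction of OTUs
#' fall below the species-level identity threshold (and will aggregate to
#' "<genus> sp."). Purely synthetic labels for pipeline plumbing and tests.
#'
#' @param taxa Archetype tibble from [generate_taxa()].
#' @param p_species_level Fraction of OTUs with identity >= 97.
#' @param n_genera Size of the synthetic genus pool.
#' @param seed Integer seed.
#' @return A taxonomy tibble (all rows flagged fungal) and guild map pairs
#'   consistent with the archetypes' guilds.
#' @export
generate_taxonomy <- function(taxa, p_species_level = 0.8, n_genera = 25,
                              seed = 1) {
  n <- nrow(taxa)
  withr::with_seed(split_seed(seed, 5L), {
    genus <- sprintf("Genus%02d", sample.int(n_genera, n, replace = TRUE))
    species_hit <- runif(n) < p_species_level
    identity <- ifelse(species_hit, runif(n, 97, 100), runif(n, 80, 96.9))
    taxonomy <- tibble::tibble(
      otu_id = taxa$taxon_id,
      species = ifelse(species_hit,
                       paste(genus, sprintf("species%02d",
                                            sample.int(40, n, TRUE))),
                       NA_character_),
      genus = genus,
      identity_pct = round(identity, 1),
      coverage_pct = round(runif(n, 95, 100), 1),
      kingdom_flag = "fungal"
    )
    # one guild per genus, taken from the first archetype carrying it
    guild_map <- dplyr::distinct(
      tibble::tibble(genus = genus, guild = taxa$guild),
      .data$genus, .keep_all = TRUE)
    list(taxonomy = taxonomy, guild_map = guild_map)
  })
}
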