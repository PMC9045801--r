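# End-to-end orchestration: simulate -> prep -> diversity -> succession ->
# multivariate -> report, from a flat key=value config with seed provenance.

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  n_blocks = 4L,
  n_years = 6L,
  n_taxa = 200L,
  specialist_fraction = 0.3,
  overdispersion = 0.05,
  chem_noise_sd = 0.05,
  depth = 2000L,
  filter_preset = "ordination",
  distance = "euclidean",
  n_perm_permanova = 9999L,
  n_perm_mantel = 99999L,
  n_perm_envfit = 999L,
  n_perm_varpart = 999L
)

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' an error (listed), missing keys take the package defaults, which mirror
#' the study settings (4 blocks, 6 years, rarefaction depth 2000,
#' 9999/99999/999 permutations).
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return A named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- PIPELINE_DEFAULTS
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  unknown <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("malformed config line: ", ln))
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (!key %in% names(cfg)) {
      unknown <- c(unknown, key)
      next
    }
    cfg[[key]] <- if (is.numeric(PIPELINE_DEFAULTS[[key]])) {
      as.numeric(val)
    } else {
      val
    }
  }
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!cfg$filter_preset %in% FILTER_PRESETS) {
    abort(paste0("unknown filter preset: ", cfg$filter_preset))
  }
  if (!cfg$distance %in% c("euclidean", "bray_curtis")) {
    abort(paste0("unknown distance: ", cfg$distance))
  }
  cfg
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates the factorial design, taxa, counts and chemistry; writes the
#' raw tables; aggregates to species level, rarefies, computes relative
#' abundances; then produces the diversity table, the per-taxon succession
#' records, PERMANOVA on the chosen community distance, a Mantel test
#' between community and chemistry distances, and variation partitioning
#' between tree species and canopy. All stage outputs are written as TSV
#' under `out_dir` and every seed is recorded in the summary.
#'
#' @param config Named list from [read_run_config()] (or a partial list;
#'   missing entries take defaults).
#' @param out_dir Output directory, created if needed. `NULL` keeps
#'   results in memory only.
#' @return Invisibly, a list with every stage result and a `summary`
#'   tibble of stage-level counts.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL) {
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, as.list(config))
  extra <- setdiff(names(cfg), names(PIPELINE_DEFAULTS))
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (!cfg$filter_preset %in% FILTER_PRESETS) {
    abort(paste0("unknown filter preset: ", cfg$filter_preset))
  }
  seed <- as.integer(cfg$seed)

  design <- generate_design(cfg$n_blocks, cfg$n_years)
  taxa <- generate_taxa(cfg$n_taxa, cfg$specialist_fraction, seed = seed)
  sim <- generate_community_counts(design, taxa, depth = cfg$depth * 2,
                                   overdispersion = cfg$overdispersion,
                                   seed = seed)
  chem <- generate_chemistry(design, noise_sd = cfg$chem_noise_sd,
                             seed = seed)
  taxinfo <- generate_taxonomy(taxa, seed = seed)

  species <- aggregate_to_species(sim$counts, taxinfo$taxonomy)
  rare <- rarefy_counts(species, depth = cfg$depth, seed = seed)
  rel <- relative_abundance(rare)
  hel <- hellinger(rare)

  div <- diversity_table(rare)
  succ <- succession_table(rel, design)
  kept <- apply_abundance_filter(rel, cfg$filter_preset, design)

  hel_m <- t(counts_matrix(hel))
  d_comm <- pairwise_distances(
    hel_m, if (cfg$distance == "euclidean") "euclidean" else "bray_curtis")
  meta <- design[match(rownames(hel_m), design$sample_id), ]
  perm <- permanova(d_comm, meta, c("tree", "canopy"),
                    n_perm = cfg$n_perm_permanova, seed = seed)
  chem_m <- as.matrix(chem[match(rownames(hel_m), chem$sample_id),
                           c("pH", "ergosterol", "C", "N")])
  rownames(chem_m) <- rownames(hel_m)
  d_chem <- pairwise_distances(scale(chem_m), "euclidean")
  man <- mantel_test(d_comm, d_chem, n_perm = cfg$n_perm_mantel, seed = seed)
  vp <- variation_partitioning(scale(hel_m, scale = FALSE),
                               meta["tree"], meta["canopy"],
                               n_perm = cfg$n_perm_varpart, seed = seed)

  summary <- tibble::tibble(
    stage = c("design", "taxa", "species_table", "rarefied",
              "filtered_taxa"),
    n = c(nrow(design), nrow(taxa), nrow(species), ncol(rare) - 1L,
          length(kept)),
    seed = seed
  )

  out <- list(config = cfg, design = design, taxa = taxa,
              counts = sim$counts, truth = sim$truth, chemistry = chem,
              taxonomy = taxinfo$taxonomy, guild_map = taxinfo$guild_map,
              species_counts = species, rarefied = rare, relative = rel,
              hellinger = hel, diversity = div, succession = succ,
              filtered_taxa = kept, permanova = perm, mantel = man,
              varpart = vp, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_metadata(design, p("metadata.tsv"))
    write_count_table(sim$counts, p("counts.tsv"))
    write_tsv_na(sim$truth, p("truth.tsv"))
    write_chemistry(chem, p("chemistry.tsv"))
    write_taxonomy(taxinfo$taxonomy, p("taxonomy.tsv"))
    write_guild_map(taxinfo$guild_map, p("guild_map.tsv"))
    write_count_table(species, p("species_counts.tsv"))
    write_count_table(rare, p("rarefied_counts.tsv"))
    write_tsv_na(div, p("diversity.tsv"))
    write_tsv_na(succ, p("succession.tsv"))
    write_tsv_na(tidy(perm), p("permanova.tsv"))
    write_tsv_na(tidy(vp), p("varpart.tsv"))
    write_tsv_na(summary, p("summary.tsv"))
  }
  invisible(out)
}
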