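# Factorial study design: blocks x canopy x plot kind x tree species x year.

#' Generate the factorial sampling design
#'
#' Builds the sample metadata for a randomised block experiment in which
#' freshly cut beech and fir branches decompose on forest plots under open
#' (cleared) or closed canopies. Each block x canopy stratum holds six plots:
#' two pure-beech, two pure-fir and two mixed plots; every plot contributes
#' samples of a single tree species per branch, so a mixed plot yields one
#' beech and one fir composite sample. At the defaults (4 blocks, 6 years)
#' this gives 8 samples per block per canopy, 64 samples per year and 384
#' samples in total.
#'
#' @param n_blocks Number of spatially independent blocks (default 4).
#' @param n_years Number of annual sampling campaigns (default 6).
#' @param seed Unused for layout (the design is deterministic); accepted so
#'   all generator functions share a signature.
#' @return A tibble with columns `sample_id`, `tree` (beech/fir), `canopy`
#'   (open/closed), `block`, `plot`, `mixture` (logical plot-level flag) and
#'   `year` (integer, 1-based).
#' @examples
#' d <- generate_design()
#' nrow(d)            # 384
#' table(d$year)      # 64 per year
#' @export
generate_design <- function(n_blocks = 4, n_years = 6, seed = NULL) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  n_years <- check_count(n_years, "n_years")

  # per block x canopy: plot kind -> (plot suffix, trees sampled)
  plot_layout <- tibble::tibble(
    plot_kind = c("pure_beech", "pure_beech", "pure_fir", "pure_fir",
                  "mixed", "mixed", "mixed", "mixed"),
    plot_rep  = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
    tree      = c("beech", "beech", "fir", "fir",
                  "beech", "beech", "fir", "fir")
  )

  grid <- tidyr::expand_grid(
    year = seq_len(n_years),
    block = seq_len(n_blocks),
    canopy = c("open", "closed"),
    plot_layout
  )

  grid |>
    dplyr::mutate(
      mixture = .data$plot_kind == "mixed",
      plot = paste0("B", .data$block, "_", substr(.data$canopy, 1, 2), "_",
                    .data$plot_kind, .data$plot_rep),
      sample_id = paste0(.data$plot, "_", .data$tree, "_Y", .data$year)
    ) |>
    dplyr::select("sample_id", "tree", "canopy", "block", "plot",
                  "mixture", "year") |>
    dplyr::mutate(
      block = as.integer(.data$block),
      year = as.integer(.data$year)
    )
}
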