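# Wood-chemistry covariates: pH, ergosterol, C, N, moisture per sample.

# Deterministic trajectories (year 1..6). pH and ergosterol follow the
# canonical course of decomposition; C is anchored at the year-1 C:N ratios,
# N is held at its year-1 value (no trend), moisture rises and is
# higher in beech. Linear interpolation between anchors, flat beyond.
chem_trajectory <- function(tree, variable, year) {
  anchors <- list(
    beech = list(
      pH = c(1, 5.3, 6, 4.0),
      ergosterol = c(1, 31, 6, 110),
      C = c(1, 41.6, 6, 46),
      N = c(1, 0.27, 6, 0.27),
      moisture = c(1, 30, 6, 55)
    ),
    fir = list(
      pH = c(1, 5.3, 6, 4.0),
      ergosterol = c(1, 10, 5, 48), # plateau after year 5
      C = c(1, 43.2, 6, 48),
      N = c(1, 0.16, 6, 0.16),
      moisture = c(1, 25, 6, 45)
    )
  )
  a <- anchors[[tree]][[variable]]
  y <- pmin(pmax(year, a[1]), a[3])
  if (a[3] == a[1]) return(rep(a[2], length(year)))
  a[2] + (a[4] - a[2]) * (y - a[1]) / (a[3] - a[1])
}

#' Generate wood-chemistry covariates for a sampling design
#'
#' Produces per-sample pH, ergosterol (fungal biomass proxy, ug per g dry
#' mass), carbon and nitrogen content (% dry mass) and moisture (% fresh
#' mass) following the deterministic decomposition trajectories: pH falls
#' linearly from 5.3 (year 1) to 4.0 (year 6) in both tree species;
#' ergosterol rises from 31 to 110 ug/g in beech over years 1-6 and from
#' 10 to 48 ug/g in fir over years 1-5, then stays flat; year-1 N is 0.27%
#' in beech and 0.16% in fir.
#'
#' Gaussian noise with standard deviation `noise_sd` times the variable's
#' year-1 to year-6 trajectory range is added (one knob across units);
#' values are clipped at physical bounds (pH in (0, 14), ergosterol >= 0,
#' moisture in \[0, 100\]).
#'
#' @param design Sample metadata tibble from [generate_design()].
#' @param noise_sd Non-negative relative noise level; 0 gives the exact
#'   deterministic trajectories.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `pH`, `ergosterol`, `C`, `N`,
#'   `moisture`.
#' @examples
#' d <- generate_design(1, 6)
#' ch <- generate_chemistry(d, noise_sd = 0)
#' ch$pH[d$year == 6][1]  # 4.0
#' @export
generate_chemistry <- function(design, noise_sd = 0.05, seed = 1) {
  if (length(noise_sd) != 1 || is.na(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number")
  }
  vars <- c("pH", "ergosterol", "C", "N", "moisture")
  base <- purrr::map(setNames(vars, vars), function(v) {
    ifelse(design$tree == "beech",
           chem_trajectory("beech", v, design$year),
           chem_trajectory("fir", v, design$year))
  })

  out <- tibble::tibble(sample_id = design$sample_id, !!!base)
  if (noise_sd > 0) {
    out <- withr::with_seed(split_seed(seed, 4L), {
      for (v in vars) {
        rng_beech <- abs(diff(range(chem_trajectory("beech", v, c(1, 6)))))
        rng_fir <- abs(diff(range(chem_trajectory("fir", v, c(1, 6)))))
        scale <- ifelse(design$tree == "beech", rng_beech, rng_fir)
        scale[scale == 0] <- abs(out[[v]][scale == 0]) # flat trajectories
        out[[v]] <- out[[v]] + rnorm(nrow(out), sd = noise_sd * scale)
      }
      out
    })
  }
  out$pH <- pmin(pmax(out$pH, 1e-6), 14 - 1e-6)
  out$ergosterol <- pmax(out$ergosterol, 0)
  out$C <- pmin(pmax(out$C, 0), 100)
  out$N <- pmin(pmax(out$N, 0), 100)
  out$moisture <- pmin(pmax(out$moisture, 0), 100)
  out
}
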