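# Per-taxon succession statistics: habitat specificity and its classing,
# abundance-weighted succession time, 90% occurrence duration.

#' Tree or canopy specificity per taxon
#'
#' Specificity is the fraction of a taxon's total relative abundance found
#' on the reference level of a factor: the sum of its per-sample relative
#' abundances over beech samples (or closed-canopy samples) divided by the
#' sum over all samples. A value of 1 means the taxon occurs exclusively on
#' beech (closed canopy), 0.5 means it is equally abundant on both levels,
#' 0 means it occurs exclusively on fir (open canopy). Taxa absent from
#' every sample are undefined and reported as `NA`, never as 0 or 1.
#'
#' Per-sample relative abundances (not raw counts) are summed, so unequal
#' sample depths cannot bias the index.
#'
#' @param rel Wide relative-abundance tibble.
#' @param metadata Sample metadata tibble.
#' @param factor `"tree"` (reference beech) or `"canopy"` (reference closed).
#' @return A tibble with `taxon_id`, `specificity` and a `reference`
#'   attribute naming the reference level.
#' @export
taxon_specificity <- function(rel, metadata, factor = c("tree", "canopy")) {
  factor <- match.arg(factor)
  reference <- c(tree = "beech", canopy = "closed")[[factor]]
  m <- counts_matrix(rel)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")
  ref <- meta[[factor]] == reference
  total <- rowSums(m)
  s <- unname(rowSums(m[, ref, drop = FALSE]) / total)
  s[total <= 0] <- NA_real_
  out <- tibble::tibble(taxon_id = rownames(m), specificity = s)
  attr(out, "reference") <- reference
  out
}

#' Classify a specificity value
#'
#' Taxa with specificity between 1.0 and 0.95 (inclusive) are specific to
#' the reference level (beech / closed canopy); between 0.05 and 0.00
#' (inclusive) specific to the alternative level (fir / open canopy);
#' anything else is unspecific. `NA` stays `NA`.
#'
#' @param s Numeric specificity values in \[0, 1\].
#' @param factor `"tree"` or `"canopy"` (controls the class labels).
#' @return Character vector of classes.
#' @export
classify_specificity <- function(s, factor = c("tree", "canopy")) {
  factor <- match.arg(factor)
  if (any(s < 0 | s > 1, na.rm = TRUE)) {
    abort("specificity must lie in [0, 1]")
  }
  labels <- if (factor == "tree") {
    c(ref = "beech_specific", alt = "fir_specific")
  } else {
    c(ref = "closed_specific", alt = "open_specific")
  }
  dplyr::case_when(
    is.na(s) ~ NA_character_,
    s >= 0.95 ~ labels[["ref"]],
    s <= 0.05 ~ labels[["alt"]],
    .default = "unspecific"
  )
}

#' Succession time of a yearly abundance profile
#'
#' The abundance-weighted mean year of occurrence:
#' \eqn{T = \sum_y y\, w_y / \sum_y w_y}, where \eqn{w_y} is the mean
#' relative abundance of the taxon across the samples of year y. Invariant
#' to rescaling the profile.
#'
#' @param profile Non-negative yearly weights, named by year or positional
#'   (element i = year i).
#' @return Succession time in years (real).
#' @examples
#' succession_time(c(0, 0, 1, 3, 0, 0))  # 3.75
#' @export
succession_time <- function(profile) {
  w <- as.numeric(profile)
  if (any(w < 0)) abort("profile weights must be non-negative")
  if (sum(w) <= 0) abort("zero profile: succession time undefined")
  years <- profile_years(profile)
  sum(years * w) / sum(w)
}

#' Occurrence duration of a yearly abundance profile
#'
#' The length (whole years) of the shortest contiguous run of years whose
#' summed weight reaches 90% of the profile total; ties broken by the
#' earliest window. A central-interval alternative — the span between the
#' years where the cumulative profile passes 5% and 95% — is available via
#' `method = "central"`.
#'
#' @inheritParams succession_time
#' @param method `"contiguous"` (default) or `"central"`.
#' @param coverage Fraction of total abundance the window must cover
#'   (default 0.9).
#' @return Duration in whole years (integer).
#' @examples
#' occurrence_duration(rep(1, 6))                      # 6
#' occurrence_duration(c(0.05, 0.90, 0.05, 0, 0, 0))   # 1
#' @export
occurrence_duration <- function(profile, method = c("contiguous", "central"),
                                coverage = 0.9) {
  method <- match.arg(method)
  w <- as.numeric(profile)
  if (any(w < 0)) abort("profile weights must be non-negative")
  total <- sum(w)
  if (total <= 0) abort("zero profile: duration undefined")
  n <- length(w)
  if (method == "central") {
    cum <- cumsum(w) / total
    # years strictly inside the lower tail are excluded
    lo <- which(cum > (1 - coverage) / 2 + 1e-12)[1]
    hi <- which(cum >= 1 - (1 - coverage) / 2 - 1e-12)[1]
    return(as.integer(hi - lo + 1L))
  }
  target <- coverage * total - 1e-12 # guard float error at exact coverage
  for (len in seq_len(n)) {
    for (start in seq_len(n - len + 1L)) {
      if (sum(w[start:(start + len - 1L)]) >= target) {
        return(as.integer(len))
      }
    }
  }
  as.integer(n)
}

profile_years <- function(profile) {
  nm <- names(profile)
  if (!is.null(nm) && !anyNA(suppressWarnings(as.numeric(nm)))) {
    as.numeric(nm)
  } else {
    seq_along(profile)
  }
}

#' Mean yearly abundance profiles for every taxon
#'
#' @param rel Wide relative-abundance tibble.
#' @param metadata Sample metadata with `year`.
#' @return A taxa-by-years matrix of mean relative abundances (columns
#'   named by year).
#' @export
yearly_profiles <- function(rel, metadata) {
  m <- counts_matrix(rel)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")
  year <- meta$year
  prof <- t(rowsum(t(m), group = year) / as.vector(table(year)))
  colnames(prof) <- sort(unique(year))
  prof
}

#' Full per-taxon succession record table
#'
#' Combines tree and canopy specificity (with classes), succession time and
#' occurrence duration into the per-taxon record underlying successional
#' and specificity displays.
#'
#' @param rel Wide relative-abundance tibble.
#' @param metadata Sample metadata tibble.
#' @param duration_method Passed to [occurrence_duration()].
#' @return A tibble with columns `taxon_id`, `s_tree`, `class_tree`,
#'   `s_canopy`, `class_canopy`, `succession_time`, `duration`.
#' @export
succession_table <- function(rel, metadata,
                             duration_method = c("contiguous", "central")) {
  duration_method <- match.arg(duration_method)
  st <- taxon_specificity(rel, metadata, "tree")
  sc <- taxon_specificity(rel, metadata, "canopy")
  prof <- yearly_profiles(rel, metadata)
  present <- rowSums(prof) > 0
  t_vals <- rep(NA_real_, nrow(prof))
  d_vals <- rep(NA_integer_, nrow(prof))
  t_vals[present] <- apply(prof[present, , drop = FALSE], 1, succession_time)
  d_vals[present] <- apply(prof[present, , drop = FALSE], 1,
                           occurrence_duration, method = duration_method)
  tibble::tibble(
    taxon_id = st$taxon_id,
    s_tree = st$specificity,
    class_tree = classify_specificity(st$specificity, "tree"),
    s_canopy = sc$specificity,
    class_canopy = classify_specificity(sc$specificity, "canopy"),
    succession_time = t_vals,
    duration = d_vals
  )
}

#' Correlation between succession time and specificity
#'
#' Spearman rank correlation (with t-approximation p-value) between each
#' taxon's succession time and its specificity for the chosen factor.
#'
#' @param records Tibble from [succession_table()].
#' @param factor `"tree"` or `"canopy"`.
#' @return A one-row tibble: `rho`, `p_value`, `n`. `rho` is `NA` when
#'   either variable has zero rank variance.
#' @export
specificity_vs_time <- function(records, factor = c("tree", "canopy")) {
  factor <- match.arg(factor)
  s <- records[[if (factor == "tree") "s_tree" else "s_canopy"]]
  t_ <- records$succession_time
  ok <- !is.na(s) & !is.na(t_)
  if (sum(ok) < 3) abort("need >= 3 complete records")
  res <- spearman_cor(t_[ok], s[ok])
  tibble::tibble(rho = res$rho, p_value = res$p_value, n = sum(ok))
}
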