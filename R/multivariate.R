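# Permutation multivariate statistics: distances, PERMANOVA, Mantel,
# vector fitting, Spearman, and univariate group tests.

#' Pairwise sample distances
#'
#' @param x Samples-by-features numeric matrix (or data frame).
#' @param metric `"euclidean"` or `"bray_curtis"`
#'   (\eqn{\sum |x - y| / \sum (x + y)}; requires non-negative features).
#' @return A `dist` object with sample labels.
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "bray_curtis")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need >= 2 samples")
  if (metric == "euclidean") {
    dist(x)
  } else {
    if (any(x < 0)) abort("bray_curtis requires non-negative features")
    vegan::vegdist(x, method = "bray")
  }
}

# Gower-centered inner-product matrix from a distance matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n). tr(G) is the total sum of squares
# of the McArdle-Anderson distance-based linear model.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

hat_matrix <- function(x) {
  q <- qr.Q(qr(x))
  tcrossprod(q)
}

# F statistics for every term given a permutation of sample identities.
# hats: list with full-model hat and, per term, the hats of the models
# with and without that term (Type II). G is fixed; permuting samples is
# equivalent to permuting rows/cols of G.
permanova_stats <- function(G, hats, df_terms, df_res, perm = NULL) {
  Gp <- if (is.null(perm)) G else G[perm, perm]
  ss_total <- sum(diag(Gp))
  ss_res <- ss_total - sum(hats$full * Gp)
  vapply(seq_along(hats$with), function(i) {
    ss_term <- sum(hats$with[[i]] * Gp) - sum(hats$without[[i]] * Gp)
    (ss_term / df_terms[i]) / (ss_res / df_res)
  }, numeric(1))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based linear model: the distance matrix is Gower-centered and
#' sums of squares are obtained by projecting it onto the dummy-coded
#' design (McArdle-Anderson). One or two crossed factors are supported,
#' with the two-way model including the interaction by default; term sums
#' of squares are Type II (each term adjusted for the other main effect)
#' and the residual comes from the full model. The permutation null
#' permutes sample identities freely and recomputes each pseudo-F;
#' p = (b + 1)/(m + 1) counting the observed statistic. Set
#' `permutations = "exact"` to enumerate all distinct relabellings
#' (one-way only, small n).
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param data Data frame of factors, rows aligned with `d`.
#' @param factors Character vector of 1 or 2 column names in `data`.
#' @param interaction Include the interaction term (two-way only).
#' @param n_perm Number of permutations (default 9999).
#' @param permutations `"free"` (default), or `"exact"` for complete
#'   enumeration of label permutations in the one-way case.
#' @param strata Optional factor; when given, permutations shuffle samples
#'   only within its levels (restricted permutation).
#' @param seed Integer seed, recorded in the result.
#' @return An object of class `fwd_permanova`: a list with a per-term
#'   tibble (`terms`: term, df, ss, pseudo_f, r2, p_value), `n_perm`,
#'   `seed`.
#' @export
permanova <- function(d, data, factors, interaction = TRUE, n_perm = 9999,
                      permutations = c("free", "exact"), strata = NULL,
                      seed = 1) {
  permutations <- match.arg(permutations)
  if (!length(factors) %in% 1:2) abort("1 or 2 factors required")
  G <- gower_center(d)
  n <- nrow(G)
  fac <- lapply(factors, function(f) {
    v <- factor(data[[f]])
    if (nlevels(v) < 2) abort(sprintf("factor `%s` has a single level", f))
    v
  })
  names(fac) <- factors
  if (any(lengths(fac) != n)) abort("factor length must match distance size")

  intercept <- matrix(1, n, 1)
  mm <- lapply(fac, function(v) stats::model.matrix(~v)[, -1, drop = FALSE])
  two_way <- length(fac) == 2
  use_int <- two_way && interaction
  if (use_int) {
    mm_int <- stats::model.matrix(~ fac[[1]] * fac[[2]])
    mm_int <- mm_int[, grepl(":", colnames(mm_int)), drop = FALSE]
  }

  terms <- factors
  if (use_int) terms <- c(terms, paste(factors, collapse = ":"))
  df_terms <- unname(vapply(fac, function(v) nlevels(v) - 1L, integer(1)))
  if (use_int) df_terms <- c(df_terms, prod(df_terms[1:2]))

  full_x <- cbind(intercept, do.call(cbind, mm), if (use_int) mm_int)
  if (qr(full_x)$rank < ncol(full_x)) {
    # empty design cells or aliased factors
    abort("design is rank-deficient (empty cells or aliased factors)")
  }
  df_res <- n - qr(full_x)$rank
  if (df_res < 1) abort("no residual degrees of freedom")

  with_h <- list()
  without_h <- list()
  if (!two_way) {
    with_h[[1]] <- hat_matrix(cbind(intercept, mm[[1]]))
    without_h[[1]] <- hat_matrix(intercept)
  } else {
    both <- cbind(intercept, mm[[1]], mm[[2]])
    for (i in 1:2) {
      with_h[[i]] <- hat_matrix(both)
      without_h[[i]] <- hat_matrix(cbind(intercept, mm[[3 - i]]))
    }
    if (use_int) {
      with_h[[3]] <- hat_matrix(full_x)
      without_h[[3]] <- hat_matrix(both)
    }
  }
  hats <- list(full = hat_matrix(full_x), with = with_h, without = without_h)

  obs <- permanova_stats(G, hats, df_terms, df_res)
  ss_total <- sum(diag(G))
  ss_res <- ss_total - sum(hats$full * G)
  ss_terms <- obs * df_terms * (ss_res / df_res)

  if (permutations == "exact") {
    if (two_way) abort("exact enumeration supports one-way designs only")
    perms <- all_label_permutations(fac[[1]])
    perm_f <- vapply(perms, function(p)
      permanova_stats(G, hats, df_terms, df_res, p), numeric(1))
    # enumeration includes the identity; p is the exact fraction at least
    # as extreme as the observed statistic
    p_vals <- sum(perm_f >= obs[1] - 1e-12) / length(perm_f)
    n_used <- length(perm_f)
  } else {
    perm_f <- withr::with_seed(split_seed(seed, 7L), {
      vapply(seq_len(n_perm), function(i) {
        p <- permute_indices(n, strata)
        permanova_stats(G, hats, df_terms, df_res, p)
      }, numeric(length(terms)))
    })
    perm_f <- matrix(perm_f, nrow = length(terms))
    p_vals <- vapply(seq_along(terms), function(i)
      perm_pvalue(perm_f[i, ], obs[i]), numeric(1))
    n_used <- n_perm
  }

  structure(list(
    terms = tibble::tibble(
      term = terms,
      df = as.integer(df_terms),
      ss = ss_terms,
      pseudo_f = obs,
      r2 = ss_terms / ss_total,
      p_value = p_vals
    ),
    df_res = df_res, ss_res = ss_res, ss_total = ss_total,
    n_perm = n_used, permutations = permutations, seed = seed
  ), class = "fwd_permanova")
}

permute_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lev in unique(strata)) {
    sel <- which(strata == lev)
    idx[sel] <- sel[sample.int(length(sel))]
  }
  idx
}

# All distinct permutations of group labels for a one-way design,
# expressed as sample orderings (choose which samples carry level 1, ...).
all_label_permutations <- function(groups) {
  n <- length(groups)
  levs <- levels(groups)
  if (length(levs) != 2) abort("exact enumeration implemented for 2 groups")
  a <- which(groups == levs[1])
  b <- which(groups == levs[2])
  picks <- combn(n, length(a), simplify = FALSE)
  lapply(picks, function(pick) {
    # p maps design positions to data samples: the original level-1
    # positions now read the samples in `pick`
    idx <- integer(n)
    idx[a] <- pick
    idx[b] <- setdiff(seq_len(n), pick)
    idx
  })
}

#' Mantel test between two distance matrices
#'
#' Correlates the off-diagonal entries of two distance matrices and builds
#' the null by simultaneous row/column permutation of the second matrix.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   (matching labels if present).
#' @param method `"pearson"` or `"spearman"` correlation of distances.
#' @param n_perm Number of permutations (default 99999).
#' @param seed Integer seed.
#' @return A `fwd_permtest` list: `statistic` (r), `n_perm`, `p_value`,
#'   `seed`, `method`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 99999, seed = 1) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) abort("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    abort("distance matrices have mismatched sample ids")
  }
  n <- nrow(m1)
  lower <- lower.tri(m1)
  r_obs <- cor(m1[lower], m2[lower], method = method)
  perm_r <- withr::with_seed(split_seed(seed, 8L), {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(m1[lower], m2[p, p][lower], method = method)
    }, numeric(1))
  })
  structure(list(statistic = r_obs, effect_size = r_obs,
                 p_value = perm_pvalue(perm_r, r_obs),
                 n_perm = n_perm, seed = seed, method = method,
                 test = "mantel"),
            class = "fwd_permtest")
}

#' Fit an environmental vector to ordination coordinates
#'
#' Least-squares regression of a variable on the (two) ordination axes;
#' the fitted direction is the unit vector of the regression coefficients
#' and R2 the variance fraction explained. Significance by permuting the
#' variable across samples. Constant variables yield a missing result.
#'
#' @param coords Samples-by-axes coordinate matrix (e.g. from [nmds()]).
#' @param variable Numeric per-sample variable, no missing values.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A `fwd_permtest` list with `direction` (unit vector), `r2`,
#'   `p_value`; `r2` is `NA` for a constant variable.
#' @export
envfit_vector <- function(coords, variable, n_perm = 999, seed = 1) {
  coords <- as.matrix(coords)
  if (anyNA(variable)) abort("variable has missing values")
  if (length(variable) != nrow(coords)) {
    abort("variable length must match coordinate rows")
  }
  if (sd(variable) == 0) {
    return(structure(list(direction = rep(NA_real_, ncol(coords)),
                          r2 = NA_real_, statistic = NA_real_,
                          p_value = NA_real_, n_perm = n_perm, seed = seed,
                          test = "envfit"),
                     class = "fwd_permtest"))
  }
  r2_of <- function(v) {
    fit <- stats::lm.fit(cbind(1, coords), v)
    1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  }
  r2_obs <- r2_of(variable)
  beta <- stats::lm.fit(cbind(1, coords), variable)$coefficients[-1]
  direction <- beta / sqrt(sum(beta^2))
  perm_r2 <- withr::with_seed(split_seed(seed, 9L), {
    vapply(seq_len(n_perm), function(i) r2_of(sample(variable)), numeric(1))
  })
  structure(list(direction = unname(direction), r2 = r2_obs,
                 statistic = r2_obs, effect_size = r2_obs,
                 p_value = perm_pvalue(perm_r2, r2_obs),
                 n_perm = n_perm, seed = seed, test = "envfit"),
            class = "fwd_permtest")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); two-sided p
#' from the t approximation with n - 2 degrees of freedom. Zero rank
#' variance in either variable gives a missing result.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need n >= 3")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    return(list(rho = rho, p_value = 0))
  }
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Univariate group tests: two-way ANOVA or Kruskal-Wallis
#'
#' One factor: Kruskal-Wallis H (tie-corrected) and one-way ANOVA F.
#' Two factors: two-way ANOVA with Type II sums of squares (robust to mild
#' imbalance), interaction included when every cell has >= 2 observations.
#'
#' @param values Numeric per-sample response.
#' @param data Data frame with the factor columns.
#' @param factors Character vector of 1 or 2 column names.
#' @return A tibble with `term`, `statistic` (F or H), `df`, `p_value`,
#'   `test`.
#' @export
group_tests <- function(values, data, factors) {
  if (!length(factors) %in% 1:2) abort("1 or 2 factors required")
  for (f in factors) {
    if (length(unique(data[[f]])) < 2) {
      abort(sprintf("factor `%s` has a single level", f))
    }
  }
  df <- data.frame(.y = values, data[factors], check.names = FALSE)
  if (length(factors) == 1) {
    kw <- kruskal.test(df$.y, factor(df[[factors]]))
    # all-ties response: zero rank variance carries no evidence, H = 0
    if (is.nan(kw$statistic)) {
      kw$statistic[] <- 0
      kw$p.value <- 1
    }
    fit <- stats::aov(stats::reformulate(factors, ".y"), data = df)
    an <- summary(fit)[[1]]
    return(tibble::tibble(
      term = c(factors, factors),
      statistic = c(an$`F value`[1], unname(kw$statistic)),
      ss = c(an$`Sum Sq`[1], NA_real_),
      df = c(an$Df[1], unname(kw$parameter)),
      p_value = c(an$`Pr(>F)`[1], kw$p.value),
      test = c("anova_F", "kruskal_wallis_H")
    ))
  }
  cells <- table(df[[factors[1]]], df[[factors[2]]])
  use_int <- all(cells >= 2)
  rss <- function(rhs) {
    sum(stats::residuals(stats::lm(stats::reformulate(rhs, ".y"),
                                   data = df))^2)
  }
  a <- factors[1]
  b <- factors[2]
  rss_a <- rss(a)
  rss_b <- rss(b)
  rss_ab <- rss(paste(a, "+", b))
  full_rhs <- if (use_int) paste(a, "*", b) else paste(a, "+", b)
  fit_full <- stats::lm(stats::reformulate(full_rhs, ".y"), data = df)
  rss_full <- sum(stats::residuals(fit_full)^2)
  df_res <- fit_full$df.residual

  la <- length(unique(df[[a]]))
  lb <- length(unique(df[[b]]))
  term <- c(a, b, if (use_int) paste0(a, ":", b))
  ss <- c(rss_b - rss_ab, rss_a - rss_ab,
          if (use_int) rss_ab - rss_full)
  dfs <- c(la - 1L, lb - 1L, if (use_int) (la - 1L) * (lb - 1L))
  ms_res <- rss_full / df_res
  eps <- 1e-12 * max(1, sum((df$.y - mean(df$.y))^2))
  f_stat <- if (ms_res > eps) {
    (ss / dfs) / ms_res
  } else {
    ifelse(ss > eps, Inf, NaN) # perfect fit: infinite F where SS remains
  }
  p <- ifelse(is.nan(f_stat), NA_real_,
              stats::pf(f_stat, dfs, df_res, lower.tail = FALSE))
  tibble::tibble(term = term, statistic = f_stat, ss = ss, df = dfs,
                 p_value = p, test = "anova_F_typeII")
}
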