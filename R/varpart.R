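# Variation partitioning between two predictor blocks via redundancy
# analysis with adjusted R2 (pure, shared and residual fractions).

# Redundancy-analysis R2 of a (column-centered) response matrix on a
# predictor block: SS(fitted)/SS(total) from ordinary least squares.
rda_r2 <- function(y, x) {
  y <- scale(as.matrix(y), scale = FALSE)
  qx <- qr(cbind(1, as.matrix(x)))
  fitted <- qr.fitted(qx, y)
  sum(fitted^2) / sum(y^2)
}

adjust_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

block_matrix <- function(x) {
  x <- as.data.frame(x)
  mm <- stats::model.matrix(~., data = x)[, -1, drop = FALSE]
  mm
}

#' Variation partitioning between two predictor blocks
#'
#' Partitions the variance of a community matrix (typically Hellinger
#' coordinates) explained by two predictor blocks into the pure fraction of
#' each block (a, c), their shared fraction (b) and the residual, using
#' redundancy-analysis R2 adjusted as
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}. By construction
#' a + b = adjR2(X1), b + c = adjR2(X2) and a + b + c = adjR2(X1 u X2).
#' The testable fractions (each block's marginal contribution and the pure
#' fractions via partial RDA pseudo-F) get Monte Carlo permutation p-values
#' by freely permuting the rows of the response.
#'
#' @param y Samples-by-species response matrix (e.g. from [hellinger()],
#'   transposed to samples-in-rows) or data frame.
#' @param x1,x2 Predictor blocks: data frames/factors/matrices; factors are
#'   dummy-coded.
#' @param n_perm Permutations for the fraction tests (default 999); 0 skips
#'   testing.
#' @param seed Integer seed.
#' @return An object of class `fwd_varpart`: tibble `fractions` with
#'   columns fraction (a, b, c, residual), adj_r2, p_value (NA where not
#'   testable), plus `r2` (unadjusted), `n`, `seed`.
#' @export
variation_partitioning <- function(y, x1, x2, n_perm = 999, seed = 1) {
  y <- as.matrix(y)
  m1 <- block_matrix(x1)
  m2 <- block_matrix(x2)
  n <- nrow(y)
  if (nrow(m1) != n || nrow(m2) != n) {
    abort("predictor blocks must match response rows")
  }
  p1 <- qr(cbind(1, m1))$rank - 1L
  p2 <- qr(cbind(1, m2))$rank - 1L
  p12 <- qr(cbind(1, m1, m2))$rank - 1L
  if (n <= p12 + 1) abort("saturated or collinear design: n too small")
  if (p1 == 0 || p2 == 0) {
    abort("saturated or collinear design: a predictor block is constant")
  }

  r2_1 <- rda_r2(y, m1)
  r2_2 <- rda_r2(y, m2)
  r2_12 <- rda_r2(y, cbind(m1, m2))
  a1 <- adjust_r2(r2_1, n, p1)
  a2 <- adjust_r2(r2_2, n, p2)
  a12 <- adjust_r2(r2_12, n, p12)

  a <- a12 - a2 # pure X1
  c_ <- a12 - a1 # pure X2
  b <- a1 - a # shared
  resid <- 1 - a12

  # permutation tests: marginal blocks via their R2; pure fractions via
  # the partial pseudo-F (semipartial R2), permuting response rows freely
  p_vals <- rep(NA_real_, 4)
  if (n_perm > 0) {
    stat_pure1 <- r2_12 - rda_r2(y, m2)
    stat_pure2 <- r2_12 - rda_r2(y, m1)
    perms <- withr::with_seed(split_seed(seed, 11L), {
      t(vapply(seq_len(n_perm), function(i) {
        yp <- y[sample.int(n), , drop = FALSE]
        r12p <- rda_r2(yp, cbind(m1, m2))
        c(r12p - rda_r2(yp, m2), r12p - rda_r2(yp, m1))
      }, numeric(2)))
    })
    p_vals[1] <- perm_pvalue(perms[, 1], stat_pure1)
    p_vals[3] <- perm_pvalue(perms[, 2], stat_pure2)
  }

  structure(list(
    fractions = tibble::tibble(
      fraction = c("a_pure_x1", "b_shared", "c_pure_x2", "residual"),
      adj_r2 = c(a, b, c_, resid),
      p_value = p_vals
    ),
    adj_r2_x1 = a1, adj_r2_x2 = a2, adj_r2_both = a12,
    r2 = c(x1 = r2_1, x2 = r2_2, both = r2_12),
    n = n, n_perm = n_perm, seed = seed
  ), class = "fwd_varpart")
}

#' @export
print.fwd_varpart <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  print(x$fractions)
  invisible(x)
}
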