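# Non-metric multidimensional scaling: Kruskal stress-1 minimised by
# alternating isotonic regression (disparities) and Guttman-transform
# configuration updates, with random restarts plus a metric-scaling start.

config_distances <- function(x) as.matrix(dist(x))

# Kruskal stress-1 given configuration distances and disparities:
# sqrt( sum((d - dhat)^2) / sum(d^2) ) over the lower triangle.
stress1 <- function(d_config, d_hat, lower) {
  sqrt(sum((d_config[lower] - d_hat[lower])^2) /
         sum(d_config[lower]^2))
}

# Monotone (primary/weak ties) regression of configuration distances on
# dissimilarity ranks via PAVA (stats::isoreg).
disparities <- function(diss_order, d_config_vec) {
  fit <- isoreg(d_config_vec[diss_order])
  out <- numeric(length(diss_order))
  out[diss_order] <- fit$yf
  out
}

nmds_single_start <- function(diss, x0, max_iter, tol) {
  n <- nrow(x0)
  lower_idx <- which(lower.tri(matrix(0, n, n)))
  diss_vec <- as.matrix(diss)[lower_idx]
  diss_order <- order(diss_vec)

  x <- x0
  dc <- config_distances(x)
  dhat_vec <- disparities(diss_order, dc[lower_idx])
  stress_path <- stress1(dc, to_full(dhat_vec, n, lower_idx), lower_idx)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # Guttman transform: X <- (1/n) B(X) X with B from current disparities
    dhat <- to_full(dhat_vec, n, lower_idx)
    ratio <- ifelse(dc > 0, dhat / dc, 0)
    b <- -ratio
    diag(b) <- -rowSums(b)
    x_new <- (b %*% x) / n
    dc_new <- config_distances(x_new)
    dhat_vec_new <- disparities(diss_order, dc_new[lower_idx])
    s_new <- stress1(dc_new, to_full(dhat_vec_new, n, lower_idx), lower_idx)

    if (s_new > utils::tail(stress_path, 1) + 1e-12) {
      # stress would rise (normalization effect near a stationary point):
      # keep the previous configuration and stop
      converged <- TRUE
      break
    }
    improvement <- utils::tail(stress_path, 1) - s_new
    x <- x_new
    dc <- dc_new
    dhat_vec <- dhat_vec_new
    stress_path <- c(stress_path, s_new)
    if (improvement < tol) {
      converged <- TRUE
      break
    }
  }
  list(coords = x, stress = utils::tail(stress_path, 1),
       stress_path = stress_path, converged = converged)
}

to_full <- function(vec, n, lower_idx) {
  m <- matrix(0, n, n)
  m[lower_idx] <- vec
  m + t(m)
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Embeds a distance matrix in `dims` dimensions preserving the rank order
#' of dissimilarities, minimising Kruskal stress-1. Each start alternates
#' isotonic regression of configuration distances on dissimilarity ranks
#' (primary treatment of ties) with a Guttman-transform update; the stress
#' sequence within a start is non-increasing by construction. Starts
#' comprise one metric-scaling (principal coordinates) configuration plus
#' `n_starts - 1` random configurations; the lowest-stress solution is
#' returned, so its stress never exceeds the metric-scaling start's.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param dims Embedding dimension (default 2).
#' @param n_starts Total starts including the metric start (default 20).
#' @param max_iter Iterations per start (default 200).
#' @param tol Stop a start when the stress improvement falls below this.
#' @param seed Integer seed for the random starts.
#' @return An object of class `fwd_nmds`: `coords` (samples x dims, named),
#'   `stress`, `stress_path` (best start), `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(d, dims = 2, n_starts = 20, max_iter = 200, tol = 1e-7,
                 seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < dims + 1) abort("need at least dims + 1 samples")
  labels <- rownames(dm) %||% paste0("s", seq_len(n))

  # metric-scaling start; cmdscale may return fewer axes for degenerate d
  x_metric <- cmdscale(dm, k = dims)
  if (ncol(x_metric) < dims) {
    x_metric <- cbind(x_metric,
                      matrix(0, n, dims - ncol(x_metric)))
  }
  starts <- withr::with_seed(split_seed(seed, 10L), {
    c(list(x_metric),
      lapply(seq_len(max(0, n_starts - 1)), function(i)
        matrix(rnorm(n * dims, sd = mean(dm)), n, dims)))
  })

  fits <- lapply(starts, nmds_single_start, diss = dm,
                 max_iter = max_iter, tol = tol)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  coords <- best$coords
  # centre and rotate to principal axes for a reproducible orientation
  coords <- scale(coords, scale = FALSE)
  coords <- coords %*% svd(coords)$v
  dimnames(coords) <- list(labels, paste0("NMDS", seq_len(dims)))

  structure(list(coords = coords, stress = best$stress,
                 stress_path = best$stress_path,
                 converged = best$converged, n_starts = n_starts,
                 seed = seed),
            class = "fwd_nmds")
}

#' @export
print.fwd_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress-1 = %.4g (%s)\n",
              nrow(x$coords), ncol(x$coords), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
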