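# broom-style tidy()/glance() methods for fitted objects.

#' @exportS3Method generics::tidy
tidy.fwd_permanova <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.fwd_permanova <- function(x, ...) {
  tibble::tibble(
    ss_total = x$ss_total, ss_residual = x$ss_res, df_residual = x$df_res,
    n_perm = x$n_perm, permutations = x$permutations, seed = x$seed
  )
}

#' @export
print.fwd_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s permutations, n_perm = %d)\n",
              x$permutations, x$n_perm))
  print(x$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fwd_permtest <- function(x, ...) {
  tibble::tibble(
    test = x$test %||% "permutation",
    statistic = x$statistic,
    p_value = x$p_value,
    n_perm = x$n_perm
  )
}

#' @exportS3Method generics::glance
glance.fwd_permtest <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, seed = x$seed)
}

#' @export
print.fwd_permtest <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (%d permutations)\n",
              x$test %||% "permutation", x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fwd_varpart <- function(x, ...) x$fractions

#' @exportS3Method generics::glance
glance.fwd_varpart <- function(x, ...) {
  tibble::tibble(
    adj_r2_x1 = x$adj_r2_x1, adj_r2_x2 = x$adj_r2_x2,
    adj_r2_both = x$adj_r2_both, n = x$n, n_perm = x$n_perm, seed = x$seed
  )
}

#' @exportS3Method generics::tidy
tidy.fwd_nmds <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$coords), rownames = "sample_id")
}

#' @exportS3Method generics::glance
glance.fwd_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, converged = x$converged,
                 n_starts = x$n_starts, seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.fwd_stock <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.fwd_stock <- function(x, ...) {
  tibble::tibble(total_t_ha = x$total_t_ha, n_plots = x$n_plots)
}
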