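# Resampling and exact tests for group comparisons of overlap and
# interaction summaries.

#' Two-sample permutation t-test
#'
#' Welch-style t statistic, group labels permuted `n_perm` times, two-sided
#' p = (1 + #{|t*| >= |t_obs|}) / (n_perm + 1) — the add-one convention keeps
#' p away from zero at finite n_perm.
#'
#' @param x,y numeric samples (>= 2 each).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return Class `"dyad_test"`: `statistic`, `p.value`, `n_perm`, `method`,
#'   `n` (group sizes), `seed`.
#' @export
permutation_two_sample <- function(x, y, n_perm = 999, seed = NULL) {
  stopifnot(length(x) >= 2, length(y) >= 2, n_perm >= 1)
  if (!is.null(seed)) local_seed(seed)
  t_obs <- welch_t(x, y)
  if (is.na(t_obs)) {  # zero variance in both groups
    t_obs <- 0
    p <- if (mean(x) == mean(y)) 1 else 1 / (n_perm + 1)
    return(new_dyad_test(t_obs, p, "permutation t-test", n_perm,
                         c(length(x), length(y)), seed))
  }
  pool <- sort(c(x, y))  # canonical order: the permutation null is label-free
  nx <- length(x)
  t_star <- replicate(n_perm, {
    idx <- sample.int(length(pool), nx)
    welch_t(pool[idx], pool[-idx])
  })
  t_star[is.na(t_star)] <- 0
  p <- (1 + sum(abs(t_star) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  new_dyad_test(t_obs, p, "permutation t-test", n_perm,
                c(length(x), length(y)), seed)
}

welch_t <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(vx + vy)
}

#' Wilcoxon rank test (grouped or paired)
#'
#' Thin wrapper with the package's result container around the standard
#' rank-sum / signed-rank machinery: exact null for small samples without
#' ties, tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples; equal lengths when `mode = "paired"`.
#' @param mode `"grouped"` (rank-sum) or `"paired"` (signed-rank).
#' @return A `"dyad_test"`.
#' @export
rank_test_paired_or_grouped <- function(x, y, mode = c("grouped", "paired")) {
  mode <- match.arg(mode)
  paired <- mode == "paired"
  if (paired) {
    stopifnot(length(x) == length(y))
    if (all(x == y)) {
      return(new_dyad_test(0, 1, "Wilcoxon signed-rank", NA,
                           c(length(x), length(y)), NULL))
    }
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = NULL, correct = TRUE))
  new_dyad_test(unname(wt$statistic), wt$p.value,
                if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
                NA, c(length(x), length(y)), NULL)
}

#' Fisher exact test for an r x c table
#'
#' Exact hypergeometric enumeration for 2 x 2 tables; Monte Carlo over tables
#' with fixed margins for larger ones (seed-reproducible).
#'
#' @param table non-negative integer matrix (>= 2 x 2).
#' @param n_mc Monte Carlo replicates for tables larger than 2 x 2.
#' @param seed optional integer seed.
#' @return A `"dyad_test"`.
#' @export
fisher_exact_rxc <- function(table, n_mc = 100000, seed = NULL) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: test is degenerate; p = 1")
    return(new_dyad_test(NA_real_, 1, "Fisher exact", NA, dim(table), seed))
  }
  if (!is.null(seed)) local_seed(seed)
  if (all(dim(table) == 2)) {
    ft <- stats::fisher.test(table)
    meth <- "Fisher exact (2x2)"
    np <- NA
  } else {
    ft <- stats::fisher.test(table, simulate.p.value = TRUE, B = n_mc)
    meth <- "Fisher exact (Monte Carlo)"
    np <- n_mc
  }
  new_dyad_test(NA_real_, ft$p.value, meth, np, dim(table), seed)
}

new_dyad_test <- function(statistic, p, method, n_perm, n, seed) {
  structure(list(statistic = statistic, p.value = p, method = method,
                 n_perm = n_perm, n = n, seed = seed),
            class = "dyad_test")
}

#' @export
print.dyad_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat("  statistic:", signif(x$statistic, 4), "\n")
  cat("  p-value:", signif(x$p.value, 4))
  if (!is.na(x$n_perm)) cat("  (", x$n_perm, "resamples )")
  cat("\n  group sizes:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

# Set the RNG seed for the calling function only, restoring the prior state
# on exit so seeded tests do not disturb the session RNG stream.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(seed, .local_envir = env)
  invisible(seed)
}
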