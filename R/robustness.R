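#' Nonparametric bootstrap of edge weights and expected influence
#'
#' Resamples rows with replacement `B` times, re-estimates the full network
#' (Spearman correlations then EBIC-selected graphical lasso) per
#' replicate, and summarises per-edge 95% percentile confidence intervals
#' plus bootstrapped difference tests: two edges (or two nodes' expected
#' influences) differ significantly when the bootstrap CI of their
#' difference excludes zero.
#'
#' @param table data.frame of observations.
#' @param columns node columns (default as in [estimate_network()]).
#' @param B bootstrap replicates (values below 1000 draw a warning when
#'   `warn_small` is TRUE).
#' @param seed integer seed; identical seeds reproduce the report exactly.
#' @param gamma EBIC gamma.
#' @param warn_small warn when `B < 1000`.
#' @return a `bootstrap_report`: list with `edge_ci` (data.frame: edge,
#'   estimate, lower, upper), `edge_diff` and `ei_diff` (logical
#'   significance matrices), `ei_ci`, `B`, `n_failed`, `seed`.
#' @export
bootstrap_edges <- function(table, columns = NULL, B = 1000, seed = 1L,
                            gamma = 0.5, warn_small = TRUE) {
  stopifnot(B >= 100)
  if (warn_small && B < 1000)
    warning("B = ", B, " bootstrap samples (reference analysis used 1000)")
  if (is.null(columns))
    columns <- intersect(.vocanet_vars, names(table))
  full <- estimate_network(table, columns, gamma = gamma)
  p <- length(columns)
  ut <- which(upper.tri(full$weights), arr.ind = TRUE)
  edge_names <- paste(columns[ut[, 1]], columns[ut[, 2]], sep = "--")
  n <- nrow(table)
  set.seed(as.integer(seed))
  boot_w <- matrix(NA_real_, B, nrow(ut))
  boot_ei <- matrix(NA_real_, B, p)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(estimate_network(table[idx, , drop = FALSE], columns,
                                     gamma = gamma),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    boot_w[b, ] <- fit$weights[ut]
    boot_ei[b, ] <- expected_influence(fit)
  }
  if (n_failed > 0.05 * B)
    stop(n_failed, " of ", B, " bootstrap replicates failed to estimate")
  ok <- stats::complete.cases(boot_w)
  qs <- apply(boot_w[ok, , drop = FALSE], 2, quantile, c(0.025, 0.975))
  edge_ci <- data.frame(edge = edge_names, estimate = full$weights[ut],
                        lower = qs[1, ], upper = qs[2, ],
                        stringsAsFactors = FALSE)
  diff_sig <- function(mat) {
    k <- ncol(mat)
    sig <- matrix(FALSE, k, k)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      d <- quantile(mat[ok, a] - mat[ok, b], c(0.025, 0.975))
      sig[a, b] <- sig[b, a] <- d[1] > 0 || d[2] < 0
    }
    sig
  }
  edge_diff <- diff_sig(boot_w)
  dimnames(edge_diff) <- list(edge_names, edge_names)
  ei_diff <- diff_sig(boot_ei)
  dimnames(ei_diff) <- list(columns, columns)
  ei_qs <- apply(boot_ei[ok, , drop = FALSE], 2, quantile, c(0.025, 0.975))
  ei_ci <- data.frame(node = columns, estimate = expected_influence(full),
                      lower = ei_qs[1, ], upper = ei_qs[2, ],
                      stringsAsFactors = FALSE)
  structure(list(edge_ci = edge_ci, edge_diff = edge_diff,
                 ei_diff = ei_diff, ei_ci = ei_ci, network = full,
                 B = B, n_failed = n_failed, seed = as.integer(seed)),
            class = "bootstrap_report")
}

#' Correlation-stability (CS) coefficient by case-dropping bootstrap
#'
#' For each drop proportion, `B` subsamples (without replacement) are
#' re-estimated and the Pearson correlation between the subsample
#' expected-influence vector and the full-sample one is recorded. The CS
#' coefficient is the largest drop proportion whose 5th-percentile
#' correlation is still at least 0.7 (0 when none is). Values above 0.5
#' are conventionally considered stable; below 0.25, unstable.
#'
#' @param table data.frame of observations.
#' @param columns node columns.
#' @param drops drop-proportion grid.
#' @param B subsamples per drop proportion.
#' @param seed integer seed.
#' @param gamma EBIC gamma.
#' @param cor_threshold correlation retained with 95% certainty (0.7).
#' @return a `cs_report`: list with `cs_coefficient`, `cs_curve`
#'   (data.frame: drop, q05, median, q95, n_failed), `stability_flag`
#'   (`"stable"`, `"moderate"`, `"unstable"`), `seed`.
#' @export
cs_coefficient <- function(table, columns = NULL,
                           drops = seq(0.05, 0.75, by = 0.05), B = 1000,
                           seed = 1L, gamma = 0.5, cor_threshold = 0.7) {
  if (is.null(columns))
    columns <- intersect(.vocanet_vars, names(table))
  n <- nrow(table)
  p <- length(columns)
  if (round((1 - max(drops)) * n) < 3 * p)
    warning("largest drop proportion leaves fewer than 3p rows")
  full <- estimate_network(table, columns, gamma = gamma)
  ei_full <- expected_influence(full)
  set.seed(as.integer(seed))
  curve <- lapply(drops, function(d) {
    m <- round((1 - d) * n)
    cors <- numeric(B)
    failed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      fit <- tryCatch(estimate_network(table[idx, , drop = FALSE], columns,
                                       gamma = gamma),
                      error = function(e) NULL)
      if (is.null(fit)) {
        failed <- failed + 1L
        cors[b] <- -Inf      # counted as failing the threshold
        next
      }
      ei <- expected_influence(fit)
      r <- suppressWarnings(cor(ei, ei_full))
      cors[b] <- if (is.na(r)) -Inf else r
    }
    data.frame(drop = d,
               q05 = quantile(cors, 0.05),
               median = median(cors),
               q95 = quantile(cors, 0.95),
               n_failed = failed)
  })
  curve <- do.call(rbind, curve)
  passing <- curve$drop[curve$q05 >= cor_threshold]
  cs <- if (length(passing) > 0) max(passing) else 0
  flag <- if (cs > 0.5) "stable" else if (cs >= 0.25) "moderate" else
    "unstable"
  structure(list(cs_coefficient = cs, cs_curve = curve,
                 stability_flag = flag, seed = as.integer(seed)),
            class = "cs_report")
}
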