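#' Spearman correlation matrix of a feature table
#'
#' Pairwise Spearman rank correlations (average ranks for ties) on the
#' listwise-complete rows. If the result is not positive definite it is
#' repaired by clipping eigenvalues at `1e-6` and renormalizing to unit
#' diagonal; repaired matrices carry attribute `pd_repaired = TRUE`.
#'
#' @param table data.frame of observations.
#' @param columns columns to use (default: all numeric columns).
#' @return a `correlation_matrix`: list with `matrix`, `labels`, `n`.
#' @export
spearman_matrix <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- table[, columns, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("fewer than 3 complete rows after listwise deletion")
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const))
    stop("constant column(s): ", paste(columns[const], collapse = ", "))
  S <- cor(as.matrix(x), method = "spearman")
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    lam <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    repaired <- TRUE
  }
  structure(list(matrix = S, labels = columns, n = nrow(x),
                 pd_repaired = repaired), class = "correlation_matrix")
}

#' Graphical lasso at a fixed penalty
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` (diagonal
#' unpenalized) by blockwise coordinate descent.
#'
#' @param S a `correlation_matrix` or plain symmetric matrix.
#' @param lambda penalty (>= 0).
#' @param tol convergence tolerance on the estimated covariance updates,
#'   relative to the mean absolute off-diagonal of `S`.
#' @param maxit maximum outer sweeps.
#' @return list with `w` (estimated covariance), `wi` (precision matrix
#'   `K`), `lambda`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-8, maxit = 1000) {
  M <- if (inherits(S, "correlation_matrix")) S$matrix else S
  stopifnot(is.matrix(M), nrow(M) == ncol(M), lambda >= 0)
  res <- .glasso_cpp(M, lambda, tol, maxit)
  if (!res$converged)
    stop("graphical lasso failed to converge at lambda = ", lambda,
         " within ", maxit, " sweeps")
  dimnames(res$w) <- dimnames(res$wi) <- dimnames(M)
  list(w = res$w, wi = res$wi, lambda = lambda)
}

#' Partial correlations from a precision matrix
#'
#' `w_ij = -K_ij / sqrt(K_ii * K_jj)`, diagonal set to zero. Exact zeros in
#' `K` stay exactly zero.
#'
#' @param K precision matrix (or a `precision_matrix` from
#'   [build_precision()]); must be positive definite.
#' @return symmetric partial-correlation matrix with zero diagonal.
#' @export
precision_to_pcor <- function(K) {
  if (inherits(K, "precision_matrix")) {
    lab <- K$labels
    K <- K$matrix
    dimnames(K) <- list(lab, lab)
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite")
  d <- sqrt(diag(K))
  W <- -K / outer(d, d)
  diag(W) <- 0
  W
}

#' EBIC-selected graphical-lasso network
#'
#' Fits the graphical lasso along a log-spaced penalty path from
#' `lambda_max` (the largest absolute off-diagonal of `S`, giving an empty
#' graph) down to `lambda_max * lambda_min_ratio`, scores each fit with
#' `EBIC_gamma = -2 l + E log n + 4 E gamma log p` where
#' `l = (n/2)(log det K - tr(SK))` and `E` is the number of nonzero edges,
#' and returns the minimizer as a partial-correlation network.
#'
#' @param S a `correlation_matrix` from [spearman_matrix()] (or a plain
#'   matrix, in which case `n` must be given).
#' @param n sample size behind `S`.
#' @param gamma EBIC hyperparameter; 0.5 is edge-conservative.
#' @param n_lambdas path length.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @return a `network_model`: list with `labels`, `weights` (partial
#'   correlations, zero diagonal), `precision`, `lambda_selected`, `gamma`,
#'   `ebic_path` (data.frame of lambda, edge count, log-likelihood, EBIC),
#'   and `n`.
#' @export
ebic_select <- function(S, n = NULL, gamma = 0.5, n_lambdas = 100,
                        lambda_min_ratio = 0.01) {
  if (inherits(S, "correlation_matrix")) {
    if (is.null(n)) n <- S$n
    labels <- S$labels
    M <- S$matrix
  } else {
    stopifnot(!is.null(n))
    M <- S
    labels <- colnames(M)
    if (is.null(labels)) labels <- paste0("V", seq_len(ncol(M)))
  }
  p <- ncol(M)
  if (n < p + 1) warning("n (", n, ") < p + 1: estimates may be unstable")
  lam_max <- max(abs(M[upper.tri(M)]))
  if (lam_max <= 0) lam_max <- 0.1
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambdas))
  res <- .ebic_path_cpp(M, n, gamma, lambdas)
  K <- res$wi
  dimnames(K) <- list(labels, labels)
  W <- precision_to_pcor(K)
  structure(list(labels = labels, weights = W, precision = K,
                 lambda_selected = lambdas[res$best_index], gamma = gamma,
                 ebic_path = data.frame(lambda = lambdas,
                                        n_edges = as.integer(res$ecount),
                                        loglik = res$loglik,
                                        ebic = res$ebic),
                 n = n), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("network_model: %d nodes, %d edges (lambda = %.4g, gamma = %.2g, n = %d)\n",
              length(x$labels), E, x$lambda_selected, x$gamma, x$n))
  invisible(x)
}

#' Estimate a network from a feature table
#'
#' Convenience wrapper: [spearman_matrix()] then [ebic_select()].
#'
#' @param table data.frame of observations.
#' @param columns node columns (default: the five acoustic parameters plus
#'   `anxiety` when present).
#' @param gamma,n_lambdas,lambda_min_ratio passed to [ebic_select()].
#' @return a `network_model`.
#' @export
estimate_network <- function(table, columns = NULL, gamma = 0.5,
                             n_lambdas = 100, lambda_min_ratio = 0.01) {
  if (is.null(columns))
    columns <- intersect(.vocanet_vars, names(table))
  S <- spearman_matrix(table, columns)
  ebic_select(S, gamma = gamma, n_lambdas = n_lambdas,
              lambda_min_ratio = lambda_min_ratio)
}

#' Expected influence
#'
#' One-step expected influence: the signed sum of all edge weights incident
#' to each node.
#'
#' @param W a `network_model` or a symmetric weight matrix with zero
#'   diagonal.
#' @return named numeric vector of per-node expected influence.
#' @export
expected_influence <- function(W) {
  if (inherits(W, "network_model")) W <- W$weights
  stopifnot(is.matrix(W), all(abs(diag(W)) < 1e-12))
  colSums(W)
}

#' Node-redundancy screen
#'
#' Flags a node pair as redundant when its zero-order Spearman correlation
#' is at least `r_min` in magnitude and fewer than `prop_max` of the
#' remaining nodes correlate significantly differently with the two (a
#' dependent-correlation z-test with common index; Steiger's method by
#' default, the Hittner back-transformed variant as option).
#'
#' @param table data.frame of observations.
#' @param columns node columns (default: all numeric).
#' @param r_min minimum absolute zero-order correlation.
#' @param prop_max maximum proportion of significantly different profiles.
#' @param alpha significance level of the dependent-correlation test.
#' @param method `"steiger"` or `"hittner"`.
#' @return a `redundancy_report`: data.frame of candidate pairs with their
#'   correlation, proportion of differing profiles, and a `redundant` flag;
#'   attribute `untestable` is TRUE when n is too small for the z-test.
#' @export
goldbricker <- function(table, columns = NULL, r_min = 0.50,
                        prop_max = 0.25, alpha = 0.05,
                        method = c("steiger", "hittner")) {
  method <- match.arg(method)
  if (is.null(columns))
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(columns) < 4) stop("redundancy screen needs at least 4 columns")
  x <- table[, columns, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  S <- cor(as.matrix(x), method = "spearman")
  p <- ncol(S)
  pairs <- which(upper.tri(S), arr.ind = TRUE)
  out <- data.frame(node_i = columns[pairs[, 1]],
                    node_j = columns[pairs[, 2]],
                    r = S[pairs], prop_diff = NA_real_,
                    redundant = FALSE, stringsAsFactors = FALSE)
  untestable <- n < 4 || n - 3 <= 0
  if (!untestable) {
    for (k in seq_len(nrow(out))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (abs(S[i, j]) < r_min) next
      others <- setdiff(seq_len(p), c(i, j))
      pv <- vapply(others, function(h) {
        .dependent_cor_test(S[i, h], S[j, h], S[i, j], n, method)
      }, numeric(1))
      out$prop_diff[k] <- mean(pv < alpha)
      out$redundant[k] <- out$prop_diff[k] < prop_max
    }
  }
  structure(out, untestable = untestable, class = c("redundancy_report",
                                                    class(out)))
}

# two-sided p for H0: rho_1h = rho_2h (dependent correlations sharing h),
# Steiger (common-index) z; "hittner" uses the back-transformed mean r
.dependent_cor_test <- function(r1, r2, r12, n, method = "steiger") {
  if (n <= 3) return(NA_real_)
  clip <- function(r) pmin(0.999999, pmax(-0.999999, r))
  r1 <- clip(r1); r2 <- clip(r2); r12 <- clip(r12)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rm <- if (method == "hittner") tanh((z1 + z2) / 2) else (r1 + r2) / 2
  rm2 <- rm^2
  cov <- (r12 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r12^2)) /
    (1 - rm2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov))
  2 * stats::pnorm(-abs(z))
}

#' Fruchterman-Reingold network layout
#'
#' Force-directed 2-D coordinates with absolute edge weights as attraction
#' strengths; deterministic under a fixed seed. Coordinates are centered on
#' the origin.
#'
#' @param W a `network_model` or symmetric weight matrix.
#' @param seed integer seed.
#' @param iterations FR iterations.
#' @return matrix of coordinates (nodes x 2), row names = labels.
#' @export
fr_layout <- function(W, seed = 1L, iterations = 500L) {
  if (inherits(W, "network_model")) W <- W$weights
  p <- nrow(W)
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  if (p == 1) {
    xy <- matrix(0, 1, 2, dimnames = list(labels, c("x", "y")))
    return(xy)
  }
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(as.integer(seed))
  xy <- igraph::layout_with_fr(g, niter = as.integer(iterations),
                               weights = igraph::E(g)$weight)
  xy <- scale(xy, scale = FALSE)
  dimnames(xy) <- list(labels, c("x", "y"))
  xy[, , drop = FALSE]
}
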