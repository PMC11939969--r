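#' Permutation network comparison test
#'
#' Estimates one network per group (Spearman + EBIC graphical lasso) and
#' compares them on (1) the global expected-influence difference
#' `S = |sum w_A - sum w_B|` over unique edges, (2) the maximum and
#' individual edge-weight differences, and (3) per-node expected-influence
#' differences. Group labels are then permuted `P` times (group sizes
#' preserved), both networks re-estimated per permutation, and each
#' statistic's p-value computed with the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + P)`.
#'
#' @param table_a,table_b data.frames with identical node columns.
#' @param columns node columns; the default uses the five acoustic
#'   parameters only (set `include_anxiety = TRUE` to add the rating node).
#' @param P permutations.
#' @param seed integer seed.
#' @param gamma EBIC gamma.
#' @param include_anxiety include the `anxiety` node (default FALSE: group
#'   networks are compared on the speech indicators).
#' @return a `comparison_result`: list with `global` (per-group summed edge
#'   weights, observed `S`, `p`), `max_edge` (observed `M`, `p`),
#'   `edges` (data.frame: edge, weight in each group, difference, p),
#'   `nodes` (data.frame: node, expected influence in each group,
#'   difference, p), `P`, `n_failed`, `seed`.
#' @export
nct <- function(table_a, table_b, columns = NULL, P = 1000, seed = 1L,
                gamma = 0.5, include_anxiety = FALSE) {
  if (is.null(columns)) {
    columns <- intersect(.vocanet_speech_vars, names(table_a))
    if (include_anxiety) columns <- c("anxiety", columns)
  }
  stopifnot(all(columns %in% names(table_a)),
            all(columns %in% names(table_b)))
  p <- length(columns)
  na <- nrow(table_a); nb <- nrow(table_b)
  if (na < 3 * p || nb < 3 * p)
    stop("each group needs at least 3p rows (p = ", p, ")")
  fit <- function(tab) estimate_network(tab, columns, gamma = gamma)
  stats_of <- function(wa, wb) {
    ut <- upper.tri(wa)
    list(global = abs(sum(wa[ut]) - sum(wb[ut])),
         max_edge = max(abs(wa - wb)),
         edges = abs(wa[ut] - wb[ut]),
         nodes = abs(colSums(wa) - colSums(wb)))
  }
  net_a <- fit(table_a)
  net_b <- fit(table_b)
  obs <- stats_of(net_a$weights, net_b$weights)
  pooled <- rbind(table_a[, columns, drop = FALSE],
                  table_b[, columns, drop = FALSE])
  set.seed(as.integer(seed))
  ge_global <- ge_max <- 0L
  ge_edges <- numeric(length(obs$edges))
  ge_nodes <- numeric(p)
  n_failed <- 0L
  for (b in seq_len(P)) {
    idx <- sample.int(na + nb, na)
    perm <- tryCatch({
      fa <- fit(pooled[idx, , drop = FALSE])
      fb <- fit(pooled[-idx, , drop = FALSE])
      stats_of(fa$weights, fb$weights)
    }, error = function(e) NULL)
    if (is.null(perm)) {
      n_failed <- n_failed + 1L
      next
    }
    ge_global <- ge_global + (perm$global >= obs$global)
    ge_max <- ge_max + (perm$max_edge >= obs$max_edge)
    ge_edges <- ge_edges + (perm$edges >= obs$edges)
    ge_nodes <- ge_nodes + (perm$nodes >= obs$nodes)
  }
  if (n_failed > 0.05 * P)
    stop(n_failed, " of ", P, " permutations failed to estimate")
  P_eff <- P - n_failed
  pval <- function(ge) (1 + ge) / (1 + P_eff)
  ut <- which(upper.tri(net_a$weights), arr.ind = TRUE)
  edge_names <- paste(columns[ut[, 1]], columns[ut[, 2]], sep = "--")
  structure(list(
    global = list(sum_a = sum(net_a$weights[upper.tri(net_a$weights)]),
                  sum_b = sum(net_b$weights[upper.tri(net_b$weights)]),
                  S = obs$global, p = pval(ge_global)),
    max_edge = list(M = obs$max_edge, p = pval(ge_max)),
    edges = data.frame(edge = edge_names,
                       weight_a = net_a$weights[upper.tri(net_a$weights)],
                       weight_b = net_b$weights[upper.tri(net_b$weights)],
                       diff = obs$edges, p = pval(ge_edges),
                       stringsAsFactors = FALSE),
    nodes = data.frame(node = columns,
                       ei_a = expected_influence(net_a),
                       ei_b = expected_influence(net_b),
                       diff = obs$nodes, p = pval(ge_nodes),
                       stringsAsFactors = FALSE),
    network_a = net_a, network_b = net_b,
    P = P, n_failed = n_failed, seed = as.integer(seed)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "network comparison test (P = %d permutations)\nglobal expected influence: group A = %.2f; group B = %.2f; S = %.2f, p = %.2f\n",
    x$P, x$global$sum_a, x$global$sum_b, x$global$S, x$global$p))
  cat(sprintf("maximum edge difference: M = %.3f, p = %.2f\n",
              x$max_edge$M, x$max_edge$p))
  sig <- x$edges[x$edges$p <= 0.05, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("edges differing at alpha = 0.05:\n")
    for (k in seq_len(nrow(sig)))
      cat(sprintf("  %s (p = %.2f)\n", sig$edge[k], sig$p[k]))
  } else {
    cat("no individual edge differs at alpha = 0.05\n")
  }
  invisible(x)
}
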