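# shared fixtures: small feature tables and the speech-variable set
speech_vars <- c("jitter", "f0", "f1f2", "intensity", "speech_rate")

ref_marginals <- function(which = "total") {
  t1 <- table1_reference()
  m <- t1[[paste0("mean_", which)]][match(speech_vars, t1$variable)]
  s <- t1[[paste0("sd_", which)]][match(speech_vars, t1$variable)]
  list(means = stats::setNames(m, speech_vars),
       sds = stats::setNames(s, speech_vars))
}

# independent-columns spec (empty planted graph)
null_spec <- function(n = 300) {
  mg <- ref_marginals()
  group_spec("null", n, mg$means, mg$sds, list(), c(0.25, 0.25, 0.25, 0.25))
}

# total-network spec: 6 nodes, study topology and rating mix
total_spec <- function(n = 316) {
  mg <- ref_marginals()
  group_spec("total", n, mg$means, mg$sds, study_edges("total"),
             c(0.30 * 119, 0.70 * 119, 0.49 * 197, 0.51 * 197) / 316)
}

# objective value of the glasso problem (diagonal unpenalized)
glasso_objective <- function(K, S, lambda) {
  determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K) -
    lambda * sum(abs(K - diag(diag(K))))
}

# independent oracle: iterated coordinate grid search over symmetric PD K
# (p = 3), refining each free entry on a shrinking 1-D grid
grid_search_glasso <- function(S, lambda, sweeps = 60) {
  p <- nrow(S)
  K <- diag(1 / diag(S))
  idx <- rbind(cbind(seq_len(p), seq_len(p)),
               which(upper.tri(S), arr.ind = TRUE))
  radius <- 1
  for (s in seq_len(sweeps)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      grid <- K[i, j] + seq(-radius, radius, length.out = 21)
      best <- -Inf; bestv <- K[i, j]
      for (v in grid) {
        Kt <- K
        Kt[i, j] <- Kt[j, i] <- v
        ev <- eigen(Kt, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 1e-10) next
        o <- glasso_objective(Kt, S, lambda)
        if (o > best) { best <- o; bestv <- v }
      }
      K[i, j] <- K[j, i] <- bestv
    }
    radius <- radius * 0.7
  }
  K
}
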