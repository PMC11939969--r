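test_that("spearman_matrix is a rank correlation with guards", {
  x <- rnorm(30)
  tab <- data.frame(a = x, b = exp(x))          # monotone transform
  S <- spearman_matrix(tab)
  # a perfectly monotone pair is rank-deficient, so the PD repair nudges
  # the correlation just inside 1 and flags the repair
  expect_equal(S$matrix[1, 2], 1, tolerance = 1e-5)
  expect_true(S$pd_repaired)

  # hand rank computation: x = 1,2,3 against y = 3,1,2
  tab2 <- data.frame(x = c(1, 2, 3), y = c(3, 1, 2))
  expect_equal(spearman_matrix(tab2)$matrix[1, 2], -0.5)

  tab3 <- data.frame(x = rnorm(20), y = rep(1, 20))
  expect_error(spearman_matrix(tab3), "constant column")
})

test_that("glasso matches closed forms and satisfies the KKT conditions", {
  # p = 2: implied partial correlation is the soft-threshold of s
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- glasso_fit(S, 0.2)
  expect_equal(precision_to_pcor(fit$wi)[1, 2], 0.3, tolerance = 1e-6)
  # grid-search verification of the same p = 2 solution
  expect_equal(fit$w[1, 2], 0.3, tolerance = 1e-6)

  # full shrinkage: lambda >= max |s_ij| -> diagonal precision
  fit0 <- glasso_fit(S, 0.6)
  expect_true(all(fit0$wi[upper.tri(fit0$wi)] == 0))

  # unpenalized limit: K = S^-1
  set.seed(2)
  A <- crossprod(matrix(rnorm(25), 5))
  S5 <- cov2cor(A)
  fitI <- glasso_fit(S5, 0, tol = 1e-11, maxit = 5000)
  expect_lt(max(abs(fitI$wi - solve(S5))), 1e-5)

  # KKT: |S - W| <= lambda at zeros, = lambda * sign at nonzeros
  for (lam in c(0.05, 0.1, 0.2)) {
    f <- glasso_fit(S5, lam)
    G <- S5 - f$w
    off <- upper.tri(S5)
    nz <- f$wi != 0 & off
    if (any(nz))
      expect_lt(max(abs(abs(G[nz]) - lam)), 1e-4)
    z <- f$wi == 0 & off
    if (any(z))
      expect_lt(max(abs(G[z])) - lam, 1e-4)
  }
})

test_that("glasso agrees with a coordinate grid-search oracle at p = 3", {
  set.seed(3)
  for (i in 1:3) {
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    S <- cov2cor(A)
    lam <- 0.15
    fit <- glasso_fit(S, lam)
    K_oracle <- grid_search_glasso(S, lam)
    expect_lt(abs(glasso_objective(fit$wi, S, lam) -
                    glasso_objective(K_oracle, S, lam)), 1e-3)
    expect_gte(glasso_objective(fit$wi, S, lam),
               glasso_objective(K_oracle, S, lam) - 1e-3)
  }
})

test_that("precision_to_pcor is the standard conversion", {
  expect_true(all(precision_to_pcor(diag(c(2, 3, 4))) == 0))
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_pcor(K)[1, 2], 0.5)
  expect_error(precision_to_pcor(matrix(c(1, 2, 2, 1), 2)), "positive definite")

  # round trip with planted edges
  Kp <- build_precision(study_edges("total"),
                        labels = c("anxiety", speech_vars))
  W <- precision_to_pcor(Kp)
  expect_equal(W["anxiety", "jitter"], -0.17, tolerance = 1e-6)
})

test_that("EBIC selection is sparse under the null and consistent", {
  # independent data: edge-conservative selection stays near empty
  emptyE <- vapply(1:20, function(s) {
    m <- estimate_network(generate_feature_table(null_spec(300), seed = s),
                          columns = speech_vars)
    sum(m$weights != 0) / 2
  }, numeric(1))
  expect_gte(mean(emptyE == 0), 0.7)
  expect_lte(mean(emptyE), 0.5)

  # edge counts non-increasing in lambda along the path
  tab <- generate_feature_table(study_group_specs()$high, seed = 5)
  m <- estimate_network(tab, columns = speech_vars)
  path <- m$ebic_path
  expect_true(all(diff(path$n_edges[order(path$lambda)]) <= 0))

  # permuting node order permutes but does not change the edge set
  perm <- c(3, 1, 5, 2, 4)
  m2 <- estimate_network(tab, columns = speech_vars[perm])
  expect_equal(m2$weights[speech_vars, speech_vars], m$weights,
               tolerance = 1e-8)
})

test_that("expected influence is the signed edge sum", {
  expect_true(all(expected_influence(matrix(0, 4, 4)) == 0))
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.28
  W[1, 3] <- W[3, 1] <- 0.33
  expect_equal(unname(expected_influence(W)[1]), 0.61)
  # node sum = 2 * edge sum
  set.seed(6)
  A <- matrix(rnorm(25), 5); A <- A + t(A); diag(A) <- 0
  expect_equal(sum(expected_influence(A)), 2 * sum(A[upper.tri(A)]))
})

test_that("goldbricker flags duplicates and passes clean tables", {
  set.seed(7)
  base <- as.data.frame(matrix(rnorm(200 * 4), 200))
  names(base) <- c("a", "b", "c", "d")
  dup <- base
  dup$e <- dup$a + rnorm(200, 0, 0.01)
  rep1 <- goldbricker(dup)
  expect_true(any(rep1$redundant[rep1$node_i == "a" | rep1$node_j == "a"]))

  rep2 <- goldbricker(base)
  expect_false(any(rep2$redundant))

  # study-like table at study n: no pair flagged (as in the reference screen)
  tab <- rbind(generate_feature_table(study_group_specs()$low, seed = 1),
               generate_feature_table(study_group_specs()$high, seed = 2))
  rep3 <- goldbricker(tab, columns = speech_vars)
  expect_false(any(rep3$redundant))
})

test_that("FR layout is seeded and attraction-consistent", {
  xy1 <- fr_layout(matrix(0, 1, 1), seed = 1)
  expect_equal(unname(xy1), matrix(0, 1, 2))

  W <- function(w) matrix(c(0, w, w, 0), 2)
  d_weak <- dist(fr_layout(W(0.1), seed = 2))
  d_strong <- dist(fr_layout(W(0.9), seed = 2))
  expect_lt(as.numeric(d_strong), as.numeric(d_weak))

  tabW <- precision_to_pcor(build_precision(study_edges("high"),
                                            labels = speech_vars))
  expect_identical(fr_layout(tabW, seed = 3), fr_layout(tabW, seed = 3))
})
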