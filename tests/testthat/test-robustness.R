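test_that("bootstrap reports are seed-deterministic and cover sanely", {
  tab <- generate_feature_table(study_group_specs()$high, seed = 9)
  r1 <- suppressWarnings(bootstrap_edges(tab, speech_vars, B = 100, seed = 5))
  r2 <- suppressWarnings(bootstrap_edges(tab, speech_vars, B = 100, seed = 5))
  expect_identical(r1$edge_ci, r2$edge_ci)
  expect_identical(r1$edge_diff, r2$edge_diff)

  # CI brackets the point estimates for (nearly) all edges
  ok <- with(r1$edge_ci, lower <= estimate + 1e-12 &
               estimate <= upper + 1e-12)
  expect_gte(mean(ok), 0.95)

  expect_error(suppressWarnings(bootstrap_edges(tab, speech_vars, B = 50)),
               "B >= 100")
})

test_that("a strong planted edge is bootstrap-significant, null edges are not", {
  mg <- ref_marginals()
  sp <- group_spec("strong", 500, mg$means, mg$sds,
                   list(list("jitter", "f0", 0.6)), c(0.25, 0.25, 0.25, 0.25))
  hits <- vapply(1:20, function(m) {
    tab <- generate_feature_table(sp, seed = 100 + m)
    r <- suppressWarnings(bootstrap_edges(tab, speech_vars, B = 200,
                                          seed = m))
    ci <- r$edge_ci[r$edge_ci$edge == "jitter--f0", ]
    ci$lower > 0 || ci$upper < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # independent data: at least 95% of edge CIs cover zero
  tab0 <- generate_feature_table(null_spec(300), seed = 77)
  r0 <- suppressWarnings(bootstrap_edges(tab0, speech_vars, B = 200,
                                         seed = 1))
  covers <- with(r0$edge_ci, lower <= 0 & upper >= 0)
  expect_gte(mean(covers), 0.95)
})

test_that("CS coefficient sits on its grid and responds to signal", {
  tab <- generate_feature_table(study_group_specs()$high, seed = 13)
  cs <- suppressWarnings(cs_coefficient(tab, speech_vars, B = 40, seed = 3))
  expect_true(cs$cs_coefficient %in% c(0, seq(0.05, 0.75, 0.05)))
  expect_identical(
    cs$cs_curve,
    suppressWarnings(cs_coefficient(tab, speech_vars, B = 40,
                                    seed = 3))$cs_curve)
  expect_true(cs$stability_flag %in% c("stable", "moderate", "unstable"))

  # stability is non-decreasing in n on the same planted network
  sp <- study_group_specs()$high
  sp$n <- 150L
  t_small <- generate_feature_table(sp, seed = 21)
  sp$n <- 600L
  t_big <- generate_feature_table(sp, seed = 21)
  cs_small <- suppressWarnings(
    cs_coefficient(t_small, speech_vars, B = 40, seed = 2))$cs_coefficient
  cs_big <- suppressWarnings(
    cs_coefficient(t_big, speech_vars, B = 40, seed = 2))$cs_coefficient
  expect_gte(cs_big, cs_small)
})
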