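test_that("lognormal quartile fits reproduce printed summaries", {
  fit <- fit_lognormal_from_quartiles(4.24, 1.69, 7.52)
  expect_equal(unname(fit), c(1.4446, 1.1068), tolerance = 1e-4)

  expect_equal(unname(fit_lognormal_from_quartiles(1, 1, 1)), c(0, 0))
  expect_error(fit_lognormal_from_quartiles(0, -1, 2), "positive")

  fit2 <- fit_lognormal_from_quartiles(2, 1, 4)
  expect_equal(unname(fit2["sigma"]), log(4) / 1.34898, tolerance = 1e-5)
  # symmetric-in-log case: sampled quartiles recover (1, 2, 4) within 1%
  set.seed(1)
  qs <- quantile(rlnorm(1e6, fit2["mu"], fit2["sigma"]), c(.25, .5, .75))
  expect_equal(unname(qs), c(1, 2, 4), tolerance = 0.01)
})

test_that("group generation matches the spec marginals and edge cases", {
  specs <- cohort_summary_specs("nhanes", quiet = TRUE)
  cfg <- generator_config(seed = 21)
  tab <- generate_group(specs["crp"], "psa", 50000, cfg)
  expect_equal(median(tab$crp), 4.24, tolerance = 0.03)

  expect_equal(nrow(generate_group(specs["crp"], "psa", 0, cfg)), 0)

  point <- variable_spec("flat", "serum", "lognormal",
                         list(pso = c(median = 2, q1 = 2, q3 = 2)))
  flat <- generate_group(list(point), "pso", 100, cfg)
  expect_true(all(flat$flat == 2))

  expect_error(generate_group(specs["crp"], "psa", 5,
                              generator_config()) -> ok, NA)
  expect_error(
    generate_group(list(variable_spec("x", "serum", "normal",
                                      list(pso = c(1, 1)))), "psa", 5, cfg),
    "no parameters")
})

test_that("study generation honours sizes, labels and determinism", {
  st <- generate_study(generator_config(seed = 4))
  expect_equal(nrow(st$nhanes_like), 719)
  expect_equal(nrow(st$chinese_like), 135)
  expect_equal(sum(st$nhanes_like$label), 145)
  expect_equal(sum(st$chinese_like$label), 37)

  st2 <- generate_study(generator_config(seed = 4))
  expect_identical(st, st2)

  small <- generate_study(generator_config(
    nhanes_n = c(pso = 10, psa = 5), chinese_n = c(pso = 4, psa = 2),
    seed = 4))
  expect_equal(nrow(small$nhanes_like), 15)
  expect_equal(nrow(small$chinese_like), 6)

  # generated counts, percentages and CRP strictly positive; pct <= 100
  nh <- st$nhanes_like
  expect_true(all(nh$crp > 0) && all(nh$neutrophil_count > 0))
  pcts <- c("lymphocyte_pct", "neutrophil_pct", "monocyte_pct",
            "eosinophil_pct", "basophil_pct", "hematocrit")
  for (v in pcts) expect_true(all(nh[[v]] > 0 & nh[[v]] <= 100))
})

test_that("gaussian copula induces the requested dependence", {
  specs <- cohort_summary_specs("nhanes", quiet = TRUE)[c("crp",
                                                  "neutrophil_count")]
  R <- matrix(c(1, 0.6, 0.6, 1), 2,
              dimnames = list(c("crp", "neutrophil_count"),
                              c("crp", "neutrophil_count")))
  cfg <- generator_config(dependence = "gaussian-copula", rank_cor = R,
                          seed = 31)
  tab <- generate_group(specs, "pso", 20000, cfg)
  expect_equal(cor(tab$crp, tab$neutrophil_count, method = "spearman"),
               0.6, tolerance = 0.03)
  # marginals preserved under the copula
  expect_equal(median(tab$crp), 0.43, tolerance = 0.03)

  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(generator_config(dependence = "gaussian-copula",
                                rank_cor = bad), "semi-definite")
})

test_that("missingness injection is binomial at the requested rate", {
  tab <- toy_cohort(n = 1000)
  for (extra in paste0("v", 1:16)) tab[[extra]] <- rnorm(1000)

  out0 <- inject_missingness(tab, 0, seed = 1)
  expect_identical(out0$table, tab)
  expect_equal(sum(out0$mask), 0)

  out <- inject_missingness(tab, 0.05, seed = 2)
  n_cells <- 1000 * 20
  expected <- n_cells * 0.05
  sd3 <- 3 * sqrt(n_cells * 0.05 * 0.95)
  expect_lt(abs(sum(out$mask) - expected), sd3)
  expect_equal(sum(is.na(out$table[cohort_variables(tab)])), sum(out$mask))

  expect_error(inject_missingness(tab, 0.4, seed = 1), "1/3")
})

test_that("log-PSAII of lognormal components is normal with summed moments", {
  # analytic cross-check: under independence, log PSAII = log lymph% +
  # log CRP - log neut - log eos - log 10, a sum of normals
  specs <- cohort_summary_specs("nhanes", quiet = TRUE,
                        lognormal_method = "symmetric")
  comp <- c("lymphocyte_pct", "crp", "neutrophil_count", "eosinophil_count")
  fits <- lapply(comp, function(v) {
    p <- specs[[v]]$params$psa
    fit_lognormal_from_quartiles(p[1], p[2], p[3])
  })
  mu <- fits[[1]]["mu"] + fits[[2]]["mu"] - fits[[3]]["mu"] -
    fits[[4]]["mu"] - log(10)
  sg <- sqrt(sum(vapply(fits, function(f) f[["sigma"]]^2, 0)))
  tab <- generate_group(specs[comp], "psa", 50000,
                        generator_config(seed = 41))
  lp <- log(compute_index(index_catalogue()$PSAII, tab))
  expect_equal(mean(lp), unname(mu), tolerance = 0.02)
  expect_equal(sd(lp), unname(sg), tolerance = 0.02)
  expect_gt(shapiro.test(sample(lp, 3000))$p.value, 1e-4)
})
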