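test_that("CSV loading round-trips, enforces schema and preserves gaps", {
  d <- data.frame(subject_id = 1:3, label = c(0, 1, 0),
                  crp = c(0.4, 4.2, NA), age = c(40, 55, 60))
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  tab <- load_cohort(f, schema = c("crp", "age"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$crp, d$crp)
  expect_equal(sum(is.na(tab$crp)), 1)

  no_label <- tempfile(fileext = ".csv")
  write.csv(d[setdiff(names(d), "label")], no_label, row.names = FALSE)
  expect_error(load_cohort(no_label, schema = c("crp", "age")), "label")

  expect_warning(load_cohort(f, schema = "crp"), "unknown column")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("label,crp", "0,1.2", "1,3 .4"), bad)
  expect_error(load_cohort(bad, schema = "crp"), "parse error")
})

test_that("categorical encoding follows the documented codes and decodes back", {
  tab <- data.frame(subject_id = 1:3, label = c(0, 1, 0),
                    gender = c("male", "female", "male"),
                    smoking = c("no", "yes", "no"),
                    race = c("Non-Hispanic Black", "Mexican American",
                             "Other"),
                    rash_range = c("Little or no psoriasis",
                                   "Extensive psoriasis",
                                   "Only a few patches"),
                    stringsAsFactors = FALSE)
  enc <- encode_categories(tab)
  expect_equal(enc$gender, c(1, 0, 1))
  expect_equal(enc$smoking, c(0, 1, 0))
  expect_equal(enc$race, c(4, 1, 5))
  expect_equal(enc$rash_range, c(1, 4, 2))

  expect_error(encode_categories(
    data.frame(label = 0, gender = "unknown_token")), "unknown_token")

  # bijection on every documented vocabulary
  for (v in c("gender", "race", "rash_range", "education", "smoking")) {
    book <- category_codebook()
    cls <- switch(v, gender = "sex", race = "race",
                  rash_range = "rash_range", education = "education",
                  "yesno")
    tokens <- names(book[[cls]])
    df <- data.frame(label = rep(0, length(tokens)), x = tokens,
                     stringsAsFactors = FALSE)
    names(df)[2] <- v
    expect_equal(decode_categories(encode_categories(df)[[v]], v), tokens)
  }
})

test_that("imputation is a seeded no-op-preserving chained forest", {
  full <- toy_cohort(n = 40)
  expect_identical(impute_missing(full, seed = 1), full)

  inj <- inject_missingness(full, rate = 0.1, seed = 3)
  imp1 <- suppressMessages(impute_missing(inj$table, seed = 9, ntree = 50))
  imp2 <- suppressMessages(impute_missing(inj$table, seed = 9, ntree = 50))
  expect_identical(imp1, imp2)                    # bit-identical given seed
  expect_false(anyNA(imp1[cohort_variables(imp1)]))
  # observed cells untouched; align on subject_id in case the 1/3 rule
  # dropped anyone
  kept <- match(imp1$subject_id, full$subject_id)
  for (v in cohort_variables(full)) {
    obs <- !inj$mask[kept, v]
    expect_equal(imp1[[v]][obs], full[[v]][kept][obs])
  }
  # imputed values inside the observed range
  for (v in cohort_variables(full)) {
    gap <- inj$mask[kept, v]
    if (!any(gap)) next
    rng <- range(inj$table[[v]], na.rm = TRUE)
    expect_true(all(imp1[[v]][gap] >= rng[1] & imp1[[v]][gap] <= rng[2]))
  }
})

test_that("subjects beyond the 1/3 missingness rule are dropped", {
  tab <- toy_cohort(n = 10)
  vars <- cohort_variables(tab)           # 4 variables; blank 3 of them
  tab[1, vars[1:3]] <- NA
  expect_message(out <- impute_missing(tab, seed = 1, ntree = 30),
                 "dropping 1")
  expect_equal(nrow(out), 9)

  allmiss <- toy_cohort(n = 6)
  allmiss$noise1 <- NA_real_
  expect_error(impute_missing(allmiss, seed = 1), "entirely missing")
})

test_that("imputation recovers injected MCAR gaps to within the marker SD", {
  spec <- cohort_summary_specs("nhanes", quiet = TRUE)
  vars <- c("crp", "neutrophil_count", "lymphocyte_pct",
            "eosinophil_count", "wbc_count", "lymphocyte_count",
            "monocyte_count", "platelet_count")
  serum <- spec[vars]
  # correlated cohort: imputation needs neighbours that carry information
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  R[upper.tri(R)] <- 0.45
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  cfg <- generator_config(seed = 11, dependence = "gaussian-copula",
                          rank_cor = R)
  tab <- generate_group(serum, "pso", 1000, cfg, cohort = "sim")
  gap <- tab
  set.seed(12)
  miss <- runif(1000) < 0.05
  gap$crp[miss] <- NA
  imp <- impute_missing(gap, seed = 13, ntree = 60)
  rmse <- sqrt(mean((imp$crp[miss] - tab$crp[miss])^2))
  expect_lt(rmse, sd(tab$crp))
})

test_that("min-max normalization applies the printed formula with train/apply split", {
  train <- data.frame(label = c(0, 1, 0), x = c(1, 2, 3))
  p <- fit_minmax(train, "x")
  expect_equal(minmax_normalize(p, train)$x, c(0, 0.5, 1))
  # applied rows may leave [0,1]; x = min maps to 0
  apply_tab <- data.frame(label = 0:1, x = c(1, 5))
  expect_equal(minmax_normalize(p, apply_tab)$x, c(0, 2))
  # constant column convention
  const <- data.frame(label = c(0, 1), x = c(4, 4))
  expect_equal(minmax_normalize(fit_minmax(const, "x"), const)$x, c(0, 0))
  expect_error(minmax_normalize(p, data.frame(label = 0, y = 1)), "absent")
  # affine and order-preserving
  set.seed(5)
  z <- data.frame(label = rep(0:1, 10), x = rnorm(20))
  zn <- minmax_normalize(fit_minmax(z, "x"), z)
  expect_equal(order(zn$x), order(z$x))
  expect_true(all(zn$x >= 0 & zn$x <= 1))
})
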