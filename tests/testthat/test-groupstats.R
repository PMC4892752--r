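test_that("Lilliefors screen is calibrated, powered and affine-invariant", {
  set.seed(12)
  p_null <- replicate(2000, lilliefors(rnorm(50))$p)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.015)
  p_exp <- replicate(300, lilliefors(rexp(50))$p)
  expect_gt(mean(p_exp < 0.05), 0.5)
  x <- rlnorm(30)
  expect_equal(lilliefors(x)$p, lilliefors(3.7 * x + 11)$p)
  expect_error(lilliefors(rep(1, 10)), "constant")
  expect_error(lilliefors(1:4), "at least 5")
})

test_that("transform policy logs deviant tasks once and only once", {
  co <- generate_cohort(cohort_config(), seed = 4)
  tp <- apply_transform_policy(co)
  expect_true(all(tp$transformed %in% battery_task_ids()))
  expect_equal(nrow(tp$decisions), 12)
  # logged columns really are on the log scale now
  for (task in tp$transformed)
    expect_equal(tp$cohort[[task]], log(co[[task]]))
  # idempotence: a second pass transforms nothing
  tp2 <- apply_transform_policy(tp$cohort)
  expect_identical(tp2$cohort, tp$cohort)
  expect_identical(tp2$transformed, tp$transformed)

  # shifting a logged task below zero leaves the (location-scale-free)
  # screening decision unchanged but must refuse the log transform
  stopifnot("r2" %in% tp$transformed)
  co$r2 <- co$r2 - min(co$r2) - 1e-9
  expect_error(apply_transform_policy(co), "non-positive")
})

test_that("group contrast is one-sided towards patient deficit", {
  co <- generate_cohort(cohort_config(), seed = 6)
  tco <- apply_transform_policy(co)$cohort
  res <- group_compare(tco)
  expect_equal(nrow(res), 12)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_equal(res$significant_bonferroni, res$p < 0.05 / 12)

  # patients better than controls can never be flagged
  co2 <- flat_controls(n = 46)
  co2$group <- c(rep("control", 28), rep(c("SV", "NFV", "LV"),
                                         c(8, 6, 4)))
  co2$r3[co2$group != "control"] <- co2$r3[co2$group != "control"] - 10
  res2 <- group_compare(co2)
  expect_gt(res2$p[res2$task == "r3"], 0.5)
  expect_false(res2$significant_uncorrected[res2$task == "r3"])
  expect_error(group_compare(co2[, setdiff(names(co2), "m4")]),
               "missing task")
})

test_that("null cohorts produce flags at the nominal rates only", {
  set.seed(9)
  res <- replicate(400, {
    co <- flat_controls(n = 46, seed = sample.int(1e6, 1))
    co$group <- c(rep("control", 28), rep("SV", 18))
    r <- group_compare(co)
    c(unc = sum(r$significant_uncorrected),
      cor = sum(r$significant_bonferroni))
  })
  expect_lt(abs(mean(res["unc", ]) / 12 - 0.05), 0.02)
  expect_lt(mean(res["cor", ] > 0), 0.10)
})

test_that("implanted group shifts are detected with high power", {
  set.seed(10)
  shifted <- c("p1", "p2", "r1", "r2", "m1", "m2")
  hit <- replicate(100, {
    co <- flat_controls(n = 46, seed = sample.int(1e6, 1))
    co$group <- c(rep("control", 28), rep("SV", 18))
    for (task in shifted)
      co[[task]][co$group != "control"] <-
        co[[task]][co$group != "control"] + 4   # +2 SD
    r <- group_compare(co)
    all(r$significant_bonferroni[r$task %in% shifted]) &&
      !any(r$significant_bonferroni[!r$task %in% shifted])
  })
  expect_gt(mean(hit), 0.9)
})

test_that("Kruskal-Wallis arithmetic and invariances hold", {
  expect_lt(abs(kw_pvalue(9.36, 2) - 0.0093), 1e-4)
  expect_lt(abs(kw_pvalue(6.03, 2) - 0.049), 1e-3)
  # df = 2 closed form
  for (H in c(0.5, 3, 9.36))
    expect_equal(kw_pvalue(H, 2), exp(-H / 2), tolerance = 1e-12)

  set.seed(13)
  x <- rnorm(18)
  g <- rep(c("SV", "NFV", "LV"), c(8, 6, 4))
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, kw_pvalue(kw$H, 2))
  # invariant under strictly monotone transforms of the pooled data
  kw2 <- kruskal_wallis(exp(x), g)
  expect_equal(kw2$H, kw$H)
  expect_error(kruskal_wallis(rep(1, 18), g), "tied")
  expect_error(kruskal_wallis(x, rep("SV", 18)), "2 groups")
})

test_that("rank-based Tukey-Kramer flags exactly the separated group", {
  set.seed(14)
  vals <- c(rnorm(8), rnorm(6) + 50, rnorm(4))
  g <- rep(c("SV", "NFV", "LV"), c(8, 6, 4))
  ph <- tukey_kramer_ranks(vals, g)
  expect_equal(nrow(ph), 3)
  sig <- ph$significant
  names(sig) <- paste(ph$group1, ph$group2)
  expect_true(sig[["LV NFV"]])
  expect_true(sig[["NFV SV"]])
  expect_false(sig[["LV SV"]])

  # identical groups: empty set in >= 95% of null draws
  any_sig <- replicate(200,
    any(tukey_kramer_ranks(rnorm(18), g)$significant))
  expect_gte(mean(!any_sig), 0.93)
})

test_that("subtype pipeline reproduces an NFV-specific rhythm deficit", {
  set.seed(15)
  hits <- replicate(40, {
    co <- generate_cohort(cohort_config(), seed = sample.int(1e6, 1))
    tco <- apply_transform_policy(co)$cohort
    st <- subtype_compare(tco, tasks = "r4")
    if (!st$omnibus$significant) return(c(FALSE, FALSE, FALSE))
    ph <- st$posthoc$r4
    key <- paste(ph$group1, ph$group2)
    c(ph$significant[key == "LV NFV"], ph$significant[key == "NFV SV"],
      ph$significant[key == "LV SV"])
  })
  # NFV separates from both other subtypes more often than LV-SV fires
  expect_gt(mean(hits[1, ]), 0.5)
  expect_gt(mean(hits[1, ] & hits[2, ]), mean(hits[3, ]))
  expect_lt(mean(hits[3, ]), 0.2)
})

test_that("correlation screens respect direction, rank and Bonferroni", {
  df <- data.frame(x = 1:10, y = (1:10) * 2, z = exp(1:10 / 3))
  r1 <- corr_tests(df, "x", c("y"), method = "pearson")
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)
  rho <- corr_tests(df, "x", "z", method = "spearman")
  expect_equal(rho$r, 1)
  expect_lt(corr_tests(df, "x", "z", method = "pearson")$r, 1)

  set.seed(16)
  fam <- replicate(400, {
    d <- as.data.frame(matrix(rnorm(18 * 13), 18))
    names(d) <- c("x", paste0("y", 1:12))
    any(corr_tests(d, "x", paste0("y", 1:12), n_tests = 12)$p_corrected
        < 0.05)
  })
  expect_lte(mean(fam), 0.07)
  expect_error(corr_tests(data.frame(x = 1:10, y = rep(1, 10)), "x", "y"),
               "zero variance")
  expect_error(corr_tests(data.frame(x = c(1, 2, NA, NA, NA, NA),
                                     y = c(1, 2, 3, 4, 5, 6)), "x", "y"),
               "fewer than 4")
})
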