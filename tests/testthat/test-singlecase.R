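test_that("modified t-test reproduces its closed form", {
  # central case
  r0 <- crawford_t(50, control_mean = 50, control_sd = 5, n = 28)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_one_tailed, 0.5)
  expect_equal(r0$z, 0)

  r <- crawford_t(60, control_mean = 50, control_sd = 5, n = 28)
  expect_equal(r$t, 1.965215, tolerance = 1e-6)
  expect_equal(r$df, 27)
  expect_equal(r$p_one_tailed, 0.0298772, tolerance = 1e-5)
  expect_true(r$impaired_uncorrected)
  expect_false(r$impaired_bonferroni)

  # as n grows the statistic approaches the ordinary z-score
  rn <- crawford_t(60, control_mean = 50, control_sd = 5, n = 1e6)
  expect_equal(rn$t, 2, tolerance = 1e-4)

  expect_error(crawford_t(1, control_mean = 0, control_sd = 0, n = 28),
               "SD")
  expect_error(crawford_t(1, control_mean = 0, control_sd = 1, n = 1),
               "2 controls")
})

test_that("deficits map to positive Z in both outcome directions", {
  worse_threshold <- crawford_t(20, control_mean = 10, control_sd = 2,
                                n = 28, higher_worse = TRUE)
  worse_score <- crawford_t(22, control_mean = 33, control_sd = 3.5,
                            n = 28, higher_worse = FALSE)
  better <- crawford_t(5, control_mean = 10, control_sd = 2, n = 28,
                       higher_worse = TRUE)
  expect_gt(worse_threshold$z, 0)
  expect_gt(worse_score$z, 0)
  expect_lt(better$z, 0)
})

test_that("Z transform and Bonferroni criterion are consistent", {
  expect_equal(z_threshold(0.05, 12), 2.64, tolerance = 0.005)
  expect_equal(z_threshold(0.05, 1), 1.645, tolerance = 5e-4)
  expect_equal(z_threshold(0.5, 1), 0)
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.05 / 12), 2.638257, tolerance = 1e-6)
  for (z in seq(-5, 5, by = 0.5))
    expect_equal(p_to_z(1 - pnorm(z)), z, tolerance = 1e-10)
  expect_error(p_to_z(0), "strictly")
  expect_error(p_to_z(1), "strictly")

  # flag <=> p < alpha/m <=> z > z_threshold, for every result object
  set.seed(1)
  for (i in 1:200) {
    r <- crawford_t(rnorm(1, 10, 4), control_mean = 10, control_sd = 2,
                    n = 28)
    expect_equal(r$impaired_bonferroni, r$p_one_tailed < 0.05 / 12)
    expect_equal(r$impaired_bonferroni, r$z > z_threshold(0.05, 12))
  }
})

test_that("modified t-test controls the single-case type-I error", {
  set.seed(2024)
  hits <- replicate(4000, {
    ctrl <- rnorm(28)
    crawford_t(rnorm(1), controls = ctrl)$impaired_uncorrected
  })
  expect_lt(abs(mean(hits) - 0.05), 0.01)
})

test_that("covariate selection finds a real CPM effect and rejects junk", {
  co <- generate_cohort(cohort_config(), seed = 8)
  ctrl <- co[co$group == "control", ]
  sel <- select_covariates(ctrl)
  expect_true("cpm" %in% sel)
  pm <- attr(sel, "details")
  expect_lt(pm["cpm", "p2"], 0.05)

  # constant candidate dropped with a warning
  ctrl$flat <- 1
  expect_warning(s2 <- select_covariates(ctrl,
                                         candidates = c("cpm", "flat")),
                 "constant")
  expect_false("flat" %in% s2)

  # collinear candidates refused
  ctrl$cpm2 <- ctrl$cpm
  expect_error(select_covariates(ctrl, candidates = c("cpm", "cpm2")),
               "collinear")

  # with independent covariates selection happens only at the null rate
  set.seed(5)
  n_sel <- replicate(60, {
    fc <- flat_controls(seed = sample.int(1e6, 1))
    length(select_covariates(fc, candidates = c("age", "cpm")))
  })
  # per candidate: 1 - 0.95^12 ~ 46% under independence; far from certain
  expect_lt(mean(n_sel == 2), 0.6)
})

test_that("covariate-adjusted comparison matches its regression form", {
  set.seed(31)
  n <- 28
  X <- cbind(age = rnorm(n, 62, 8), cpm = rnorm(n, 32, 3))
  beta <- c(2, 0.5, -0.3)
  y <- beta[1] + X %*% beta[-1] + rnorm(n, sd = 1.5)

  # a patient exactly on the control regression surface
  fit <- lm(y ~ X)
  xs <- c(age = 70, cpm = 30)
  y_hat <- sum(coef(fit) * c(1, xs))
  r <- adjusted_singlecase(y_hat, xs, y, X)
  expect_equal(r$t, 0, tolerance = 1e-10)
  expect_equal(r$p_one_tailed, 0.5)
  expect_equal(r$df, n - 2 - 1)
  expect_true(r$adjusted)

  # growing leverage shrinks |t| for a fixed raw deviation
  ts <- sapply(c(0, 10, 25, 40), function(d) {
    xs2 <- c(age = 62 + d, cpm = 32)
    y2 <- sum(coef(fit) * c(1, xs2)) + 5
    abs(adjusted_singlecase(y2, xs2, y, X)$t)
  })
  expect_true(all(diff(ts) < 0))

  expect_error(adjusted_singlecase(1, c(age = 60, cpm = NA), y, X),
               "missing")
  expect_error(adjusted_singlecase(1, c(age = 60, a2 = 60), y,
                                   cbind(age = X[, 1], a2 = X[, 1])),
               "rank")
})

test_that("adjustment is inert when covariates carry no signal", {
  set.seed(77)
  agree <- replicate(300, {
    y <- rnorm(28, 10, 2)
    X <- cbind(cov = rnorm(28))
    ys <- rnorm(1, 10, 2)
    raw <- crawford_t(ys, controls = y)
    adj <- adjusted_singlecase(ys, c(cov = rnorm(1)), y, X)
    c(same_decision = raw$impaired_uncorrected == adj$impaired_uncorrected,
      df_shift = raw$df - adj$df)
  })
  expect_gte(mean(agree["same_decision", ]), 0.95)
  expect_true(all(agree["df_shift", ] == 1))
})

test_that("single-case tables flag implanted deficits and keep NA rows", {
  co <- generate_cohort(cohort_config(), seed = 3)
  tab <- single_case_table(co, covariates = NULL)
  expect_equal(nrow(tab), 18 * 12)
  # NFV should carry the impairments on its deficit tasks
  nfv_r4 <- tab[tab$group == "NFV" & tab$task == "r4", ]
  lv <- tab[tab$group == "LV", ]
  expect_gt(mean(nfv_r4$z), mean(lv$z, na.rm = TRUE))

  co$p1[co$group == "NFV"][1] <- NA
  tab2 <- single_case_table(co, covariates = NULL)
  expect_true(any(is.na(tab2$z)))
  expect_equal(nrow(tab2), 18 * 12)
})
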