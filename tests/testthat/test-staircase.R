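test_that("two-down one-up updates move, reset and record reversals", {
  st <- staircase_new(10, floor = 0.1, ceiling = 100)
  st <- staircase_update(st, TRUE)
  expect_equal(st$level, 10)           # one correct: no move yet
  st <- staircase_update(st, TRUE)     # second consecutive correct
  expect_equal(st$level, 5)
  expect_equal(st$consecutive_correct, 0L)
  st <- staircase_update(st, FALSE)    # error: easier, and a reversal
  expect_equal(st$level, 10)
  expect_equal(st$reversal_levels, 5)
  # error resets the streak: two more corrects needed before a down-step
  st <- staircase_update(st, TRUE)
  expect_equal(st$level, 10)

  # levels stay clipped inside [floor, ceiling]
  st2 <- staircase_new(1, floor = 0.5, ceiling = 2)
  for (i in 1:10) st2 <- staircase_update(st2, FALSE)
  expect_equal(st2$level, 2)

  # cycling correct,correct,incorrect forever: bounded oscillation whose
  # reversal count grows without bound
  st3 <- staircase_new(8, floor = 1, ceiling = 64)
  for (i in 1:60) st3 <- staircase_update(st3, i %% 3 != 0)
  expect_true(all(st3$levels >= 1 & st3$levels <= 64))
  expect_gt(length(st3$reversal_levels), 10)
  # single correct responses alone never trigger a down-step
  st4 <- staircase_new(8, floor = 1, ceiling = 64)
  for (i in 1:10) st4 <- staircase_update(st4, i %% 2 == 0)
  expect_true(all(diff(st4$levels) >= 0))
})

test_that("threshold is the geometric mean of the last six reversals", {
  expect_equal(
    estimate_threshold(list(reversal_levels = rep(3.7, 6)))$threshold, 3.7)
  est <- estimate_threshold(list(reversal_levels = c(8, 4, 8, 4, 8, 4)))
  expect_equal(est$threshold, sqrt(32))
  expect_true(est$converged)
  # earlier reversals are ignored
  est2 <- estimate_threshold(
    list(reversal_levels = c(100, 100, 8, 4, 8, 4, 8, 4)))
  expect_equal(est2$threshold, sqrt(32))
  short <- estimate_threshold(list(reversal_levels = c(8, 4, 8)))
  expect_false(short$converged)
  expect_true(is.na(short$threshold))
  expect_error(estimate_threshold(list()), "empty")
})

test_that("psychometric observer matches its closed form", {
  obs <- virtual_observer(alpha = 5, beta = 6, lapse = 0, guess = 0.5)
  expect_equal(psychometric(obs, 5), 0.75)          # midpoint, 2AFC
  expect_gt(psychometric(obs, 5000), 0.999)         # asymptote
  expect_equal(psychometric(obs, 0), 0.5)           # undecidable: chance
  obs3 <- virtual_observer(alpha = 5, beta = 6, lapse = 0.06, guess = 1 / 3)
  expect_equal(psychometric(obs3, 5), 1 / 3 + (1 - 1 / 3 - 0.06) / 2)
  # inverse round-trip
  lvl <- psychometric_target_level(obs3, 0.7)
  expect_equal(psychometric(obs3, lvl), 0.7)

  # Monte-Carlo proportion correct matches psi within 2 SE
  p_true <- psychometric(obs, 4)
  hits <- audbat:::with_seed(99,
    mean(replicate(1e4, observer_respond(obs, 4))))
  se <- sqrt(p_true * (1 - p_true) / 1e4)
  expect_lt(abs(hits - p_true), 2 * se)
})

test_that("adaptive runs are reproducible and converge on the 70.7% point", {
  task <- build_battery()$r1
  obs <- virtual_observer(alpha = 10, beta = 8, lapse = 0, guess = 0.5)
  tr1 <- run_adaptive(task, obs, 123)
  tr2 <- run_adaptive(task, obs, 123)
  expect_identical(tr1$levels, tr2$levels)
  expect_identical(tr1$threshold, tr2$threshold)
  expect_length(tr1$levels, 50)

  # near-step observer: mean estimated threshold tracks psi = sqrt(0.5)
  target <- psychometric_target_level(obs)
  ths <- vapply(1:60, function(s) run_adaptive(task, obs, s)$threshold, 0)
  expect_lt(abs(mean(ths) / target - 1), 0.15)

  # an always-correct responder descends monotonically to the floor
  perfect <- virtual_observer(alpha = 1e-9, beta = 50, lapse = 0,
                              guess = 0.5)
  trp <- run_adaptive(task, perfect, 5)
  expect_true(all(diff(trp$levels) <= 0))
  expect_equal(min(trp$levels), task$floor)

  # wrong guess rate for the paradigm is refused
  obs3 <- virtual_observer(alpha = 10, beta = 8, guess = 1 / 3)
  expect_error(run_adaptive(task, obs3, 1), "incompatible")
})

test_that("threshold estimation is scale-equivariant", {
  task <- build_battery()$r1
  for (k in c(0.5, 3)) {
    task_k <- task
    task_k$start_level <- task$start_level * k
    task_k$floor <- task$floor * k
    task_k$ceiling <- task$ceiling * k
    obs <- virtual_observer(alpha = 10, beta = 8, lapse = 0, guess = 0.5)
    obs_k <- virtual_observer(alpha = 10 * k, beta = 8, lapse = 0,
                              guess = 0.5)
    t1 <- run_adaptive(task, obs, 7)
    tk <- run_adaptive(task_k, obs_k, 7)
    expect_equal(tk$threshold, k * t1$threshold, tolerance = 1e-10)
  }
})

test_that("tracks plateau in the second half of the run", {
  task <- build_battery()$p1
  deltas <- vapply(1:40, function(s) {
    obs <- virtual_observer(alpha = 0.8 * exp(rnorm(1, sd = 0.5)), beta = 8)
    tr <- run_adaptive(task, obs, s)
    lv <- log(tr$levels)
    c(mean(abs(diff(lv[1:25]))), mean(abs(diff(lv[25:50]))))
  }, c(0, 0))
  # levels move less, per trial, once the track has levelled off
  expect_lt(stats::median(deltas[2, ]), stats::median(deltas[1, ]))
})

test_that("fixed same-different runs are balanced and score correctly", {
  task <- build_battery()$p3
  perfect <- virtual_observer(alpha = 1e-6, beta = 50, lapse = 0,
                              guess = 0.5)
  tr <- run_fixed(task, perfect, 1)
  expect_equal(tr$score, 40L)
  expect_equal(sum(tr$same), 20L)
  expect_equal(as.vector(table(tr$reference_id)), rep(2L, 20))

  # a pure guesser (threshold far beyond any presented level) scores
  # binomial(40, 0.5)
  guesser <- virtual_observer(alpha = 1e9, beta = 2, lapse = 0,
                              guess = 0.5)
  scores <- vapply(1:1000, function(s) run_fixed(task, guesser, s)$score, 0L)
  expect_lt(abs(mean(scores) - 20), 1)
  expect_gt(mean(scores >= 14 & scores <= 26), 0.93)
  expect_error(run_fixed(build_battery()$p1, perfect, 1), "not a fixed")
})

test_that("trial logs flatten to the tidy long format", {
  task <- build_battery()$r1
  obs <- virtual_observer(alpha = 10, beta = 8)
  df <- tracks_to_df(list(S1 = run_adaptive(task, obs, 1),
                          S1b = run_fixed(build_battery()$p3, obs2 <-
                            virtual_observer(2, 8), 1)))
  expect_setequal(names(df), c("subject", "task", "trial", "level",
                               "correct", "reversal_flag"))
  expect_equal(nrow(df), 90)
  expect_equal(sum(df$reversal_flag),
               length(run_adaptive(task, obs, 1)$reversal_levels))
})
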