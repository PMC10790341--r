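make_records <- function(d, li, atretic = rep(FALSE, length(d)),
                         animal = "m01", stage = "diestrus") {
  as_follicle_records(data.frame(
    follicle_id = sprintf("f%03d", seq_along(d)),
    animal_id = animal, cycle_stage = stage,
    pseudodiameter = d, labeling_index = li,
    atresia = factor(ifelse(atretic, "atretic", "non_atretic"),
                     levels = c("non_atretic", "atretic")),
    included = TRUE))
}

test_that("the median LI regression recovers a generating line", {
  set.seed(42)
  d <- runif(200, 170, 450)
  li <- pmin(1, pmax(0, 0.57 - 8e-4 * d + rnorm(200, 0, 0.02)))
  fit <- fit_li_regression(make_records(d, li), "median_all")
  expect_equal(fit$slope, -8e-4, tolerance = 0.25)   # sign and size
  expect_lt(abs(fit$slope + 8e-4), 2e-4)
  expect_lt(abs(fit$intercept - 0.57), 0.05)
  # identical LIs give slope 0
  flat <- fit_li_regression(make_records(seq(180, 340, 10), 0.3), "median_all")
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_li_regression(make_records(c(200, 250), c(0.3, 0.3))),
               "at least 3")
})

test_that("the fast subset takes the per-bin top 20% and beats the bin mean", {
  # 10 follicles in one bin -> top 2 selected
  d <- seq(221, 267, length.out = 10)
  li <- seq(0.1, 0.55, length.out = 10)
  rec <- make_records(d, li)
  sub <- fast_top20_subset(rec, min_per_bin = 0)
  in_bin <- sub$pseudodiameter >= 220 & sub$pseudodiameter < 270
  expect_equal(sum(in_bin), 2)
  expect_equal(sort(sub$labeling_index[in_bin]), c(0.50, 0.55))
  # on a full population: subset of the input; per-bin mean LI >= overall
  pop <- sample_population(population_config(), "diestrus", seed = 7)
  elig <- pop[pop$atresia == "non_atretic" & pop$pseudodiameter >= 170, ]
  fast <- fast_top20_subset(elig)
  expect_true(all(fast$follicle_id %in% elig$follicle_id))
  for (b in list(c(170, 220), c(220, 270), c(270, 320), c(320, 350))) {
    all_li <- elig$labeling_index[elig$pseudodiameter >= b[1] &
                                    elig$pseudodiameter < b[2]]
    top_li <- fast$labeling_index[fast$pseudodiameter >= b[1] &
                                    fast$pseudodiameter < b[2]]
    expect_gte(mean(top_li), mean(all_li))
  }
  # the fast regression sits above the median one across the antral range
  f_med <- fit_li_regression(pop, "median_all")
  f_fast <- fit_li_regression(pop, "fast_top20")
  expect_true(all(predict_li(f_fast, seq(180, 340, 20)) >
                    predict_li(f_med, seq(180, 340, 20))))
  expect_error(fast_top20_subset(elig[elig$pseudodiameter > 300, ]), "bin")
})

test_that("preovulatory counts filter by atresia and threshold, monotone in threshold", {
  d <- c(360, 380, 400, 370, 390, 340, 200)
  atretic <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  rec <- make_records(d, 0.3, atretic)
  out <- count_preovulatory(rec, 350)
  expect_equal(sum(out$n_preovulatory), 3)
  # lowering the threshold never decreases counts
  thresholds <- c(400, 350, 300, 250)
  counts <- vapply(thresholds,
                   function(t) sum(count_preovulatory(rec, t)$n_preovulatory),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  # empty input -> zero-row table
  empty <- count_preovulatory(rec[0, ], 350)
  expect_equal(nrow(empty), 0)
  # generator ground truth: planted diestrus cohort of 10 is recovered
  pop <- sample_population(population_config(), "diestrus", seed = 1)
  expect_equal(sum(count_preovulatory(pop)$n_preovulatory), 10)
})

test_that("cohort simulation meets targets at the oracle day and is monotone in cohort size", {
  p <- growth_params()
  # all starting preovulatory: met at day 0, minimum cycle 1 day
  sc0 <- cohort_scenario(data.frame(diameter = rep(400, 10), li = 0.2))
  sim0 <- simulate_cohort(sc0, p, seed = 1)
  expect_equal(sim0$target_met_day, 0)
  expect_equal(sim0$min_cycle_length_days, 1)
  # zero LI: unmet
  scu <- cohort_scenario(data.frame(diameter = rep(170, 10), li = 0),
                         max_days = 6)
  expect_false(simulate_cohort(scu, p, seed = 1)$target_met)
  # 12 follicles at 250 um with LI 0.45: target of 10 met at day 4 (oracle)
  sc <- cohort_scenario(data.frame(diameter = rep(250, 12), li = 0.45))
  sim <- simulate_cohort(sc, p, seed = 1)
  expect_equal(sim$target_met_day, 4)
  expect_equal(sim$min_cycle_length_days, 5)
  or_day <- with(oracle_growth(250, 0.45, 10), min(day[diameter > 350]))
  expect_equal(sim$target_met_day, or_day)
  # adding identical follicles never delays the target
  days_met <- vapply(c(10, 12, 16), function(n) {
    s <- cohort_scenario(data.frame(diameter = rep(250, n), li = 0.45))
    simulate_cohort(s, p, seed = 1)$target_met_day
  }, integer(1))
  expect_true(all(diff(days_met) <= 0))
  # per-day report bookkeeping
  expect_equal(nrow(sim$report), 11 * 12)
  expect_true(all(diff(tapply(sim$report$cumulative_preovulatory,
                              sim$report$day, unique)) >= 0))
})

test_that("survivor-effect summaries behave at the boundaries and under random survival", {
  pop <- data.frame(follicle_id = sprintf("f%03d", 1:200),
                    labeling_index = runif(200, 0.1, 0.6))
  # survivors = whole population -> zero difference
  eff <- survivor_effect(pop, pop)
  expect_equal(eff$difference_mean, 0)
  expect_equal(eff$difference_median, 0)
  expect_true(is.na(eff$p_value))
  expect_error(survivor_effect(pop, pop[0, ]), "empty")
  expect_error(survivor_effect(pop, data.frame(follicle_id = "zz",
                                               labeling_index = 0.5)),
               "subset")
  # random survivors: mean difference ~ 0 within Monte-Carlo error
  set.seed(99)
  diffs <- replicate(200, {
    surv <- pop[sample.int(200, 40), ]
    survivor_effect(pop, surv)$difference_mean
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 1e-3)
})

test_that("LI-dependent atresia enriches survivors for fast growers", {
  se <- survivor_experiment(seed = 5)
  expect_gt(se$effect$difference_mean, 0)
  expect_gt(se$effect$mean_survivors, se$effect$mean_population)
  # survivors crossed the threshold and escaped atresia
  expect_true(all(se$cohort$diameter_final[se$cohort$survivor] > 350))
  expect_true(all(!se$cohort$atretic[se$cohort$survivor]))
  # without any hazard or threshold selection the effect needs the threshold:
  # disabling the hazard still leaves threshold selection, sign preserved
  se0 <- survivor_experiment(hazard = NULL, seed = 5)
  expect_gt(se0$effect$difference_mean, 0)
})

test_that("hazard probabilities decrease with LI percentile and respect stages", {
  rule <- atresia_hazard()
  pct <- seq(0, 1, 0.1)
  h <- hazard_probability(rule, pct, "diestrus")
  expect_true(all(diff(h) < 0))
  expect_true(all(h >= 0 & h <= 1))
  expect_lt(hazard_probability(rule, 0.5, "estrus"),
            hazard_probability(rule, 0.5, "diestrus"))
  expect_error(hazard_probability(rule, 0.5, "anestrus"), "unknown")
})
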