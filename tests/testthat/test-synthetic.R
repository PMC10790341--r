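test_that("population generation is a pure function of config and seed", {
  cfg <- population_config()
  a <- sample_population(cfg, "metestrus", seed = 11)
  b <- sample_population(cfg, "metestrus", seed = 11)
  expect_identical(a, b)
  c_ <- sample_population(cfg, "metestrus", seed = 12)
  expect_false(identical(a$pseudodiameter, c_$pseudodiameter))
  expect_error(sample_population(cfg, "anestrus"), "invalid cycle stage")
})

test_that("generated populations respect the LI phase structure", {
  cfg <- population_config()
  pop <- sample_population(cfg, "diestrus", seed = 3)
  # preantral follicles (80-130 um): >= 90% of true LIs at or below 0.30
  pre <- pop$truth_li[pop$pseudodiameter < 130]
  expect_gte(mean(pre <= 0.30), 0.90)
  # mean trajectory: rise through the spurt, decline beyond 170 um
  expect_lt(li_mean_trajectory(100, cfg), li_mean_trajectory(170, cfg))
  d <- seq(170, 450, 10)
  expect_true(all(diff(li_mean_trajectory(d, cfg)) < 0))
  expect_equal(li_mean_trajectory(170, cfg), 0.434)
  # trajectory is continuous at the knots
  expect_equal(li_mean_trajectory(169.999, cfg), li_mean_trajectory(170, cfg),
               tolerance = 1e-3)
  expect_equal(li_mean_trajectory(129.999, cfg), li_mean_trajectory(130, cfg),
               tolerance = 1e-3)
})

test_that("atresia in generated populations follows onset and hazard settings", {
  cfg <- population_config()
  pop <- sample_population(cfg, "diestrus", seed = 3)
  expect_true(all(pop$pseudodiameter[pop$truth_atretic] >= 170))
  # flags and classification agree
  expect_equal(as.character(classify_atresia(pop)), as.character(pop$atresia))
  # atretic follicles skew slow-growing
  sus <- pop[pop$pseudodiameter >= 170 & !pop$truth_preovulatory, ]
  expect_lt(mean(sus$truth_li[sus$truth_atretic]),
            mean(sus$truth_li[!sus$truth_atretic]))
  # hazard off -> no atresia
  cfg0 <- population_config(atresia = atresia_hazard(base_rate = 0))
  expect_equal(sum(sample_population(cfg0, "diestrus", seed = 3)$truth_atretic), 0)
})

test_that("end-to-end slope recovery: generator -> regression within 3 fitted SEs", {
  cfg <- population_config()
  pop <- sample_population(cfg, "metestrus", seed = 21)
  fit <- fit_li_regression(pop, "median_all")
  se <- summary(fit$model)$coefficients["pseudodiameter", "Std. Error"]
  expect_lt(abs(fit$slope - (-cfg$li_slope)), 3 * se)
})

test_that("pulse-chase designs carry the label and grow follicles correctly", {
  cfg <- population_config()
  pop <- sample_population(cfg, "metestrus", seed = 8)
  # 2h: measured label ~ true instantaneous LI within noise
  pc2 <- simulate_pulse_chase(pop, "2h", seed = 1)
  expect_equal(pc2$label_li, pc2$truth_li, tolerance = 0.5)
  expect_lt(max(abs(pc2$label_li - pc2$truth_li)), 4 * cfg$li_noise_sd)
  expect_equal(pc2$pseudodiameter, pop$pseudodiameter)
  # 48h with zero LI and no hazard: diameters unchanged
  pop0 <- pop
  pop0$truth_li <- 0
  pc0 <- simulate_pulse_chase(pop0, "48h", days_elapsed = 2, hazard = NULL,
                              seed = 1)
  expect_equal(pc0$pseudodiameter, pop$pseudodiameter)
  # 48h growth matches the growth model per follicle
  pc <- simulate_pulse_chase(pop, "48h", days_elapsed = 2, hazard = NULL,
                             seed = 1)
  i <- which(pop$atresia == "non_atretic")[1:5]
  for (j in i) {
    expect_equal(pc$pseudodiameter[j],
                 simulate_growth(pop$pseudodiameter[j], pop$truth_li[j],
                                 2)$diameter[3])
  }
  expect_error(simulate_pulse_chase(pop, "48h", days_elapsed = 5), "1 or 2")
  # 48h with the hazard on: surviving preovulatory follicles carry a label
  # above the injection-time mean of their starting band (survivor effect)
  band <- pop[pop$pseudodiameter >= 250 & pop$pseudodiameter <= 350 &
                pop$atresia == "non_atretic", ]
  pch <- simulate_pulse_chase(band, "48h", days_elapsed = 2, seed = 4)
  surv <- pch[pch$pseudodiameter > 350 & pch$atresia == "non_atretic", ]
  expect_gt(nrow(surv), 0)
  expect_gt(mean(surv$truth_li), 0)
})

test_that("rendered section stacks obey sphere geometry and the inclusion rule", {
  cfg <- synthetic_histology_config()
  # centred sphere: widest area reproduces the diameter within one section
  ss <- render_section_stack(300, cfg, equator_offset = 187.5)
  w <- widest_section(ss)
  expect_equal(pseudodiameter(w$area), 300, tolerance = 5 / 300)
  expect_true(include_follicle(ss))
  # equator in the first sampled section -> excluded
  expect_false(include_follicle(render_section_stack(300, cfg, 1.8)))
  expect_false(include_follicle(render_section_stack(300, cfg, 373)))
  # diameter smaller than one section: at most one nonzero section
  tiny <- render_section_stack(4, cfg, equator_offset = 100.1)
  expect_lte(sum(tiny$area > 0), 1)
  # 48h design samples every 25th section
  cfg48 <- synthetic_histology_config(design = "48h")
  ss48 <- render_section_stack(400, cfg48, equator_offset = 430)
  expect_equal(unique(diff(ss48$section_index)), 25)
})

test_that("the derived mural-shell line matches the volume power law within 10%", {
  co <- derive_mural_thickness_coefs()
  d <- seq(170, 450, by = 10)
  r <- d / 2
  t <- co[1] + co[2] * d
  shell <- 4 / 3 * pi * (r^3 - (r - t)^3)
  expect_lt(max(abs(shell / mural_volume(d) - 1)), 0.10)
  expect_gt(co[2], 0)  # thickness grows with diameter
})

test_that("rendered masks recover the planted labeling index", {
  cfg <- synthetic_histology_config()
  m0 <- render_mask(300, 0, cfg, seed = 2)
  expect_equal(sum(m0$mask == MASK_CLASSES[["brdu_pos"]]), 0)
  m1 <- render_mask(300, 1, cfg, seed = 2)
  # at LI 1 every mural pixel is labeled; remaining BrdU- pixels are cumulus
  expect_equal(sum(m1$mask == MASK_CLASSES[["brdu_neg"]]), m1$truth$n_cumulus)
  q1 <- quantify_mask(m1$mask, m1$roi, m1$pixel_size)
  expect_equal(labeling_index(q1), 1)
  m <- render_mask(300, 0.4, cfg, seed = 2)
  q <- quantify_mask(m$mask, m$roi, m$pixel_size)
  expect_equal(labeling_index(q), 0.4, tolerance = 0.02)
  # mask is at least 200 x 200 px and mask generation is seed-pure
  expect_gte(nrow(m$mask), 200)
  expect_identical(render_mask(300, 0.4, cfg, seed = 2)$mask, m$mask)
  # omitting the cumulus exclusion biases the LI low
  q_noexcl <- quantify_mask(m$mask, region_of_interest(m$roi$basal_lamina),
                            m$pixel_size)
  expect_lt(labeling_index(q_noexcl), labeling_index(q))
  expect_equal(q_noexcl$area_brdu_negative - q$area_brdu_negative,
               m$truth$n_cumulus * m$pixel_size^2)
})
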