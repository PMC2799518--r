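test_that("division acceptance matches the probability table empirically", {
  cfg <- sim_config()
  cases <- list(
    list(scenario = "on_pm_or_wound", dp = 0.90, n = 1e4),
    list(scenario = "normal_uninhibited", dp = 0.40, n = 1e4),
    list(scenario = "stratified_ta_in_wound", dp = 0.05, n = 1e4),
    list(scenario = "contact_inhibited_ta", dp = 0.02, n = 1e5),
    list(scenario = "contact_inhibited_stem", dp = 0.01, n = 1e5)
  )
  set.seed(1)
  for (cs in cases) {
    who <- if (grepl("ta", cs$scenario)) "TA" else "stem"
    frac <- mean(division_decision(who, cs$scenario, LRCE = 0, cfg, n = cs$n))
    se <- sqrt(cs$dp * (1 - cs$dp) / cs$n)
    expect_lt(abs(frac - cs$dp), 3 * se,
              label = paste0(cs$scenario, ": ", frac, " vs ", cs$dp))
  }
})

test_that("endosomal complex inhibits division with the hyperbolic law", {
  cfg <- sim_config()
  # PRR = 0.40 / (1 + 0.1 * 10) = 0.20
  set.seed(2)
  frac <- mean(division_decision("TA", "normal_uninhibited", LRCE = 10,
                                 cfg, n = 1e5))
  se <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(frac - 0.20), 3 * se)
  # monotone: more signal, fewer divisions
  set.seed(3)
  f_hi <- mean(division_decision("stem", "on_pm_or_wound", LRCE = 50,
                                 cfg, n = 2e4))
  expect_lt(f_hi, 0.20)  # 0.9/6 = 0.15 expected
})

test_that("non-proliferative subtypes cannot attempt division", {
  expect_error(division_decision("committed", "normal_uninhibited", 0),
               "stem and TA")
  expect_error(division_decision(3, "normal_uninhibited", 0), "stem and TA")
})

test_that("scenario classification covers the probability table rows", {
  cfg <- sim_config()
  # stem touching a PM tile
  expect_equal(classify_scenario("stem", on_pm = TRUE, in_wound = TRUE,
                                 D = 5, n_neighbors = 0, config = cfg),
               "on_pm_or_wound")
  # unstratified cell over the wound bed, not touching PM
  expect_equal(classify_scenario("TA", FALSE, TRUE, D = 5, 0, config = cfg),
               "on_pm_or_wound")
  # stratified TA over the wound bed
  expect_equal(classify_scenario("TA", FALSE, TRUE, D = 15, 0, config = cfg),
               "stratified_ta_in_wound")
  # crowded interior cells in normal epidermis
  expect_equal(classify_scenario("stem", FALSE, FALSE, 5,
                                 cfg$contact_inhibit_neighbors + 1,
                                 config = cfg),
               "contact_inhibited_stem")
  expect_equal(classify_scenario("TA", FALSE, FALSE, 5,
                                 cfg$contact_inhibit_neighbors, config = cfg),
               "contact_inhibited_ta")
  # sustained mechanical compression arrests an otherwise uncrowded cell
  expect_equal(classify_scenario("TA", FALSE, FALSE, 5, 2,
                                 pressure_inhibited = TRUE, config = cfg),
               "contact_inhibited_ta")
  # default branch
  expect_equal(classify_scenario("TA", FALSE, FALSE, 5, 2, config = cfg),
               "normal_uninhibited")
})

test_that("differentiation cascade fires on its documented triggers", {
  cfg <- sim_config()
  per <- cfg$strat_persist_h
  # stem stratified long enough -> TA
  expect_equal(differentiation_step("stem", strat_time_h = per, 6, 10, 0,
                                    0, FALSE, cfg), 1L)
  # transient bump does not convert
  expect_equal(differentiation_step("stem", strat_time_h = per / 2, 6, 10, 0,
                                    0, FALSE, cfg), 0L)
  # interior stem of a small colony stays stem
  expect_equal(differentiation_step("stem", 0, 6, 10, 0, 0, FALSE, cfg), 0L)
  # edge stem of a large colony converts
  expect_equal(differentiation_step("stem", 0, 3,
                                    cfg$colony_size_threshold, 0, 0, FALSE,
                                    cfg), 1L)
  # stratified TA far from any stem commits
  expect_equal(differentiation_step("TA", per, 0, 0,
                                    cfg$ta_distance_threshold + 10, 0, FALSE,
                                    cfg), 2L)
  # basal TA never commits, however far from stems
  expect_equal(differentiation_step("TA", 0, 0, 0, 1e3, 0, FALSE, cfg), 1L)
  # committed matures after its dwell, halved in corneocyte contact
  expect_equal(differentiation_step("committed", per, 0, 0, Inf,
                                    cfg$committed_dwell_h, FALSE, cfg), 3L)
  expect_equal(differentiation_step("committed", per, 0, 0, Inf,
                                    cfg$committed_dwell_h / 2, TRUE, cfg), 3L)
  expect_equal(differentiation_step("committed", per, 0, 0, Inf,
                                    cfg$committed_dwell_h / 2, FALSE, cfg), 2L)
  # timed desquamation only with a finite dwell
  expect_equal(differentiation_step("corneocyte", per, 0, 0, Inf, 1e6, FALSE,
                                    cfg), 3L)
  cfg_shed <- sim_config(corneocyte_dwell_h = 96)
  expect_true(is.na(differentiation_step("corneocyte", per, 0, 0, Inf, 96,
                                         FALSE, cfg_shed)))
})

test_that("differentiation is a forward-only cascade", {
  cfg <- sim_config()
  set.seed(9)
  for (k in 1:200) {
    st <- sample(0:3, 1)
    out <- differentiation_step(st, runif(1, 0, 20), sample(0:8, 1),
                                sample(0:60, 1), runif(1, 0, 60),
                                runif(1, 0, 200), sample(c(TRUE, FALSE), 1),
                                cfg)
    if (!is.na(out)) expect_gte(out, st)
  }
})

test_that("TA cells migrate 30 um per iteration while in contact", {
  cfg <- sim_config()
  nb <- matrix(c(10, 0, 5), ncol = 3)  # one adjacent neighbour
  set.seed(4)
  d <- migration_step("TA", c(0, 0, 5), nb, config = cfg)
  expect_equal(sqrt(sum(d^2)), 30)  # 1 um/min for 30 min
  expect_equal(d[3], 0)             # horizontal motion
  # isolated cell does not move
  expect_equal(migration_step("TA", c(0, 0, 5),
                              matrix(c(100, 0, 5), ncol = 3), config = cfg),
               c(0, 0, 0))
  expect_equal(migration_step("TA", c(0, 0, 5),
                              matrix(numeric(0), ncol = 3), config = cfg),
               c(0, 0, 0))
  # non-TA subtypes never move actively
  for (st in c("stem", "committed", "corneocyte")) {
    expect_equal(migration_step(st, c(0, 0, 5), nb, config = cfg), c(0, 0, 0))
  }
})

test_that("migration is biased toward provisional matrix", {
  cfg <- sim_config()
  nb <- matrix(c(10, 0, 5), ncol = 3)
  pm <- matrix(c(50, 0), ncol = 2)  # PM tile due east, within sensing radius
  set.seed(6)
  disp <- t(replicate(10000, migration_step("TA", c(0, 0, 5), nb, pm,
                                            config = cfg)))
  # mixture: p_bias straight east + (1 - p_bias) uniform => E[dx] = 24
  expect_equal(mean(disp[, 1]), cfg$p_bias * 30, tolerance = 0.02)
  expect_lt(abs(mean(disp[, 2])), 1)
  # out-of-range PM tile: no bias
  far <- matrix(c(500, 0), ncol = 2)
  set.seed(7)
  disp2 <- t(replicate(2000, migration_step("TA", c(0, 0, 5), nb, far,
                                            config = cfg)))
  expect_lt(abs(mean(disp2[, 1])), 1.5)
})
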