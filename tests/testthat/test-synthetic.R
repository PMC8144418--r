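test_that("invalid simulator configurations name the offending field", {
  expect_error(clinic_sim_config(n_transfers = 0), "n_transfers")
  expect_error(clinic_sim_config(category_mix = c("fresh morula" = 1)),
               "category_mix")
  expect_error(clinic_sim_config(embryos_per_transfer = c("0" = 1)),
               "embryos_per_transfer")
  expect_error(clinic_sim_config(true_uni = c(fresh = 0.7, frozen = 1.2)),
               "true_uni")
  # a rate above the cycle's uni makes the mechanism ill-formed
  expect_error(clinic_sim_config(
    true_lbr_curve = function(a, s, c) 0.9,
    true_uni = c(fresh = 0.7, frozen = 0.7)), "true_lbr_curve")
})

test_that("simulation is reproducible and schema-complete", {
  cfg <- clinic_sim_config(n_transfers = 300, seed = 10)
  r1 <- simulate_clinic(cfg)
  r2 <- simulate_clinic(cfg)
  expect_identical(r1, r2)
  expect_named(r1, c("age_at_retrieval", "embryo_stage", "cycle_type",
                     "n_transferred", "n_live_born", "n_fetal_heartbeats"))
  expect_true(all(r1$n_live_born <= r1$n_transferred))
  expect_true(all(r1$n_live_born >= 0))
})

test_that("per-embryo birth rate converges to the marginal truth", {
  # the marginal rate must be lbr regardless of uni
  for (uni in c(0.7, 1)) {
    rec <- simulate_clinic(two_embryo_config(25000, lbr = 0.3, uni = uni,
                                             seed = 50 + round(10 * uni)))
    emp <- sum(rec$n_live_born) / sum(rec$n_transferred)
    se <- sqrt(0.3 * 0.7 / sum(rec$n_transferred))  # conservative SE
    expect_lt(abs(emp - 0.3), 3 * se * 2)  # allow for birth correlation
  }
})

test_that("zero rates produce zero births", {
  cfg <- clinic_sim_config(n_transfers = 200,
                           true_lbr_curve = function(a, s, c) 0,
                           seed = 3)
  expect_true(all(simulate_clinic(cfg)$n_live_born == 0))
})

test_that("empirical twin rate matches L1*L2/uni", {
  rec <- simulate_clinic(two_embryo_config(40000, lbr = 0.3, uni = 0.7,
                                           seed = 17))
  p_twin <- 0.09 / 0.7
  emp <- mean(rec$n_live_born == 2)
  se <- sqrt(p_twin * (1 - p_twin) / nrow(rec))
  expect_lt(abs(emp - p_twin), 3 * se)
})

test_that("outcome frequencies match the exact distribution (chi-square)", {
  for (seed in c(2, 23)) {
    rec <- simulate_clinic(clinic_sim_config(
      n_transfers = 6000,
      age_distribution = c("30" = 1),
      category_mix = c("frozen cleavage" = 1),
      embryos_per_transfer = c("3" = 1),
      true_lbr_curve = function(a, s, c) 0.25,
      true_uni = c(fresh = 0.6, frozen = 0.6),
      seed = seed))
    expected <- outcome_distribution(rep(0.25, 3), 0.6)
    observed <- tabulate(rec$n_live_born + 1L, nbins = 4)
    gof <- chisq.test(observed, p = expected)
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("simulate -> fit recovers the rate curve and uni end to end", {
  cfg <- clinic_sim_config(n_transfers = 8000, seed = 101)
  rec <- simulate_clinic(cfg)
  tab <- fit_lbr_table(rec, B = 200, seed = 5)
  # each well-populated cell within 3 bootstrap SEs of its estimand (the
  # n^2-weighted true rate over the ages its window pools)
  big <- tab[tab$n_transfers >= 100 & !is.na(tab$ci_low), ]
  truth <- vapply(seq_len(nrow(big)), function(i) {
    tg <- if (big$age_label[i] == "<=34") "<=34" else
      as.integer(big$age_label[i])
    sel <- assign_age_group(rec$age_at_retrieval, tg) &
      rec$embryo_stage == big$stage[i] & rec$cycle_type == big$cycle[i]
    Ltrue <- default_lbr_curve(rec$age_at_retrieval[sel],
                               big$stage[i], big$cycle[i])
    sum(rec$n_transferred[sel]^2 * Ltrue) / sum(rec$n_transferred[sel]^2)
  }, numeric(1))
  boot_se <- (big$ci_high - big$ci_low) / (2 * 1.96)
  expect_true(all(abs(big$lbr - truth) < 3 * boot_se))
  fit <- suppressMessages(fit_uni(rec, tab, on_missing_cell = "drop"))
  expect_lt(abs(fit$value - 0.70), 0.05)
})

test_that("uni precision improves as 1/sqrt(n) across cohort sizes", {
  study <- uni_sample_size_study(n_grid = c(800, 3200), n_replicates = 50,
                                 B = 200, seed = 4)
  expect_lt(study$mean_half_width[2], study$mean_half_width[1])
  # quadrupling n should halve the half-width, within 20%
  ratio <- study$mean_half_width[1] / study$mean_half_width[2]
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})
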