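test_that("age-group membership follows the pooled/moving-window scheme", {
  expect_true(assign_age_group(33, 35))   # window 33-37
  expect_false(assign_age_group(38, 35))
  expect_true(assign_age_group(29, "<=34"))
  expect_true(assign_age_group(22, 30))   # under-25 ages join the pooled group
  expect_false(assign_age_group(35, "<=34"))
  expect_true(all(assign_age_group(41:45, 43)))  # edge window extends to 45
  expect_error(assign_age_group(30, 44), "outside the supported range")
  expect_error(assign_age_group(30, "35-39"), "unknown age-group label")
})

test_that("least-squares rate matches the closed form and a generic solver", {
  rec <- transfer_df(c(2, 1), c(1, 0))
  expect_equal(estimate_lbr(rec), 0.4)  # (2*1 + 1*0) / (4 + 1)
  expect_equal(estimate_lbr(transfer_df(c(2, 2), c(2, 0))), 0.5)
  # all single-embryo transfers reduce to the sample mean
  expect_equal(estimate_lbr(transfer_df(rep(1, 4), c(1, 0, 0, 0))), 0.25)
  # generic least-squares oracle: lm through the origin on n
  rec2 <- transfer_df(c(3, 2, 2, 1, 1), c(2, 1, 0, 1, 0))
  fit <- lm(n_live_born ~ 0 + n_transferred, data = rec2)
  expect_equal(estimate_lbr(rec2), unname(coef(fit)), tolerance = 1e-12)
  expect_error(estimate_lbr(transfer_df(1, 1)[0, ]), "zero")
})

test_that("simplified mode is the pooled ratio and matches LS for equal n", {
  expect_equal(estimate_lbr_simplified(transfer_df(c(2, 1), c(1, 0))), 1 / 3)
  expect_equal(estimate_lbr_simplified(transfer_df(c(2, 2, 3), c(2, 0, 1))),
               3 / 7)
  set.seed(11)
  for (n_per in c(1, 2, 3)) {
    rec <- transfer_df(rep(n_per, 30), rbinom(30, n_per, 0.4))
    expect_equal(estimate_lbr(rec), estimate_lbr_simplified(rec),
                 tolerance = 1e-12)
  }
})

test_that("least-squares estimate is invariant to duplicating the records", {
  rec <- transfer_df(c(3, 2, 1, 2), c(1, 2, 0, 1))
  expect_equal(estimate_lbr(rbind(rec, rec)), estimate_lbr(rec),
               tolerance = 1e-12)
})

test_that("ongoing-pregnancy outcome uses heartbeat counts", {
  rec <- transfer_df(c(2, 2), c(0, 1))
  rec$n_fetal_heartbeats <- c(2L, 1L)
  expect_equal(estimate_lbr(rec, outcome = "ongoing_pregnancy"), 6 / 8)
  rec$n_fetal_heartbeats <- NULL
  expect_error(estimate_lbr(rec, outcome = "ongoing_pregnancy"),
               "n_fetal_heartbeats")
})

test_that("bootstrap CI is deterministic, degenerate-safe, and ordered", {
  rec <- transfer_df(rep(1, 10), c(rep(1, 4), rep(0, 6)))
  ci1 <- bootstrap_lbr_ci(rec, B = 300, seed = 42)
  ci2 <- bootstrap_lbr_ci(rec, B = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1[["ci_low"]] <= ci1[["ci_high"]])
  # identical records: the resampled estimator never moves
  all_same <- transfer_df(rep(1, 5), rep(1, 5))
  expect_equal(unname(bootstrap_lbr_ci(all_same, B = 200, seed = 1)),
               c(1, 1))
  expect_warning(ci <- bootstrap_lbr_ci(rec[1, ], B = 200, seed = 1),
                 "CI undefined")
  expect_true(all(is.na(ci)))
  expect_error(bootstrap_lbr_ci(rec, B = 50, seed = 1), "at least 200")
})

test_that("bootstrap CI covers the truth at roughly the nominal rate", {
  # 60 simulation replicates of 300 single-embryo transfers at rate 0.3;
  # binomial(60, 0.95) leaves coverage below 51/60 with prob < 1e-3
  hits <- 0L
  for (r in 1:60) {
    set.seed(1000 + r)
    rec <- transfer_df(rep(1, 300), rbinom(300, 1, 0.3))
    ci <- bootstrap_lbr_ci(rec, B = 400, seed = r)
    hits <- hits + (ci[["ci_low"]] <= 0.3 && 0.3 <= ci[["ci_high"]])
  }
  expect_gte(hits, 51L)
})

test_that("fitted table has one cell per populated group and recovers rates", {
  cfg <- clinic_sim_config(n_transfers = 3000,
                           true_lbr_curve = function(a, s, c) 0.3,
                           seed = 5)
  rec <- simulate_clinic(cfg)
  tab <- fit_lbr_table(rec, B = 300, seed = 2)
  expect_s3_class(tab, "lbr_table")
  expect_true(all(tab$n_transfers >= 1))
  expect_true(all(tab$lbr >= 0 & tab$lbr <= 1))
  ok <- !is.na(tab$ci_low)
  expect_true(all(tab$ci_low[ok] <= tab$lbr[ok] + 1e-12) &&
                all(tab$lbr[ok] <= tab$ci_high[ok] + 1e-12))
  # constant true rate: every well-populated cell lands near 0.3
  big <- tab[tab$n_transfers >= 50, ]
  expect_true(all(abs(big$lbr - 0.3) < 0.08))
})

test_that("records only in the pooled ages yield only reachable cells", {
  set.seed(4)
  # ages up to 32 sit below every moving window: pooled cell only
  rec <- transfer_df(rep(2, 16), rbinom(16, 2, 0.3), age = rep(25:32, 2))
  tab <- fit_lbr_table(rec, ci = FALSE)
  expect_identical(unique(tab$age_label), "<=34")
  # a category with no records is absent, not zero
  expect_false(any(tab$cycle == "frozen"))
  # raw ages 33-34 additionally feed the windows centered on 35 and 36
  rec2 <- transfer_df(rep(2, 20), rbinom(20, 2, 0.3), age = rep(25:34, 2))
  tab2 <- fit_lbr_table(rec2, ci = FALSE)
  expect_setequal(unique(tab2$age_label), c("<=34", "35", "36"))
})

test_that("cell lookup maps ages to their reporting cells", {
  rec <- rbind(transfer_df(rep(2, 30), rbinom(30, 2, 0.4), age = 30),
               transfer_df(rep(2, 30), rbinom(30, 2, 0.3), age = 37))
  tab <- fit_lbr_table(rec, ci = FALSE)
  L <- lookup_lbr(tab, c(28, 37, 44), "blastocyst", "fresh")
  expect_equal(L[1], tab$lbr[tab$age_label == "<=34"])
  expect_equal(L[2], tab$lbr[tab$age_label == "37"])
  expect_true(is.na(L[3]))  # beyond the moving range: no cell
})
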