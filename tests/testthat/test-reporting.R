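test_that("risk bands split exactly at 10, 20, and 30 percent", {
  expect_equal(risk_band(c(0, 9.999, 10, 19.999, 20, 29.999, 30, 95)),
               c("green", "green", "yellow", "yellow", "red", "red",
                 "gray", "gray"))
})

test_that("prediction table reproduces the two-embryo binomial arithmetic", {
  tab <- build_prediction_table(0.3, 1, max_embryos = 2)
  expect_equal(tab$total_delivery_rate, c(0.3, 0.51), tolerance = 1e-12)
  expect_equal(tab$pct_multiples[1], 0)
  expect_equal(tab$risk_band[1], "green")
  expect_equal(tab$pct_twins[2], 100 * 0.09 / 0.51, tolerance = 1e-12)
  expect_equal(tab$risk_band[2], "yellow")
})

test_that("prediction table rows match the enumeration oracle", {
  for (n in 2:3) {
    tab <- build_prediction_table(0.35, 0.70, max_embryos = n)
    o <- oracle_distribution(rep(0.35, n), 0.70)
    expect_equal(tab$total_delivery_rate[n], 1 - o[1], tolerance = 1e-12)
    twins <- 100 * o[3] / (1 - o[1])
    expect_equal(tab$pct_twins[n], twins, tolerance = 1e-12)
    expect_equal(tab$pct_multiples[n],
                 tab$pct_twins[n] + tab$pct_triplet_or_more[n],
                 tolerance = 1e-12)
    expect_equal(tab$risk_band[n], risk_band(tab$pct_multiples[n]))
  }
})

test_that("delivery rate and multiples risk grow with embryos transferred", {
  for (case in list(c(0.2, 0.7), c(0.35, 0.7), c(0.3, 1))) {
    tab <- build_prediction_table(case[1], case[2], max_embryos = 5)
    expect_true(all(diff(tab$total_delivery_rate) > 0))
    expect_true(all(diff(tab$pct_multiples[-1]) > 0))
  }
  # and multiples risk falls as uni rises (fixed rate, 2 embryos)
  pm <- vapply(seq(0.35, 1, by = 0.05), function(u) {
    build_prediction_table(0.35, u, max_embryos = 2)$pct_multiples[2]
  }, numeric(1))
  expect_true(all(diff(pm) < 0))
})

test_that("zero-rate and ill-formed inputs are flagged, not tabulated", {
  tab <- build_prediction_table(0, 0.7, max_embryos = 3)
  expect_true(all(tab$total_delivery_rate == 0))
  expect_true(all(!tab$defined))
  expect_true(all(is.na(tab$pct_multiples)))
  expect_error(build_prediction_table(0.8, 0.7), "ill-formed")
})

test_that("clinic tables cover every fitted cell and flag lbr > uni", {
  rec <- simulate_clinic(clinic_sim_config(n_transfers = 1500, seed = 9))
  lbr_tab <- fit_lbr_table(rec, ci = FALSE)
  tabs <- build_clinic_tables(lbr_tab, uni_fresh = 0.68, uni_frozen = 0.75)
  expect_length(tabs, nrow(lbr_tab))
  has_table <- vapply(tabs, function(e) !is.null(e$table), TRUE)
  flagged <- vapply(tabs, function(e) !is.null(e$warning), TRUE)
  expect_true(all(xor(has_table, flagged)))
  expect_true(all(lbr_tab$lbr[flagged] >
                    ifelse(lbr_tab$cycle[flagged] == "fresh", 0.68, 0.75)))
  # a low artificial uni forces identifiability warnings
  tabs2 <- build_clinic_tables(lbr_tab, uni_fresh = 0.01, uni_frozen = 0.01)
  expect_true(any(vapply(tabs2, function(e) !is.null(e$warning), TRUE)))
})

test_that("simplified reference grid handles the boundary lbr = uni", {
  grid <- simplified_reference_table(uni = 0.70,
                                     lbr_grid = c(0, 0.35, 0.70, 0.75),
                                     max_embryos = 2)
  # lbr = uni: conditional rate 1, so delivery rate = uni, all twins
  at_bound <- grid[grid$lbr == 0.70 & grid$n_embryos == 2, ]
  expect_equal(at_bound$total_delivery_rate, 0.70, tolerance = 1e-12)
  expect_equal(at_bound$pct_twins, 100, tolerance = 1e-12)
  # lbr = 0 rows are flagged as undefined
  expect_true(all(!grid$defined[grid$lbr == 0]))
  # lbr above uni is an ill-formed grid entry, flagged not computed
  expect_true(all(!grid$defined[grid$lbr == 0.75]))
  # interior entries match the oracle
  o <- oracle_distribution(c(0.35, 0.35), 0.70)
  mid <- grid[grid$lbr == 0.35 & grid$n_embryos == 2, ]
  expect_equal(mid$total_delivery_rate, 1 - o[1], tolerance = 1e-12)
})

test_that("curve export carries rates and intervals for plotting", {
  rec <- simulate_clinic(clinic_sim_config(n_transfers = 800, seed = 2))
  tab <- fit_lbr_table(rec, B = 200, seed = 3)
  path <- tempfile(fileext = ".csv")
  lbr_curve_export(tab, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$lbr, tab$lbr, tolerance = 1e-9)
})
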