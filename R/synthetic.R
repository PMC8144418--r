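# --- synthetic clinic simulator --------------------------------------------
#
# The clinic's own transfer records are not public, so tests and worked
# examples run on synthetic cohorts generated under the exact mechanism the
# model assumes: per transfer, universal conditions are favorable with
# probability uni; when unfavorable no embryo implants; when favorable each
# embryo delivers independently at its conditional rate lbr/uni.

#' Default age trend of per-embryo live birth rates
#'
#' A simple clinic-shaped rate surface used by the default simulator
#' configuration: category base rates (fresh blastocyst 0.40, frozen
#' blastocyst 0.35, fresh cleavage 0.25, frozen cleavage 0.15) held flat
#' through age 34, then declining linearly by 9% of the base per year so
#' that rates at 44 are a tenth of the young-group rate — mimicking the
#' steep age decline clinics observe between 35 and 44.
#'
#' @param age,stage,cycle vectors (recycled) describing transfers.
#' @return Numeric vector of per-embryo rates.
#' @export
default_lbr_curve <- function(age, stage, cycle) {
  base <- ifelse(cycle == "fresh",
                 ifelse(stage == "blastocyst", 0.40, 0.25),
                 ifelse(stage == "blastocyst", 0.35, 0.15))
  mult <- pmax(1 - 0.09 * pmax(age - 34, 0), 0.1)
  base * mult
}

#' Configuration for a synthetic clinic cohort
#'
#' Defaults mirror a mid-size IVF clinic cohort: 684 transfers averaging
#' 2.4 embryos per transfer, ages 25-44 centered in the mid-30s, all four
#' transfer categories with frozen cleavage the rarest, and a common true
#' universal factors fraction of 0.70 for both cycle types.
#'
#' @param n_transfers number of transfers to simulate.
#' @param age_distribution named numeric vector: sampling weight per age.
#' @param category_mix named weights over
#'   `"fresh blastocyst"`, `"frozen blastocyst"`, `"fresh cleavage"`,
#'   `"frozen cleavage"`.
#' @param embryos_per_transfer named weights over embryos placed (names are
#'   counts).
#' @param true_lbr_curve function `(age, stage, cycle) -> rate` giving the
#'   true marginal per-embryo live birth rate.
#' @param true_uni named numeric `c(fresh = , frozen = )` true universal
#'   factors fraction per cycle type, each in (0, 1].
#' @param seed integer seed.
#' @return Object of class `clinic_sim_config`.
#' @export
clinic_sim_config <- function(n_transfers = 684L,
                              age_distribution = NULL,
                              category_mix = c("fresh blastocyst" = 0.40,
                                               "frozen blastocyst" = 0.30,
                                               "fresh cleavage" = 0.17,
                                               "frozen cleavage" = 0.13),
                              embryos_per_transfer = c("1" = 0.15,
                                                       "2" = 0.30,
                                                       "3" = 0.55),
                              true_lbr_curve = default_lbr_curve,
                              true_uni = c(fresh = 0.70, frozen = 0.70),
                              seed = 1L) {
  if (is.null(age_distribution)) {
    ages <- 25:44
    age_distribution <- stats::setNames(stats::dnorm(ages, 35, 5), ages)
  }
  cfg <- list(n_transfers = as.integer(n_transfers),
              age_distribution = age_distribution,
              category_mix = category_mix,
              embryos_per_transfer = embryos_per_transfer,
              true_lbr_curve = true_lbr_curve,
              true_uni = true_uni,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "clinic_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_transfers < 1L) stop("n_transfers must be >= 1", call. = FALSE)
  for (fld in c("age_distribution", "category_mix", "embryos_per_transfer")) {
    w <- cfg[[fld]]
    if (is.null(names(w)) || any(w < 0) || sum(w) <= 0) {
      stop("invalid `", fld, "`: named non-negative weights with positive ",
           "sum required", call. = FALSE)
    }
  }
  cats <- strsplit(names(cfg$category_mix), " ", fixed = TRUE)
  for (cc in cats) {
    if (length(cc) != 2L || !cc[1] %in% CYCLES || !cc[2] %in% STAGES) {
      stop("invalid `category_mix` name: expected '<cycle> <stage>' such as ",
           "'fresh blastocyst'", call. = FALSE)
    }
  }
  if (any(as.integer(names(cfg$embryos_per_transfer)) < 1L)) {
    stop("invalid `embryos_per_transfer`: counts must be >= 1",
         call. = FALSE)
  }
  if (!all(CYCLES %in% names(cfg$true_uni)) ||
      any(cfg$true_uni <= 0) || any(cfg$true_uni > 1)) {
    stop("invalid `true_uni`: need fresh and frozen values in (0, 1]",
         call. = FALSE)
  }
  # every reachable (age, category) must satisfy lbr <= uni of its cycle
  ages <- as.integer(names(cfg$age_distribution))
  for (cc in cats) {
    rates <- cfg$true_lbr_curve(ages, cc[2], cc[1])
    if (any(rates < 0 | rates > 1)) {
      stop("invalid `true_lbr_curve`: rates outside [0, 1]", call. = FALSE)
    }
    if (any(rates > cfg$true_uni[[cc[1]]])) {
      stop("invalid `true_lbr_curve`: rate exceeds true_uni for ",
           cc[1], " ", cc[2], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate a synthetic clinic's transfer records
#'
#' Draws each transfer's age, category and embryo count from the
#' configured mixes, then its outcome under the universal-factors
#' mechanism. Fetal-heartbeat counts are reported equal to live-birth
#' counts (no pregnancy-loss dynamics are simulated).
#'
#' @param config a [clinic_sim_config()].
#' @return Data frame of transfer records with columns `age_at_retrieval`,
#'   `embryo_stage`, `cycle_type`, `n_transferred`, `n_live_born`,
#'   `n_fetal_heartbeats`.
#' @export
simulate_clinic <- function(config = clinic_sim_config()) {
  validate_sim_config(config)
  n <- config$n_transfers
  with_seed(config$seed, {
    ages <- as.integer(names(config$age_distribution))
    age <- ages[sample.int(length(ages), n, replace = TRUE,
                           prob = config$age_distribution)]
    cat_idx <- sample(seq_along(config$category_mix), n, replace = TRUE,
                      prob = config$category_mix)
    parts <- strsplit(names(config$category_mix), " ", fixed = TRUE)
    cycle <- vapply(parts, `[`, "", 1L)[cat_idx]
    stage <- vapply(parts, `[`, "", 2L)[cat_idx]
    n_emb <- as.integer(names(config$embryos_per_transfer))[
      sample(seq_along(config$embryos_per_transfer), n, replace = TRUE,
             prob = config$embryos_per_transfer)]
    lbr <- config$true_lbr_curve(age, stage, cycle)
    uni <- unname(config$true_uni[cycle])
    favorable <- stats::runif(n) < uni
    births <- integer(n)
    births[favorable] <- rbinom(sum(favorable), n_emb[favorable],
                                (lbr / uni)[favorable])
    data.frame(age_at_retrieval = age,
               embryo_stage = stage,
               cycle_type = cycle,
               n_transferred = n_emb,
               n_live_born = births,
               n_fetal_heartbeats = births,
               stringsAsFactors = FALSE)
  })
}

#' How many multiple-embryo transfers does a precise UNI need?
#'
#' Simulates cohorts of two-embryo transfers at a common true per-embryo
#' rate and true universal factors fraction, fits the rate and UNI to each
#' cohort, bootstraps the 95% CI for UNI, and reports the mean CI
#' half-width per cohort size. Precision scales as 1/sqrt(n), so the
#' half-width column can be read as a sample-size requirement for a target
#' CI width.
#'
#' @param true_lbr,true_uni true simulation parameters (defaults 0.30 and
#'   0.70, typical of a blastocyst program).
#' @param n_grid ascending cohort sizes (numbers of two-embryo transfers).
#' @param n_replicates simulated cohorts per size (>= 50).
#' @param B bootstrap resamples per cohort.
#' @param seed integer seed.
#' @param grid_step UNI grid resolution.
#' @return Data frame of class `uni_power_study`: `n`, `mean_half_width`,
#'   `sd_half_width`, `mean_uni`, `n_replicates`. The attribute
#'   `"crossing_n"` holds the smallest grid size whose mean half-width is
#'   at or below the attribute `"target_half_width"` (0.05).
#' @export
uni_sample_size_study <- function(true_lbr = 0.30, true_uni = 0.70,
                                  n_grid = c(1250L, 2500L, 5000L, 10000L,
                                             20000L),
                                  n_replicates = 50L, B = 200L, seed = 1L,
                                  grid_step = 0.01) {
  stopifnot(!is.unsorted(n_grid), n_replicates >= 50L,
            true_lbr >= 0, true_lbr <= true_uni, true_uni <= 1)
  rows <- lapply(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    hw <- numeric(n_replicates)
    est <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, gi * 100003L + r)
      cfg <- clinic_sim_config(
        n_transfers = n,
        age_distribution = c("30" = 1),
        category_mix = c("fresh blastocyst" = 1),
        embryos_per_transfer = c("2" = 1),
        true_lbr_curve = function(age, stage, cycle) true_lbr,
        true_uni = c(fresh = true_uni, frozen = true_uni),
        seed = rep_seed)
      records <- simulate_clinic(cfg)
      tab <- fit_lbr_table(records, ci = FALSE)
      boot <- bootstrap_uni_ci(records, tab, B = B,
                               seed = derive_seed(rep_seed, 1L),
                               grid_step = grid_step)
      hw[r] <- boot$half_width
      est[r] <- boot$value
    }
    data.frame(n = n, mean_half_width = mean(hw), sd_half_width = sd(hw),
               mean_uni = mean(est), n_replicates = n_replicates)
  })
  out <- do.call(rbind, rows)
  target <- 0.05
  below <- out$n[out$mean_half_width <= target]
  attr(out, "target_half_width") <- target
  attr(out, "crossing_n") <- if (length(below)) min(below) else NA_integer_
  class(out) <- c("uni_power_study", "data.frame")
  out
}

#' @export
print.uni_power_study <- function(x, ...) {
  cat("Precision of the fitted universal factors fraction by cohort size\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  cat("Smallest size with mean 95% CI half-width <=",
      attr(x, "target_half_width"), ":", attr(x, "crossing_n"), "\n")
  invisible(x)
}
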