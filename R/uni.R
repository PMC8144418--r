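# --- universal factors fraction (UNI): likelihood fitting ------------------
#
# Only multiple-embryo transfers are informative about UNI. Each such
# transfer with n embryos of (cell) per-embryo rate L has singleton
# probability n * L * (1 - L/uni)^(n - 1): favorable conditions (prob uni)
# times exactly one of n conditional events of rate L/uni. Larger uni means
# more singletons and fewer multiples for the same marginal rates.

# collapse multiple-embryo transfers to unique (L, n, outcome) combinations;
# the log-likelihood is then a weighted sum over a handful of combos, which
# makes grid search and bootstrap refits cheap at any cohort size.
uni_prep <- function(records, lbr_table,
                     likelihood = c("singleton", "multinomial"),
                     on_missing_cell = c("error", "drop")) {
  likelihood <- match.arg(likelihood)
  on_missing_cell <- match.arg(on_missing_cell)
  stopifnot(is.data.frame(records))
  multi <- records[records$n_transferred >= 2L, , drop = FALSE]
  if (nrow(multi) == 0L) {
    stop("no multiple-embryo transfers: UNI cannot be estimated",
         call. = FALSE)
  }
  L <- lookup_lbr(lbr_table, multi$age_at_retrieval, multi$embryo_stage,
                  multi$cycle_type)
  if (anyNA(L)) {
    if (on_missing_cell == "error") {
      stop(sum(is.na(L)), " transfer(s) fall in age-group x category cells ",
           "absent from the fitted rate table", call. = FALSE)
    }
    message("dropping ", sum(is.na(L)), " transfer(s) without a fitted cell")
    multi <- multi[!is.na(L), , drop = FALSE]
    L <- L[!is.na(L)]
    if (nrow(multi) == 0L) {
      stop("no multiple-embryo transfers with a fitted cell", call. = FALSE)
    }
  }
  out <- if (likelihood == "singleton") {
    as.integer(multi$n_live_born == 1L)
  } else {
    multi$n_live_born
  }
  codes <- as.integer(interaction(L, multi$n_transferred, out, drop = TRUE))
  first <- !duplicated(codes)
  combos <- data.frame(L = L[first], n = multi$n_transferred[first],
                       out = out[first])
  combos <- combos[order(codes[first]), , drop = FALSE]  # row i <-> code i
  rownames(combos) <- NULL
  list(
    likelihood = likelihood,
    id = codes,
    n_records = nrow(multi),
    combos = combos,
    counts = tabulate(codes, nbins = max(codes))
  )
}

singleton_prob <- function(L, n, uni) {
  n * L * (1 - L / uni)^(n - 1)
}

uni_ll_combos <- function(combos, counts, uni, likelihood) {
  keep <- counts > 0
  if (likelihood == "singleton") {
    p <- singleton_prob(combos$L[keep], combos$n[keep], uni)
    y <- combos$out[keep]
    terms <- ifelse(y == 1L, log(p), log1p(-p))
  } else {
    terms <- mapply(function(L, n, k) {
      log(outcome_distribution(rep(L, n), uni)[[k + 1L]])
    }, combos$L[keep], combos$n[keep], combos$out[keep])
  }
  sum(counts[keep] * terms)
}

uni_grid <- function(lower, grid_step) {
  base <- seq(0, 1, by = grid_step)
  if (base[length(base)] < 1) base <- c(base, 1)
  sort(unique(c(lower, base[base > lower + 1e-12])))
}

fit_uni_core <- function(combos, counts, grid_step, likelihood) {
  keep <- counts > 0
  lower <- max(combos$L[keep])
  if (lower == 0) {
    stop("all cell live birth rates are zero: UNI is not identifiable",
         call. = FALSE)
  }
  grid <- uni_grid(lower, grid_step)
  ll <- vapply(grid, function(u) uni_ll_combos(combos, counts, u, likelihood),
               numeric(1))
  best <- max(ll)
  idx <- max(which(ll == best))  # ties broken toward the larger uni
  m <- length(grid)
  rising_at_one <- m >= 2L && ll[m] > ll[m - 1L] + 1e-12
  # observed vs predicted singleton counts at uni = 1 (the independence
  # model); an excess that not even independence can explain — beyond 2
  # binomial SEs, so chance fluctuations under a true uni of 1 rarely
  # trip it — marks the fit as non-identifiable within (0, 1]
  s_obs <- sum(counts[keep][combos$out[keep] == 1L])
  p1 <- singleton_prob(combos$L[keep], combos$n[keep], 1)
  s_pred1 <- sum(counts[keep] * p1)
  s_sd1 <- sqrt(sum(counts[keep] * p1 * (1 - p1)))
  list(value = grid[idx],
       non_identifiable = rising_at_one && s_obs > s_pred1 + 2 * s_sd1,
       grid = data.frame(uni = grid, log_lik = ll))
}

#' Log-likelihood of a universal factors fraction
#'
#' Sums, over every multiple-embryo transfer, the Bernoulli log-likelihood
#' of its singleton indicator (default), or the full multinomial
#' log-likelihood of its exact live-birth count, under the universal-factors
#' outcome model with the transfer's fitted cell rate.
#'
#' @param records transfer records; only rows with `n_transferred >= 2`
#'   contribute.
#' @param lbr_table fitted rate table ([fit_lbr_table()]) supplying each
#'   transfer's per-embryo rate.
#' @param uni candidate universal factors fraction; must be at least the
#'   largest cell rate among the transfers.
#' @param likelihood `"singleton"` (the fitting target: singleton vs
#'   non-singleton outcome) or `"multinomial"` (all outcome counts; provided
#'   for sensitivity analysis).
#' @return The log-likelihood (may be `-Inf`).
#' @export
uni_log_likelihood <- function(records, lbr_table, uni,
                               likelihood = c("singleton", "multinomial")) {
  likelihood <- match.arg(likelihood)
  prep <- uni_prep(records, lbr_table, likelihood)
  keep <- prep$counts > 0
  lower <- max(prep$combos$L[keep])
  if (uni < lower - 1e-12 || uni > 1 || uni <= 0) {
    stop("`uni` must lie in [max cell rate, 1] = [", signif(lower, 3),
         ", 1]", call. = FALSE)
  }
  uni_ll_combos(prep$combos, prep$counts, uni, likelihood)
}

#' Fit the universal factors fraction by likelihood grid search
#'
#' Grid search over `uni` in `[max cell rate, 1]` at `grid_step` resolution,
#' maximizing the singleton-indicator likelihood of the multiple-embryo
#' transfers (ties broken toward the larger `uni`). When the likelihood is
#' still rising at `uni = 1` and the observed singleton count exceeds even
#' the independence model's prediction, the fit is flagged non-identifiable
#' (the value reported is the constrained maximum at 1).
#'
#' @inheritParams uni_log_likelihood
#' @param grid_step grid resolution (default 0.01: rates are counselled to
#'   two decimals).
#' @param on_missing_cell `"error"` (default) rejects transfers whose
#'   age-group x category cell is absent from `lbr_table`; `"drop"`
#'   excludes them with a message (e.g. ages beyond the moving range).
#' @return Object of class `uni_estimate`: `value`, `non_identifiable`,
#'   `grid` (data frame of `uni`, `log_lik`), `n_multiple_transfers`,
#'   `likelihood`.
#' @export
fit_uni <- function(records, lbr_table, grid_step = 0.01,
                    likelihood = c("singleton", "multinomial"),
                    on_missing_cell = c("error", "drop")) {
  likelihood <- match.arg(likelihood)
  prep <- uni_prep(records, lbr_table, likelihood, on_missing_cell)
  core <- fit_uni_core(prep$combos, prep$counts, grid_step, likelihood)
  structure(
    list(value = core$value, non_identifiable = core$non_identifiable,
         grid = core$grid, n_multiple_transfers = prep$n_records,
         likelihood = likelihood, grid_step = grid_step),
    class = "uni_estimate"
  )
}

#' @export
print.uni_estimate <- function(x, ...) {
  cat("Universal factors fraction (", x$likelihood, " likelihood, ",
      x$n_multiple_transfers, " multiple-embryo transfers)\n", sep = "")
  cat("  UNI =", format(x$value, digits = 3),
      if (x$non_identifiable) " [non-identifiable: outcomes exceed the uni = 1 prediction]" else "",
      "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the fitted universal factors fraction
#'
#' Resamples the multiple-embryo transfers with replacement and refits
#' `uni` against the same (fixed) rate table, i.e. the interval describes
#' the second-stage uncertainty of UNI given the fitted per-embryo rates.
#'
#' @inheritParams fit_uni
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return List with `ci` (`c(ci_low, ci_high)`), `half_width`, `value`
#'   (point estimate on the full data), and `boot` (the resampled
#'   estimates).
#' @export
bootstrap_uni_ci <- function(records, lbr_table, B = 200L, level = 0.95,
                             seed = 1L, grid_step = 0.01,
                             likelihood = c("singleton", "multinomial"),
                             on_missing_cell = c("error", "drop")) {
  likelihood <- match.arg(likelihood)
  prep <- uni_prep(records, lbr_table, likelihood, on_missing_cell)
  core <- fit_uni_core(prep$combos, prep$counts, grid_step, likelihood)
  m <- prep$n_records
  nbin <- nrow(prep$combos)
  # resampling m transfers with replacement induces multinomial counts over
  # the unique (L, n, outcome) combinations; drawing those counts directly
  # is identical in distribution and independent of cohort size
  boot <- with_seed(seed, {
    draws <- stats::rmultinom(B, m, prob = prep$counts / m)
    vapply(seq_len(B), function(b) {
      tryCatch(fit_uni_core(prep$combos, draws[, b], grid_step,
                            likelihood)$value,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  list(ci = c(ci_low = ci[1], ci_high = ci[2]),
       half_width = (ci[2] - ci[1]) / 2,
       value = core$value, boot = boot)
}
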