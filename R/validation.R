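# --- cross-validation of the fitted model ----------------------------------

#' Randomly assign transfers to cross-validation folds
#'
#' Each record is assigned to one of `k` folds by an independent uniform
#' draw (fold sizes are therefore unequal); an assignment that leaves any
#' fold empty is redrawn so that every fold is usable.
#'
#' @param records data frame of transfer records.
#' @param k number of folds (default 10).
#' @param seed integer seed; assignment is reproducible given the seed.
#' @return Integer vector of fold ids (1..k), one per record, with the seed
#'   kept in attribute `"seed"`.
#' @export
assign_folds <- function(records, k = 10L, seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n == 0L) stop("no records to assign", call. = FALSE)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (k > n) stop("more folds than records", call. = FALSE)
  folds <- with_seed(seed, {
    for (attempt in 1:1000) {
      f <- sample.int(k, n, replace = TRUE)
      if (length(unique(f)) == k) break
    }
    f
  })
  if (length(unique(folds)) < k) {
    stop("could not draw an assignment with all folds non-empty",
         call. = FALSE)
  }
  structure(folds, seed = seed)
}

# simulate one transfer's outcome count B times under the model
simulate_outcomes <- function(L, n_emb, uni, B) {
  probs <- outcome_distribution(rep(L, n_emb), uni)
  sample.int(n_emb + 1L, B, replace = TRUE, prob = probs) - 1L
}

#' Cross-validate the universal-factors model
#'
#' Tenfold (by default) cross-validation: for each fold, the per-embryo
#' rate table and the universal factors fraction (separately for fresh and
#' frozen transfers) are fitted on the other folds, the held-out transfers'
#' outcomes are simulated `n_bootstrap` times from the fitted model, and
#' the fold's observed rates of singleton deliveries (exactly 1 infant),
#' twin deliveries (exactly 2), and total deliveries (at least 1) per
#' transfer are compared with their predictive distributions. The
#' standardized error of a fold-level rate is
#' (observed - predictive mean) / predictive SD; mean standardized errors
#' are tested against zero with a two-tailed Z-test (SE `1/sqrt(k)`).
#'
#' Held-out transfers whose age-group x category cell is unpopulated in the
#' training folds cannot be predicted; they are excluded and counted. A
#' degenerate predictive distribution (SD 0) yields a flagged `NA`
#' standardized error rather than an infinity.
#'
#' @inheritParams assign_folds
#' @param n_bootstrap predictive simulations per fold (>= 1000 recommended).
#' @param comparison_mode `"fitted_uni"` predicts with the fitted universal
#'   factors fraction; `"uni_equals_1"` predicts with the independence
#'   model (universal factors always favorable) for comparison.
#' @param scheme an [age_group_scheme()].
#' @param outcome,mode passed to [fit_lbr_table()].
#' @param grid_step passed to [fit_uni()].
#' @return Object of class `validation_report`: `folds` (one row per fold
#'   per outcome with observed, predicted mean/SD, standardized error),
#'   `z_pvalues`, `qq` (per-outcome quantile pairs), `n_unpredictable`,
#'   `comparison_mode`.
#' @export
cross_validate <- function(records, k = 10L, n_bootstrap = 1000L, seed = 1L,
                           comparison_mode = c("fitted_uni", "uni_equals_1"),
                           scheme = age_group_scheme(),
                           outcome = c("live_birth", "ongoing_pregnancy"),
                           mode = c("least_squares", "simplified"),
                           grid_step = 0.01) {
  comparison_mode <- match.arg(comparison_mode)
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  folds <- assign_folds(records, k = k, seed = seed)
  rows <- list()
  n_unpredictable <- 0L
  for (f in sort(unique(folds))) {
    train <- records[folds != f, , drop = FALSE]
    test <- records[folds == f, , drop = FALSE]
    tab <- fit_lbr_table(train, scheme = scheme, outcome = outcome,
                         mode = mode, ci = FALSE)
    # UNI fitted separately per cycle type on the training folds
    uni_by_cycle <- sapply(CYCLES, function(cy) {
      if (comparison_mode == "uni_equals_1") return(1)
      sub <- train[train$cycle_type == cy, , drop = FALSE]
      tryCatch(suppressMessages(fit_uni(sub, tab, grid_step = grid_step,
                                        on_missing_cell = "drop")$value),
               error = function(e) NA_real_)
    })
    L <- lookup_lbr(tab, test$age_at_retrieval, test$embryo_stage,
                    test$cycle_type)
    uni <- uni_by_cycle[test$cycle_type]
    # a zero-rate cell predicts zero births whatever uni is, so such
    # transfers stay predictable even when UNI itself was unfittable
    uni[is.na(uni) & !is.na(L) & L == 0] <- 1
    # a transfer is predictable only if its cell exists, its cycle's UNI
    # could be fitted, and the fitted model is well-formed (L <= uni)
    ok <- !is.na(L) & !is.na(uni) & L <= uni
    n_unpredictable <- n_unpredictable + sum(!ok)
    pred <- test[ok, , drop = FALSE]
    Lp <- L[ok]
    unip <- uni[ok]
    if (nrow(pred) == 0L) next
    obs_k <- outcome_counts(pred, outcome)
    sim <- with_seed(derive_seed(seed, f), {
      vapply(seq_len(nrow(pred)), function(i) {
        simulate_outcomes(Lp[i], pred$n_transferred[i], unip[i], n_bootstrap)
      }, integer(n_bootstrap))
    })
    if (is.null(dim(sim))) sim <- matrix(sim, nrow = n_bootstrap)
    rate_obs <- c(singleton = mean(obs_k == 1L),
                  twin = mean(obs_k == 2L),
                  total = mean(obs_k >= 1L))
    rate_sim <- cbind(singleton = rowMeans(sim == 1L),
                      twin = rowMeans(sim == 2L),
                      total = rowMeans(sim >= 1L))
    for (oc in colnames(rate_sim)) {
      mu <- mean(rate_sim[, oc])
      sdv <- sd(rate_sim[, oc])
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, outcome = oc, observed = rate_obs[[oc]],
        predicted_mean = mu, predicted_sd = sdv,
        std_error = if (sdv > 0) (rate_obs[[oc]] - mu) / sdv else NA_real_,
        n_heldout = nrow(test), n_predicted = nrow(pred),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    stop("no fold produced predictions; training data too sparse",
         call. = FALSE)
  }
  folds_df <- do.call(rbind, rows)
  rownames(folds_df) <- NULL
  outcomes <- unique(folds_df$outcome)
  z_pvalues <- sapply(outcomes, function(oc) {
    e <- folds_df$std_error[folds_df$outcome == oc]
    e <- e[!is.na(e)]
    if (length(e) == 0L) return(NA_real_)
    z <- mean(e) * sqrt(length(e))
    2 * pnorm(-abs(z))
  })
  qq <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    e <- folds_df$std_error[folds_df$outcome == oc]
    e <- e[!is.na(e)]
    if (length(e) >= 3L) qq_points(e) else NULL
  })
  structure(
    list(folds = folds_df, z_pvalues = z_pvalues, qq = qq,
         n_unpredictable = n_unpredictable,
         comparison_mode = comparison_mode, k = k, seed = seed,
         n_bootstrap = n_bootstrap),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cross-validation (", x$k, " folds, ", x$n_bootstrap,
      " predictive simulations, mode = ", x$comparison_mode, ")\n", sep = "")
  agg <- stats::aggregate(std_error ~ outcome, data = x$folds, FUN = mean,
                          na.action = stats::na.omit)
  agg$z_pvalue <- x$z_pvalues[agg$outcome]
  names(agg)[2] <- "mean_std_error"
  print.data.frame(agg, digits = 3, row.names = FALSE)
  if (x$n_unpredictable > 0) {
    cat(x$n_unpredictable, "held-out transfer(s) were unpredictable",
        "(cell absent or UNI unavailable in training folds)\n")
  }
  invisible(x)
}

#' Normal quantile-quantile points for standardized errors
#'
#' Pairs the ordered errors with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`.
#'
#' @param errors numeric vector of at least 3 standardized errors.
#' @return Data frame with columns `theoretical` and `observed`.
#' @export
qq_points <- function(errors) {
  errors <- errors[!is.na(errors)]
  n <- length(errors)
  if (n < 3L) stop("need at least 3 errors for a Q-Q plot", call. = FALSE)
  data.frame(theoretical = qnorm(((1:n) - 0.5) / n),
             observed = sort(errors))
}
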