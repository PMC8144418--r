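STAGES <- c("cleavage", "blastocyst")
CYCLES <- c("fresh", "frozen")

outcome_counts <- function(records,
                           outcome = c("live_birth", "ongoing_pregnancy")) {
  outcome <- match.arg(outcome)
  if (outcome == "live_birth") {
    return(records$n_live_born)
  }
  if (is.null(records$n_fetal_heartbeats) ||
      anyNA(records$n_fetal_heartbeats)) {
    stop("ongoing-pregnancy outcome requested but `n_fetal_heartbeats` is ",
         "missing for some records", call. = FALSE)
  }
  records$n_fetal_heartbeats
}

#' Least-squares live birth rate per embryo for one group of transfers
#'
#' Each transfer contributes one equation, (embryos transferred) x LBR =
#' (live births observed); the scalar least-squares solution over a group of
#' transfers is `sum(n_i * b_i) / sum(n_i^2)`. When every transfer places
#' the same number of embryos this reduces to the simple pooled ratio, but
#' in general transfers of more embryos carry more weight. All records
#' passed in are assumed to belong to one age-group x category cell.
#'
#' @param records data frame of transfer records (columns `n_transferred`,
#'   `n_live_born`, optionally `n_fetal_heartbeats`).
#' @param outcome `"live_birth"` (default) or `"ongoing_pregnancy"` (fetal
#'   heartbeat at 6-8 weeks).
#' @return The least-squares rate, a probability.
#' @seealso [estimate_lbr_simplified()] for the pooled-ratio clinic mode.
#' @export
estimate_lbr <- function(records, outcome = c("live_birth",
                                              "ongoing_pregnancy")) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot estimate a live birth rate from zero transfers",
         call. = FALSE)
  }
  b <- outcome_counts(records, outcome)
  n <- records$n_transferred
  est <- sum(n * b) / sum(n^2)
  if (est < 0 || est > 1) {
    stop("least-squares rate outside [0, 1]; check record counts",
         call. = FALSE)
  }
  est
}

#' Simplified live birth rate: births divided by embryos transferred
#'
#' The pooled-ratio estimator `sum(b_i) / sum(n_i)` that a clinic can
#' compute by hand; identical to [estimate_lbr()] whenever every transfer
#' in the group places the same number of embryos.
#'
#' @inheritParams estimate_lbr
#' @return The pooled rate, a probability.
#' @export
estimate_lbr_simplified <- function(records,
                                    outcome = c("live_birth",
                                                "ongoing_pregnancy")) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot estimate a live birth rate from zero transfers",
         call. = FALSE)
  }
  b <- outcome_counts(records, outcome)
  sum(b) / sum(records$n_transferred)
}

#' Percentile-bootstrap confidence interval for a cell's live birth rate
#'
#' Resamples whole transfers (the independent units of the model's
#' equations) with replacement and recomputes the chosen estimator.
#'
#' @inheritParams estimate_lbr
#' @param B number of bootstrap resamples (at least 200).
#' @param mode `"least_squares"` or `"simplified"` estimator.
#' @param level confidence level.
#' @param seed integer seed; the interval is reproducible given the seed.
#' @return `c(ci_low, ci_high)`, or `c(NA, NA)` (with a warning) when the
#'   cell holds fewer than 2 transfers and no interval is defined.
#' @export
bootstrap_lbr_ci <- function(records, B = 500L,
                             outcome = c("live_birth", "ongoing_pregnancy"),
                             mode = c("least_squares", "simplified"),
                             level = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  if (B < 200L) stop("use at least 200 bootstrap resamples", call. = FALSE)
  m <- nrow(records)
  if (is.null(m) || m < 2L) {
    warning("fewer than 2 transfers in cell: CI undefined", call. = FALSE)
    return(c(ci_low = NA_real_, ci_high = NA_real_))
  }
  b <- outcome_counts(records, outcome)
  n <- records$n_transferred
  est_fun <- if (mode == "least_squares") {
    function(idx) sum(n[idx] * b[idx]) / sum(n[idx]^2)
  } else {
    function(idx) sum(b[idx]) / sum(n[idx])
  }
  stats <- with_seed(seed, {
    vapply(seq_len(B), function(i) est_fun(sample.int(m, m, replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Fit the full live-birth-rate table by age group and transfer category
#'
#' Estimates one live birth rate per embryo for every populated combination
#' of age group (pooled young group plus each moving-window target age) and
#' transfer category (fresh/frozen x cleavage/blastocyst). Because moving
#' windows overlap, a record can contribute to up to `2 * half_width + 1`
#' cells. Cells with no transfers are absent from the table rather than
#' reported as zero.
#'
#' @param records validated transfer records (see [load_transfers()] or
#'   [simulate_clinic()]).
#' @param scheme an [age_group_scheme()].
#' @inheritParams bootstrap_lbr_ci
#' @param ci logical; compute bootstrap CIs per cell (set `FALSE` to skip,
#'   e.g. inside cross-validation refits).
#' @return A data frame of class `lbr_table` with columns `age_label`,
#'   `stage`, `cycle`, `lbr`, `ci_low`, `ci_high`, `n_transfers`,
#'   `n_embryos`.
#' @export
fit_lbr_table <- function(records, scheme = age_group_scheme(),
                          outcome = c("live_birth", "ongoing_pregnancy"),
                          mode = c("least_squares", "simplified"),
                          ci = TRUE, B = 500L, seed = 1L) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  est_fun <- switch(mode, least_squares = estimate_lbr,
                    simplified = estimate_lbr_simplified)
  targets <- age_group_targets(scheme)
  rows <- list()
  cell_seed <- 0L
  for (tg in targets) {
    tg_arg <- if (grepl("^<=", tg)) tg else as.integer(tg)
    in_group <- assign_age_group(records$age_at_retrieval, tg_arg, scheme)
    for (cy in CYCLES) {
      for (st in STAGES) {
        sel <- in_group & records$cycle_type == cy & records$embryo_stage == st
        if (!any(sel)) next
        cell <- records[sel, , drop = FALSE]
        cell_seed <- cell_seed + 1L
        est <- est_fun(cell, outcome = outcome)
        if (ci && nrow(cell) >= 2L) {
          bounds <- bootstrap_lbr_ci(cell, B = B, outcome = outcome,
                                     mode = mode,
                                     seed = seed + cell_seed)
        } else {
          bounds <- c(ci_low = NA_real_, ci_high = NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          age_label = tg, stage = st, cycle = cy, lbr = est,
          ci_low = bounds[[1]], ci_high = bounds[[2]],
          n_transfers = nrow(cell), n_embryos = sum(cell$n_transferred),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    stop("no populated age-group x category cells in the records",
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "scheme") <- scheme
  attr(tab, "outcome") <- outcome
  attr(tab, "mode") <- mode
  class(tab) <- c("lbr_table", "data.frame")
  tab
}

#' Look up the fitted per-embryo rate for individual transfers
#'
#' Maps each transfer's exact age to its reporting cell (pooled group for
#' ages at or below the pooled maximum, own-age moving-window cell inside
#' the moving range) and returns that cell's fitted rate.
#'
#' @param lbr_table a fitted [fit_lbr_table()] result.
#' @param age,stage,cycle vectors describing the transfers (recycled to a
#'   common length).
#' @return Numeric vector of fitted rates; `NA` where no cell exists (age
#'   beyond the scheme, or a cell unpopulated in the training data).
#' @export
lookup_lbr <- function(lbr_table, age, stage, cycle) {
  scheme <- attr(lbr_table, "scheme")
  if (is.null(scheme)) scheme <- age_group_scheme()
  lab <- age_to_label(age, scheme)
  key <- paste(lab, stage, cycle)
  tab_key <- paste(lbr_table$age_label, lbr_table$stage, lbr_table$cycle)
  lbr_table$lbr[match(key, tab_key)]
}

#' @export
print.lbr_table <- function(x, ...) {
  cat("Live birth rates per embryo (", attr(x, "outcome"), ", ",
      attr(x, "mode"), " fit): ", nrow(x), " cells\n", sep = "")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
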