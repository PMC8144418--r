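# --- counseling tables and exports -----------------------------------------

#' Risk band for a predicted percentage of multiple deliveries
#'
#' Bands: `[0, 10)` green, `[10, 20)` yellow, `[20, 30)` red, `>= 30` gray.
#' Banding is always computed on the unrounded percentage.
#'
#' @param pct_multiples percentage (0-100 scale) of deliveries that are
#'   multiples.
#' @return Character vector of band names.
#' @export
risk_band <- function(pct_multiples) {
  as.character(cut(pct_multiples, breaks = c(-Inf, 10, 20, 30, Inf),
                   labels = c("green", "yellow", "red", "gray"),
                   right = FALSE))
}

#' Counseling table for one live birth rate and universal factors fraction
#'
#' One row per number of embryos transferred (1..`max_embryos`), assigning
#' every embryo the same per-embryo rate: the total live birth rate per
#' transfer, the percentages of deliveries that are multiples, twins, and
#' triplets-or-more, and the multiples risk band. When the delivery rate is
#' zero the percentage columns are undefined (`NA`) and flagged.
#'
#' @param lbr per-embryo live birth rate (must not exceed `uni`).
#' @param uni universal factors fraction.
#' @param max_embryos largest transfer size tabulated (default 4).
#' @return Data frame of class `prediction_table` with columns `n_embryos`,
#'   `total_delivery_rate`, `pct_multiples`, `pct_twins`,
#'   `pct_triplet_or_more`, `risk_band`, `defined`.
#' @export
build_prediction_table <- function(lbr, uni, max_embryos = 4L) {
  stopifnot(max_embryos >= 1L)
  check_transfer_spec(lbr, uni)  # rejects lbr > uni up front
  rows <- lapply(seq_len(max_embryos), function(n) {
    dist <- outcome_distribution(rep(lbr, n), uni)
    total <- 1 - dist[[1L]]
    if (total > 0) {
      fr <- multiples_fractions(rep(lbr, n), uni)
      data.frame(n_embryos = n, total_delivery_rate = total,
                 pct_multiples = 100 * fr[["multiple"]],
                 pct_twins = 100 * fr[["twin"]],
                 pct_triplet_or_more = 100 * fr[["triplet_or_more"]],
                 risk_band = risk_band(100 * fr[["multiple"]]),
                 defined = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(n_embryos = n, total_delivery_rate = 0,
                 pct_multiples = NA_real_, pct_twins = NA_real_,
                 pct_triplet_or_more = NA_real_, risk_band = NA_character_,
                 defined = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "lbr") <- lbr
  attr(out, "uni") <- uni
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("Predicted transfer outcomes (LBR per embryo = ",
      format(attr(x, "lbr"), digits = 3), ", UNI = ",
      format(attr(x, "uni"), digits = 3), ")\n", sep = "")
  disp <- data.frame(
    `embryos` = x$n_embryos,
    `LBR` = sprintf("%d%%", round(100 * x$total_delivery_rate)),
    `% mult.` = ifelse(x$defined, sprintf("%d%%", round(x$pct_multiples)), "-"),
    `% twins` = ifelse(x$defined, sprintf("%d%%", round(x$pct_twins)), "-"),
    `% trip. or >` = ifelse(x$defined,
                            sprintf("%d%%", round(x$pct_triplet_or_more)), "-"),
    band = ifelse(x$defined, x$risk_band, "-"),
    check.names = FALSE)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Counseling tables for every fitted clinic cell
#'
#' Builds one [build_prediction_table()] per populated cell of a fitted
#' rate table; fresh cells use `uni_fresh`, frozen cells `uni_frozen`.
#' Cells whose fitted rate exceeds the applicable universal factors
#' fraction are ill-formed under the model and are returned as
#' identifiability warnings instead of tables.
#'
#' @param lbr_table fitted [fit_lbr_table()].
#' @param uni_fresh,uni_frozen universal factors fractions per cycle type
#'   (numbers or `uni_estimate` objects).
#' @param max_embryos largest transfer size tabulated.
#' @return List of class `clinic_tables`; each element has `age_label`,
#'   `stage`, `cycle`, `lbr`, and either `table` (a `prediction_table`) or
#'   `warning` (a message).
#' @export
build_clinic_tables <- function(lbr_table, uni_fresh, uni_frozen,
                                max_embryos = 4L) {
  if (inherits(uni_fresh, "uni_estimate")) uni_fresh <- uni_fresh$value
  if (inherits(uni_frozen, "uni_estimate")) uni_frozen <- uni_frozen$value
  out <- lapply(seq_len(nrow(lbr_table)), function(i) {
    row <- lbr_table[i, ]
    uni <- if (row$cycle == "fresh") uni_fresh else uni_frozen
    entry <- list(age_label = row$age_label, stage = row$stage,
                  cycle = row$cycle, lbr = row$lbr, uni = uni)
    if (row$lbr > uni) {
      entry$warning <- paste0("fitted rate ", signif(row$lbr, 3),
                              " exceeds UNI ", signif(uni, 3),
                              ": cell not identifiable under the model")
    } else {
      entry$table <- build_prediction_table(row$lbr, uni, max_embryos)
    }
    entry
  })
  names(out) <- paste(lbr_table$age_label, lbr_table$cycle, lbr_table$stage)
  class(out) <- "clinic_tables"
  out
}

#' @export
print.clinic_tables <- function(x, ...) {
  cat("Counseling tables for", length(x), "fitted cells\n")
  for (nm in names(x)) {
    cat("\n--", nm, "--\n")
    if (!is.null(x[[nm]]$warning)) cat(" ", x[[nm]]$warning, "\n")
    else print(x[[nm]]$table)
  }
  invisible(x)
}

#' Simplified reference grid of predicted outcomes
#'
#' The clinic-facing lookup grid: predicted outcomes for combinations of an
#' average live birth rate per embryo and a number of embryos transferred,
#' at a single universal factors fraction (default 0.70, usable for both
#' fresh and frozen transfers in the simplified mode).
#'
#' @param uni universal factors fraction (default 0.70).
#' @param lbr_grid per-embryo rates to tabulate.
#' @param max_embryos largest transfer size tabulated.
#' @return Long data frame: `lbr`, `n_embryos`, `total_delivery_rate`,
#'   `pct_multiples`, `pct_twins`, `pct_triplet_or_more`, `risk_band`,
#'   `defined` (`FALSE` rows are flagged grid entries, e.g. `lbr > uni`).
#' @export
simplified_reference_table <- function(uni = 0.70,
                                       lbr_grid = seq(0.05, 0.70, by = 0.05),
                                       max_embryos = 4L) {
  rows <- lapply(lbr_grid, function(L) {
    if (L > uni) {
      data.frame(lbr = L, n_embryos = seq_len(max_embryos),
                 total_delivery_rate = NA_real_, pct_multiples = NA_real_,
                 pct_twins = NA_real_, pct_triplet_or_more = NA_real_,
                 risk_band = NA_character_, defined = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      tab <- build_prediction_table(L, uni, max_embryos)
      cbind(lbr = L, as.data.frame(tab))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uni") <- uni
  out
}

#' Export a fitted rate table as tidy curve points
#'
#' One row per (age label, category) cell with the fitted rate and its CI:
#' the machine-readable form of the rate-by-age curves.
#'
#' @param lbr_table fitted [fit_lbr_table()].
#' @param path optional CSV path; when given the data frame is also written.
#' @return The curve data frame, invisibly when `path` is given.
#' @export
lbr_curve_export <- function(lbr_table, path = NULL) {
  out <- as.data.frame(lbr_table)[, c("age_label", "stage", "cycle", "lbr",
                                      "ci_low", "ci_high")]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
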