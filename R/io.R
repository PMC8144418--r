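# --- clinic CSV input/output -----------------------------------------------
#
# One row per embryo transfer. Required columns (header names matched
# case-insensitively): age_at_retrieval, embryo_stage (cleavage|blastocyst),
# cycle_type (fresh|frozen), n_transferred (>= 1), n_live_born (0..n);
# optional: n_fetal_heartbeats (0..n). Inputs are expected to be
# pre-filtered to analyzable transfers; validation here is schema-level.

REQUIRED_COLS <- c("age_at_retrieval", "embryo_stage", "cycle_type",
                   "n_transferred", "n_live_born")

is_integerish <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v) & v == round(v)
}

# per-row schema checks; returns data.frame(row, field, reason)
transfer_row_problems <- function(df) {
  probs <- list()
  note <- function(rows, field, reason) {
    if (any(rows)) {
      probs[[length(probs) + 1L]] <<- data.frame(
        row = which(rows), field = field, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  age_ok <- is_integerish(df$age_at_retrieval)
  note(!age_ok, "age_at_retrieval", "not an integer")
  age <- suppressWarnings(as.numeric(df$age_at_retrieval))
  note(age_ok & (age < 18 | age > 50), "age_at_retrieval",
       "outside the plausible range [18, 50]")
  note(!tolower(trimws(df$embryo_stage)) %in% STAGES, "embryo_stage",
       "must be 'cleavage' or 'blastocyst'")
  note(!tolower(trimws(df$cycle_type)) %in% CYCLES, "cycle_type",
       "must be 'fresh' or 'frozen'")
  nt_ok <- is_integerish(df$n_transferred)
  note(!nt_ok, "n_transferred", "not an integer")
  nt <- suppressWarnings(as.numeric(df$n_transferred))
  note(nt_ok & nt < 1, "n_transferred", "must be >= 1")
  nb_ok <- is_integerish(df$n_live_born)
  note(!nb_ok, "n_live_born", "not an integer")
  nb <- suppressWarnings(as.numeric(df$n_live_born))
  note(nb_ok & nb < 0, "n_live_born", "must be >= 0")
  note(nb_ok & nt_ok & nb > nt, "n_live_born",
       "exceeds the number of embryos transferred")
  if (!is.null(df$n_fetal_heartbeats)) {
    present <- !is.na(df$n_fetal_heartbeats) &
      trimws(as.character(df$n_fetal_heartbeats)) != ""
    hb_ok <- is_integerish(df$n_fetal_heartbeats)
    note(present & !hb_ok, "n_fetal_heartbeats", "not an integer")
    hb <- suppressWarnings(as.numeric(df$n_fetal_heartbeats))
    note(present & hb_ok & (hb < 0 | (nt_ok & hb > nt)),
         "n_fetal_heartbeats", "outside [0, n_transferred]")
  }
  if (length(probs) == 0L) {
    return(data.frame(row = integer(), field = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, probs)
  out[order(out$row), , drop = FALSE]
}

#' Load and validate a clinic transfer CSV
#'
#' Reads a comma-delimited, header-first table of embryo transfers (RFC
#' 4180 quoting, UTF-8, header names case-insensitive), enforces the
#' record-level invariants, and either drops invalid rows with a rejection
#' report (lenient, the default) or aborts on the first problem set
#' (strict).
#'
#' @param path path to the CSV file.
#' @param strict abort on any invalid row instead of dropping it.
#' @return List with `records` (canonicalized data frame) and `rejections`
#'   (data frame of `row`, `field`, `reason`; file row numbers exclude the
#'   header).
#' @export
load_transfers <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  names(raw) <- tolower(trimws(names(raw)))
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), c(REQUIRED_COLS, "n_fetal_heartbeats"))
  if (length(extra)) {
    message("ignoring ", length(extra), " extra column(s): ",
            paste(extra, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    stop("no transfer rows in ", path, call. = FALSE)
  }
  problems <- transfer_row_problems(raw)
  if (nrow(problems) > 0L && strict) {
    stop("invalid rows in ", path, " (strict mode): e.g. row ",
         problems$row[1], " [", problems$field[1], "] ", problems$reason[1],
         "; ", length(unique(problems$row)), " row(s) affected",
         call. = FALSE)
  }
  bad_rows <- unique(problems$row)
  keep <- setdiff(seq_len(nrow(raw)), bad_rows)
  if (length(bad_rows)) {
    message("dropped ", length(bad_rows), " invalid row(s); see rejections")
  }
  kept <- raw[keep, , drop = FALSE]
  records <- data.frame(
    age_at_retrieval = as.integer(as.numeric(kept$age_at_retrieval)),
    embryo_stage = tolower(trimws(kept$embryo_stage)),
    cycle_type = tolower(trimws(kept$cycle_type)),
    n_transferred = as.integer(as.numeric(kept$n_transferred)),
    n_live_born = as.integer(as.numeric(kept$n_live_born)),
    stringsAsFactors = FALSE)
  if (!is.null(kept$n_fetal_heartbeats)) {
    hb <- trimws(as.character(kept$n_fetal_heartbeats))
    records$n_fetal_heartbeats <- ifelse(hb == "" | is.na(hb), NA_integer_,
                                         as.integer(as.numeric(hb)))
  }
  rownames(records) <- NULL
  list(records = records, rejections = problems)
}

#' Write transfer records to CSV
#'
#' The inverse of [load_transfers()]: records written here load back
#' identically.
#'
#' @param records data frame of transfer records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfers <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
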