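#' Moving age-group scheme for live birth rate estimation
#'
#' Live birth rates per embryo are estimated within age groups: patients up
#' to `pooled_young_max` years at oocyte retrieval form a single pooled
#' group (birth rates change slowly below 35 and the per-age counts are
#' small), while each target age in `moving_range` uses the 5-year moving
#' window centered on it (e.g. ages 33-37 estimate the rate reported for
#' 35-year-olds). Windows at the edges of the range extend symmetrically
#' and simply use whatever records fall inside them.
#'
#' @param pooled_young_max oldest age included in the pooled young group.
#' @param window_half_width half-width of the moving window in years.
#' @param moving_range integer vector `c(lo, hi)` of target ages that get a
#'   moving-window estimate.
#' @return An object of class `age_group_scheme`.
#' @export
age_group_scheme <- function(pooled_young_max = 34L,
                             window_half_width = 2L,
                             moving_range = c(35L, 43L)) {
  stopifnot(length(pooled_young_max) == 1L, length(window_half_width) == 1L,
            length(moving_range) == 2L, moving_range[1] <= moving_range[2],
            window_half_width >= 0, pooled_young_max < moving_range[1])
  structure(
    list(pooled_young_max = as.integer(pooled_young_max),
         window_half_width = as.integer(window_half_width),
         moving_range = as.integer(moving_range)),
    class = "age_group_scheme"
  )
}

pooled_label <- function(scheme) paste0("<=", scheme$pooled_young_max)

#' All target labels of a scheme (pooled group first)
#' @param scheme an [age_group_scheme()].
#' @return Character vector of age labels, e.g. `"<=34", "35", ..., "43"`.
#' @export
age_group_targets <- function(scheme = age_group_scheme()) {
  c(pooled_label(scheme),
    as.character(seq(scheme$moving_range[1], scheme$moving_range[2])))
}

#' Does a record's age belong to the group used for a target age?
#'
#' @param age integer age(s) at oocyte retrieval.
#' @param target a target: either an integer age within the scheme's moving
#'   range, an integer at or below `pooled_young_max` (the pooled group), or
#'   the pooled group's label (e.g. `"<=34"`).
#' @param scheme an [age_group_scheme()].
#' @return Logical vector: membership of each `age` in the target's group.
#' @examples
#' assign_age_group(33, 35)        # TRUE: window 33-37
#' assign_age_group(38, 35)        # FALSE
#' assign_age_group(29, "<=34")    # TRUE: pooled group
#' @export
assign_age_group <- function(age, target, scheme = age_group_scheme()) {
  stopifnot(is.numeric(age), length(target) == 1L)
  if (is.character(target)) {
    if (target != pooled_label(scheme)) {
      stop("unknown age-group label: ", target, call. = FALSE)
    }
    return(age <= scheme$pooled_young_max)
  }
  target <- as.integer(target)
  if (target <= scheme$pooled_young_max) {
    return(age <= scheme$pooled_young_max)
  }
  if (target < scheme$moving_range[1] || target > scheme$moving_range[2]) {
    stop("target age ", target, " outside the supported range (pooled group",
         " or ", scheme$moving_range[1], "-", scheme$moving_range[2], ")",
         call. = FALSE)
  }
  abs(age - target) <= scheme$window_half_width
}

# map an exact age to the label of the cell that reports it (NA when the
# scheme provides no estimate for that age, e.g. beyond the moving range)
age_to_label <- function(age, scheme = age_group_scheme()) {
  lab <- rep(NA_character_, length(age))
  lab[age <= scheme$pooled_young_max] <- pooled_label(scheme)
  in_rng <- age >= scheme$moving_range[1] & age <= scheme$moving_range[2]
  lab[in_rng] <- as.character(age[in_rng])
  lab
}
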