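#' Exact outcome distribution for one embryo transfer
#'
#' Computes the probability of delivering exactly k live-born infants
#' (k = 0, ..., n) when n embryos are transferred together under the
#' universal-factors mechanism: with probability `1 - uni` transfer-level
#' conditions are unfavorable and no embryo can implant; with probability
#' `uni` conditions are favorable and embryo i results in a live birth
#' independently of the others with conditional probability `lbr[i] / uni`.
#' Each embryo's marginal birth probability is therefore exactly `lbr[i]`,
#' while births of embryos transferred together are positively correlated
#' whenever `uni < 1`.
#'
#' With `uni = 1` the distribution reduces to the Poisson-binomial
#' distribution of independent per-embryo events; with a single embryo it
#' reduces to a Bernoulli(`lbr`) draw regardless of `uni`.
#'
#' The favorable-branch Poisson-binomial is evaluated by dynamic-programming
#' convolution (O(n^2)), which is numerically stable for heterogeneous
#' per-embryo rates.
#'
#' @param lbr numeric vector of marginal live birth rates, one per embryo
#'   transferred; each in `[0, 1]` and at most `uni`.
#' @param uni universal factors fraction, a single probability in `(0, 1]`.
#' @return Named numeric vector of length `length(lbr) + 1`; element `"k"`
#'   is the probability of exactly k live births. Entries sum to 1.
#' @examples
#' outcome_distribution(c(0.3, 0.3), uni = 0.7)
#' outcome_distribution(0.4, uni = 0.7)  # single embryo: c(0.6, 0.4)
#' @export
outcome_distribution <- function(lbr, uni) {
  check_transfer_spec(lbr, uni)
  n <- length(lbr)
  p <- pmin(lbr / uni, 1)
  # conditional (favorable-branch) Poisson-binomial by convolution
  pb <- 1
  for (pi in p) {
    pb <- c(pb * (1 - pi), 0) + c(0, pb * pi)
  }
  out <- uni * pb
  out[1] <- (1 - uni) + uni * pb[1]
  names(out) <- as.character(0:n)
  out
}

check_transfer_spec <- function(lbr, uni) {
  if (!is.numeric(uni) || length(uni) != 1L || is.na(uni) ||
      uni <= 0 || uni > 1) {
    stop("`uni` must be a single probability in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(lbr) || length(lbr) < 1L || anyNA(lbr)) {
    stop("`lbr` must be a non-empty numeric vector (one rate per embryo)",
         call. = FALSE)
  }
  if (any(lbr < 0) || any(lbr > 1)) {
    stop("per-embryo live birth rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(lbr > uni)) {
    stop("model ill-formed: per-embryo live birth rate exceeds `uni` ",
         "(the conditional rate lbr/uni would exceed 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Probability of at least one live birth from a transfer
#'
#' Convenience wrapper around [outcome_distribution()]: the total live birth
#' rate per embryo transfer (the "LBR" column of a counseling table).
#'
#' @inheritParams outcome_distribution
#' @return Single probability `1 - P(0 births)`.
#' @export
delivery_rate <- function(lbr, uni) {
  1 - outcome_distribution(lbr, uni)[[1L]]
}

#' Fractions of deliveries that are multiples, twins, triplets-or-more
#'
#' Conditional on at least one live birth, the probability that the delivery
#' is a multiple (>= 2 infants), a twin delivery (exactly 2), or a
#' triplet-or-greater delivery (>= 3). Only dizygotic multiples (distinct
#' embryos) are represented; monozygotic splitting is outside the model.
#'
#' @inheritParams outcome_distribution
#' @return Named numeric vector `c(multiple, twin, triplet_or_more)`, each a
#'   fraction of deliveries.
#' @export
multiples_fractions <- function(lbr, uni) {
  dist <- outcome_distribution(lbr, uni)
  any_birth <- 1 - dist[[1L]]
  if (any_birth <= 0) {
    stop("multiples fractions undefined: probability of delivery is 0",
         call. = FALSE)
  }
  twin <- if (length(dist) >= 3L) dist[[3L]] else 0
  trip <- if (length(dist) >= 4L) sum(dist[4:length(dist)]) else 0
  c(multiple = (twin + trip) / any_birth,
    twin = twin / any_birth,
    triplet_or_more = trip / any_birth)
}
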