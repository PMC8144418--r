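# Brute-force oracle for the transfer outcome distribution: enumerate the
# favorable/unfavorable branch times all 2^n per-embryo outcomes and sum
# path probabilities. Independent of the package's convolution code path.
oracle_distribution <- function(lbr, uni) {
  n <- length(lbr)
  p <- lbr / uni
  out <- numeric(n + 1)
  out[1] <- 1 - uni
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(s))[seq_len(n)]
    path <- uni * prod(ifelse(bits == 1L, p, 1 - p))
    k <- sum(bits)
    out[k + 1] <- out[k + 1] + path
  }
  out
}

# random well-formed (lbr, uni) specs for property tests
random_spec <- function(n) {
  uni <- runif(1, 0.05, 1)
  list(lbr = runif(n, 0, uni), uni = uni)
}

# small homogeneous cohort data frame builder
transfer_df <- function(n_transferred, n_live_born, age = 30L,
                        stage = "blastocyst", cycle = "fresh") {
  data.frame(age_at_retrieval = as.integer(age), embryo_stage = stage,
             cycle_type = cycle, n_transferred = as.integer(n_transferred),
             n_live_born = as.integer(n_live_born),
             stringsAsFactors = FALSE)
}

# two-embryo homogeneous cohort config used across estimation tests
two_embryo_config <- function(n, lbr = 0.30, uni = 0.70, seed = 1L) {
  clinic_sim_config(
    n_transfers = n,
    age_distribution = c("30" = 1),
    category_mix = c("fresh blastocyst" = 1),
    embryos_per_transfer = c("2" = 1),
    true_lbr_curve = function(age, stage, cycle) lbr,
    true_uni = c(fresh = uni, frozen = uni),
    seed = seed)
}
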