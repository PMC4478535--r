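# Independent oracles used across tests.

# step-by-step per-generation recursion of the loss model, independent of
# the closed form in forward_ratio(); integer generations only
recur_ratio <- function(m, beta, n, R0, n_plus0 = 1) {
  np <- n_plus0
  nm <- R0 * n_plus0
  g <- 2^(1 / beta)
  for (i in seq_len(n)) {
    shed <- 2 * m * np
    np <- 2 * (1 - m) * np
    nm <- g * nm + shed
  }
  nm / np
}

# two-sided Fisher p by full enumeration over the hypergeometric support
fisher_p_enum <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, rs[1], rs[2], cs[1])
  obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# log-normal two-mode event table with known labels
planted_events <- function(n_events, frac_pos, neg_median = 100,
                           pos_median = 10000, log10_sd = 0.2) {
  n_pos <- round(n_events * frac_pos)
  lab <- c(rep("pos", n_pos), rep("neg", n_events - n_pos))
  mu <- ifelse(lab == "pos", log10(pos_median), log10(neg_median))
  tibble::tibble(event_id = seq_len(n_events),
                 gfp_intensity = 10^rnorm(n_events, mu, log10_sd),
                 truth_label = lab)
}
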