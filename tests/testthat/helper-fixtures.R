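# shared fixture builders; everything is generated in code

toy_dataset <- function(n_snps = 10, n_ind = 100, trait_type = "binary",
                        seed = 1, missing_rate = 0) {
  d <- simulate_null(n_snps, n_ind, trait_type, seed = seed)
  if (missing_rate > 0) d <- inject_missing(d, missing_rate)
  d
}

# dataset built from explicit genotype columns for hand-checked examples
explicit_dataset <- function(g1, g2, trait, trait_type = "auto") {
  mbmdr_dataset(cbind(g1, g2), trait, trait_type)
}

# exhaustive pure-R scan used as oracle for the compiled kernel
brute_force_scan <- function(dataset, alpha_cell = 0.1, adjust_main = FALSE) {
  s <- ncol(dataset$genotypes)
  pairs <- t(utils::combn(s, 2))
  stat <- apply(pairs, 1, function(p)
    pair_statistic(dataset, p, alpha_cell, adjust_main))
  data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2], statistic = stat)
}

# causal-pair detection at FWER alpha
detected <- function(fit, causal, alpha = 0.05) {
  row <- fit$table[fit$table$snp_a == causal[1] &
                     fit$table$snp_b == causal[2], ]
  nrow(row) > 0 && row$p_adj[1] < alpha
}
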