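# shared builders for small in-code datasets

prof <- function(id, positions, alleles = NULL) {
  variant_profile(id, positions, alleles = alleles)
}

make_pop <- function(label, pos_list, period = "test") {
  recs <- lapply(seq_along(pos_list), function(i)
    sample_record(sprintf("%s%02d", label, i), period = period,
                  profile = prof(sprintf("%s%02d", label, i), pos_list[[i]])))
  population_dataset(label, recs, period = period)
}

random_positions <- function(max_k = 6) {
  k <- sample(0:max_k, 1)
  sort(sample(16051:16400, k))
}

random_pos_list <- function(n, max_k = 6, n_haplotypes = NULL) {
  if (is.null(n_haplotypes)) {
    replicate(n, random_positions(max_k), simplify = FALSE)
  } else {
    haps <- replicate(n_haplotypes, random_positions(max_k), simplify = FALSE)
    lapply(sample(seq_len(n_haplotypes), n, replace = TRUE), function(i) haps[[i]])
  }
}
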