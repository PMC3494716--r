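# Independent brute-force oracles.  These deliberately avoid the package's
# internal code paths: distances come from materialized sequences compared
# character by character, and the AMOVA sums of squares are written out as
# literal double loops.

oracle_seq_diff <- function(p1, p2, reference) {
  s1 <- strsplit(profile_to_sequence(p1, reference), "")[[1]]
  s2 <- strsplit(profile_to_sequence(p2, reference), "")[[1]]
  sum(s1 != s2)
}

oracle_pi <- function(pop, reference) {
  profiles <- pop_profiles(pop)
  n <- length(profiles)
  L <- nchar(reference)
  total <- 0
  npairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + oracle_seq_diff(profiles[[i]], profiles[[j]], reference)
    npairs <- npairs + 1
  }
  (total / npairs) / L
}

# literal AMOVA: delta2[i,j] = squared distance (= difference count),
# groups = factor of length N with 2+ levels
oracle_phi_st <- function(delta2, groups) {
  n <- length(groups)
  lv <- unique(groups)
  g <- length(lv)
  ss_total <- 0
  for (i in 1:n) for (j in 1:n) ss_total <- ss_total + delta2[i, j]
  ss_total <- ss_total / (2 * n)
  ss_within <- 0
  for (lev in lv) {
    idx <- which(groups == lev)
    s <- 0
    for (i in idx) for (j in idx) s <- s + delta2[i, j]
    ss_within <- ss_within + s / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  sizes <- sapply(lv, function(lev) sum(groups == lev))
  sigma_w <- ss_within / (n - g)
  n_bar <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_a <- (ss_among / (g - 1) - sigma_w) / n_bar
  if (sigma_a + sigma_w == 0) 0 else sigma_a / (sigma_a + sigma_w)
}

oracle_phi_for_pops <- function(pop_a, pop_b, reference) {
  profiles <- c(pop_profiles(pop_a), pop_profiles(pop_b))
  n <- length(profiles)
  delta2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    delta2[i, j] <- oracle_seq_diff(profiles[[i]], profiles[[j]], reference)
  groups <- rep(c("a", "b"), c(length(pop_profiles(pop_a)),
                               length(pop_profiles(pop_b))))
  oracle_phi_st(delta2, groups)
}
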