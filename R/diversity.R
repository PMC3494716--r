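#' Haplotype partition of a population
#'
#' Two samples carry the same haplotype iff their variant sets (positions
#' plus allele codes) over a common window are identical.
#'
#' @param pop A \code{\link{population_dataset}} or list of records /
#'   profiles.
#' @return List with \code{K} (number of distinct haplotypes) and
#'   \code{counts}, a named integer vector of haplotype multiplicities
#'   summing to N.
#' @export
distinct_haplotypes <- function(pop) {
  profiles <- assert_common_window(pop_profiles(pop))
  keys <- vapply(profiles, haplotype_key, "")
  tab <- table(keys)
  list(K = length(tab), counts = setNames(as.integer(tab), names(tab)))
}

#' Number of segregating (polymorphic) sites
#'
#' A position is polymorphic when at least two allelic states occur in
#' the sample: it is carried as a variant by some but not all samples,
#' or carried by all samples with more than one derived allele.
#'
#' @inheritParams distinct_haplotypes
#' @return Integer count S; 0 for a single-sample population.
#' @export
segregating_sites <- function(pop) {
  profiles <- assert_common_window(pop_profiles(pop))
  n <- length(profiles)
  if (n < 2L) return(0L)
  all_pos <- sort(unique(unlist(lapply(profiles, `[[`, "positions"))))
  poly <- vapply(all_pos, function(p) {
    states <- vapply(profiles, function(pr) {
      i <- match(p, pr$positions)
      if (is.na(i)) "ref"
      else if (is.na(pr$alleles[i])) "ts" else pr$alleles[i]
    }, "")
    length(unique(states)) > 1L
  }, TRUE)
  sum(poly)
}

#' Nei gene diversity with sampling standard deviation
#'
#' Computes the unbiased gene (haplotype) diversity
#' \eqn{\hat H = \frac{N}{N-1}\bigl(1 - \sum_i p_i^2\bigr)} and its
#' sampling standard deviation from Nei's variance formula
#' \eqn{V = \frac{2}{N(N-1)}\Bigl\{2(N-2)\bigl[\sum p_i^3 -
#' (\sum p_i^2)^2\bigr] + \sum p_i^2 - (\sum p_i^2)^2\Bigr\}}.
#'
#' @param counts Integer vector of haplotype multiplicities (from
#'   \code{\link{distinct_haplotypes}}), or a population object.
#' @return List with \code{H} and \code{sd}.
#' @examples
#' gene_diversity(c(3, 2, rep(1, 11)))  # H = 0.967, sd = 0.036
#' @export
gene_diversity <- function(counts) {
  if (!is.numeric(counts)) counts <- distinct_haplotypes(counts)$counts
  n <- sum(counts)
  if (n < 2) stop("gene diversity requires N >= 2")
  p <- counts / n
  sp2 <- sum(p^2); sp3 <- sum(p^3)
  h <- n / (n - 1) * (1 - sp2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  list(H = h, sd = sqrt(max(v, 0)))
}

# count of differing positions between two profiles (symmetric difference
# of variant sets; positions shared with unequal allele codes also count)
pairwise_differences <- function(p1, p2) {
  pos <- union(p1$positions, p2$positions)
  if (!length(pos)) return(0L)
  state <- function(pr, p) {
    i <- match(p, pr$positions)
    ifelse(is.na(i), "ref",
           ifelse(is.na(pr$alleles[i]), "ts", pr$alleles[i]))
  }
  sum(state(p1, pos) != state(p2, pos))
}

#' Nucleotide diversity with sampling standard deviation
#'
#' \eqn{\pi} is the mean number of pairwise differences per site over
#' all \eqn{\binom{N}{2}} sample pairs and the window length L.  The
#' standard deviation follows Tajima's no-recombination sampling
#' variance of the mean pairwise difference,
#' \eqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi +
#' \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.  No substitution-model correction
#' is applied.
#'
#' @inheritParams distinct_haplotypes
#' @return List with \code{pi}, \code{sd}, \code{mean_pairwise} (the
#'   unscaled mean difference count) and \code{L}.
#' @export
nucleotide_diversity <- function(pop) {
  profiles <- assert_common_window(pop_profiles(pop))
  n <- length(profiles)
  if (n < 2L) stop("nucleotide diversity requires N >= 2")
  L <- window_length(profiles[[1]])
  total <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    total <- total + pairwise_differences(profiles[[i]], profiles[[j]])
  mean_d <- total / choose(n, 2)
  pi <- mean_d / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, sd = sqrt(v), mean_pairwise = mean_d, L = L)
}

#' Per-population diversity summary
#'
#' Bundles the classic intra-population HVS-I summary: sample size N,
#' haplotype count K (and K%), segregating sites S (and S% of the window
#' length), Nei gene diversity with sd, and nucleotide diversity with sd.
#'
#' @param pop A \code{\link{population_dataset}}.
#' @return An object of class \code{"diversity_stats"} (a list).
#' @examples
#' diversity_stats(altai_populations()$iron)
#' @export
diversity_stats <- function(pop) {
  label <- if (inherits(pop, "population_dataset")) pop$label else "pop"
  profiles <- assert_common_window(pop_profiles(pop))
  n <- length(profiles)
  L <- window_length(profiles[[1]])
  dh <- distinct_haplotypes(pop)
  s <- segregating_sites(pop)
  gd <- if (n >= 2) gene_diversity(dh$counts) else list(H = NA_real_, sd = NA_real_)
  nd <- if (n >= 2) nucleotide_diversity(pop)
        else list(pi = NA_real_, sd = NA_real_)
  structure(list(population = label, N = n, K = dh$K,
                 K_pct = 100 * dh$K / n, S = s, S_pct = 100 * s / L,
                 H_hat = gd$H, H_sd = gd$sd,
                 pi = nd$pi, pi_sd = nd$sd, L = L,
                 counts = dh$counts),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("%s: N=%d  K=%d (%.2f%%)  S=%d (%.2f%%)  H=%.3f+-%.3f  pi=%.4f+-%.4f\n",
              x$population, x$N, x$K, x$K_pct, x$S, x$S_pct,
              x$H_hat, x$H_sd, x$pi, x$pi_sd))
  invisible(x)
}

#' Tabulate diversity statistics for several populations
#'
#' @param pops List of \code{\link{population_dataset}}s.
#' @return Data frame with one row per population and the columns of
#'   \code{\link{diversity_stats}}.
#' @export
diversity_table <- function(pops) {
  do.call(rbind, lapply(pops, function(p) {
    s <- diversity_stats(p)
    data.frame(population = s$population, N = s$N, K = s$K,
               K_pct = round(s$K_pct, 2), S = s$S, S_pct = round(s$S_pct, 2),
               H_hat = round(s$H_hat, 3), H_sd = round(s$H_sd, 3),
               pi = round(s$pi, 4), pi_sd = round(s$pi_sd, 4),
               stringsAsFactors = FALSE)
  }))
}
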