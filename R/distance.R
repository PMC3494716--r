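#' Pairwise difference matrix between profiles
#'
#' @param profiles List of \code{\link{variant_profile}}s sharing a
#'   window (or a population / record list).
#' @return Symmetric integer matrix of pairwise difference counts.
#' @export
pairwise_diff_matrix <- function(profiles) {
  profiles <- assert_common_window(pop_profiles(profiles))
  n <- length(profiles)
  d <- matrix(0, n, n)
  if (n > 1) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    d[i, j] <- d[j, i] <- pairwise_differences(profiles[[i]], profiles[[j]])
  d
}

# AMOVA variance components from a matrix of squared inter-individual
# distances and a group factor (Excoffier-style; for haplotype data the
# pairwise difference count plays the role of the squared distance)
amova_components <- function(delta2, groups) {
  groups <- as.factor(groups)
  n <- length(groups)
  sizes <- table(groups)
  g <- nlevels(groups)
  stopifnot(nrow(delta2) == n, g >= 2)
  ssd_total <- sum(delta2[upper.tri(delta2)]) / n
  ssd_within <- sum(vapply(levels(groups), function(lv) {
    idx <- which(groups == lv)
    sum(delta2[idx, idx][upper.tri(delta2[idx, idx])]) / length(idx)
  }, 0))
  ssd_among <- ssd_total - ssd_within
  df_a <- g - 1L
  df_w <- n - g
  sigma_w <- if (df_w > 0) ssd_within / df_w else 0
  n_bar <- (n - sum(sizes^2) / n) / df_a
  sigma_a <- (ssd_among / df_a - sigma_w) / n_bar
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       ssd_among = ssd_among, ssd_within = ssd_within)
}

phi_from_components <- function(cmp) {
  tot <- cmp$sigma_a + cmp$sigma_w
  if (tot == 0) 0 else cmp$sigma_a / tot
}

#' AMOVA-based pairwise PhiST between two populations
#'
#' Computes the fixation index PhiST from the analysis of molecular
#' variance with the inter-haplotype distance taken as the pairwise
#' difference count: \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a +
#' \sigma^2_w)} from the among/within sums of squared distances.  The
#' raw estimate may be negative; negatives are truncated only by
#' \code{\link{slatkin_linearize}}.
#'
#' @param pop_a,pop_b \code{\link{population_dataset}}s (each N >= 2)
#'   sharing the HVS-I window.
#' @return PhiST estimate (scalar).
#' @export
phi_st <- function(pop_a, pop_b) {
  pa <- pop_profiles(pop_a); pb <- pop_profiles(pop_b)
  if (length(pa) < 2L || length(pb) < 2L)
    stop("PhiST requires at least 2 samples per population")
  profiles <- assert_common_window(c(pa, pb))
  delta2 <- pairwise_diff_matrix(profiles)
  groups <- rep(c("a", "b"), c(length(pa), length(pb)))
  phi_from_components(amova_components(delta2, groups))
}

#' Permutation test for pairwise PhiST
#'
#' Permutes individuals across the two populations and recomputes PhiST;
#' the p-value is \eqn{(1 + \#\{\Phi^{perm} \ge \Phi^{obs}\}) /
#' (n_{perm} + 1)}.
#'
#' @inheritParams phi_st
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (required, for reproducibility).
#' @return List with \code{phi} (observed), \code{p} and \code{n_perm}.
#' @export
phi_st_permutation_test <- function(pop_a, pop_b, n_perm = 1000, seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  pa <- pop_profiles(pop_a); pb <- pop_profiles(pop_b)
  if (length(pa) < 2L || length(pb) < 2L)
    stop("PhiST requires at least 2 samples per population")
  profiles <- assert_common_window(c(pa, pb))
  delta2 <- pairwise_diff_matrix(profiles)
  na <- length(pa); n <- na + length(pb)
  groups <- rep(c("a", "b"), c(na, n - na))
  obs <- phi_from_components(amova_components(delta2, groups))
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      phi_from_components(amova_components(delta2[idx, idx], groups)) >=
        obs - 1e-12
    }, TRUE))
  })
  list(phi = obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Pairwise distance matrices over several populations
#'
#' @param pops List of \code{\link{population_dataset}}s (>= 2).
#' @param n_perm Permutations per pair for the significance test; 0
#'   skips testing.
#' @param seed Integer seed (required when \code{n_perm > 0}).
#' @param alpha Significance level for the boolean matrix.
#' @return Object of class \code{"distance_matrix"}: list with
#'   \code{labels}, symmetric \code{fst}, \code{linearized} (Slatkin),
#'   \code{p} and \code{significant} matrices (the latter two NULL when
#'   \code{n_perm = 0}).
#' @export
phi_st_matrix <- function(pops, n_perm = 0, seed = NULL, alpha = 0.05) {
  if (length(pops) < 2L) stop("need at least two populations")
  labels <- vapply(pops, `[[`, "", "label")
  g <- length(pops)
  fst <- matrix(0, g, g, dimnames = list(labels, labels))
  pmat <- if (n_perm > 0) fst else NULL
  for (i in seq_len(g - 1L)) for (j in seq.int(i + 1L, g)) {
    if (n_perm > 0) {
      res <- phi_st_permutation_test(pops[[i]], pops[[j]], n_perm,
                                     seed = seed + i * 1000L + j)
      fst[i, j] <- fst[j, i] <- res$phi
      pmat[i, j] <- pmat[j, i] <- res$p
    } else {
      fst[i, j] <- fst[j, i] <- phi_st(pops[[i]], pops[[j]])
    }
  }
  structure(list(labels = labels, fst = fst,
                 linearized = slatkin_linearize(fst),
                 p = pmat,
                 significant = if (!is.null(pmat)) pmat <= alpha else NULL),
            class = "distance_matrix")
}

#' Slatkin linearization of FST
#'
#' \code{max(fst, 0) / (1 - max(fst, 0))}, making the distance roughly
#' proportional to divergence time.  Values >= 1 yield \code{Inf} with a
#' warning.
#'
#' @param fst Numeric scalar, vector or matrix of FST estimates.
#' @return Same shape as the input.
#' @examples
#' slatkin_linearize(c(-0.02, 0, 0.5))
#' @export
slatkin_linearize <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE))
    warning("FST >= 1: linearized distance is infinite")
  f <- pmax(fst, 0)
  out <- ifelse(f >= 1, Inf, f / (1 - f))
  if (is.matrix(fst)) { out <- matrix(out, nrow(fst), dimnames = dimnames(fst)) }
  out
}

#' Low-dimensional ordination of a distance matrix
#'
#' Classical (Torgerson) metric multidimensional scaling via double
#' centering and eigendecomposition, keeping the top \code{k}
#' non-negative eigenpairs; or Kruskal's non-metric MDS
#' (\code{method = "nonmetric"}).  Goodness of fit is reported as
#' Kruskal stress-1 between the input and embedded distances.  Axes are
#' sign-fixed so that the first population's coordinates are
#' non-negative.
#'
#' @param d Symmetric, zero-diagonal distance matrix.
#' @param k Embedding dimension (default 2).
#' @param method \code{"classical"} (default) or \code{"nonmetric"}.
#' @return Object of class \code{"ordination"}: list with \code{points}
#'   (one row per population), \code{eig} (eigenvalues; classical only)
#'   and \code{stress}.
#' @export
classical_mds <- function(d, k = 2, method = c("classical", "nonmetric")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(abs(diag(d)) > 1e-12))
    stop("input must be a symmetric matrix with a zero diagonal")
  n <- nrow(d)
  if (method == "classical") {
    fit <- cmdscale(d, k = min(k, n - 1), eig = TRUE)
    pts <- fit$points
    if (ncol(pts) < k)
      pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    eig <- fit$eig
  } else {
    init <- cmdscale(d, k = k)
    fit <- MASS::isoMDS(structure(d[lower.tri(d)], Size = n, class = "dist",
                                  Diag = FALSE, Upper = FALSE),
                        y = init, k = k, trace = FALSE)
    pts <- fit$points
    eig <- NULL
  }
  for (ax in seq_len(ncol(pts)))
    if (pts[1, ax] < 0) pts[, ax] <- -pts[, ax]
  emb <- as.matrix(dist(pts))
  denom <- sum(d^2)
  stress <- if (denom > 0) sqrt(sum((d - emb)^2) / denom) else 0
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eig = eig, stress = stress, method = method),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s MDS, %d points, stress-1 = %.4g\n",
              x$method, nrow(x$points), x$stress))
  invisible(x)
}
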