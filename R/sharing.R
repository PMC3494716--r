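#' Cross-population haplotype sharing summary
#'
#' Haplotype identity is identical variant sets over a common window
#' (trim comparative data to the study window before comparison).  The
#' summary counts distinct haplotypes across all populations, how many
#' occur in two or more populations, and a symmetric matrix of pairwise
#' shared-haplotype counts whose diagonal holds each population's K.
#'
#' @param pops List of two or more \code{\link{population_dataset}}s.
#' @return Object of class \code{"sharing_summary"}: list with
#'   \code{labels}, \code{total_distinct}, \code{shared} (count of
#'   haplotypes in >= 2 populations), \code{shared_fraction} (percent,
#'   1 decimal), \code{matrix}, \code{shared_keys} and
#'   \code{representatives} (one profile per distinct haplotype).
#' @examples
#' p <- altai_populations()
#' shared_haplotype_matrix(list(p$bronze, p$iron))
#' @export
shared_haplotype_matrix <- function(pops) {
  if (!length(pops)) stop("empty population list")
  if (length(pops) < 2L) stop("need at least two populations")
  labels <- vapply(pops, `[[`, "", "label")
  prof_sets <- lapply(pops, function(p) assert_common_window(pop_profiles(p)))
  assert_common_window(unlist(prof_sets, recursive = FALSE))
  key_sets <- lapply(prof_sets, function(ps)
    unique(vapply(ps, haplotype_key, "")))
  all_keys <- unique(unlist(key_sets))
  occur <- vapply(all_keys, function(k)
    sum(vapply(key_sets, function(ks) k %in% ks, TRUE)), 0L)
  shared_keys <- all_keys[occur >= 2L]
  g <- length(pops)
  m <- matrix(0L, g, g, dimnames = list(labels, labels))
  for (i in seq_len(g)) for (j in seq_len(g))
    m[i, j] <- length(intersect(key_sets[[i]], key_sets[[j]]))
  reps <- list()
  for (ps in prof_sets) for (p in ps) {
    k <- haplotype_key(p)
    if (is.null(reps[[k]])) reps[[k]] <- p
  }
  structure(list(labels = labels,
                 total_distinct = length(all_keys),
                 shared = length(shared_keys),
                 shared_fraction = round(100 * length(shared_keys) /
                                           length(all_keys), 1),
                 matrix = m, shared_keys = shared_keys,
                 representatives = reps),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d distinct haplotypes, %d shared (%.1f%%)\n",
              x$total_distinct, x$shared, x$shared_fraction))
  print(x$matrix)
  invisible(x)
}

#' Partition shared haplotypes by geographic lineage class
#'
#' Each shared haplotype is haplogroup-called from its HVS-I profile and
#' mapped to a geographic class.
#'
#' @param summary A \code{\link{shared_haplotype_matrix}} result.
#' @param table Geographic class table.
#' @param motifs Motif rule table for the haplogroup calls.
#' @return Data frame with one row per shared haplotype: \code{key},
#'   \code{haplogroup}, \code{class}; zero rows when nothing is shared.
#' @export
shared_by_class <- function(summary, table = geo_classes(),
                            motifs = hvr1_motifs()) {
  stopifnot(inherits(summary, "sharing_summary"))
  if (!length(summary$shared_keys))
    return(data.frame(key = character(), haplogroup = character(),
                      class = character(), stringsAsFactors = FALSE))
  rows <- lapply(summary$shared_keys, function(k) {
    hg <- call_from_hvr1(summary$representatives[[k]], motifs)$haplogroup
    data.frame(key = k, haplogroup = hg, class = geo_class(hg, table),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
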