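#' Packaged haplogroup rule tables
#'
#' \code{hvr1_motifs()} loads the motif table: one row per haplogroup with
#' its parent in a reduced mtDNA phylogeny and its diagnostic HVS-I motif
#' (possibly empty for nodes defined only by coding-region variation,
#' e.g. HV or U).  \code{rflp_markers()} loads the coding-region marker
#' map: one diagnostic restriction-site state per (enzyme, position),
#' e.g. site 663 HaeIII present is diagnostic for haplogroup A.  Both are
#' plain TSV files; pass your own path to extend or replace the defaults.
#'
#' @param path Optional TSV path overriding the packaged table.
#' @return \code{hvr1_motifs()}: data frame with columns
#'   \code{haplogroup}, \code{parent} and list-column \code{motif}
#'   (integer rCRS positions).  \code{rflp_markers()}: data frame with
#'   columns \code{enzyme}, \code{position}, \code{diagnostic_state},
#'   \code{haplogroup}.
#' @export
hvr1_motifs <- function(path = NULL) {
  df <- read.delim(path %||% extdata("hvr1_motifs.tsv"),
                   colClasses = "character", na.strings = NULL)
  df$motif <- lapply(df$motif %||% rep("", nrow(df)), function(m) {
    m <- trimws(strsplit(if (is.na(m)) "" else m, ",")[[1]])
    as.integer(m[nzchar(m)])
  })
  # parent chains must be acyclic and closed
  for (hg in df$haplogroup) {
    seen <- character(); cur <- hg
    repeat {
      p <- df$parent[match(cur, df$haplogroup)]
      if (is.na(p) || p == "root" || !nzchar(p)) break
      if (p %in% seen) stop("cycle in motif table at ", hg)
      if (!p %in% df$haplogroup) stop("unknown parent '", p, "' for ", cur)
      seen <- c(seen, p); cur <- p
    }
  }
  df
}

#' @rdname hvr1_motifs
#' @export
rflp_markers <- function(path = NULL) {
  df <- read.delim(path %||% extdata("rflp_markers.tsv"),
                   colClasses = "character", na.strings = NULL)
  df$position <- as.integer(df$position)
  stopifnot(all(df$diagnostic_state %in% c("present", "absent")),
            !anyDuplicated(df[c("enzyme", "position")]))
  df
}

hg_ancestors <- function(haplogroup, rules) {
  out <- character(); cur <- haplogroup
  repeat {
    p <- rules$parent[match(cur, rules$haplogroup)]
    if (is.na(p) || p == "root" || !nzchar(p)) break
    out <- c(out, p); cur <- p
  }
  out
}

hg_depth <- function(haplogroup, rules) length(hg_ancestors(haplogroup, rules))

#' Is one haplogroup an ancestor of another?
#'
#' @param a,b Haplogroup labels present in the rule table.
#' @param rules Motif table (supplies the tree via its parent column).
#' @return \code{TRUE} if \code{a} is a strict ancestor of \code{b}.
#' @export
is_ancestor <- function(a, b, rules = hvr1_motifs()) {
  a %in% hg_ancestors(b, rules)
}

new_call <- function(haplogroup, score = 0L, unmatched_private = 0L,
                     evidence = "hvr1", concordant = NA,
                     low_confidence = FALSE, ranking = NULL) {
  structure(list(haplogroup = haplogroup, score = as.integer(score),
                 unmatched_private = as.integer(unmatched_private),
                 evidence = evidence, concordant = concordant,
                 low_confidence = low_confidence, ranking = ranking),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("<haplogroup_call> %s  (evidence: %s, score %d, %d private)%s\n",
              x$haplogroup, x$evidence, x$score, x$unmatched_private,
              if (isTRUE(x$low_confidence)) "  [low confidence]" else ""))
  if (!is.na(x$concordant))
    cat("  concordant:", x$concordant, "\n")
  invisible(x)
}

#' Call a haplogroup from an HVS-I motif match
#'
#' Scores every haplogroup in the motif table against the profile with a
#' simple parsimony criterion: matched motif positions count +1, motif
#' positions absent from the profile count \code{-penalty}.  Candidates
#' are ranked by net score, ties broken by deeper node (longer motif) and
#' then lexicographically, so output is deterministic.  Profile variants
#' outside the winning motif are reported as private.
#'
#' An empty profile matches the reference and is returned as
#' \code{"reference-like (H2a2-like)"} with a low-confidence flag.
#'
#' @param profile A \code{\link{variant_profile}}.
#' @param rules Motif table, see \code{\link{hvr1_motifs}}.
#' @param penalty Cost per motif position missing from the profile.
#' @return A \code{haplogroup_call}; its \code{$ranking} element holds the
#'   full scored candidate table.
#' @examples
#' call_from_hvr1(variant_profile("x", c(16069, 16126)))$haplogroup  # "J"
#' @export
call_from_hvr1 <- function(profile, rules = hvr1_motifs(), penalty = 1) {
  if (!nrow(rules)) stop("empty motif rule set")
  pos <- profile$positions
  if (!length(pos))
    return(new_call("reference-like (H2a2-like)", evidence = "hvr1",
                    low_confidence = TRUE))
  matched <- vapply(rules$motif, function(m) sum(m %in% pos), 0L)
  missing <- lengths(rules$motif) - matched
  net <- matched - penalty * missing
  ranking <- data.frame(haplogroup = rules$haplogroup, matched = matched,
                        missing = missing, net = net,
                        motif_length = lengths(rules$motif),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$net, -ranking$motif_length,
                           ranking$haplogroup), ]
  rownames(ranking) <- NULL
  top <- ranking[1, ]
  motif <- rules$motif[[match(top$haplogroup, rules$haplogroup)]]
  new_call(top$haplogroup, score = top$matched,
           unmatched_private = length(setdiff(pos, motif)),
           evidence = "hvr1", low_confidence = top$net <= 0,
           ranking = ranking)
}

#' Call a haplogroup from coding-region RFLP states
#'
#' Matches observed restriction-site states against the diagnostic marker
#' map.  If one or more diagnostic states are hit, the deepest hit wins,
#' provided all hits are mutually compatible on the haplogroup tree
#' (e.g. 12308 HinfI present = U together with 9052 HaeII absent = K);
#' incompatible simultaneous hits raise an error naming both.  When no
#' diagnostic state is hit but exclusion states were typed, the narrowest
#' compatible label is returned (7025 AluI present excludes H within R0:
#' with 4577 NlaIII present this yields \code{"HV"}, otherwise
#' \code{"R0"}).  An all-missing panel yields \code{"undetermined"}.
#'
#' @param obs Data frame of RFLP observations (columns \code{enzyme},
#'   \code{position}, \code{state}).
#' @param rules Marker map, see \code{\link{rflp_markers}}.
#' @param motifs Motif table supplying the haplogroup tree.
#' @return A \code{haplogroup_call} with evidence \code{"rflp"}.
#' @export
call_from_rflp <- function(obs, rules = rflp_markers(),
                           motifs = hvr1_motifs()) {
  obs <- validate_rflp(obs)
  observed <- obs[obs$state != "missing", , drop = FALSE]
  if (!nrow(observed))
    return(new_call("undetermined", evidence = "rflp", low_confidence = TRUE))
  j <- match(observed$position, rules$position)
  known <- !is.na(j)
  hit <- known & observed$state == rules$diagnostic_state[j]
  hits <- unique(rules$haplogroup[j[hit]])
  if (length(hits) >= 2L) {
    for (a in hits) for (b in hits) {
      if (a < b && !is_ancestor(a, b, motifs) && !is_ancestor(b, a, motifs))
        stop(sprintf("conflicting diagnostic RFLP states: %s vs %s", a, b))
    }
  }
  if (length(hits)) {
    deepest <- hits[which.max(vapply(hits, hg_depth, 0L, rules = motifs))]
    return(new_call(deepest, score = length(hits), evidence = "rflp"))
  }
  state_at <- function(position) {
    s <- observed$state[observed$position == position]
    if (length(s)) s[1] else NA_character_
  }
  # exclusion logic within R0: site 7025 present rules out H
  if (identical(state_at(7025L), "present")) {
    label <- if (identical(state_at(4577L), "present")) "HV" else "R0"
    return(new_call(label, evidence = "rflp", low_confidence = TRUE))
  }
  new_call("undetermined", evidence = "rflp", low_confidence = TRUE)
}

#' Combine HVS-I and RFLP haplogroup calls
#'
#' The two evidence sources are concordant when they name the same
#' haplogroup or one is an ancestor of the other on the rule tree (RFLP
#' "U" vs HVS-I "U5a1"); the final label is then the deeper of the two.
#' When the RFLP call is undetermined (or the profile reference-like),
#' concordance is not evaluable (\code{NA}).  Discordant calls keep the
#' HVS-I label with \code{concordant = FALSE}.
#'
#' @param hvr1_call,rflp_call \code{haplogroup_call} objects.
#' @param motifs Motif table supplying the tree.
#' @return A combined \code{haplogroup_call}.
#' @export
combine_calls <- function(hvr1_call, rflp_call, motifs = hvr1_motifs()) {
  h <- hvr1_call$haplogroup; r <- rflp_call$haplogroup
  not_evaluable <- r == "undetermined" || !h %in% motifs$haplogroup
  if (not_evaluable)
    return(new_call(h, score = hvr1_call$score,
                    unmatched_private = hvr1_call$unmatched_private,
                    evidence = "combined", concordant = NA,
                    low_confidence = hvr1_call$low_confidence))
  if (h == r || is_ancestor(r, h, motifs))
    final <- h
  else if (is_ancestor(h, r, motifs))
    final <- r
  else
    return(new_call(h, score = hvr1_call$score,
                    unmatched_private = hvr1_call$unmatched_private,
                    evidence = "combined", concordant = FALSE))
  new_call(final, score = hvr1_call$score,
           unmatched_private = hvr1_call$unmatched_private,
           evidence = "combined", concordant = TRUE)
}

#' Call haplogroups for a set of sample records
#'
#' Convenience wrapper running \code{\link{call_from_hvr1}},
#' \code{\link{call_from_rflp}} and \code{\link{combine_calls}} over a
#' list of records.
#'
#' @param records List of \code{\link{sample_record}}s or a
#'   \code{\link{population_dataset}}.
#' @param motifs,markers Rule tables.
#' @param penalty Motif mismatch penalty, see \code{\link{call_from_hvr1}}.
#' @return Data frame with one row per sample: \code{sample_id},
#'   \code{period}, \code{hvr1}, \code{rflp}, \code{haplogroup} (final),
#'   \code{concordant}, \code{n_private}.
#' @examples
#' head(call_haplogroups(altai_pazyryk()))
#' @export
call_haplogroups <- function(records, motifs = hvr1_motifs(),
                             markers = rflp_markers(), penalty = 1) {
  if (inherits(records, "population_dataset")) records <- records$records
  rows <- lapply(records, function(r) {
    hc <- call_from_hvr1(r$profile, motifs, penalty)
    rc <- call_from_rflp(r$rflp, markers, motifs)
    cc <- combine_calls(hc, rc, motifs)
    data.frame(sample_id = r$sample_id, period = r$period,
               hvr1 = hc$haplogroup, rflp = rc$haplogroup,
               haplogroup = cc$haplogroup, concordant = cc$concordant,
               n_private = hc$unmatched_private, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
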