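#' Site-specific weight scheme for network construction
#'
#' Two-tier weighting of HVS-I positions: fast (hotspot) positions get a
#' low weight so that recurrent mutations at them count less towards
#' inter-haplotype distances.  The packaged hotspot list covers the
#' classic HVS-I hotspots inside the window; both the list and the two
#' weights are configurable.
#'
#' @param hotspots Integer vector of hotspot positions (default: packaged
#'   list).
#' @param hotspot_weight,default_weight Positive weights for hotspot and
#'   ordinary positions.
#' @return Object of class \code{"weight_scheme"}.
#' @export
weight_scheme <- function(hotspots = NULL, hotspot_weight = 1,
                          default_weight = 2) {
  if (is.null(hotspots))
    hotspots <- read.delim(extdata("hvr1_hotspots.tsv"))$position
  if (hotspot_weight <= 0 || default_weight <= 0)
    stop("weights must be positive")
  structure(list(hotspots = as.integer(hotspots),
                 hotspot_weight = hotspot_weight,
                 default_weight = default_weight),
            class = "weight_scheme")
}

#' @rdname weight_scheme
#' @details \code{unit_weights()} is the unweighted scheme (every
#'   position weight 1), under which weighted distances reduce to
#'   Hamming distances between variant sets.
#' @export
unit_weights <- function() weight_scheme(integer(), 1, 1)

position_weights <- function(positions, scheme) {
  ifelse(positions %in% scheme$hotspots, scheme$hotspot_weight,
         scheme$default_weight)
}

as_positions <- function(h) {
  if (inherits(h, "variant_profile")) h$positions
  else sort(as.integer(h))
}

#' Weighted distance between two haplotypes
#'
#' Sum of position weights over the symmetric difference of the two
#' variant-position sets (binary presence/absence state model).
#'
#' @param h1,h2 Variant profiles or integer position vectors.
#' @param scheme A \code{\link{weight_scheme}}.
#' @return Non-negative scalar.
#' @export
weighted_distance <- function(h1, h2, scheme = unit_weights()) {
  a <- as_positions(h1); b <- as_positions(h2)
  diff <- c(setdiff(a, b), setdiff(b, a))
  sum(position_weights(diff, scheme))
}

weighted_dist_matrix <- function(haps, scheme) {
  n <- length(haps)
  d <- matrix(0, n, n)
  if (n > 1) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    d[i, j] <- d[j, i] <- weighted_distance(haps[[i]], haps[[j]], scheme)
  d
}

# Prim's algorithm; returns edge list (i, j, w) and total cost
mst_edges <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(list(edges = cbind(i = integer(), j = integer(),
                                         w = numeric()), cost = 0))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]; parent <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3, dimnames = list(NULL, c("i", "j", "w")))
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[k, ] <- c(min(parent[v], v), max(parent[v], v), best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best
    parent[upd] <- v; best[upd] <- d[v, upd]
  }
  list(edges = edges, cost = sum(edges[, "w"]))
}

mst_cost <- function(d) mst_edges(d)$cost

# minimax (bottleneck) distance between all pairs, computed on the MST
minimax_matrix <- function(d) {
  n <- nrow(d)
  mst <- mst_edges(d)$edges
  adj <- lapply(seq_len(n), function(i) list())
  for (k in seq_len(nrow(mst))) {
    i <- mst[k, "i"]; j <- mst[k, "j"]; w <- mst[k, "w"]
    adj[[i]] <- c(adj[[i]], list(c(j, w)))
    adj[[j]] <- c(adj[[j]], list(c(i, w)))
  }
  mm <- matrix(0, n, n)
  for (s in seq_len(n)) {
    # DFS from s tracking the max edge weight en route
    stack <- list(c(s, 0)); visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (e in adj[[top[1]]]) {
        if (!visited[e[1]]) {
          visited[e[1]] <- TRUE
          mm[s, e[1]] <- max(top[2], e[2])
          stack <- c(stack, list(c(e[1], mm[s, e[1]])))
        }
      }
    }
  }
  mm
}

#' Minimum spanning network over a set of haplotypes
#'
#' The epsilon-relaxed minimum spanning network: a link (u, v) is kept
#' when its weighted distance does not exceed the level at which u's and
#' v's clusters first join under single linkage (the minimax path
#' distance) by more than \code{epsilon}.  At \code{epsilon = 0} this is
#' exactly the union of all minimum spanning trees, retaining every tie;
#' increasing epsilon only ever adds links.
#'
#' @param haplotypes List of distinct haplotypes (profiles or position
#'   vectors), length >= 2.
#' @param scheme Weight scheme.
#' @param epsilon Non-negative relaxation parameter.
#' @return Data frame of edges: \code{from}, \code{to} (indices into
#'   \code{haplotypes}), \code{weight}.
#' @export
minimum_spanning_network <- function(haplotypes, scheme = unit_weights(),
                                     epsilon = 0) {
  if (length(haplotypes) < 2L) stop("need at least 2 haplotypes")
  haps <- lapply(haplotypes, as_positions)
  keys <- vapply(haps, paste, "", collapse = "-")
  if (anyDuplicated(keys)) stop("haplotypes must be distinct")
  d <- weighted_dist_matrix(haps, scheme)
  msn_edges_from_d(d, epsilon)
}

msn_edges_from_d <- function(d, epsilon) {
  n <- nrow(d)
  mm <- minimax_matrix(d)
  keep <- which(upper.tri(d) & d <= mm + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2],
             weight = d[keep], stringsAsFactors = FALSE)
}

triplet_median <- function(a, b, c) {
  pos <- sort(unique(c(a, b, c)))
  pos[(pos %in% a) + (pos %in% b) + (pos %in% c) >= 2]
}

#' Median-joining haplotype network
#'
#' Implements the median-joining construction over binary variant-set
#' haplotypes: iteratively (1) build the epsilon-relaxed minimum
#' spanning network over the current node set, (2) propose the median
#' (position-wise majority) of every connected triplet, (3) add the
#' median vector that most reduces the total network cost (minimum
#' spanning tree weight), repeating until no proposed median reduces the
#' cost, then (4) prune obsolete unobserved nodes (degree <= 2 in the
#' final network).  Input haplotypes are deduplicated and processed in a
#' deterministic order (multiplicity descending, then lexicographic
#' variant string).
#'
#' @param haplotypes List of variant profiles or position vectors
#'   (duplicates allowed; they become node multiplicities), >= 2 distinct.
#' @param populations Optional character vector of population labels
#'   aligned with \code{haplotypes}, recorded per node.
#' @param scheme Weight scheme.
#' @param epsilon Non-negative relaxation parameter (default 0).
#' @param max_iter Guard on median-addition rounds.
#' @return Object of class \code{"haplotype_network"}: list with
#'   \code{haplotypes} (position vectors; observed first, then median
#'   vectors), \code{observed}, \code{multiplicity}, \code{populations}
#'   (per-node label counts), and \code{edges} (data frame: from, to,
#'   weight, plus a list-column \code{positions} of mutated positions).
#' @export
mj_network <- function(haplotypes, populations = NULL,
                       scheme = unit_weights(), epsilon = 0,
                       max_iter = 100L) {
  haps_in <- lapply(haplotypes, as_positions)
  keys_in <- vapply(haps_in, paste, "", collapse = "-")
  if (!is.null(populations) && length(populations) != length(haps_in))
    stop("populations must align with haplotypes")
  ukeys <- unique(keys_in)
  if (length(ukeys) < 2L) stop("need at least 2 distinct haplotypes")
  mult <- vapply(ukeys, function(k) sum(keys_in == k), 0L)
  pops <- lapply(ukeys, function(k) {
    if (is.null(populations)) character() else populations[keys_in == k]
  })
  ord <- order(-mult, ukeys)
  nodes <- lapply(ukeys[ord], function(k) haps_in[[match(k, keys_in)]])
  mult <- unname(mult[ord]); pops <- pops[ord]
  observed <- rep(TRUE, length(nodes))

  # median-addition phase
  for (iter in seq_len(max_iter + 1L)) {
    if (iter > max_iter)
      stop("median-joining did not converge within max_iter = ", max_iter,
           " rounds (", length(nodes), " nodes); raise max_iter")
    d <- weighted_dist_matrix(nodes, scheme)
    edges <- msn_edges_from_d(d, epsilon)
    keys <- vapply(nodes, paste, "", collapse = "-")
    # connected triplets: two MSN links sharing a node
    cand <- list()
    for (v in seq_along(nodes)) {
      nb <- sort(unique(c(edges$to[edges$from == v],
                          edges$from[edges$to == v])))
      if (length(nb) >= 2L) {
        prs <- combn(nb, 2)
        for (cix in seq_len(ncol(prs))) {
          m <- triplet_median(nodes[[prs[1, cix]]], nodes[[v]],
                              nodes[[prs[2, cix]]])
          k <- paste(m, collapse = "-")
          if (!k %in% keys && !k %in% names(cand)) cand[[k]] <- m
        }
      }
    }
    if (!length(cand)) break
    cost <- mst_cost(d)
    reductions <- vapply(cand, function(m) {
      d2 <- rbind(cbind(d, 0), 0)
      nn <- length(nodes) + 1L
      for (i in seq_along(nodes))
        d2[i, nn] <- d2[nn, i] <- weighted_distance(nodes[[i]], m, scheme)
      cost - mst_cost(d2)
    }, 0)
    if (max(reductions) <= 1e-9) break
    best <- names(cand)[order(-reductions, names(cand))][1]
    nodes <- c(nodes, list(cand[[best]]))
    observed <- c(observed, FALSE)
    mult <- c(mult, 0L)
    pops <- c(pops, list(character()))
  }

  # prune obsolete median vectors (unobserved, degree <= 2)
  repeat {
    d <- weighted_dist_matrix(nodes, scheme)
    edges <- msn_edges_from_d(d, epsilon)
    deg <- tabulate(c(edges$from, edges$to), nbins = length(nodes))
    drop <- which(!observed & deg <= 2L)
    if (!length(drop)) break
    keep <- setdiff(seq_along(nodes), drop)
    nodes <- nodes[keep]; observed <- observed[keep]
    mult <- mult[keep]; pops <- pops[keep]
  }

  d <- weighted_dist_matrix(nodes, scheme)
  edges <- msn_edges_from_d(d, epsilon)
  edges$positions <- lapply(seq_len(nrow(edges)), function(k) {
    a <- nodes[[edges$from[k]]]; b <- nodes[[edges$to[k]]]
    sort(c(setdiff(a, b), setdiff(b, a)))
  })
  structure(list(haplotypes = nodes, observed = observed,
                 multiplicity = mult,
                 populations = lapply(pops, function(p) table(p)),
                 edges = edges, epsilon = epsilon, scheme = scheme),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d nodes (%d observed, %d median vectors), %d edges, epsilon = %g\n",
              length(x$haplotypes), sum(x$observed), sum(!x$observed),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Convert a haplotype network to an igraph graph
#'
#' Nodes carry \code{name} (variant string or \code{mv<k>} for median
#' vectors), \code{observed} (0/1), \code{size} (multiplicity) and
#' \code{pops} (population composition string); edges carry
#' \code{weight} and \code{positions} (space-separated mutated
#' positions).
#'
#' @param net A \code{\link{mj_network}} result.
#' @return An \pkg{igraph} graph.
#' @export
as_igraph <- function(net) {
  n <- length(net$haplotypes)
  if (!n) stop("empty network")
  keys <- vapply(net$haplotypes, paste, "", collapse = "-")
  mv <- which(!net$observed)
  keys[mv] <- paste0("mv", seq_along(mv))
  pops <- vapply(net$populations, function(tb) {
    if (!length(tb)) "" else paste0(names(tb), ":", as.integer(tb),
                                    collapse = ",")
  }, "")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "observed", value = as.integer(net$observed))
  g <- igraph::set_vertex_attr(g, "size", value = as.numeric(net$multiplicity))
  g <- igraph::set_vertex_attr(g, "pops", value = pops)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
    g <- igraph::set_edge_attr(g, "positions",
                               value = vapply(net$edges$positions, paste, "",
                                              collapse = " "))
  }
  g
}

#' Export a haplotype network to GML or DOT
#'
#' @param net A \code{\link{mj_network}} result (non-empty).
#' @param path Output file.
#' @param format \code{"gml"} (round-trippable with
#'   \code{igraph::read_graph}) or \code{"dot"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("gml", "dot")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
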