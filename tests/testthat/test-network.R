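test_that("weighted distances sum position weights over the symmetric difference", {
  expect_equal(weighted_distance(c(16093, 16189), c(16093, 16189)), 0)
  expect_equal(weighted_distance(c(16223), integer(0)), 1)
  # unit weights reduce to Hamming distance between variant sets
  expect_equal(weighted_distance(c(16060, 16070), c(16070, 16080)), 2)
  # default two-tier scheme down-weights nothing but fast sites
  w <- weight_scheme()
  expect_equal(weighted_distance(c(16093), integer(0), w), 1)   # hotspot
  expect_equal(weighted_distance(c(16100), integer(0), w), 2)   # ordinary
  expect_error(weight_scheme(hotspot_weight = 0), "positive")
})

test_that("minimum spanning networks keep ties and respect the relaxation threshold", {
  # two haplotypes: single edge
  e2 <- minimum_spanning_network(list(c(16093), c(16093, 16189)))
  expect_identical(nrow(e2), 1L)

  # chain: d(AB) = d(BC) = 1, d(AC) = 2 -> path only at epsilon = 0
  chain <- list(integer(0), c(16093), c(16093, 16189))
  e3 <- minimum_spanning_network(chain)
  expect_identical(nrow(e3), 2L)
  expect_false(any(e3$from == 1 & e3$to == 3))
  # at epsilon = 1 the A-C link becomes feasible
  e3r <- minimum_spanning_network(chain, epsilon = 1)
  expect_identical(nrow(e3r), 3L)

  # four haplotypes all pairwise distance 1: complete tie structure retained
  sch <- weight_scheme(hotspots = c(16061, 16062, 16063, 16064),
                       hotspot_weight = 0.5)
  quad <- list(c(16061), c(16062), c(16063), c(16064))
  e4 <- minimum_spanning_network(quad, sch)
  expect_identical(nrow(e4), 6L)

  expect_error(minimum_spanning_network(list(c(16093))), "at least 2")
  expect_error(minimum_spanning_network(list(c(16093), c(16093))), "distinct")
})

test_that("epsilon relaxation is monotone: larger epsilon never removes links", {
  set.seed(41)
  for (k in 1:15) {
    haps <- unique(random_pos_list(6, max_k = 4))
    if (length(haps) < 3) next
    key <- function(e) paste(e$from, e$to)
    e0 <- minimum_spanning_network(haps, epsilon = 0)
    e1 <- minimum_spanning_network(haps, epsilon = 1)
    e2 <- minimum_spanning_network(haps, epsilon = 2)
    expect_true(all(key(e0) %in% key(e1)))
    expect_true(all(key(e1) %in% key(e2)))
  }
})

test_that("median-joining adds cost-reducing latent nodes and recovers stars", {
  # median of {0, {a}, {b}} is 0 itself: plain star, no latent nodes
  net <- mj_network(list(integer(0), c(16093), c(16189)))
  expect_identical(length(net$haplotypes), 3L)
  expect_identical(sum(!net$observed), 0L)
  expect_identical(nrow(net$edges), 2L)

  # {a,b}, {a,c}, 0 -> median {a} added as a degree-3 latent node
  net2 <- mj_network(list(c(16093, 16189), c(16093, 16311), integer(0)))
  expect_identical(sum(!net2$observed), 1L)
  mv <- which(!net2$observed)
  expect_identical(net2$haplotypes[[mv]], 16093L)
  deg <- tabulate(c(net2$edges$from, net2$edges$to),
                  nbins = length(net2$haplotypes))
  expect_identical(deg[mv], 3L)
  # all original pairwise links are replaced by paths through the median
  expect_identical(nrow(net2$edges), 3L)

  # two haplotypes: single edge, no medians ever
  net3 <- mj_network(list(c(16093), c(16311)))
  expect_identical(nrow(net3$edges), 1L)
  expect_identical(sum(!net3$observed), 0L)

  # observed perfect star is returned exactly
  center <- c(16100L, 16200L)
  leaves <- list(c(center, 16060L), c(center, 16070L), c(center, 16080L))
  net4 <- mj_network(c(list(center), leaves))
  expect_identical(length(net4$haplotypes), 4L)
  expect_identical(sum(!net4$observed), 0L)
  expect_identical(nrow(net4$edges), 3L)
  ci <- which(vapply(net4$haplotypes, function(h)
    identical(h, center), TRUE))
  expect_true(all(net4$edges$from == ci | net4$edges$to == ci))
})

test_that("networks stay connected, contain all observed haplotypes, and honour the triangle bound", {
  set.seed(42)
  for (k in 1:10) {
    pos_list <- random_pos_list(8, max_k = 5, n_haplotypes = 5)
    if (length(unique(lapply(pos_list, identity))) < 2) next
    net <- mj_network(pos_list)
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g))
    in_keys <- unique(vapply(pos_list, paste, "", collapse = "-"))
    node_keys <- vapply(net$haplotypes, paste, "", collapse = "-")
    expect_true(all(in_keys %in% node_keys[net$observed]))
    # weighted shortest path >= direct weighted distance
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    n_obs <- which(net$observed)
    for (i in n_obs) for (j in n_obs) if (i < j)
      expect_gte(sp[i, j] + 1e-9,
                 weighted_distance(net$haplotypes[[i]], net$haplotypes[[j]]))
  }
})

test_that("node multiplicities and population composition are tracked through deduplication", {
  pos_list <- list(c(16093), c(16093), c(16311), integer(0))
  net <- mj_network(pos_list, populations = c("P1", "P1", "P2", "P2"))
  keys <- vapply(net$haplotypes, paste, "", collapse = "-")
  i <- match("16093", keys)
  expect_identical(net$multiplicity[i], 2L)
  expect_identical(as.integer(net$populations[[i]]["P1"]), 2L)
})

test_that("network export round-trips node and edge counts through GML", {
  net <- mj_network(list(c(16093), c(16311)))
  path <- tempfile(fileext = ".gml")
  export_network(net, path)
  g <- igraph::read_graph(path, format = "gml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  # fixture subset: all Iron Age haplotypes
  iron <- altai_populations()$iron
  net2 <- mj_network(pop_profiles(iron), scheme = weight_scheme())
  path2 <- tempfile(fileext = ".gml")
  export_network(net2, path2)
  g2 <- igraph::read_graph(path2, format = "gml")
  expect_equal(igraph::vcount(g2), length(net2$haplotypes))
  expect_equal(igraph::ecount(g2), nrow(net2$edges))

  empty <- net; empty$haplotypes <- list(); empty$observed <- logical()
  expect_error(export_network(empty, tempfile()), "empty")
})
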