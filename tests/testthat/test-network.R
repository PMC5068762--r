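test_that("largest_component picks the biggest (then lexicographic) piece", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c", "d", "f", "g"),
               to = c("b", "c", "d", "e", "g", "h")),
    directed = FALSE)
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c", "d", "e"))
  # connected graph: itself
  h <- igraph::make_ring(4)
  igraph::V(h)$name <- letters[1:4]
  expect_equal(igraph::vcount(largest_component(h)), 4L)
  # union-find style oracle on a random graph
  set.seed(13)
  r <- igraph::sample_gnp(60, 0.03)
  igraph::V(r)$name <- sprintf("v%02d", 1:60)
  memb <- igraph::components(r)$membership
  expect_equal(igraph::vcount(largest_component(r)),
               max(table(memb)))
  expect_error(largest_component(igraph::make_empty_graph(0)), "empty")
})

test_that("path and star centralities match hand-derived values", {
  path <- igraph::make_graph(~ A - B, B - C)
  ns <- node_stats(path)
  b <- ns[ns$node == "B", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$stress, 1)
  expect_equal(b$betweenness, 1.0)
  expect_equal(b$eccentricity, 1L)
  expect_equal(b$avg_shortest_path, 1.0)
  a <- ns[ns$node == "A", ]
  expect_equal(a$degree, 1L)
  expect_equal(a$stress, 0)
  expect_equal(a$betweenness, 0)
  expect_equal(a$eccentricity, 2L)
  expect_equal(a$avg_shortest_path, 1.5)

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  ns <- node_stats(star)
  hub <- ns[ns$node == "hub", ]
  expect_equal(hub$stress, 10)          # C(5,2) leaf pairs
  expect_equal(hub$betweenness, 1.0)
  expect_equal(hub$eccentricity, 1L)
  expect_equal(ns$stress[ns$node != "hub"], rep(0, 5))
  expect_equal(ns$eccentricity[ns$node != "hub"], rep(2L, 5))

  # complete graph: all betweenness zero
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(node_stats(k5)$betweenness, rep(0, 5))
})

test_that("all five statistics equal the brute-force oracle on random graphs", {
  set.seed(7)
  for (rep in 1:5) {
    g <- random_connected_graph(30, 0.2)
    got <- node_stats(g)
    want <- oracle_node_stats(igraph_to_adj(g))
    expect_equal(got$degree, want$degree)
    expect_equal(got$stress, want$stress)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$eccentricity, want$eccentricity)
    expect_equal(got$avg_shortest_path, want$avg_shortest_path,
                 tolerance = 1e-12)
    # cross-check against igraph's own centralities
    expect_equal(got$betweenness * (29 * 28 / 2),
                 unname(igraph::betweenness(g)), tolerance = 1e-9)
    expect_equal(got$eccentricity, unname(igraph::eccentricity(g)))
    # eccentricity dominates the mean distance at every node
    expect_true(all(got$eccentricity >= got$avg_shortest_path))
  }
})

test_that("total stress satisfies the path-length consistency identity", {
  set.seed(29)
  g <- random_connected_graph(25, 0.2)
  got <- node_stats(g)
  # sum over pairs of sigma_st * (interior length) equals total stress
  sp <- igraph::distances(g)
  adj <- igraph_to_adj(g)
  n <- igraph::vcount(g)
  total <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    # count shortest paths by BFS sigma from s
    dist <- rep(-1L, n); sigma <- rep(0, n)
    dist[s] <- 0L; sigma[s] <- 1; q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    total <- total + sigma[t] * (sp[s, t] - 1)
  }
  expect_equal(sum(got$stress), total)
})

test_that("node_stats validates connectivity and symmetrizes direction", {
  two <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = FALSE)
  expect_error(node_stats(two), "largest_component")
  dg <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")), directed = TRUE)
  ns <- node_stats(dg)
  expect_equal(ns$degree[ns$node == "b"], 2L)
})

test_that("group comparison: symmetry null, planted hubs, input checks", {
  # vertex-transitive cycle: any split has ratio 1 and p near 1
  ring <- igraph::make_ring(20)
  igraph::V(ring)$name <- sprintf("r%02d", 1:20)
  ns <- node_stats(ring)
  set.seed(3)
  grp <- sample(ns$node, 8)
  cmp <- compare_groups(ns, grp, "degree")
  expect_equal(cmp$ratio, 1.0)
  expect_gt(cmp$p_value, 0.9)

  # preferential-attachment graph: earliest nodes are planted hubs
  set.seed(21)
  pa <- igraph::sample_pa(2000, power = 1, m = 2, zero.appeal = 1,
                          directed = FALSE)
  igraph::V(pa)$name <- sprintf("g%04d", 1:2000)
  ns <- node_stats(pa)
  hubs <- sprintf("g%04d", 1:40)
  cmp <- compare_groups(ns, hubs, "degree")
  expect_gt(cmp$ratio, 2)
  expect_lt(cmp$p_value, 0.01)

  expect_error(compare_groups(ns, character(0), "degree"), "empty")
  expect_error(compare_groups(ns, ns$node, "degree"), "every node")
})

test_that("rank-sum p agrees with exact permutation for small groups", {
  set.seed(41)
  worst <- 0
  for (i in 1:200) {
    n <- sample(30:45, 1)
    gsize <- sample(8:10, 1)
    vals <- rnorm(n) + c(rep(0.8, gsize), rep(0, n - gsize))
    stats <- data.frame(node = sprintf("x%02d", 1:n), degree = vals)
    cmp <- compare_groups(stats, stats$node[1:gsize], "degree")
    p_exact <- wilcox.test(vals[1:gsize], vals[-(1:gsize)],
                           exact = TRUE)$p.value
    worst <- max(worst, abs(cmp$p_value - p_exact))
  }
  expect_lt(worst, 0.01)
})
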