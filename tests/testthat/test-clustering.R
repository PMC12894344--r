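# Term networks, Markov Clustering, cluster selection and labelling.

test_that("network pruning keeps edges at or above the cutoff", {
  sib <- sibling_graph()
  net <- build_network(c("B1", "B2"), sib, cutoff = 0.5)
  expect_equal(nrow(net$edges), 0L)        # sibling sim ~0.444 < 0.5
  expect_setequal(net$nodes, c("B1", "B2"))   # isolated nodes kept
  ch <- chain_graph()
  net2 <- build_network(c("A", "B"), ch, cutoff = 0.5)
  expect_equal(nrow(net2$edges), 1L)       # parent/child sim ~0.764
  expect_equal(net2$edges$weight, 3.24 / 4.24, tolerance = 1e-12)
  # cutoff 0 -> complete graph (all same-namespace sims are positive)
  s <- synth_fixture()
  ids <- s$graph$terms$term_id[5:10]
  full <- build_network(ids, s$graph, cutoff = 0)
  expect_equal(nrow(full$edges), choose(6, 2))
})

test_that("MCL separates disconnected components and keeps singletons", {
  tri <- function(nodes) {
    idx <- utils::combn(3, 2)
    data.frame(a = nodes[idx[1, ]], b = nodes[idx[2, ]], weight = 1,
               stringsAsFactors = FALSE)
  }
  net <- direct_network(c(sprintf("x%d", 1:3), sprintf("y%d", 1:3)),
                        rbind(tri(sprintf("x%d", 1:3)),
                              tri(sprintf("y%d", 1:3))))
  cl <- mcl(net)
  expect_length(cl$clusters, 2L)
  expect_equal(sort(lengths(cl$clusters)), c(3L, 3L))
  expect_equal(canonical_partition(cl$clusters),
               canonical_partition(list(sprintf("x%d", 1:3),
                                        sprintf("y%d", 1:3))))
  lone <- direct_network("z1", data.frame(a = character(), b = character(),
                                          weight = numeric()))
  expect_equal(mcl(lone)$clusters, list("z1"))
})

test_that("MCL at inflation 5 recovers the planted two-block network", {
  net <- two_block_network()
  cl <- mcl(net, inflation = 5.0)
  expect_equal(canonical_partition(cl$clusters),
               canonical_partition(list(sprintf("a%d", 1:6),
                                        sprintf("b%d", 1:6))))
})

test_that("MCL agrees with the independent dense oracle on random networks", {
  set.seed(501)
  for (rep in 1:12) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    # random geometric-ish weights, keep ~40% of pairs
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < 0.4
    edges <- data.frame(a = nodes[idx[1, keep]], b = nodes[idx[2, keep]],
                        weight = stats::runif(sum(keep), 0.5, 1),
                        stringsAsFactors = FALSE)
    net <- direct_network(nodes, edges)
    for (r in c(1.5, 5.0)) {
      got <- mcl(net, inflation = r)$clusters
      want <- oracle_mcl(net, inflation = r)
      expect_equal(canonical_partition(got), canonical_partition(want))
    }
  }
})

test_that("MCL output is a partition and is insertion-order independent", {
  set.seed(502)
  n <- 18
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < 0.35
  edges <- data.frame(a = nodes[idx[1, keep]], b = nodes[idx[2, keep]],
                      weight = stats::runif(sum(keep), 0.5, 1),
                      stringsAsFactors = FALSE)
  cl <- mcl(direct_network(nodes, edges))
  expect_setequal(unlist(cl$clusters), nodes)
  expect_equal(sum(lengths(cl$clusters)), n)   # disjoint cover
  # shuffle node and edge order
  perm <- sample(n)
  cl2 <- mcl(direct_network(nodes[perm],
                            edges[sample(nrow(edges)), , drop = FALSE]))
  expect_equal(cl$clusters, cl2$clusters)
})

test_that("higher inflation yields at least as many clusters on planted blocks", {
  net <- two_block_network()
  n_15 <- length(mcl(net, inflation = 1.5)$clusters)
  n_50 <- length(mcl(net, inflation = 5.0)$clusters)
  expect_gte(n_50, n_15)
})

test_that("major-cluster selection applies size floor and count cap", {
  fake <- function(sizes) {
    structure(list(clusters = lapply(seq_along(sizes), function(i)
      sprintf("c%d_%d", i, seq_len(sizes[i]))),
      inflation = 5, converged = TRUE, iterations = 1L),
      class = "cluster_set")
  }
  expect_length(select_major_clusters(fake(rep(1, 10))), 0L)
  expect_length(select_major_clusters(fake(rep(3, 20))), 15L)
  expect_length(select_major_clusters(fake(c(5, 4, 3, 3, 2, 1))), 4L)
})

test_that("cluster labelling suggests the deepest common ancestor", {
  ch <- chain_graph()
  one <- annotate_clusters(list("B"), ch)
  expect_equal(one$common_ancestor, "B")
  two <- annotate_clusters(list(c("A", "B")), ch)
  expect_equal(two$common_ancestor, "A")
  expect_equal(two$deepest_member, "B")
  dia <- diamond_graph()
  # diamond members: common ancestors by exhaustive intersection
  members <- c("A1", "A2", "B")
  common <- Reduce(intersect, lapply(members, function(t)
    union(t, oracle_ancestors(dia, t))))
  got <- annotate_clusters(list(members), dia)
  expect_true(got$common_ancestor %in% common)
  expect_equal(got$common_ancestor, "R")
})
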