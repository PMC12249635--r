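test_that("two-node diffusion matches the closed-form kernel", {
  net <- two_node_network()
  m <- compute_similarity_matrix(net, beta = 0.5, convention = "hotnet2")
  expect_equal(unname(m$S), matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-12)
})

test_that("zero node weights give a zero similarity matrix", {
  net <- random_network(8, seed = 3)
  net$weights[] <- 0
  m <- compute_similarity_matrix(net, beta = 0.4)
  expect_true(all(m$S == 0))
})

test_that("hotnet2 columns conserve heat: column j sums to w_j", {
  for (seed in 1:3) {
    net <- random_network(50, p_edge = 0.1, seed = seed)
    m <- compute_similarity_matrix(net, beta = 0.4)
    expect_equal(colSums(m$S), m$weights, tolerance = 1e-8)
  }
})

test_that("the literal operator is singular at beta = 0.5 on connected graphs", {
  for (seed in 1:3) {
    net <- random_network(20, p_edge = 0.15, seed = seed)
    expect_error(compute_similarity_matrix(net, beta = 0.5,
                                           convention = "literal"),
                 "singular|ill-conditioned")
  }
  # away from the eigenvalue the literal form is well-defined
  net <- random_network(10, p_edge = 0.3, seed = 9)
  m <- compute_similarity_matrix(net, beta = 0.9, convention = "literal")
  expect_true(all(is.finite(m$S)))
})

test_that("solve-based kernel matches the explicit inverse", {
  net <- random_network(15, p_edge = 0.2, seed = 4)
  m <- compute_similarity_matrix(net, beta = 0.4)
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph,
                                             sparse = FALSE))[net$genes,
                                                              net$genes]
  W <- sweep(A, 2, colSums(A), "/")
  S_ref <- (0.4 * solve(diag(15) - 0.6 * W)) %*% diag(m$weights)
  expect_lt(max(abs(unname(m$S) - S_ref)), 1e-10)
})

test_that("SCC partitions match the mutual-reachability oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    S <- matrix(runif(n * n), n)
    diag(S) <- 0
    th <- sort(unique(S[row(S) != col(S)]), decreasing = TRUE)
    memb <- mprsnet:::.scc_memberships(S, th)
    for (t in seq_along(th)) {
      expect_true(same_partition(memb[t, ], scc_oracle(S, th[t])))
    }
  }
})

test_that("asymmetric high/low pairs are not strongly connected", {
  S <- matrix(0, 3, 3)
  S[1, 2] <- 0.9  # edge 2 -> 1 strong
  S[2, 1] <- 0.1  # edge 1 -> 2 weak
  memb <- mprsnet:::.scc_memberships(S, 0.5)[1, ]
  expect_equal(length(unique(memb)), 3L)  # all singletons at delta = 0.5
  memb2 <- mprsnet:::.scc_memberships(S, 0.05)[1, ]
  expect_equal(memb2[1], memb2[2])        # mutual at delta below both
})

test_that("hierarchy partitions nest as the threshold decreases", {
  net <- random_network(20, p_edge = 0.15, seed = 21)
  m <- compute_similarity_matrix(net, beta = 0.4)
  h <- build_scc_hierarchy(m)
  for (t in seq_len(nrow(h$membership) - 1L)) {
    finer <- h$membership[t, ]
    coarser <- h$membership[t + 1L, ]
    # every finer block is contained in one coarser block
    expect_true(all(tapply(coarser, finer,
                           function(x) length(unique(x))) == 1L))
  }
  expect_true(all(diff(h$n_components) <= 0))
})

test_that("weight permutation preserves the multiset and is seeded", {
  net <- random_network(30, p_edge = 0.15, seed = 8)
  p1 <- permute_node_weights(net, seed = 5, n_bins = 1)
  p2 <- permute_node_weights(net, seed = 5, n_bins = 1)
  p3 <- permute_node_weights(net, seed = 6, n_bins = 1)
  expect_identical(p1$weights, p2$weights)
  expect_false(identical(p1$weights, p3$weights))
  expect_equal(sort(unname(p1$weights)), sort(unname(net$weights)))
  expect_equal(p1$edges, net$edges)
  # degree-binned permutation keeps weights within their bin
  pb <- permute_node_weights(net, seed = 5, n_bins = 100)
  expect_equal(sort(unname(pb$weights)), sort(unname(net$weights)))
})

test_that("a planted clique with dominant weights is recovered at small n_perm", {
  # 8-clique with weight 5 on a weight-0 background ring
  clique <- sprintf("C%d", 1:8)
  ring <- sprintf("R%02d", 1:32)
  edges <- rbind(
    as.data.frame(t(utils::combn(clique, 2)), stringsAsFactors = FALSE),
    data.frame(V1 = ring, V2 = c(ring[-1], ring[1]),
               stringsAsFactors = FALSE),
    data.frame(V1 = "C1", V2 = "R01", stringsAsFactors = FALSE))
  names(edges) <- c("from", "to")
  w <- stats::setNames(c(rep(5, 8), rep(0, 32)), c(clique, ring))
  net <- make_network(edges, w)
  suppressMessages(
    det <- select_cut_and_score(net, beta = 0.4, n_perm = 99, seed = 2,
                                n_bins = 1))
  expect_gte(nrow(det$modules), 1L)
  top <- det$modules$genes[[1L]]
  expect_setequal(top, clique)
  expect_equal(det$modules$perm_p[1L], 1 / 100)
})

test_that("equal node weights yield no significant module", {
  # permuting identical weights reproduces the observation exactly, so
  # every exceedance probability is 1 and the screen returns nothing
  for (seed in 1:3) {
    net <- random_network(30, p_edge = 0.15, seed = 40 + seed)
    net$weights[] <- 1
    suppressMessages(det <- select_cut_and_score(net, n_perm = 19,
                                                 seed = seed, n_bins = 1))
    expect_equal(nrow(det$modules), 0L)
    expect_true(is.na(det$delta_star))
  }
})

test_that("permutation p-values respect the add-one floor", {
  net <- random_network(25, p_edge = 0.2, seed = 13)
  suppressMessages(
    det <- select_cut_and_score(net, n_perm = 19, seed = 3, n_bins = 1,
                                alpha = 1.1))
  if (nrow(det$modules) > 0L) {
    expect_true(all(det$modules$perm_p >= 1 / 20))
    expect_true(all(det$modules$perm_p <= 1))
  }
  expect_error(select_cut_and_score(net, n_perm = 10, seed = 3), "19")
})
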