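test_that("theta estimates count joint states and partition to one", {
  expect_equal(unname(theta_estimates(c(1, 1, 0, 0), c(1, 0, 1, 0))),
               c(0.25, 0.25, 0.25, 0.25))
  expect_equal(unname(theta_estimates(c(1, 0, 1, 0), c(1, 0, 1, 0))),
               c(0.5, 0, 0, 0.5))
  set.seed(5)
  for (i in 1:20) {
    a <- runif(17) > 0.5; b <- runif(17) > 0.3
    th <- theta_estimates(a, b)
    expect_equal(sum(th), 1)
    # 2x2 table margins are the per-node alteration rates
    expect_equal(unname(th["theta1"] + th["theta2"]), mean(a))
    expect_equal(unname(th["theta1"] + th["theta3"]), mean(b))
  }
  expect_error(theta_estimates(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("Patel's kappa reproduces hand-derived cases exactly", {
  expect_equal(patel_kappa(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(patel_kappa(c(0.5, 0, 0, 0.5)), 1, tolerance = 1e-12)
  expect_equal(patel_kappa(c(0.1, 0.4, 0.4, 0.1)), -0.6, tolerance = 1e-12)
  expect_warning(k <- patel_kappa(c(1, 0, 0, 0)), "constant-state")
  expect_equal(k, 0)
  expect_error(patel_kappa(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("kappa agrees with the transcribed oracle and is a<->b symmetric", {
  set.seed(17)
  th <- random_thetas(2000)
  got <- patel_kappa(th)
  want <- vapply(seq_len(nrow(th)), function(i)
    kappa_oracle(th[i, 1], th[i, 2], th[i, 3], th[i, 4]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= -1 - 1e-12 & got <= 1 + 1e-12))
  # swapping a and b swaps theta2 and theta3 and leaves kappa unchanged
  expect_equal(patel_kappa(th[, c(1, 3, 2, 4)]), got, tolerance = 1e-12)
  # sign(kappa) = sign(theta1 - E)
  E <- (th[, 1] + th[, 2]) * (th[, 1] + th[, 3])
  expect_equal(sign(got), sign(th[, 1] - E))
})

test_that("alteration states reflect the truncated kernel support", {
  g <- tiny_grid(c(41, 41, 41))
  spec <- kernel_spec(10, 0, truncation_sigmas = 3.5)   # sigma 4.2466
  set <- experiment_set(list(
    foci_experiment("near", 10, c(0, 0, 0)),
    foci_experiment("far", 10, c(30, 30, 30))))
  nodes <- data.frame(id = 1:3,
                      x = c(0, 5, 0), y = c(0, 0, 20), z = 0,
                      ale_value = 1, is_root = NA)
  st <- alteration_states(nodes, set, g, spec)
  expect_equal(dim(st), c(2L, 3L))
  expect_true(st["near", "1"])       # node exactly at the focus
  expect_true(st["near", "2"])       # 5 mm < 3.5 * 4.2466 mm away
  expect_false(st["near", "3"])      # 20 mm: outside the truncated support
  expect_false(any(st["far", ]))
  # the explicit MA-map route agrees with the direct evaluation
  st2 <- alteration_states(nodes, ma_map_set(set, g, spec))
  expect_identical(unname(st), unname(st2))
})

test_that("network edges keep strictly positive kappa pairs", {
  # identical non-constant state vectors -> kappa 1 edge
  states <- cbind(a = c(TRUE, TRUE, FALSE, FALSE),
                  b = c(TRUE, TRUE, FALSE, FALSE),
                  c = c(TRUE, FALSE, TRUE, FALSE),
                  d = c(TRUE, TRUE, TRUE, TRUE))    # constant: excluded
  nodes <- data.frame(id = 1:4, x = 1:4, y = 0, z = 0, ale_value = 1,
                      is_root = NA)
  net <- build_network(states, nodes)
  expect_s3_class(net, "coalteration_network")
  expect_equal(net$diagnostics$excluded_nodes, 4L)
  ab <- net$edges[net$edges$node_a == 1 & net$edges$node_b == 2, ]
  expect_equal(ab$kappa, 1, tolerance = 1e-12)
  # a/c have theta1 = E exactly: kappa 0 fails the strict criterion
  expect_false(any(net$edges$node_a == 1 & net$edges$node_b == 3))
  expect_false(any(net$edges$node_a == 2 & net$edges$node_b == 3))
  expect_false(4L %in% c(net$edges$node_a, net$edges$node_b))
})

test_that("build_network is invariant to experiment and node order", {
  set.seed(23)
  N <- 30; K <- 6
  states <- matrix(runif(N * K) < 0.4, N, K)
  colnames(states) <- seq_len(K)
  nodes <- data.frame(id = seq_len(K), x = seq_len(K), y = 0, z = 0,
                      ale_value = 1, is_root = NA)
  net <- build_network(states, nodes)
  perm <- sample(N)
  net2 <- build_network(states[perm, , drop = FALSE], nodes)
  expect_equal(net2$edges, net$edges)
})

test_that("independent planted pairs have near-zero mean kappa", {
  set.seed(31)
  N <- 500; K <- 8
  states <- matrix(runif(N * K) < 0.35, N, K)
  nodes <- data.frame(id = seq_len(K), x = seq_len(K), y = 0, z = 0,
                      ale_value = 1, is_root = NA)
  # recompute kappa for every pair regardless of sign
  kap <- apply(utils::combn(K, 2), 2, function(p)
    patel_kappa(theta_estimates(states[, p[1]], states[, p[2]])))
  expect_lt(abs(mean(kap)), 0.05)
})

test_that("the permutation null separates coupled from constant pairs", {
  set.seed(41)
  a <- rep(c(TRUE, FALSE), 10)
  states <- cbind(a = a, b = a, cst = rep(TRUE, 20))
  res <- kappa_permutation_null(states, c("a", "b"), n_perm = 999, seed = 7)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$kappa_obs, 1, tolerance = 1e-12)
  expect_equal(kappa_permutation_null(states, c("a", "cst"),
                                      n_perm = 999)$p_value, 1)
  # reproducible given a seed
  res2 <- kappa_permutation_null(states, c("a", "b"), n_perm = 999, seed = 7)
  expect_identical(res, res2)
})

test_that("roots are the nodes whose voxel lies inside the mask", {
  g <- tiny_grid(c(21, 21, 21))
  mv <- array(FALSE, dim = c(21, 21, 21)); mv[8:14, 8:14, 8:14] <- TRUE
  roi <- binary_mask(mv, g)
  nodes <- data.frame(id = 1:3, x = c(0, -18, 8), y = c(0, 0, 0),
                      z = c(0, 0, 0), ale_value = 1, is_root = NA)
  net <- structure(list(nodes = nodes, edges = empty_edges(),
                        diagnostics = list(), n_experiments = 2L),
                   class = "coalteration_network")
  out <- identify_roots(net, roi)
  expect_equal(out$nodes$is_root, c(TRUE, FALSE, FALSE))
  allout <- net; allout$nodes$x <- c(-18, -18, 18)
  expect_error(identify_roots(allout, roi), "no node")
})

test_that("first-neighbor subnetwork drops non-root-only edges and orphans", {
  nodes <- data.frame(id = 1:5, x = 1:5, y = 0, z = 0, ale_value = 1,
                      is_root = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  edges <- data.frame(node_a = c(1, 1, 1, 2), node_b = c(2, 3, 4, 3),
                      kappa = c(0.8, 0.6, 0.9, 0.7),
                      theta1 = 0.2, theta2 = 0.2, theta3 = 0.2, theta4 = 0.4)
  net <- structure(list(nodes = nodes, edges = edges, diagnostics = list(),
                        n_experiments = 10L), class = "coalteration_network")
  sub <- first_neighbor_subnetwork(net)
  expect_equal(nrow(sub$edges), 3L)                 # 2-3 removed
  expect_true(all(sub$edges$node_a == 1))
  expect_equal(sub$nodes$id, 1:4)                   # node 5 dropped
  # two roots joined by an edge keep it
  net2 <- net; net2$nodes$is_root[2] <- TRUE
  expect_true(any(first_neighbor_subnetwork(net2)$edges$node_a == 2 |
                  first_neighbor_subnetwork(net2)$edges$node_b == 2))
})

test_that("profile matrix holds kappa per root-node pair and zeros elsewhere", {
  nodes <- data.frame(id = 1:4, x = 1:4, y = 0, z = 0, ale_value = 1,
                      is_root = c(TRUE, TRUE, FALSE, FALSE))
  edges <- data.frame(node_a = c(1, 1, 1, 2), node_b = c(2, 3, 4, 3),
                      kappa = c(0.8, 0.6, 0.9, 0.5),
                      theta1 = 0.2, theta2 = 0.2, theta3 = 0.2, theta4 = 0.4)
  net <- structure(list(nodes = nodes, edges = edges, diagnostics = list(),
                        n_experiments = 10L), class = "coalteration_network")
  pm <- profile_matrix(first_neighbor_subnetwork(net))
  expect_equal(dim(pm), c(2L, 4L))
  expect_equal(sum(pm["1", ] != 0), 3L)
  expect_equal(pm["1", "2"], 0.8)
  expect_equal(pm["2", "1"], 0.8)                   # symmetric orientation
  expect_equal(pm["1", "1"], 0)                     # no self-entries
  # root-column zeroing keeps shape and non-root entries
  pm2 <- drop_root_edges(pm)
  expect_equal(dim(pm2), dim(pm))
  expect_equal(pm2["1", "2"], 0)
  expect_equal(pm2["2", "1"], 0)
  expect_equal(pm2["1", "3"], pm["1", "3"])
})
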