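# a toy first-neighbor subnetwork on a small grid: two roots in cluster 1,
# neighbors spread over atlas labels
make_toy_decomposition <- function() {
  g <- tiny_grid(c(21, 21, 5))
  av <- array(0L, dim = c(21, 21, 5))
  av[1:10, 1:10, ] <- 7L                          # DMN block
  av[11:21, 1:10, ] <- 1L                         # VIS block
  atlas <- label_volume(av, g)
  # roots 1,2 (cluster 1) and root 3 (cluster 2); neighbors 4..13
  nb_xy <- rbind(c(-16, -16), c(-10, -12), c(-4, -16),      # DMN
                 c(4, -16), c(10, -12), c(16, -16), c(4, -10),  # VIS
                 c(-16, 8), c(16, 8), c(0, 14))              # unassigned
  nodes <- data.frame(id = 1:13,
                      x = c(-6, 6, 0, nb_xy[, 1]),
                      y = c(2, 2, 6, nb_xy[, 2]),
                      z = 0, ale_value = 1,
                      is_root = c(TRUE, TRUE, TRUE, rep(FALSE, 10)))
  kap <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.95)
  edges <- data.frame(node_a = c(rep(1, 5), rep(2, 5), 1),
                      node_b = c(4:8, 9:13, 2),
                      kappa = c(kap, 0.99),
                      theta1 = 0.2, theta2 = 0.2, theta3 = 0.2, theta4 = 0.4)
  sub <- structure(list(nodes = nodes, edges = edges, diagnostics = list(),
                        n_experiments = 10L), class = "coalteration_network")
  sol <- structure(list(cardinality = 2L,
                        labels = c(`1` = 1L, `2` = 1L, `3` = 2L)),
                   class = "cluster_solution")
  list(sub = sub, sol = sol, atlas = atlas, grid = g, kappas = kap)
}

test_that("decomposition counts neighbors by atlas label with brute force", {
  toy <- make_toy_decomposition()
  res <- decompose_cluster(toy$sub, toy$sol, 1, toy$atlas,
                           percentiles = c(0, 30, 60, 90))
  expect_equal(sort(unique(res$percentile)), c(0, 30, 60, 90))
  # threshold 0: all 10 neighbors counted (the 1-2 root-root edge is not a
  # neighbor edge)
  r0 <- res[res$percentile == 0, ]
  expect_equal(sum(r0$count), 10L)
  expect_equal(r0$count[r0$network == "DMN"], 3L)
  expect_equal(r0$pct[r0$network == "DMN"], 30)
  expect_equal(r0$count[r0$network == "VIS"], 4L)
  expect_equal(r0$count[r0$network == "unassigned"], 3L)
  # brute-force agreement at every percentile
  for (p in c(0, 30, 60, 90)) {
    thr <- unname(quantile(toy$kappas, p / 100))
    keep_nb <- toy$sub$edges$node_b[toy$sub$edges$kappa >= thr &
                                      toy$sub$edges$node_b > 3]
    rp <- res[res$percentile == p, ]
    expect_equal(sum(rp$count), length(unique(keep_nb)))
    expect_equal(rp$threshold[1], thr)
  }
})

test_that("percentages sum to 100 and counts are monotone in the threshold", {
  toy <- make_toy_decomposition()
  res <- decompose_cluster(toy$sub, toy$sol, 1, toy$atlas,
                           percentiles = c(0, 30, 60, 90))
  for (p in unique(res$percentile))
    expect_equal(sum(res$pct[res$percentile == p]), 100)
  for (net in unique(res$network)) {
    cnt <- res$count[res$network == net][order(unique(res$percentile))]
    expect_true(all(diff(cnt) <= 0))
  }
  # a threshold above the maximum kappa yields zero counts
  res100 <- decompose_cluster(toy$sub, toy$sol, 1, toy$atlas,
                              percentiles = 100)
  keep <- toy$sub$edges$kappa >= max(toy$kappas)
  expect_equal(sum(res100$count), 1L)   # only the kappa = 0.95 neighbor
})

test_that("single-label neighborhoods decompose to 100 percent", {
  toy <- make_toy_decomposition()
  sub <- toy$sub
  sub$edges <- sub$edges[sub$edges$node_b %in% 4:6, ]      # DMN only
  res <- decompose_cluster(sub, toy$sol, 1, toy$atlas, percentiles = 0)
  expect_equal(res$pct[res$network == "DMN"], 100)
  expect_equal(sum(res$count), 3L)
})

test_that("map correlation summary equals a brute-force all-pairs oracle", {
  set.seed(53)
  g <- tiny_grid(c(6, 6, 6))
  M <- matrix(rnorm(5 * 216), 5, 216,
              dimnames = list(as.character(1:5), NULL))
  ms <- map_set(M, g)
  sol <- structure(list(cardinality = 2L,
                        labels = c(`1` = 1L, `2` = 1L, `3` = 1L,
                                   `4` = 2L, `5` = 2L)),
                   class = "cluster_solution")
  out <- map_correlation_summary(ms, sol)
  R <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) R[i, j] <- cor(M[i, ], M[j, ])
  expect_equal(unname(out$pairwise), R, tolerance = 1e-12)
  w1 <- c(R[1, 2], R[1, 3], R[2, 3])
  b1 <- as.vector(R[1:3, 4:5])
  s1 <- out$summary[out$summary$cluster == 1, ]
  expect_equal(s1$within_mean, mean(w1), tolerance = 1e-12)
  expect_equal(s1$within_max, max(w1), tolerance = 1e-12)
  expect_equal(s1$between_mean, mean(b1), tolerance = 1e-12)
  expect_equal(s1$between_max, max(b1), tolerance = 1e-12)
  expect_equal(s1$max_is_within, max(w1) > max(b1))
})

test_that("template-plus-noise maps correlate within clusters", {
  set.seed(59)
  nv <- 500
  t1 <- rnorm(nv); t2 <- rnorm(nv)
  M <- rbind(t1 + rnorm(nv, sd = 0.3), t1 + rnorm(nv, sd = 0.3),
             t2 + rnorm(nv, sd = 0.3), t2 + rnorm(nv, sd = 0.3))
  rownames(M) <- as.character(1:4)
  ms <- map_set(M, tiny_grid(c(5, 10, 10)))
  sol <- structure(list(cardinality = 2L,
                        labels = c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L)),
                   class = "cluster_solution")
  s <- map_correlation_summary(ms, sol)$summary
  expect_true(all(s$within_mean > s$between_mean))
  expect_true(all(s$max_is_within))
  # orthogonal random templates: between-cluster mean near 0
  expect_lt(abs(s$between_mean[1]), 0.15)
})

test_that("map clustering joins duplicates first and ignores order", {
  set.seed(61)
  g <- tiny_grid(c(5, 5, 5))
  m <- rnorm(125); m2 <- rnorm(125)
  ms <- map_set(rbind(a = m, b = m, c = m2), g)
  dend <- cluster_maps(ms)
  expect_equal(dend$merge[1, ], c(-1L, -2L))
  expect_equal(dend$height[1], 0)
  ms_perm <- map_set(rbind(c = m2, a = m, b = m), g)
  dend2 <- cluster_maps(ms_perm)
  lab <- cut_clusters(dend, 2)$labels
  lab2 <- cut_clusters(dend2, 2)$labels
  expect_equal(unname(lab[c("a", "b", "c")] == lab[c("a", "a", "a")]),
               unname(lab2[c("a", "b", "c")] == lab2[c("a", "a", "a")]))
  # planted two-template grouping is recovered at c = 2
  M <- rbind(a = m + rnorm(125, sd = 0.1), b = m + rnorm(125, sd = 0.1),
             c = m2 + rnorm(125, sd = 0.1), d = m2 + rnorm(125, sd = 0.1))
  sol <- cut_clusters(cluster_maps(map_set(M, g)), 2)
  expect_equal(unname(sol$labels["a"]), unname(sol$labels["b"]))
  expect_equal(unname(sol$labels["c"]), unname(sol$labels["d"]))
  expect_false(unname(sol$labels["a"]) == unname(sol$labels["c"]))
})
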