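# Independent oracles and small fixtures, built in code at test time.

# scalar Patel's kappa, transcribed separately from the package's
# vectorized implementation. D interpolates 0 -> 1 as theta1 runs from its
# attainable minimum to its attainable maximum (0.5 at independence), which
# is what keeps kappa inside [-1, 1].
kappa_oracle <- function(t1, t2, t3, t4) {
  E <- (t1 + t2) * (t1 + t3)
  max_t1 <- min(t1 + t2, t1 + t3)
  min_t1 <- max(0, 2 * t1 + t2 + t3 - 1)
  if (t1 >= E) {
    D <- (t1 - E) / (2 * (max_t1 - E)) + 0.5
  } else {
    D <- (t1 - E) / (2 * (E - min_t1)) + 0.5
  }
  (t1 - E) / (D * (max_t1 - E) + (1 - D) * (E - min_t1))
}

# random valid theta quadruples (Dirichlet-uniform on the simplex)
random_thetas <- function(n) {
  g <- matrix(stats::rexp(4 * n), n, 4)
  g / rowSums(g)
}

# naive agglomerator recomputing every inter-cluster distance from the
# ORIGINAL matrix: complete = max over member pairs, average = mean over
# member pairs, wpgma = bilinear form with per-leaf weights that halve at
# each merge. Same lexicographic tie rule, different computation path.
naive_linkage <- function(d0, method) {
  n <- nrow(d0)
  members <- as.list(seq_len(n))
  weights <- lapply(seq_len(n), function(i) { w <- numeric(n); w[i] <- 1; w })
  cl_id <- -(seq_len(n)); order_id <- seq_len(n); active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L); height <- numeric(n - 1L)
  cdist <- function(i, j) {
    switch(method,
      complete = max(d0[members[[i]], members[[j]]]),
      average  = mean(d0[members[[i]], members[[j]]]),
      wpgma    = sum(outer(weights[[i]], weights[[j]]) * d0))
  }
  for (s in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; bd <- Inf
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      i <- act[ii]; j <- act[jj]
      a <- if (order_id[i] < order_id[j]) i else j
      b <- if (order_id[i] < order_id[j]) j else i
      dij <- cdist(i, j)
      better <- dij < bd ||
        (dij == bd && (order_id[a] < order_id[best[1]] ||
         (order_id[a] == order_id[best[1]] &&
          order_id[b] < order_id[best[2]])))
      if (better) { bd <- dij; best <- c(a, b) }
    }
    u <- best[1]; v <- best[2]
    merge[s, ] <- c(cl_id[u], cl_id[v]); height[s] <- bd
    members[[u]] <- c(members[[u]], members[[v]])
    weights[[u]] <- (weights[[u]] + weights[[v]]) / 2
    active[v] <- FALSE; cl_id[u] <- s; order_id[u] <- n + s
  }
  list(merge = merge, height = height)
}

cophenetic_of <- function(merge, height, n) {
  as.matrix(stats::cophenetic(structure(
    list(merge = merge, height = height, order = seq_len(n),
         labels = as.character(seq_len(n)), method = "x"),
    class = "hclust")))
}

random_distance_matrix <- function(n) {
  d <- matrix(stats::runif(n * n), n, n)
  d <- d + t(d); diag(d) <- 0
  dimnames(d) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  d
}

# small centred grid for kernel/peak tests
tiny_grid <- function(shape = c(31, 31, 31), res = 2) {
  tr <- -(shape - 1) / 2 * res
  volume_grid(shape, rbind(c(res, 0, 0, tr[1]), c(0, res, 0, tr[2]),
                           c(0, 0, res, tr[3]), c(0, 0, 0, 1)))
}

# brute-force 26-neighbour local-maximum check
brute_force_peaks <- function(v, min_value) {
  shp <- dim(v)
  out <- NULL
  for (x in seq_len(shp[1])) for (y in seq_len(shp[2])) for (z in seq_len(shp[3])) {
    if (v[x, y, z] < min_value) next
    is_max <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > shp[1] || yy < 1 || yy > shp[2] ||
          zz < 1 || zz > shp[3]) next
      if (v[xx, yy, zz] > v[x, y, z]) { is_max <- FALSE; break }
    }
    if (is_max) out <- rbind(out, c(x, y, z))
  }
  out
}

empty_edges <- function() {
  data.frame(node_a = integer(0), node_b = integer(0), kappa = numeric(0),
             theta1 = numeric(0), theta2 = numeric(0), theta3 = numeric(0),
             theta4 = numeric(0))
}

# a deterministic two-experiment set for io tests
toy_experiment_set <- function() {
  experiment_set(list(
    foci_experiment("study_a", 12L, rbind(c(-2, 4, 10), c(6, -8, 2),
                                          c(0, 0, 0))),
    foci_experiment("study_b", 30L, rbind(c(10, 20, 30), c(-10, -20, -30)),
                    meta = list(header = "diagnosis: synthetic"))))
}
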