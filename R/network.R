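#' Joint alteration probabilities of two nodes
#'
#' Plug-in (frequency) estimates of the four joint states over experiments:
#' theta1 = P(a=1, b=1), theta2 = P(a=1, b=0), theta3 = P(a=0, b=1),
#' theta4 = P(a=0, b=0); they partition to 1 and their 2x2 table margins are
#' the per-node alteration probabilities. An optional conjugate add-alpha
#' smoothing ((count + alpha) / (N + 4 alpha)) is available for degenerate
#' state vectors.
#'
#' @param a,b logical (or 0/1) vectors of equal length N >= 2: the node's
#'   alteration state in each experiment.
#' @param alpha non-negative smoothing pseudo-count per cell (default 0).
#' @return Named numeric vector `c(theta1, theta2, theta3, theta4)`.
#' @export
theta_estimates <- function(a, b, alpha = 0) {
  if (length(a) != length(b)) stop("state vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 experiments")
  a <- as.logical(a); b <- as.logical(b)
  if (anyNA(a) || anyNA(b)) stop("states must be TRUE/FALSE")
  counts <- c(theta1 = sum(a & b), theta2 = sum(a & !b),
              theta3 = sum(!a & b), theta4 = sum(!a & !b))
  (counts + alpha) / (n + 4 * alpha)
}

#' Patel's kappa from joint alteration probabilities
#'
#' kappa = (theta1 - E) / (D (max(theta1) - E) + (1 - D)(E - min(theta1)))
#' with E = (theta1 + theta2)(theta1 + theta3) the independence expectation,
#' max(theta1) = min(theta1 + theta2, theta1 + theta3),
#' min(theta1) = max(0, 2 theta1 + theta2 + theta3 - 1), and the weight
#' D = 0.5 + (theta1 - E) / (2 (max(theta1) - E)) when theta1 >= E,
#' D = 0.5 + (theta1 - E) / (2 (E - min(theta1))) otherwise, so that D runs
#' from 0 at theta1 = min(theta1) through 0.5 at independence to 1 at
#' theta1 = max(theta1). kappa therefore lies in \[-1, 1\] (-1 and 1 exactly
#' at the attainable bounds of theta1), is 0 exactly when theta1 = E, and is
#' positive when joint alteration is more likely than under independence.
#'
#' For a constant-state node (a margin of 0 or 1) the bounds collapse onto E
#' and kappa is undefined; it is returned as 0 with a warning.
#'
#' @param theta length-4 vector `(theta1..theta4)` summing to 1, or an
#'   n x 4 matrix of such rows (vectorized).
#' @return Numeric kappa value(s) in \[-1, 1\].
#' @export
patel_kappa <- function(theta) {
  th <- if (is.null(dim(theta))) matrix(theta, nrow = 1L) else as.matrix(theta)
  if (ncol(th) != 4L) stop("theta must have 4 components")
  if (any(!is.finite(th)) || any(th < -1e-12) || any(th > 1 + 1e-12))
    stop("theta components must be probabilities")
  if (any(abs(rowSums(th) - 1) > 1e-8))
    stop("theta components must sum to 1")
  t1 <- th[, 1]; t2 <- th[, 2]; t3 <- th[, 3]
  E <- (t1 + t2) * (t1 + t3)
  maxt <- pmin(t1 + t2, t1 + t3)
  mint <- pmax(0, 2 * t1 + t2 + t3 - 1)
  num <- t1 - E
  k <- numeric(length(t1))
  degen <- (maxt - E) <= 0 & (E - mint) <= 0
  if (any(degen & abs(num) < 1e-12))
    warning("constant-state node: Patel's kappa undefined, returned as 0")
  pos <- num > 0 & !degen
  neg <- num < 0 & !degen
  if (any(pos)) {
    D <- num[pos] / (2 * (maxt[pos] - E[pos])) + 0.5
    k[pos] <- num[pos] / (D * (maxt[pos] - E[pos]) + (1 - D) * (E[pos] - mint[pos]))
  }
  if (any(neg)) {
    D <- 0.5 + num[neg] / (2 * (E[neg] - mint[neg]))
    k[neg] <- num[neg] / (D * (maxt[neg] - E[neg]) + (1 - D) * (E[neg] - mint[neg]))
  }
  pmin(1, pmax(-1, k))
}

#' Alteration-state matrix of nodes across experiments
#'
#' A node is altered in an experiment when the experiment's
#' modeled-alteration map has a non-zero value at the node's voxel, i.e. the
#' node lies within the truncated kernel support of at least one focus.
#'
#' @param nodes node data.frame from [detect_peaks()].
#' @param x an `ma_map_set` (from [ma_map_set()]) or an [experiment_set()];
#'   the latter evaluates MA values at the node voxels directly without
#'   building full volumes — the two routes agree exactly.
#' @param grid,spec required when `x` is an [experiment_set()].
#' @return Logical experiments x nodes matrix with dimnames.
#' @export
alteration_states <- function(nodes, x, grid = NULL, spec = kernel_spec()) {
  pts <- node_points(nodes)
  if (inherits(x, "ma_map_set")) {
    idx <- mm_to_voxel(pts, x$grid)
    states <- vapply(x$maps, function(m) m$values[idx] > 0,
                     logical(nrow(idx)))
  } else if (inherits(x, "experiment_set")) {
    if (is.null(grid)) stop("grid is required with an experiment_set")
    states <- vapply(x$experiments,
                     function(e) ma_values_at(pts, e, grid, spec) > 0,
                     logical(nrow(pts)))
  } else stop("x must be an ma_map_set or experiment_set")
  states <- t(states)                      # experiments x nodes
  dimnames(states) <- list(if (inherits(x, "ma_map_set")) names(x$maps)
                           else experiment_ids(x),
                           nodes$id)
  states
}

#' Build the morphometric co-alteration network
#'
#' For every unordered pair of non-degenerate nodes, estimates the joint
#' alteration probabilities and Patel's kappa; an edge is kept when kappa
#' exceeds `kappa_threshold` (strictly), i.e. by default whenever joint
#' alteration is more likely than independent alteration. Nodes altered in
#' none or in all experiments have undefined kappa and are excluded from
#' pairing; their ids are reported in the diagnostics.
#'
#' @param states logical experiments x nodes matrix from
#'   [alteration_states()].
#' @param nodes the matching node data.frame.
#' @param kappa_threshold strict lower bound for keeping an edge (default 0).
#' @param alpha add-alpha smoothing passed to the theta estimates (default 0).
#' @return An object of class `coalteration_network`: list with `nodes`,
#'   `edges` (data.frame `node_a`, `node_b`, `kappa`, `theta1..theta4`),
#'   `diagnostics` (`excluded_nodes`), and `n_experiments`.
#' @export
build_network <- function(states, nodes, kappa_threshold = 0, alpha = 0) {
  stopifnot(is.matrix(states), nrow(states) >= 2L,
            ncol(states) == nrow(nodes))
  N <- nrow(states)
  S <- matrix(as.numeric(states), N, ncol(states))
  n_alt <- colSums(S)
  keep <- n_alt > 0 & n_alt < N
  excluded <- nodes$id[!keep]
  kidx <- which(keep)
  edges <- empty_edge_table()
  if (length(kidx) >= 2L) {
    Sk <- S[, kidx, drop = FALSE]
    C11 <- crossprod(Sk)
    m <- colSums(Sk)
    C10 <- outer(m, m, function(a, b) a) - C11   # a=1, b=0
    C01 <- t(C10)
    pair <- which(upper.tri(C11), arr.ind = TRUE)
    th <- cbind(C11[pair], C10[pair], C01[pair],
                N - C11[pair] - C10[pair] - C01[pair])
    th <- (th + alpha) / (N + 4 * alpha)
    kap <- patel_kappa(th)
    sel <- kap > kappa_threshold
    if (any(sel)) {
      ia <- kidx[pair[sel, 1]]; ib <- kidx[pair[sel, 2]]
      edges <- data.frame(node_a = pmin(nodes$id[ia], nodes$id[ib]),
                          node_b = pmax(nodes$id[ia], nodes$id[ib]),
                          kappa = kap[sel],
                          theta1 = th[sel, 1], theta2 = th[sel, 2],
                          theta3 = th[sel, 3], theta4 = th[sel, 4])
      edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 diagnostics = list(excluded_nodes = excluded),
                 n_experiments = N),
            class = "coalteration_network")
}

empty_edge_table <- function() {
  data.frame(node_a = integer(0), node_b = integer(0), kappa = numeric(0),
             theta1 = numeric(0), theta2 = numeric(0), theta3 = numeric(0),
             theta4 = numeric(0))
}

#' @export
print.coalteration_network <- function(x, ...) {
  cat("<coalteration_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_root %in% TRUE), " roots), ", nrow(x$edges),
      " edges, ", x$n_experiments, " experiments\n", sep = "")
  invisible(x)
}

#' Permutation null for one pair's Patel's kappa
#'
#' Permutes one node's state vector across experiments, recomputing kappa
#' each time; p = (1 + #\{kappa_perm >= kappa_obs\}) / (1 + n_perm). A
#' constant state vector yields p = 1.
#'
#' @param states logical experiments x nodes matrix.
#' @param pair length-2 vector of node ids (matching `colnames(states)`) or
#'   column indices.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @return List with `p_value`, `kappa_obs`, `n_perm`.
#' @export
kappa_permutation_null <- function(states, pair, n_perm = 999, seed = NULL) {
  stopifnot(length(pair) == 2L, n_perm >= 100)
  if (is.character(pair)) pair <- match(pair, colnames(states))
  if (anyNA(pair)) stop("pair not found in states columns")
  a <- states[, pair[1]]; b <- states[, pair[2]]
  N <- length(a)
  if (!is.null(seed)) set.seed(seed)
  if (all(a) || !any(a) || all(b) || !any(b))
    return(list(p_value = 1, kappa_obs = NA_real_, n_perm = n_perm))
  obs <- patel_kappa(theta_estimates(a, b))
  B <- vapply(seq_len(n_perm), function(i) b[sample.int(N)], logical(N))
  t1 <- colMeans(a & B); t2 <- colMeans(a & !B); t3 <- colMeans(!a & B)
  kap <- patel_kappa(cbind(t1, t2, t3, 1 - t1 - t2 - t3))
  p <- (1 + sum(kap >= obs)) / (1 + n_perm)
  list(p_value = p, kappa_obs = obs, n_perm = n_perm)
}

#' Flag nodes inside the region-of-interest mask as root nodes
#'
#' Membership is voxel-based: a node is a root when its containing voxel is
#' inside the mask.
#'
#' @param network a `coalteration_network`.
#' @param roi a [binary_mask()] on the analysis grid.
#' @return The network with `nodes$is_root` set.
#' @export
identify_roots <- function(network, roi) {
  stopifnot(inherits(network, "coalteration_network"),
            inherits(roi, "binary_mask"))
  idx <- mm_to_voxel(node_points(network$nodes), roi$grid, strict = FALSE)
  inb <- idx[, 1] >= 1L & idx[, 1] <= roi$grid$shape[1] &
         idx[, 2] >= 1L & idx[, 2] <= roi$grid$shape[2] &
         idx[, 3] >= 1L & idx[, 3] <= roi$grid$shape[3]
  is_root <- logical(nrow(idx))
  is_root[inb] <- roi$values[idx[inb, , drop = FALSE]]
  if (!any(is_root))
    stop("no node falls inside the ROI mask; cannot identify root nodes")
  network$nodes$is_root <- is_root
  network
}

#' First-neighbor subnetwork of the root nodes
#'
#' Keeps exactly the edges with at least one root endpoint (root-root edges
#' included) and the nodes that are roots or touch such an edge; edges
#' between two non-root nodes are removed and non-root nodes left isolated
#' by that removal are dropped.
#'
#' @param network a `coalteration_network` with `is_root` set.
#' @return A `coalteration_network`.
#' @export
first_neighbor_subnetwork <- function(network) {
  nodes <- network$nodes
  if (anyNA(nodes$is_root)) stop("run identify_roots() first")
  roots <- nodes$id[nodes$is_root]
  if (!length(roots)) stop("network has no root nodes")
  e <- network$edges
  keep <- e$node_a %in% roots | e$node_b %in% roots
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  keep_nodes <- nodes$id %in% c(roots, e$node_a, e$node_b)
  out <- network
  out$nodes <- nodes[keep_nodes, , drop = FALSE]
  rownames(out$nodes) <- NULL
  out$edges <- e
  out
}

#' Root-profile matrix of a first-neighbor subnetwork
#'
#' Rows are root nodes, columns all subnetwork nodes; entry (r, c) is the
#' Patel's kappa of edge r-c when present and 0 otherwise (including the
#' r = r diagonal-type entries). Column order follows the subnetwork node
#' table and is recorded in the dimnames.
#'
#' @param subnetwork output of [first_neighbor_subnetwork()].
#' @return Numeric roots x nodes matrix with id dimnames.
#' @export
profile_matrix <- function(subnetwork) {
  nodes <- subnetwork$nodes
  roots <- nodes$id[nodes$is_root]
  pm <- matrix(0, length(roots), nrow(nodes),
               dimnames = list(as.character(roots), as.character(nodes$id)))
  e <- subnetwork$edges
  for (k in seq_len(nrow(e))) {
    a <- as.character(e$node_a[k]); b <- as.character(e$node_b[k])
    if (a %in% rownames(pm)) pm[a, b] <- e$kappa[k]
    if (b %in% rownames(pm)) pm[b, a] <- e$kappa[k]
  }
  pm
}
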