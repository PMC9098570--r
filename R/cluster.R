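#' Correlation distance between matrix rows
#'
#' d(i, j) = 1 - r(i, j), with r the Pearson correlation of rows i and j:
#' perfectly coherent co-alteration profiles are at distance 0,
#' anticorrelated ones at 2. A constant row has undefined correlations;
#' they are set to 0 (distance 1) with a warning.
#'
#' @param mat numeric matrix with >= 2 rows (e.g. a [profile_matrix()]).
#' @return Symmetric zero-diagonal distance matrix over rows, range \[0, 2\].
#' @export
correlation_distance <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 rows")
  if (any(!is.finite(mat))) stop("matrix must be finite")
  sds <- apply(mat, 1, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("constant row(s) ", paste(rownames(mat)[const], collapse = ", "),
            ": correlations set to 0")
  r <- suppressWarnings(stats::cor(t(mat)))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  d <- 1 - r
  d[d < 0] <- 0
  (d + t(d)) / 2
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Iteratively merges the closest pair of clusters. After merging u and v,
#' the distance to any other cluster w is (d(u,w) + d(v,w)) / 2 for WPGMA,
#' the cluster-size-weighted mean for average linkage (UPGMA), and the
#' maximum for complete linkage. Exact distance ties are broken by the
#' lexicographically smallest pair of cluster indices (clusters indexed by
#' creation order: leaves first, then merges). Merge height is the merged
#' pair's distance; all three linkages are reducible, so heights are
#' non-decreasing.
#'
#' @param dist symmetric, zero-diagonal, non-negative distance matrix.
#' @param linkage one of `"wpgma"`, `"average"`, `"complete"`.
#' @return An object of class `coalt_dendrogram`: list with `merge`
#'   (hclust-style signed matrix), `height`, `labels`, `linkage`. Convert
#'   with [as.hclust.coalt_dendrogram()] or export with
#'   [dendrogram_newick()].
#' @export
hierarchical_cluster <- function(dist, linkage = c("wpgma", "average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(n >= 2L, ncol(d) == n)
  if (any(!is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  diag(d) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  cl_id <- -(seq_len(n))             # hclust coding: negative = leaf
  order_id <- seq_len(n)             # creation order for tie-breaking
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    # smallest distance; ties -> smallest (i, j) by creation order
    best <- NULL; best_d <- Inf
    for (ii in seq_along(act)) for (jj in seq_along(act)) {
      if (jj <= ii) next
      i <- act[ii]; j <- act[jj]
      a <- if (order_id[i] < order_id[j]) i else j
      b <- if (order_id[i] < order_id[j]) j else i
      dij <- d[i, j]
      if (dij < best_d ||
          (dij == best_d &&
           (order_id[a] < order_id[best[1]] ||
            (order_id[a] == order_id[best[1]] && order_id[b] < order_id[best[2]])))) {
        best_d <- dij; best <- c(a, b)
      }
    }
    u <- best[1]; v <- best[2]
    merge[step, ] <- c(cl_id[u], cl_id[v])
    height[step] <- best_d
    for (w in act) {
      if (w == u || w == v) next
      d[u, w] <- switch(linkage,
        wpgma    = (d[u, w] + d[v, w]) / 2,
        average  = (sizes[u] * d[u, w] + sizes[v] * d[v, w]) / (sizes[u] + sizes[v]),
        complete = max(d[u, w], d[v, w]))
      d[w, u] <- d[u, w]
    }
    sizes[u] <- sizes[u] + sizes[v]
    active[v] <- FALSE
    cl_id[u] <- step
    order_id[u] <- n + step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "coalt_dendrogram")
}

#' @export
print.coalt_dendrogram <- function(x, ...) {
  cat("<coalt_dendrogram> ", length(x$labels), " leaves, ", x$linkage,
      " linkage, heights [", paste(signif(range(x$height), 4), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Convert a dendrogram to a base-R hclust object
#'
#' @param x a `coalt_dendrogram`.
#' @param ... unused.
#' @return An `hclust` object (with leaf order computed by recursion).
#' @export
as.hclust.coalt_dendrogram <- function(x, ...) {
  leaf_order <- function(i) {
    if (i < 0) return(-i)
    c(leaf_order(x$merge[i, 1]), leaf_order(x$merge[i, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(nrow(x$merge)),
                 labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "correlation"),
            class = "hclust")
}

#' Cut a dendrogram into c clusters
#'
#' Undoes the last (c - 1) merges; labels 1..c are assigned by the order of
#' each cluster's smallest leaf index.
#'
#' @param dendrogram a `coalt_dendrogram`.
#' @param c number of clusters, between 1 and the number of leaves.
#' @return An object of class `cluster_solution`: list with `cardinality`
#'   and named integer `labels` (per leaf).
#' @export
cut_clusters <- function(dendrogram, c) {
  n <- length(dendrogram$labels)
  if (c < 1 || c > n) stop("c must be between 1 and ", n)
  labels <- stats::cutree(as.hclust.coalt_dendrogram(dendrogram), k = c)
  names(labels) <- dendrogram$labels
  structure(list(cardinality = as.integer(c), labels = labels),
            class = "cluster_solution")
}

#' Zero the root-node columns of a profile matrix
#'
#' Repeats the clustering input with local (within-ROI) co-alteration
#' removed: every entry whose column id is a root id (a row id) is set to
#' 0; all other entries are untouched and the shape is unchanged.
#'
#' @param matrix a [profile_matrix()].
#' @return The matrix with root columns zeroed.
#' @export
drop_root_edges <- function(matrix) {
  root_cols <- colnames(matrix) %in% rownames(matrix)
  matrix[, root_cols] <- 0
  matrix
}

#' Local (root-root) subnetwork above a kappa threshold
#'
#' Keeps only root-root edges with kappa >= `threshold`; nodes with no
#' surviving edge are dropped.
#'
#' @param network a `coalteration_network` with roots identified.
#' @param threshold kappa threshold in \[0, 1\] (default 0.5, the display
#'   rule for the strongest local co-alteration).
#' @return A `coalteration_network` of surviving roots and edges.
#' @export
local_subnetwork <- function(network, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  nodes <- network$nodes
  if (anyNA(nodes$is_root)) stop("run identify_roots() first")
  roots <- nodes$id[nodes$is_root]
  e <- network$edges
  keep <- e$node_a %in% roots & e$node_b %in% roots & e$kappa >= threshold
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  out <- network
  out$edges <- e
  out$nodes <- nodes[nodes$id %in% c(e$node_a, e$node_b), , drop = FALSE]
  rownames(out$nodes) <- NULL
  out
}

#' Voxel-wise parcellation of the ROI by nearest root node
#'
#' Every ROI voxel (centre, mm) is assigned the cluster label of its
#' Euclidean-nearest root node; exact distance ties go to the root with the
#' smallest id. Distances are computed in millimetres, so anisotropic grids
#' are handled correctly.
#'
#' @param roi a [binary_mask()].
#' @param roots node data.frame of the labelled root nodes.
#' @param solution a `cluster_solution` whose names match the root ids.
#' @return A [label_volume()]: cluster labels over ROI voxels, 0 outside.
#' @export
voxel_parcellation <- function(roi, roots, solution) {
  stopifnot(inherits(roi, "binary_mask"),
            inherits(solution, "cluster_solution"))
  if (nrow(roots) == 0L) stop("no root nodes")
  lab <- solution$labels[as.character(roots$id)]
  if (anyNA(lab)) stop("every root must be labelled in the solution")
  ord <- order(roots$id)
  roots <- roots[ord, , drop = FALSE]; lab <- lab[ord]
  idx <- which(roi$values, arr.ind = TRUE)
  mm <- voxel_to_mm(idx, roi$grid)
  rp <- node_points(roots)
  d2 <- outer(rowSums(mm^2), rep(1, nrow(rp))) - 2 * mm %*% t(rp) +
        outer(rep(1, nrow(mm)), rowSums(rp^2))
  nearest <- max.col(-d2, ties.method = "first")   # cols sorted by root id
  vals <- array(0L, dim = roi$grid$shape)
  vals[idx] <- as.integer(lab[nearest])
  label_volume(vals, roi$grid)
}

#' Export a dendrogram as Newick text
#'
#' @param dendrogram a `coalt_dendrogram`.
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(as.hclust.coalt_dendrogram(dendrogram))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
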