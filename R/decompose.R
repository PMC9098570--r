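#' Canonical seven resting-state network names
#'
#' Labels 1..7 of a Yeo-style atlas: visual, somatomotor, dorsal attention,
#' ventral attention, limbic, fronto-parietal, default mode. Label 0 is
#' reported as "unassigned".
#' @export
network_names <- c("VIS", "SM", "dATT", "vATT", "LIMB", "fr-par", "DMN")

#' Functional-network decomposition of one cluster's first neighbors
#'
#' Takes the edges joining the chosen cluster's root nodes to nodes outside
#' that cluster. For each requested percentile p, the threshold is the p-th
#' percentile (linear interpolation) of the kappa values over that edge
#' set; the distinct neighbor nodes retaining at least one edge with
#' kappa >= threshold are counted by the atlas label at their voxel
#' (label 0 reported as "unassigned" and included in the percentage
#' denominator).
#'
#' @param subnetwork a first-neighbor `coalteration_network`.
#' @param solution a `cluster_solution` over the root ids.
#' @param cluster_id which cluster's roots to decompose.
#' @param atlas a [label_volume()] with labels 0..7 on the analysis grid.
#' @param percentiles percentiles of the kappa distribution to threshold at
#'   (default `c(0, 30, 60, 90)`).
#' @return A data.frame with columns `percentile`, `threshold`, `network`,
#'   `count`, `pct`; within each percentile the `pct` column sums to 100
#'   (or is all zero when no edge survives, with a warning).
#' @export
decompose_cluster <- function(subnetwork, solution, cluster_id, atlas,
                              percentiles = c(0, 30, 60, 90)) {
  stopifnot(inherits(atlas, "label_volume"),
            inherits(solution, "cluster_solution"),
            all(percentiles >= 0), all(percentiles <= 100))
  if (max(atlas$values) > 7L) stop("atlas labels must be in 0..7")
  nodes <- subnetwork$nodes
  cluster_roots <- as.integer(names(solution$labels)[solution$labels == cluster_id])
  if (!length(cluster_roots)) stop("cluster ", cluster_id, " has no roots")
  e <- subnetwork$edges
  a_in <- e$node_a %in% cluster_roots
  b_in <- e$node_b %in% cluster_roots
  sel <- xor(a_in, b_in)          # root-to-first-neighbor edges of the cluster
  e <- e[sel, , drop = FALSE]
  neighbor <- ifelse(a_in[sel], e$node_b, e$node_a)
  lab_of_node <- function(ids) {
    pts <- node_points(nodes[match(ids, nodes$id), , drop = FALSE])
    atlas$values[mm_to_voxel(pts, atlas$grid)]
  }
  level_names <- c("unassigned", network_names)
  out <- list()
  for (p in percentiles) {
    if (nrow(e) == 0L) {
      warning("no root-to-neighbor edges for cluster ", cluster_id)
      thr <- NA_real_; counts <- integer(8)
    } else {
      thr <- stats::quantile(e$kappa, p / 100, type = 7, names = FALSE)
      nb <- unique(neighbor[e$kappa >= thr])
      counts <- tabulate(lab_of_node(nb) + 1L, nbins = 8L)
    }
    tot <- sum(counts)
    out[[length(out) + 1L]] <- data.frame(
      percentile = p, threshold = thr,
      network = level_names, count = counts,
      pct = if (tot > 0) 100 * counts / tot else rep(0, 8))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map set: one whole-brain real-valued volume per root node
#'
#' Stored as an n_maps x n_voxels matrix over one shared grid for fast
#' correlation work.
#'
#' @param maps named list of numeric 3D arrays (or `coalt_volume`s) sharing
#'   one shape, or an n_maps x n_voxels matrix.
#' @param grid the shared [volume_grid()].
#' @return An object of class `map_set` with elements `data` (matrix,
#'   rownames = map ids), `grid`.
#' @export
map_set <- function(maps, grid) {
  if (is.matrix(maps)) {
    data <- maps
  } else {
    data <- t(vapply(maps, function(m) {
      v <- if (inherits(m, "coalt_volume")) m$values else m
      as.vector(v)
    }, numeric(prod(grid$shape))))
    rownames(data) <- names(maps)
  }
  if (any(!is.finite(data))) stop("map values must be finite")
  structure(list(data = data, grid = grid), class = "map_set")
}

#' Within- versus between-cluster map correlations
#'
#' All-pairs Pearson correlations between the maps (over all voxels), then
#' per cluster: the mean and maximum within-cluster correlation, the mean
#' and maximum correlation to maps of every other cluster, and whether the
#' overall maximum for that cluster's maps is attained within the cluster.
#' Constant maps have their correlations set to 0 with a warning.
#'
#' @param maps a [map_set()].
#' @param solution a `cluster_solution` whose names match the map ids.
#' @return List with `pairwise` (the full correlation matrix) and `summary`
#'   (data.frame: `cluster`, `n_maps`, `within_mean`, `within_max`,
#'   `between_mean`, `between_max`, `max_is_within`).
#' @export
map_correlation_summary <- function(maps, solution) {
  stopifnot(inherits(maps, "map_set"), inherits(solution, "cluster_solution"))
  M <- maps$data
  if (nrow(M) < 2L) stop("need at least 2 maps")
  lab <- solution$labels[rownames(M)]
  if (anyNA(lab)) stop("every map id must be labelled in the solution")
  sds <- apply(M, 1, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("constant map(s) ", paste(rownames(M)[const], collapse = ", "),
            ": correlations set to 0")
  R <- suppressWarnings(stats::cor(t(M)))
  R[const, ] <- 0; R[, const] <- 0; diag(R) <- 1
  rows <- list()
  for (cl in sort(unique(lab))) {
    in_cl <- which(lab == cl); out_cl <- which(lab != cl)
    wr <- R[in_cl, in_cl, drop = FALSE][upper.tri(diag(length(in_cl)))]
    br <- as.vector(R[in_cl, out_cl, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, n_maps = length(in_cl),
      within_mean = if (length(wr)) mean(wr) else NA_real_,
      within_max = if (length(wr)) max(wr) else NA_real_,
      between_mean = if (length(br)) mean(br) else NA_real_,
      between_max = if (length(br)) max(br) else NA_real_,
      max_is_within = if (length(wr) && length(br)) max(wr) > max(br) else NA)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(pairwise = R, summary = summary)
}

#' Hierarchical clustering of whole-brain maps
#'
#' Vectorizes each map over the grid, then applies
#' [correlation_distance()] and [hierarchical_cluster()] (WPGMA by
#' default), exactly as for the co-alteration profiles.
#'
#' @param maps a [map_set()] with >= 2 maps.
#' @param linkage linkage method (default `"wpgma"`).
#' @return A `coalt_dendrogram` over the map ids.
#' @export
cluster_maps <- function(maps, linkage = "wpgma") {
  stopifnot(inherits(maps, "map_set"))
  hierarchical_cluster(correlation_distance(maps$data), linkage)
}
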