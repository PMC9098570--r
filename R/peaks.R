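#' Detect local maxima of an ALE map as network nodes
#'
#' A voxel is a candidate peak when its value is >= all of its 26-connected
#' neighbours, >= `min_value`, and (if given) inside `brain_mask`. Flat
#' plateaus of equal-valued, 26-connected candidates are collapsed to their
#' lexicographically smallest voxel. Candidates closer than
#' `min_distance_mm` (Euclidean, mm) are merged keeping the higher-valued
#' one; exact value ties keep the lexicographically smaller voxel index.
#' Nodes are returned sorted by descending ALE value with ids assigned in
#' that order, so the procedure is fully deterministic.
#'
#' @param ale a [probability_volume()] (typically from [ale_map()]).
#' @param min_value minimum ALE value of a reported peak, in \[0, 1).
#' @param min_distance_mm minimum separation between reported peaks (>= 0).
#' @param brain_mask optional [binary_mask()] restricting candidates.
#' @return A data.frame with columns `id`, `x`, `y`, `z` (voxel-centre mm),
#'   `ale_value`, and logical `is_root` (initialized `NA`, set by
#'   [identify_roots()]).
#' @export
detect_peaks <- function(ale, min_value = 1e-3, min_distance_mm = 10,
                         brain_mask = NULL) {
  stopifnot(inherits(ale, "probability_volume"),
            min_value >= 0, min_value < 1, min_distance_mm >= 0)
  v <- ale$values
  if (any(!is.finite(v))) stop("ALE map contains non-finite values")
  shp <- dim(v)
  cand <- v >= min_value
  if (!is.null(brain_mask)) {
    stopifnot(inherits(brain_mask, "binary_mask"))
    if (!grids_equal(brain_mask$grid, ale$grid))
      stop("brain_mask grid does not match the ALE grid")
    cand <- cand & brain_mask$values
  }
  # compare against each of the 26 shifted copies; out-of-volume neighbours
  # count as -Inf so boundary voxels can be maxima
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  for (s in seq_len(nrow(shifts))) {
    if (!any(cand)) break
    sh <- shifts[s, ]
    nb <- array(-Inf, dim = shp)
    src <- lapply(1:3, function(a) {
      i <- seq_len(shp[a]) + sh[a]
      i[i >= 1 & i <= shp[a]]
    })
    dst <- lapply(1:3, function(a) {
      i <- seq_len(shp[a])
      i[i + sh[a] >= 1 & i + sh[a] <= shp[a]]
    })
    nb[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    cand <- cand & (v >= nb)
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(empty_node_table())
  vals <- v[idx]
  # lexicographic voxel order (x, then y, then z)
  lex <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[lex, , drop = FALSE]; vals <- vals[lex]
  idx <- collapse_plateaus(idx, vals, shp, shifts)
  vals <- v[idx]
  mm <- voxel_to_mm(idx, ale$grid)
  # greedy merge: visit by descending value (ties: lexicographic order,
  # already the within-value order), keep if far enough from all kept
  ord <- order(-vals)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep)) {
      d2 <- rowSums(sweep(mm[keep, , drop = FALSE], 2, mm[i, ])^2)
      if (min(d2) < min_distance_mm^2) next
    }
    keep <- c(keep, i)
  }
  data.frame(id = seq_along(keep),
             x = mm[keep, 1], y = mm[keep, 2], z = mm[keep, 3],
             ale_value = vals[keep], is_root = NA)
}

empty_node_table <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
             ale_value = numeric(0), is_root = logical(0))
}

# collapse 26-connected components of equal-valued candidate voxels to the
# lexicographically smallest member; idx must already be in lexicographic
# order so each component's representative is its first member
collapse_plateaus <- function(idx, vals, shp, shifts) {
  n <- nrow(idx)
  if (n <= 1L) return(idx)
  key <- (idx[, 1] - 1) + shp[1] * ((idx[, 2] - 1) + shp[2] * (idx[, 3] - 1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    nb <- idx + matrix(sh, n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 & nb[, 2] <= shp[2] &
          nb[, 3] >= 1 & nb[, 3] <= shp[3]
    nbkey <- (nb[, 1] - 1) + shp[1] * ((nb[, 2] - 1) + shp[2] * (nb[, 3] - 1))
    m <- match(nbkey, key)
    hit <- which(ok & !is.na(m))
    for (i in hit) {
      j <- m[i]
      if (vals[i] == vals[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  reps <- vapply(seq_len(n), find, integer(1))
  idx[sort(unique(reps)), , drop = FALSE]
}

#' Node table of the points stored in a co-alteration network
#'
#' @param nodes a node data.frame as returned by [detect_peaks()].
#' @return n x 3 matrix of node mm coordinates, rownames = node ids.
#' @export
node_points <- function(nodes) {
  m <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(m) <- nodes$id
  m
}
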