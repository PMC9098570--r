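#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix, B = -1/2 J D2 J, and uses the
#' top-k eigenvectors scaled by the square roots of their eigenvalues as
#' coordinates. Axes whose eigenvalue is not positive (the 1 - r distance
#' need not be Euclidean) are zero-filled with a warning reporting the
#' negative eigenvalue mass fraction. The configuration is centred at the
#' origin.
#'
#' @param dist symmetric, zero-diagonal, non-negative distance matrix.
#' @param k number of output dimensions (default 2).
#' @return An object of class `embedding2d`: list with `points` (n x k
#'   matrix, rownames from the distance matrix) and `eigenvalues` (all n,
#'   sorted descending).
#' @export
torgerson_pcoa <- function(dist, k = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(n >= 2L, ncol(d) == n, k >= 1)
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  pts <- matrix(0, n, k)
  got <- if (is.null(dim(fit$points))) 0L else ncol(fit$points)
  if (got > 0) pts[, seq_len(got)] <- fit$points
  if (got < k) {
    neg_mass <- sum(pmax(-eig, 0)) / max(sum(abs(eig)), .Machine$double.eps)
    warning(sprintf(paste0("only %d positive eigenvalue axes available; ",
                           "remaining coordinates set to 0 ",
                           "(negative eigenvalue mass fraction %.3g)"),
                    got, neg_mass))
  }
  rownames(pts) <- rownames(d)
  structure(list(points = pts, eigenvalues = sort(eig, decreasing = TRUE)),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat("<embedding2d> ", nrow(x$points), " points in ", ncol(x$points),
      "D; leading eigenvalues ",
      paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

raw_stress <- function(X, d) {
  delta <- as.matrix(stats::dist(X))
  sum((d[upper.tri(d)] - delta[upper.tri(delta)])^2)
}

#' Stress-majorization (SMACOF) refinement of an embedding
#'
#' Optional iterative refinement of a [torgerson_pcoa()] configuration by
#' Guttman-transform steps; raw stress is non-increasing per iteration.
#' Off the default pipeline path so results remain closed-form
#' reproducible.
#'
#' @param embedding an `embedding2d`.
#' @param dist the target distance matrix.
#' @param max_iter maximum iterations (default 100).
#' @param tol stop when the stress decrease falls below `tol` (default 1e-8).
#' @param seed optional seed, used only to jitter exactly coincident points
#'   before the first iteration.
#' @return The refined `embedding2d` with attribute `stress` (the sequence
#'   of raw stress values).
#' @export
stress_refine <- function(embedding, dist, max_iter = 100, tol = 1e-8,
                          seed = NULL) {
  d <- as.matrix(dist)
  X <- embedding$points
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  delta <- as.matrix(stats::dist(X))
  if (any(delta[upper.tri(delta)] == 0 & d[upper.tri(d)] > 0))
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-8), n)
  stress <- raw_stress(X, d)
  for (it in seq_len(max_iter)) {
    delta <- as.matrix(stats::dist(X))
    ratio <- ifelse(delta > 0, d / delta, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    sn <- raw_stress(Xn, d)
    if (sn > stress[length(stress)] + 1e-12) break   # numerical guard
    X <- Xn
    stress <- c(stress, sn)
    if (length(stress) > 1 &&
        stress[length(stress) - 1] - sn < tol) break
  }
  out <- embedding
  out$points <- X
  attr(out, "stress") <- stress
  out
}
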