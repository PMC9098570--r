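#' Gaussian kernel specification for modeled-alteration maps
#'
#' The spatial uncertainty of a reported peak is modeled as an isotropic 3D
#' Gaussian whose full-width half-maximum combines a between-template
#' component with a between-subject component shrinking with the sample
#' size: FWHM(n) = sqrt(fwhm_template^2 + fwhm_subject^2 / n). The kernel is
#' truncated at `truncation_sigmas` standard deviations and renormalized to
#' unit mass over its discrete support, so modeled-alteration values are
#' probabilities.
#'
#' @param fwhm_template_mm non-negative mm; template (inter-lab) uncertainty.
#' @param fwhm_subject_mm non-negative mm; per-subject uncertainty, divided
#'   by sqrt(n).
#' @param truncation_sigmas support radius in units of sigma (>= 2).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(fwhm_template_mm = 5.7, fwhm_subject_mm = 11.6,
                        truncation_sigmas = 3.5) {
  stopifnot(fwhm_template_mm >= 0, fwhm_subject_mm >= 0)
  if (fwhm_template_mm <= 0 && fwhm_subject_mm <= 0)
    stop("at least one FWHM component must be positive")
  if (truncation_sigmas < 2) stop("truncation_sigmas must be >= 2")
  structure(list(fwhm_template_mm = fwhm_template_mm,
                 fwhm_subject_mm = fwhm_subject_mm,
                 truncation_sigmas = truncation_sigmas),
            class = "kernel_spec")
}

#' Standard deviation from full-width half-maximum
#'
#' sigma = FWHM / sqrt(8 ln 2).
#'
#' @param fwhm positive mm.
#' @return sigma in mm.
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  fwhm / sqrt(8 * log(2))
}

#' Sample-size-dependent kernel width
#'
#' FWHM(n) = sqrt(fwhm_template^2 + fwhm_subject^2 / n): strictly decreasing
#' in n and approaching the template component as n grows.
#'
#' @param n positive integer subject count (vectorized).
#' @param spec a [kernel_spec()].
#' @return FWHM in mm.
#' @export
fwhm_from_sample_size <- function(n, spec = kernel_spec()) {
  if (any(n < 1)) stop("n must be >= 1")
  sqrt(spec$fwhm_template_mm^2 + spec$fwhm_subject_mm^2 / n)
}

kernel_sigma <- function(n, spec) sigma_from_fwhm(fwhm_from_sample_size(n, spec))

#' Discrete truncated Gaussian kernel on a voxel grid
#'
#' Weights proportional to exp(-d^2 / (2 sigma^2)) over all voxel offsets
#' with mm distance d <= truncation_sigmas * sigma, normalized to sum
#' exactly 1 over the support. A sigma so small that the support is a single
#' voxel yields the degenerate kernel {centre: 1}.
#'
#' @param sigma positive mm.
#' @param grid a [volume_grid()] supplying voxel sizes.
#' @param spec a [kernel_spec()] supplying the truncation radius.
#' @return A 3D array of odd side lengths summing to 1, with attribute
#'   `radius_vox` (support half-width per axis, voxels).
#' @export
gaussian_kernel <- function(sigma, grid, spec = kernel_spec()) {
  stopifnot(sigma > 0)
  vs <- grid$voxel_size
  r_mm <- spec$truncation_sigmas * sigma
  r_vox <- pmax(0L, as.integer(floor(r_mm / vs)))
  off <- lapply(1:3, function(a) (-r_vox[a]):(r_vox[a]) * vs[a])
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, `+`), off[[3]]^2, `+`)
  w <- exp(-d2 / (2 * sigma^2))
  w[sqrt(d2) > r_mm] <- 0
  w <- w / sum(w)
  attr(w, "radius_vox") <- r_vox
  w
}

place_kernel_max <- function(values, kern, centre_idx) {
  r <- attr(kern, "radius_vox")
  shp <- dim(values)
  lo <- pmax(centre_idx - r, 1L)
  hi <- pmin(centre_idx + r, shp)
  if (any(lo > hi)) return(values)
  klo <- lo - (centre_idx - r) + 1L
  khi <- klo + (hi - lo)
  sub <- kern[klo[1]:khi[1], klo[2]:khi[2], klo[3]:khi[3], drop = FALSE]
  tgt <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmax(tgt, sub)
  values
}

#' Modeled-alteration (MA) map of one experiment
#'
#' Each focus is snapped to its containing voxel and spread with the
#' sample-size-dependent truncated Gaussian kernel; voxels covered by
#' several foci of the same experiment take the maximum kernel value, so
#' nearby within-experiment peaks do not inflate the map.
#'
#' @param exp a [foci_experiment()].
#' @param grid a [volume_grid()].
#' @param spec a [kernel_spec()].
#' @return A [probability_volume()].
#' @export
ma_map <- function(exp, grid, spec = kernel_spec()) {
  stopifnot(inherits(exp, "foci_experiment"))
  idx <- mm_to_voxel(exp$foci, grid, strict = FALSE)
  inb <- idx[, 1] >= 1L & idx[, 1] <= grid$shape[1] &
         idx[, 2] >= 1L & idx[, 2] <= grid$shape[2] &
         idx[, 3] >= 1L & idx[, 3] <= grid$shape[3]
  if (!any(inb))
    stop("experiment ", exp$id, ": all foci fall outside the grid")
  kern <- gaussian_kernel(kernel_sigma(exp$n_subjects, spec), grid, spec)
  vals <- array(0, dim = grid$shape)
  for (i in seq_len(nrow(idx))) vals <- place_kernel_max(vals, kern, idx[i, ])
  probability_volume(vals, grid)
}

#' MA maps for every experiment in a set
#'
#' @param set an [experiment_set()].
#' @inheritParams ma_map
#' @return An object of class `ma_map_set`: named list of
#'   [probability_volume()]s sharing one grid.
#' @export
ma_map_set <- function(set, grid, spec = kernel_spec()) {
  stopifnot(inherits(set, "experiment_set"))
  maps <- lapply(set$experiments, ma_map, grid = grid, spec = spec)
  structure(list(maps = maps, grid = grid, spec = spec), class = "ma_map_set")
}

#' Probabilistic union of MA maps (the ALE map)
#'
#' ALE(v) = 1 - prod_e (1 - MA_e(v)): the per-voxel probability that at
#' least one experiment models an alteration there. Order-invariant.
#'
#' @param maps an `ma_map_set`, or a list of [probability_volume()]s on one
#'   shared grid.
#' @return A [probability_volume()].
#' @export
ale_union <- function(maps) {
  if (inherits(maps, "ma_map_set")) maps <- maps$maps
  stopifnot(is.list(maps), length(maps) >= 1L)
  grid <- maps[[1]]$grid
  acc <- array(1, dim = grid$shape)
  for (m in maps) {
    stopifnot(inherits(m, "probability_volume"))
    if (!grids_equal(m$grid, grid)) stop("MA maps must share one grid")
    acc <- acc * (1 - m$values)
  }
  probability_volume(1 - acc, grid)
}

#' ALE map straight from an experiment set
#'
#' Streams the union accumulator so the per-experiment MA maps are never
#' all held in memory at once.
#'
#' @inheritParams ma_map_set
#' @return A [probability_volume()].
#' @export
ale_map <- function(set, grid, spec = kernel_spec()) {
  stopifnot(inherits(set, "experiment_set"))
  acc <- array(1, dim = grid$shape)
  for (e in set$experiments)
    acc <- acc * (1 - ma_map(e, grid, spec)$values)
  probability_volume(1 - acc, grid)
}

#' MA values of one experiment at a set of points
#'
#' Exact per-point evaluation of [ma_map()] without building the full
#' volume: the maximum over foci of the discrete kernel weight at the voxel
#' offset between the point's voxel and the focus's voxel.
#'
#' @param points n x 3 matrix of MNI mm points.
#' @inheritParams ma_map
#' @return Numeric vector of MA values.
#' @export
ma_values_at <- function(points, exp, grid, spec = kernel_spec()) {
  pts <- mm_to_voxel(points, grid)
  foc <- mm_to_voxel(exp$foci, grid, strict = FALSE)
  kern <- gaussian_kernel(kernel_sigma(exp$n_subjects, spec), grid, spec)
  r <- attr(kern, "radius_vox")
  out <- numeric(nrow(pts))
  for (j in seq_len(nrow(foc))) {
    off <- sweep(pts, 2, foc[j, ])
    ok <- abs(off[, 1]) <= r[1] & abs(off[, 2]) <= r[2] & abs(off[, 3]) <= r[3]
    if (!any(ok)) next
    ki <- sweep(off[ok, , drop = FALSE], 2, r + 1L, `+`)
    out[ok] <- pmax(out[ok], kern[ki])
  }
  out
}
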