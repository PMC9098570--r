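#' Volume grid: shape plus voxel-to-world affine
#'
#' A `volume_grid` couples a 3D array shape with a 4x4 affine matrix mapping
#' voxel indices to world (MNI) millimetres. The affine is stored in the
#' NIfTI convention (0-based indices); all user-facing voxel indices in this
#' package are 1-based, and the conversion happens inside [voxel_to_mm()] and
#' [mm_to_voxel()].
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param affine 4x4 numeric matrix, invertible, last row (0,0,0,1).
#' @return An object of class `volume_grid`.
#' @seealso [mni_grid()] for the standard 2 mm MNI152 grid.
#' @export
volume_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- unname(as.matrix(affine))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("affine last row must be (0, 0, 0, 1)")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel size must be strictly positive on each axis")
  structure(list(shape = shape, affine = affine, voxel_size = vs),
            class = "volume_grid")
}

#' Standard MNI152 grid
#'
#' The 91 x 109 x 91 bounding box at the given isotropic resolution, with a
#' left-right flipped first axis (radiological storage order, RAS world
#' coordinates) so that world (0,0,0) falls at 0-based voxel (45,63,36) for
#' 2 mm.
#'
#' @param res isotropic voxel size in mm (default 2).
#' @return A [volume_grid()].
#' @export
mni_grid <- function(res = 2) {
  stopifnot(res > 0)
  f <- 2 / res
  shape <- c(ceiling(91 * f), ceiling(109 * f), ceiling(91 * f))
  affine <- rbind(c(-res, 0, 0, 90),
                  c(0, res, 0, -126),
                  c(0, 0, res, -72),
                  c(0, 0, 0, 1))
  volume_grid(shape, affine)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' Convert world millimetres to voxel indices
#'
#' Applies the inverse affine and rounds: a voxel "contains" the mm points
#' that round to its index. Indices are 1-based.
#'
#' @param points numeric vector of length 3 or an n x 3 matrix of mm points.
#' @param grid a [volume_grid()].
#' @param strict error (default) if any rounded index falls outside the grid.
#' @return An n x 3 integer matrix of 1-based voxel indices.
#' @export
mm_to_voxel <- function(points, grid, strict = TRUE) {
  pts <- to_points_matrix(points)
  inv <- solve(grid$affine)
  v0 <- cbind(pts, 1) %*% t(inv)              # 0-based continuous indices
  idx <- round(v0[, 1:3, drop = FALSE]) + 1
  storage.mode(idx) <- "integer"
  if (strict) {
    bad <- which(idx[, 1] < 1L | idx[, 1] > grid$shape[1] |
                 idx[, 2] < 1L | idx[, 2] > grid$shape[2] |
                 idx[, 3] < 1L | idx[, 3] > grid$shape[3])
    if (length(bad))
      stop("point(s) outside grid bounds: row ", paste(bad, collapse = ", "))
  }
  dimnames(idx) <- NULL
  idx
}

#' Convert voxel indices to world millimetres
#'
#' @param idx length-3 vector or n x 3 matrix of 1-based voxel indices.
#' @inheritParams mm_to_voxel
#' @return An n x 3 numeric matrix of voxel-centre mm coordinates.
#' @export
voxel_to_mm <- function(idx, grid) {
  idx <- to_points_matrix(idx)
  mm <- cbind(idx - 1, 1) %*% t(grid$affine)
  mm <- mm[, 1:3, drop = FALSE]
  dimnames(mm) <- NULL
  mm
}

to_points_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    p <- matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 3L)
    storage.mode(p) <- "double"
  }
  if (any(!is.finite(p))) stop("coordinates must be finite")
  p
}

new_volume <- function(values, grid, class) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(dim(values))) dim(values) <- grid$shape
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values shape ", paste(dim(values), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  structure(list(values = values, grid = grid),
            class = c(class, "coalt_volume"))
}

#' Per-voxel probability volume (MA or ALE map)
#'
#' @param values numeric 3D array with all values in \[0, 1\].
#' @param grid a [volume_grid()].
#' @export
probability_volume <- function(values, grid) {
  if (any(!is.finite(values))) stop("probability values must be finite")
  if (min(values) < 0 || max(values) > 1)
    stop("probability values must lie in [0, 1]")
  new_volume(values, grid, "probability_volume")
}

#' Binary region-of-interest mask
#'
#' Numeric input is binarized at > 0.
#'
#' @param values logical or numeric 3D array; at least one TRUE voxel.
#' @param grid a [volume_grid()].
#' @export
binary_mask <- function(values, grid) {
  if (!is.logical(values)) {
    d <- dim(values)
    values <- values > 0
    dim(values) <- d
  }
  if (!any(values)) stop("mask must contain at least one TRUE voxel")
  new_volume(values, grid, "binary_mask")
}

#' Integer-label volume (network atlas or parcel map)
#'
#' @param values integer 3D array; 0 means unassigned/outside.
#' @param grid a [volume_grid()].
#' @export
label_volume <- function(values, grid) {
  if (any(!is.finite(values))) stop("labels must be finite")
  if (any(values < 0)) stop("labels must be non-negative integers")
  d <- dim(values)
  values <- as.integer(round(values))
  dim(values) <- d
  new_volume(values, grid, "label_volume")
}

#' @export
print.coalt_volume <- function(x, ...) {
  cat("<", class(x)[1], "> ", paste(x$grid$shape, collapse = " x "),
      ", range [", paste(signif(range(x$values), 4), collapse = ", "), "]\n",
      sep = "")
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3D volume.
#' @param as one of `"probability"`, `"mask"`, `"label"`: the domain type to
#'   coerce to. Masks binarize at > 0.
#' @return A [probability_volume()], [binary_mask()] or [label_volume()].
#' @export
read_volume <- function(path, as = c("probability", "mask", "label")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
  } else if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  grid <- volume_grid(dim(img)[1:3], aff)
  vals <- array(as.vector(img), dim = grid$shape)
  switch(as,
         probability = probability_volume(vals, grid),
         mask = binary_mask(vals, grid),
         label = label_volume(vals, grid))
}

#' Write a volume as NIfTI
#'
#' The grid affine is stored in the sform (code 2) and round-trips
#' bit-exactly; probabilities are stored as doubles, masks and labels as
#' integers.
#'
#' @param vol a `coalt_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "coalt_volume"))
  vals <- vol$values
  datatype <- "double"
  if (is.logical(vals) || inherits(vol, "label_volume")) {
    vals <- array(as.integer(vals), dim = dim(vals))
    datatype <- "int32"
  }
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
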