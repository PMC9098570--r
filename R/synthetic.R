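#' Ground truth with planted co-alteration structure
#'
#' Lays out `n_parcels` groups of alteration-prone region centres inside a
#' box-shaped ROI (one spatial slab per parcel) plus `partners_per_parcel`
#' extra-ROI "partner" centres per parcel. Each parcel's ROI regions
#' together with its partners form one coupling group that co-alters across
#' experiments; a label atlas assigns each partner region a resting-state
#' network label (spheres of 10 mm radius, labels cycling 1..7). In
#' well-separated mode all centres are at least twice the kernel truncation
#' radius apart, so their modeled-alteration supports never overlap.
#'
#' @param n_parcels number of planted parcels (>= 1).
#' @param regions_per_parcel ROI region centres per parcel.
#' @param partners_per_parcel extra-ROI partner centres per parcel.
#' @param seed integer seed for the geometry.
#' @param grid analysis [volume_grid()] (default [mni_grid()]).
#' @param spec [kernel_spec()] used to derive the separation radius.
#' @param p_group_active per-experiment probability that a coupling group
#'   is active (default 0.35).
#' @param p_background independent per-region activation probability
#'   (default 0.05).
#' @param jitter_sigma_mm isotropic Gaussian jitter of emitted foci around
#'   their region centre (default 3 mm).
#' @param n_subject_range integer interval experiment sample sizes are
#'   drawn from (default 10..30).
#' @param well_separated enforce the minimum-separation contract
#'   (default TRUE).
#' @return An object of class `coalt_ground_truth`: list with `regions`
#'   (data.frame `id`, `x`, `y`, `z`, `is_roi`, `parcel`, `network_label`),
#'   `groups`, `roi` ([binary_mask()]), `atlas` ([label_volume()]), `grid`,
#'   `spec`, `min_separation_mm` and the sampling parameters.
#' @export
make_ground_truth <- function(n_parcels = 3, regions_per_parcel = 4,
                              partners_per_parcel = 2, seed = 1,
                              grid = mni_grid(), spec = kernel_spec(),
                              p_group_active = 0.35, p_background = 0.05,
                              jitter_sigma_mm = 3,
                              n_subject_range = c(10L, 30L),
                              well_separated = TRUE) {
  stopifnot(n_parcels >= 1, regions_per_parcel >= 1, partners_per_parcel >= 0,
            p_group_active >= 0, p_group_active <= 1,
            p_background >= 0, p_background <= 1, jitter_sigma_mm >= 0,
            length(n_subject_range) == 2L,
            n_subject_range[1] >= 1, n_subject_range[2] >= n_subject_range[1])
  set.seed(seed)
  min_sep <- if (well_separated)
    2 * spec$truncation_sigmas * kernel_sigma(min(n_subject_range), spec)
  else 0
  roi_box <- rbind(c(-16, 16), c(-60, 48), c(0, 48))      # cingulate-like slab
  brain_box <- rbind(c(-66, 66), c(-96, 66), c(-38, 66))
  roi <- box_mask(roi_box, grid)

  # parcel slabs along y
  y_edges <- seq(roi_box[2, 1], roi_box[2, 2], length.out = n_parcels + 1)
  outside_roi <- function(p)
    any(p < roi_box[, 1] - 14 | p > roi_box[, 2] + 14)
  attempt_layout <- function() {
    centres <- matrix(numeric(0), 0, 3)
    place <- function(lo, hi, n, reject_fun) {
      placed <- 0L
      while (placed < n) {
        ok <- FALSE
        for (att in seq_len(2000)) {
          p <- stats::runif(3, lo, hi)
          if (!reject_fun(p)) next
          if (nrow(centres) == 0L ||
              min(sqrt(rowSums(sweep(centres, 2, p)^2))) >= min_sep) {
            centres <<- rbind(centres, p); placed <- placed + 1L; ok <- TRUE
            break
          }
        }
        if (!ok) return(FALSE)
      }
      TRUE
    }
    for (g in seq_len(n_parcels)) {
      lo <- c(roi_box[1, 1] + 4, y_edges[g] + 3, roi_box[3, 1] + 4)
      hi <- c(roi_box[1, 2] - 4, y_edges[g + 1] - 3, roi_box[3, 2] - 4)
      if (any(lo >= hi)) stop("infeasible geometry: empty parcel slab")
      if (!place(lo, hi, regions_per_parcel, function(p) TRUE)) return(NULL)
    }
    for (g in seq_len(n_parcels)) {
      if (!place(brain_box[, 1], brain_box[, 2], partners_per_parcel,
                 outside_roi)) return(NULL)
    }
    centres
  }
  centres <- NULL
  for (try in seq_len(25)) {
    centres <- attempt_layout()
    if (!is.null(centres)) break
  }
  if (is.null(centres))
    stop("infeasible geometry: cannot place region centres with separation ",
         signif(min_sep, 4), " mm")
  parcel_of <- c(rep(seq_len(n_parcels), each = regions_per_parcel),
                 rep(seq_len(n_parcels), each = partners_per_parcel))
  is_roi <- c(rep(TRUE, n_parcels * regions_per_parcel),
              rep(FALSE, n_parcels * partners_per_parcel))
  K <- nrow(centres)
  n_partner <- sum(!is_roi)
  network_label <- integer(K)
  network_label[!is_roi] <- (seq_len(n_partner) - 1L) %% 7L + 1L
  regions <- data.frame(id = seq_len(K), x = centres[, 1], y = centres[, 2],
                        z = centres[, 3], is_roi = is_roi,
                        parcel = parcel_of, network_label = network_label)
  groups <- lapply(seq_len(n_parcels), function(g) regions$id[parcel_of == g])
  atlas <- sphere_atlas(regions[!is_roi, , drop = FALSE], radius_mm = 10,
                        grid = grid)
  structure(list(regions = regions, groups = groups, roi = roi, atlas = atlas,
                 grid = grid, spec = spec, min_separation_mm = min_sep,
                 p_group_active = p_group_active, p_background = p_background,
                 jitter_sigma_mm = jitter_sigma_mm,
                 n_subject_range = as.integer(n_subject_range)),
            class = "coalt_ground_truth")
}

box_mask <- function(box, grid) {
  idx0 <- as.matrix(expand.grid(x = seq_len(grid$shape[1]),
                                y = seq_len(grid$shape[2]),
                                z = seq_len(grid$shape[3])))
  mm <- voxel_to_mm(idx0, grid)
  inside <- mm[, 1] >= box[1, 1] & mm[, 1] <= box[1, 2] &
            mm[, 2] >= box[2, 1] & mm[, 2] <= box[2, 2] &
            mm[, 3] >= box[3, 1] & mm[, 3] <= box[3, 2]
  binary_mask(array(inside, dim = grid$shape), grid)
}

sphere_atlas <- function(partners, radius_mm, grid) {
  vals <- array(0L, dim = grid$shape)
  r_vox <- ceiling(radius_mm / grid$voxel_size)
  for (i in seq_len(nrow(partners))) {
    ci <- mm_to_voxel(c(partners$x[i], partners$y[i], partners$z[i]),
                      grid, strict = FALSE)[1, ]
    lo <- pmax(ci - r_vox, 1L); hi <- pmin(ci + r_vox, grid$shape)
    if (any(lo > hi)) next
    sub <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                 z = lo[3]:hi[3]))
    mm <- voxel_to_mm(sub, grid)
    d <- sqrt(rowSums(sweep(mm, 2, c(partners$x[i], partners$y[i],
                                     partners$z[i]))^2))
    sel <- sub[d <= radius_mm, , drop = FALSE]
    vals[sel] <- partners$network_label[i]
  }
  label_volume(vals, grid)
}

#' Sample synthetic experiments from a planted ground truth
#'
#' Per experiment: each coupling group is active with `p_group_active` and
#' each region independently with `p_background`; every active region emits
#' one focus at its centre plus isotropic Gaussian jitter; the sample size
#' is drawn uniformly from `n_subject_range`. Experiments with no focus
#' inside the ROI mask are rejected and resampled, mirroring an
#' ROI-conditioned database query.
#'
#' @param gt a [make_ground_truth()] object.
#' @param n_experiments number of experiments (>= 2).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per experiment.
#' @return An [experiment_set()]; each experiment's `meta$active_regions`
#'   records the planted truth.
#' @export
sample_experiments <- function(gt, n_experiments = 150, seed = 1,
                               max_attempts = 10000) {
  stopifnot(inherits(gt, "coalt_ground_truth"), n_experiments >= 2)
  set.seed(seed)
  reg <- gt$regions
  centres <- as.matrix(reg[, c("x", "y", "z")])
  G <- length(gt$groups)
  exps <- vector("list", n_experiments)
  for (e in seq_len(n_experiments)) {
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      g_on <- stats::runif(G) < gt$p_group_active
      active <- reg$parcel %in% which(g_on) | stats::runif(nrow(reg)) < gt$p_background
      if (!any(active)) next
      foci <- centres[active, , drop = FALSE] +
        matrix(stats::rnorm(3 * sum(active), sd = gt$jitter_sigma_mm),
               ncol = 3)
      idx <- mm_to_voxel(foci, gt$grid, strict = FALSE)
      inb <- idx[, 1] >= 1L & idx[, 1] <= gt$grid$shape[1] &
             idx[, 2] >= 1L & idx[, 2] <= gt$grid$shape[2] &
             idx[, 3] >= 1L & idx[, 3] <= gt$grid$shape[3]
      in_roi <- logical(nrow(idx))
      in_roi[inb] <- gt$roi$values[idx[inb, , drop = FALSE]]
      if (!any(in_roi)) next
      n_subj <- sample(gt$n_subject_range[1]:gt$n_subject_range[2], 1L)
      exps[[e]] <- foci_experiment(sprintf("synthetic_%04d", e), n_subj, foci,
                                   meta = list(active_regions = reg$id[active]))
      done <- TRUE
      break
    }
    if (!done)
      stop("rejection sampling failed after ", max_attempts,
           " attempts: no experiment with an ROI focus (degenerate ",
           "activation probabilities?)")
  }
  experiment_set(exps)
}

#' Synthetic per-root whole-brain map fixtures
#'
#' Stands in for seed-voxel correlation maps: each planted parcel gets a
#' smooth random template (a sum of random Gaussian blobs, standardized and
#' optionally orthogonalized across parcels), and each ROI region's map is
#' its parcel template plus iid voxel noise. With `noise_sigma = 0`
#' within-parcel maps are identical; orthogonalized templates make
#' between-parcel correlations exactly zero in the noiseless case.
#'
#' @param gt a [make_ground_truth()] object.
#' @param noise_sigma sd of the additive iid voxel noise (templates have
#'   unit sd).
#' @param seed integer seed.
#' @param grid grid for the maps (default a coarse 8 mm [mni_grid()]; maps
#'   need not share the analysis grid).
#' @param n_blobs random Gaussian blobs per template (default 25).
#' @param orthogonalize make the centred templates exactly orthogonal
#'   (default TRUE).
#' @return A [map_set()] with one map per ROI region, ids = region ids.
#' @export
make_map_fixtures <- function(gt, noise_sigma = 0.1, seed = 1,
                              grid = mni_grid(8), n_blobs = 25,
                              orthogonalize = TRUE) {
  stopifnot(inherits(gt, "coalt_ground_truth"), noise_sigma >= 0)
  set.seed(seed)
  nv <- prod(grid$shape)
  idx <- as.matrix(expand.grid(x = seq_len(grid$shape[1]),
                               y = seq_len(grid$shape[2]),
                               z = seq_len(grid$shape[3])))
  mm <- voxel_to_mm(idx, grid)
  P <- length(gt$groups)
  templates <- matrix(0, nv, P)
  for (p in seq_len(P)) {
    tpl <- numeric(nv)
    for (b in seq_len(n_blobs)) {
      c_mm <- stats::runif(3, apply(mm, 2, min), apply(mm, 2, max))
      amp <- stats::rnorm(1)
      s <- stats::runif(1, 15, 40)
      tpl <- tpl + amp * exp(-rowSums(sweep(mm, 2, c_mm)^2) / (2 * s^2))
    }
    templates[, p] <- tpl
  }
  templates <- scale(templates)            # centre, unit sd
  if (orthogonalize && P > 1) {
    q <- qr.Q(qr(templates))
    templates <- scale(q)                  # orthogonal, recentred, unit sd
  }
  roi_regions <- gt$regions[gt$regions$is_roi, , drop = FALSE]
  data <- t(vapply(seq_len(nrow(roi_regions)), function(i) {
    templates[, roi_regions$parcel[i]] +
      stats::rnorm(nv, sd = noise_sigma)
  }, numeric(nv)))
  rownames(data) <- as.character(roi_regions$id)
  map_set(data, grid)
}

#' Write the planted ground truth as JSON
#'
#' @param gt a [make_ground_truth()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(list(regions = gt$regions,
                            groups = gt$groups,
                            min_separation_mm = gt$min_separation_mm,
                            p_group_active = gt$p_group_active,
                            p_background = gt$p_background,
                            jitter_sigma_mm = gt$jitter_sigma_mm,
                            n_subject_range = gt$n_subject_range),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
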