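#' Configuration for the full co-alteration parcellation pipeline
#'
#' @param foci path to a foci text file or an [experiment_set()].
#' @param roi path to a NIfTI ROI mask or a [binary_mask()]; its grid is the
#'   analysis grid.
#' @param out_dir output directory (created if missing).
#' @param atlas optional path to a label NIfTI or a [label_volume()] for
#'   the functional-network decomposition.
#' @param maps optional [map_set()] of per-root whole-brain maps.
#' @param kernel a [kernel_spec()].
#' @param peak_min_value,peak_min_distance_mm passed to [detect_peaks()].
#' @param kappa_threshold,alpha passed to [build_network()].
#' @param linkage linkage method for [hierarchical_cluster()].
#' @param cardinalities cluster counts to cut, parcellate and write.
#' @param percentiles kappa percentiles for [decompose_cluster()].
#' @param local_threshold kappa threshold for the [local_subnetwork()].
#' @param decompose_cardinality,decompose_cluster which cut / cluster id the
#'   decomposition and map comparison use.
#' @param seed master seed; every stochastic stage derives its sub-seed
#'   from it (logged in the run manifest).
#' @param write_ma_maps also write every per-experiment MA volume
#'   (default FALSE; the ALE map is always written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(foci, roi, out_dir, atlas = NULL, maps = NULL,
                            kernel = kernel_spec(), peak_min_value = 1e-3,
                            peak_min_distance_mm = 10, kappa_threshold = 0,
                            alpha = 0, linkage = "wpgma",
                            cardinalities = c(2, 3, 4),
                            percentiles = c(0, 30, 60, 90),
                            local_threshold = 0.5,
                            decompose_cardinality = 2, decompose_cluster = 1,
                            seed = 1, write_ma_maps = FALSE) {
  stopifnot(all(cardinalities >= 1), all(percentiles >= 0),
            all(percentiles <= 100))
  for (p in list(foci, roi, atlas))
    if (is.character(p) && !file.exists(p))
      stop("input path does not exist: ", p)
  structure(list(foci = foci, roi = roi, out_dir = out_dir, atlas = atlas,
                 maps = maps, kernel = kernel,
                 peak_min_value = peak_min_value,
                 peak_min_distance_mm = peak_min_distance_mm,
                 kappa_threshold = kappa_threshold, alpha = alpha,
                 linkage = linkage,
                 cardinalities = as.integer(sort(unique(cardinalities))),
                 percentiles = percentiles,
                 local_threshold = local_threshold,
                 decompose_cardinality = as.integer(decompose_cardinality),
                 decompose_cluster = as.integer(decompose_cluster),
                 seed = as.integer(seed), write_ma_maps = write_ma_maps),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# tiny polynomial fingerprint of a string (run-manifest bookkeeping only)
config_fingerprint <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(s)))
    h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full co-alteration parcellation pipeline
#'
#' Executes, in order: ALE map (and optionally per-experiment MA maps),
#' peak detection, alteration states, co-alteration network, root
#' identification, first-neighbor subnetwork, profile matrix, hierarchical
#' clustering with and without root-root edges, cluster cuts and voxel-wise
#' parcel maps per cardinality, MDS embedding, and — when an atlas or map
#' set is configured — the functional-network decomposition and the
#' within/between map-correlation comparison. All tabular outputs are CSV,
#' volumes NIfTI, dendrograms Newick; a JSON manifest records the seed,
#' parameters and a config fingerprint. Identical config and seed give
#' byte-identical tabular outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list of the in-memory artifacts (`ale`, `nodes`,
#'   `network`, `subnetwork`, `profile`, `dendrogram`,
#'   `dendrogram_no_root`, `solutions`, `parcels`, `embedding`,
#'   `decomposition`, `map_summary`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)

  set <- run_stage("read_foci", {
    if (is.character(config$foci)) read_foci_text(config$foci) else config$foci
  })
  roi <- run_stage("read_roi", {
    if (is.character(config$roi)) read_volume(config$roi, as = "mask")
    else config$roi
  })
  grid <- roi$grid
  atlas <- run_stage("read_atlas", {
    if (is.character(config$atlas)) read_volume(config$atlas, as = "label")
    else config$atlas
  })

  ale <- run_stage("ale", {
    if (config$write_ma_maps) {
      dir.create(out("ma"), showWarnings = FALSE)
      acc <- array(1, dim = grid$shape)
      for (e in set$experiments) {
        m <- ma_map(e, grid, config$kernel)
        files <- c(files, write_volume(m, out("ma", paste0(e$id, ".nii.gz"))))
        acc <- acc * (1 - m$values)
      }
      probability_volume(1 - acc, grid)
    } else ale_map(set, grid, config$kernel)
  })
  files <- c(files, write_volume(ale, out("ale.nii.gz")))

  nodes <- run_stage("peaks", detect_peaks(ale, config$peak_min_value,
                                           config$peak_min_distance_mm))
  if (nrow(nodes) == 0L) stop("pipeline stage 'peaks' failed: no peaks found")

  states <- run_stage("states",
                      alteration_states(nodes, set, grid, config$kernel))
  net <- run_stage("network", {
    n <- build_network(states, nodes, config$kappa_threshold, config$alpha)
    identify_roots(n, roi)
  })
  files <- c(files, write_table(net$nodes, out("nodes.csv")),
             write_table(net$edges, out("edges.csv")))

  sub <- run_stage("subnetwork", first_neighbor_subnetwork(net))
  files <- c(files, write_table(sub$edges, out("subnetwork_edges.csv")))

  pm <- run_stage("profile", profile_matrix(sub))
  files <- c(files, write_table(
    data.frame(root = rownames(pm), pm, check.names = FALSE),
    out("profile_matrix.csv")))

  dend <- run_stage("cluster",
                    hierarchical_cluster(correlation_distance(pm),
                                         config$linkage))
  pm_nr <- drop_root_edges(pm)
  dend_nr <- run_stage("cluster_no_root",
                       hierarchical_cluster(correlation_distance(pm_nr),
                                            config$linkage))
  files <- c(files, {
    dendrogram_newick(dend, out("dendrogram.nwk"))
    dendrogram_newick(dend_nr, out("dendrogram_no_root.nwk"))
    merge_df <- function(d) data.frame(step = seq_along(d$height),
                                       left = d$merge[, 1],
                                       right = d$merge[, 2],
                                       height = d$height)
    write_table(merge_df(dend), out("dendrogram_merges.csv"))
    write_table(merge_df(dend_nr), out("dendrogram_no_root_merges.csv"))
    out(c("dendrogram.nwk", "dendrogram_no_root.nwk",
          "dendrogram_merges.csv", "dendrogram_no_root_merges.csv"))
  })

  roots <- sub$nodes[sub$nodes$is_root, , drop = FALSE]
  cards <- config$cardinalities[config$cardinalities <= nrow(roots)]
  if (length(cards) < length(config$cardinalities))
    warning("dropping cardinalities above the root count (",
            nrow(roots), ")")
  solutions <- list(); parcels <- list()
  lab_tab <- data.frame(root = rownames(pm))
  for (k in cards) {
    sol <- run_stage(paste0("cut_c", k), cut_clusters(dend, k))
    solutions[[as.character(k)]] <- sol
    lab_tab[[paste0("c", k)]] <- unname(sol$labels[lab_tab$root])
    pv <- run_stage(paste0("parcellate_c", k),
                    voxel_parcellation(roi, roots, sol))
    parcels[[as.character(k)]] <- pv
    files <- c(files, write_volume(pv, out(sprintf("parcels_c%d.nii.gz", k))))
  }
  files <- c(files, write_table(lab_tab, out("clusters.csv")))

  emb <- run_stage("mds", torgerson_pcoa(correlation_distance(pm), k = 2))
  mds_df <- data.frame(root = rownames(emb$points),
                       mds_x = emb$points[, 1], mds_y = emb$points[, 2])
  if (length(solutions))
    mds_df$cluster <- unname(solutions[[1]]$labels[mds_df$root])
  files <- c(files, write_table(mds_df, out("mds.csv")))

  decomposition <- NULL
  if (!is.null(atlas) &&
      as.character(config$decompose_cardinality) %in% names(solutions)) {
    decomposition <- run_stage("decompose",
      decompose_cluster(sub,
                        solutions[[as.character(config$decompose_cardinality)]],
                        config$decompose_cluster, atlas, config$percentiles))
    files <- c(files, write_table(decomposition, out("decomposition.csv")))
  }

  map_summary <- NULL
  if (!is.null(config$maps) &&
      as.character(config$decompose_cardinality) %in% names(solutions)) {
    map_summary <- run_stage("mapcompare", {
      ms <- map_correlation_summary(
        config$maps, solutions[[as.character(config$decompose_cardinality)]])
      files <- c(files, write_table(ms$summary, out("map_summary.csv")))
      dendrogram_newick(cluster_maps(config$maps, config$linkage),
                        out("map_dendrogram.nwk"))
      files <- c(files, out("map_dendrogram.nwk"))
      ms
    })
  }

  manifest <- list(
    package = "coaltnet",
    version = as.character(utils::packageVersion("coaltnet")),
    seed = config$seed,
    stage_seeds = list(simulate = config$seed, permutation = config$seed + 1L),
    parameters = config[!(names(config) %in% c("foci", "roi", "atlas", "maps",
                                               "kernel"))],
    kernel = unclass(config$kernel),
    inputs = list(
      foci = if (is.character(config$foci)) config$foci else "<in-memory>",
      roi = if (is.character(config$roi)) config$roi else "<in-memory>",
      atlas = if (is.character(config$atlas)) config$atlas
              else if (is.null(config$atlas)) NULL else "<in-memory>"),
    n_experiments = length(set),
    n_nodes = nrow(net$nodes), n_roots = nrow(roots),
    n_edges = nrow(net$edges))
  manifest$config_hash <- config_fingerprint(jsonlite::toJSON(manifest$parameters,
                                                 auto_unbox = TRUE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, out("manifest.json"))

  invisible(list(ale = ale, nodes = nodes, states = states, network = net,
                 subnetwork = sub, profile = pm, dendrogram = dend,
                 dendrogram_no_root = dend_nr, solutions = solutions,
                 parcels = parcels, embedding = emb,
                 decomposition = decomposition, map_summary = map_summary,
                 files = files))
}
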