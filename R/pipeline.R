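#' Map movement corridors on a resistance surface
#'
#' Runs both corridor methods the package supports on one surface: a
#' least-cost-path network among all sampling-cell pairs (rasterized to a
#' path-count grid and written as GeoJSON by the pipeline), and all-to-one
#' circuit current maps over the individual sampling cells and over focal
#' patches. Also flags the divergence between the two methods: cells in the
#' top decile of current flow that carry no least-cost path.
#'
#' @param surface the best multivariate `resistance_surface`.
#' @param cells (row, col) matrix of sampling cells.
#' @param focal_patches list of (row, col) matrices, each a patch contracted
#'   to a single circuit node; `NULL` to skip the patch run.
#' @param labels individual labels for path naming.
#' @return list with `path_count` (`raster_grid`), `paths` (named list of
#'   path matrices), `current_individuals`, `current_patches`
#'   (`raster_grid`s or NULL), `divergence` (`raster_grid`, 1 = high-current
#'   no-LCP cell), `current_rank_cor` (Spearman correlation between the two
#'   current maps), `disconnected` (data.frame of unreachable pairs).
#' @export
map_corridors <- function(surface, cells, focal_patches = NULL,
                          labels = NULL) {
  cells <- rbind(cells)
  n <- nrow(cells)
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  g <- surface_graph(surface)
  paths <- list(); disc <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lp <- least_cost_path(surface, cells[i, ], cells[j, ], graph = g)
    nm <- paste(labels[i], labels[j], sep = "-")
    if (lp$disconnected) disc[[length(disc) + 1L]] <-
        data.frame(i = labels[i], j = labels[j])
    else paths[[nm]] <- lp$path
  }
  pc <- path_count_raster(surface, paths)
  net <- build_network(surface)
  ind_focal <- lapply(seq_len(n), function(i) cells[i, ])
  cur_ind <- solve_all_to_one(net, ind_focal)$current
  cur_pat <- NULL; rank_cor <- NA_real_
  if (!is.null(focal_patches) && length(focal_patches) >= 2) {
    cur_pat <- solve_all_to_one(net, focal_patches)$current
    ok <- !is.na(cur_ind$values) & !is.na(cur_pat$values)
    rank_cor <- stats::cor(cur_ind$values[ok], cur_pat$values[ok],
                           method = "spearman")
  }
  cur_ref <- if (!is.null(cur_pat)) cur_pat else cur_ind
  cv <- cur_ref$values
  thr <- stats::quantile(cv[!is.na(cv) & cv > 0], 0.9, names = FALSE)
  div <- (cv >= thr & pc$values == 0) * 1
  div[is.na(cv)] <- NA
  list(path_count = pc, paths = paths,
       current_individuals = cur_ind, current_patches = cur_pat,
       divergence = raster_grid(div, surface$grid$cell_size,
                                surface$grid$origin_x, surface$grid$origin_y),
       current_rank_cor = rank_cor,
       disconnected = if (length(disc)) do.call(rbind, disc) else NULL)
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    genetic_metric = "a",
    n_perm = 199,
    value_grid = BARRIER_VALUE_GRID,
    reconciliation = c("per_area_1", "per_area_2", "average", "maximum"),
    corridors = TRUE,
    synth = list(
      nrow = 60, ncol = 60, cell_size = 30,
      composition = "kittery",
      features = c("forest", "development", "fields", "water", "scrub_shrub"),
      road_classes = c(1, 3),
      lidar_cover = 0.01,
      generator = "pairwise",
      n_per_area = 12,
      true_feature = "forest", true_value = 100,
      beta_true = 0.8, noise_sd = 0.4, rho = 0.25))
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  cfg <- utils::modifyList(base, config)
  if (is.character(cfg$synth$composition))
    cfg$synth$composition <- switch(cfg$synth$composition,
                                    kittery = kittery_composition(),
                                    cape = cape_composition(),
                                    stop("unknown composition preset"))
  if (is.null(cfg$seed)) stop("config must carry a seed")
  cfg
}

# Sample two clustered point sets (left and right thirds of the grid), one
# per emulated study area.
sample_area_points <- function(grid, n_per_area, seed) {
  set.seed(seed)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  pick <- function(cmin, cmax, n) {
    cbind(row = sample(seq(max(2, round(nr * 0.15)),
                           min(nr - 1, round(nr * 0.85))), n, replace = FALSE),
          col = sample(seq(cmin, cmax), n, replace = TRUE))
  }
  a1 <- pick(max(2L, round(nc * 0.08)), round(nc * 0.30), n_per_area)
  a2 <- pick(round(nc * 0.70), min(nc - 1L, round(nc * 0.92)), n_per_area)
  cells <- rbind(a1, a2)
  list(cells = cells,
       labels = sprintf("ind%03d", seq_len(2 * n_per_area)),
       area = rep(c("area1", "area2"), each = n_per_area))
}

# Mode resolution and optimization of one feature per area.
optimize_feature_area <- function(layer, genetic, geographic, cells,
                                  value_grid, n_perm, seed) {
  modes <- switch(layer$role, barrier = "barrier",
                  facilitator = "facilitator",
                  both = c("barrier", "facilitator"))
  best <- NULL
  for (md in modes) {
    tr <- optimize_univariate(layer, md, genetic, geographic, cells,
                              value_grid = value_grid, n_perm = n_perm,
                              seed = seed)
    if (is.null(best) || max(tr$r) > max(best$r)) best <- tr
  }
  best
}

subset_dist <- function(d, idx) {
  new_dist_matrix(unclass(d)[idx, idx, drop = FALSE],
                  dist_labels(d)[idx], attr(d, "kind"))
}

#' Run the full two-step landscape-genetics pipeline
#'
#' Executes, per study area: univariate resistance optimization (partial
#' Mantel grid search per feature), the univariate MLPE/AICc table,
#' multivariate preset surfaces (including buffered-road variants) and their
#' MLPE/AICc table; then reconciles the two areas' optimized values across
#' the full extent (per-area, average and maximum candidate sets scored by
#' full-population partial Mantel r), fits the multivariate set under the
#' winning values, and maps corridors on the best surface with both
#' least-cost-path and circuit methods. All outputs and every seed used are
#' logged in a manifest.
#'
#' @param config configuration list or path to a YAML file; see
#'   `landres:::default_pipeline_config()` for the shape and defaults.
#'   Currently the synthetic input path is implemented (`synth` block);
#'   external rasters and GenePop files can be analysed with the underlying
#'   functions directly.
#' @param out_dir output directory (created if needed).
#' @return invisible list with the main in-memory artifacts: per-area
#'   traces, model tables, reconciliation table, best surface, corridor
#'   bundle, and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("landres_run_")) {
  cfg <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sy <- cfg$synth
  manifest <- list(seed = cfg$seed, genetic_metric = cfg$genetic_metric,
                   n_perm = cfg$n_perm, files = list())
  save_grid <- function(grid, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_ascii_grid(grid, p)
    manifest$files[[name]] <<- basename(p)
    p
  }
  save_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    manifest$files[[name]] <<- basename(p)
    p
  }

  ## stage: synthesis -------------------------------------------------------
  land <- generate_landscape(composition = sy$composition, nrow = sy$nrow,
                             ncol = sy$ncol, cell_size = sy$cell_size,
                             road_classes = sy$road_classes,
                             lidar_cover = sy$lidar_cover,
                             seed = cfg$seed)
  pts <- sample_area_points(land$landcover, sy$n_per_area, cfg$seed + 1L)
  road_names <- grep("^road_class_", names(land$layers), value = TRUE)
  true_layer <- land$layers[[sy$true_feature]]
  if (is.null(true_layer)) stop("stage synthesis: unknown true_feature")
  true_mode <- if (true_layer$role == "facilitator") "facilitator" else "barrier"
  true_surface <- build_univariate_surface(
    true_layer, true_mode,
    value = if (true_mode == "barrier") sy$true_value else NULL,
    value_grid = cfg$value_grid)
  cd_true <- cost_distance_matrix(true_surface, pts$cells, labels = pts$labels)
  if (!is.null(cd_true$disconnected_pairs))
    stop("stage synthesis: true surface leaves pairs disconnected")
  if (identical(sy$generator, "forward")) {
    demes <- lapply(seq_len(nrow(pts$cells)), function(i) pts$cells[i, ])
    gt <- simulate_genotypes_forward(
      demes, unclass(cd_true$distances), land$landcover,
      lambda = sy$lambda %||% 0.01, deme_size = sy$deme_size %||% 30,
      n_generations = sy$n_generations %||% 150, n_loci = sy$n_loci %||% 11,
      sample_sizes = 1, seed = cfg$seed + 2L)
    genetic <- if (cfg$genetic_metric == "dps") dps_matrix(gt) else
      rousset_a_matrix(gt)
    genetic <- new_dist_matrix(unclass(genetic), pts$labels,
                               attr(genetic, "kind"))
  } else {
    genetic <- generate_pairwise_genetic(cd_true$distances, sy$beta_true,
                                         noise_sd = sy$noise_sd,
                                         rho = sy$rho, seed = cfg$seed + 2L)
  }
  geographic <- new_dist_matrix(
    as.matrix(stats::dist(cell_centers(land$landcover, pts$cells))),
    pts$labels, "geographic")
  save_grid(land$landcover, "landcover")
  save_grid(true_surface$grid, "true_surface")

  areas <- unique(pts$area)
  feat_names <- sy$features
  opt_values <- list(); opt_modes <- list()
  uni_tables <- list(); multi_tables <- list(); traces <- list()

  for (ai in seq_along(areas)) {
    ar <- areas[ai]
    idx <- which(pts$area == ar)
    gen_a <- subset_dist(genetic, idx)
    geo_a <- subset_dist(geographic, idx)
    cells_a <- pts$cells[idx, , drop = FALSE]

    ## stage: univariate optimization ---------------------------------------
    vals <- list(); mds <- list(); tr_all <- list()
    for (fn in c(feat_names, road_names)) {
      tr <- optimize_feature_area(land$layers[[fn]], gen_a, geo_a, cells_a,
                                  cfg$value_grid, cfg$n_perm,
                                  seed = cfg$seed + 10L + ai)
      vals[[fn]] <- attr(tr, "selected_value")
      mds[[fn]] <- tr$mode[1]
      tr_all[[fn]] <- as.data.frame(tr)
    }
    opt_values[[ar]] <- vals; opt_modes[[ar]] <- mds
    traces[[ar]] <- do.call(rbind, tr_all)
    save_csv(traces[[ar]], paste0("trace_", ar))

    ## stage: univariate MLPE table -----------------------------------------
    fits <- list()
    for (fn in feat_names) {
      surf <- build_univariate_surface(
        land$layers[[fn]], mds[[fn]],
        value = if (mds[[fn]] == "barrier") vals[[fn]] else NULL,
        value_grid = cfg$value_grid)
      cd <- cost_distance_matrix(surf, cells_a, labels = dist_labels(gen_a))
      fits[[fn]] <- mlpe_fit(gen_a, cd$distances, name = fn)
    }
    if (length(road_names)) {
      bsurf <- build_buffered_road_surface(
        land$layers[road_names],
        unlist(vals[road_names]),
        buffered_classes = road_names)
      cd <- cost_distance_matrix(bsurf, cells_a, labels = dist_labels(gen_a))
      fits[["buffered_roads"]] <- mlpe_fit(gen_a, cd$distances,
                                           name = "buffered_roads")
    }
    fits[["null"]] <- mlpe_fit(gen_a, geo_a, name = "null")
    uni_tables[[ar]] <- rank_models(fits)
    save_csv(uni_tables[[ar]], paste0("univariate_table_", ar))

    ## stage: multivariate MLPE table ---------------------------------------
    multi <- fit_multivariate_set(land, feat_names, road_names, vals, mds,
                                  gen_a, geo_a, cells_a, cfg)
    multi_tables[[ar]] <- multi$table
    save_csv(multi$table, paste0("multivariate_table_", ar))
  }

  ## stage: full-extent reconciliation --------------------------------------
  candidates <- list()
  v1 <- opt_values[[areas[1]]]; v2 <- opt_values[[areas[2]]]
  candidates[["per_area_1"]] <- v1
  candidates[["per_area_2"]] <- v2
  candidates[["average"]] <- stats::setNames(
    lapply(names(v1), function(fn) (v1[[fn]] + v2[[fn]]) / 2), names(v1))
  candidates[["maximum"]] <- stats::setNames(
    lapply(names(v1), function(fn) pmax(v1[[fn]], v2[[fn]])), names(v1))
  candidates <- candidates[intersect(cfg$reconciliation, names(candidates))]
  # modes must agree across the full extent; resolve by total support
  modes_full <- stats::setNames(lapply(names(v1), function(fn) {
    m1 <- opt_modes[[areas[1]]][[fn]]; m2 <- opt_modes[[areas[2]]][[fn]]
    if (m1 == m2) m1 else {
      r1 <- max(traces[[areas[1]]]$r[traces[[areas[1]]]$feature == fn])
      r2 <- max(traces[[areas[2]]]$r[traces[[areas[2]]]$feature == fn])
      if (r1 >= r2) m1 else m2
    }
  }), names(v1))
  rec_rows <- list(); rec_surfaces <- list()
  for (cand in names(candidates)) {
    surf <- compose_from_values(land, feat_names, road_names,
                                candidates[[cand]], modes_full,
                                buffered_classes = road_names)
    cd <- cost_distance_matrix(surf, pts$cells, labels = pts$labels)
    if (!is.null(cd$disconnected_pairs)) {
      rec_rows[[cand]] <- data.frame(candidate = cand, r = NA, p = NA)
      next
    }
    mt <- partial_mantel(genetic, cd$distances, geographic,
                         n_perm = cfg$n_perm, seed = cfg$seed + 20L)
    rec_rows[[cand]] <- data.frame(candidate = cand, r = mt$r, p = mt$p)
    rec_surfaces[[cand]] <- surf
  }
  rec <- do.call(rbind, rec_rows)
  best_cand <- rec$candidate[which.max(rec$r)]
  save_csv(rec, "reconciliation")
  best_values <- candidates[[best_cand]]

  ## stage: full-population multivariate table ------------------------------
  multi_full <- fit_multivariate_set(land, feat_names, road_names,
                                     best_values, modes_full,
                                     genetic, geographic, pts$cells, cfg)
  save_csv(multi_full$table, "multivariate_table_full")
  best_model <- multi_full$table$model[1]
  best_surface <- multi_full$surfaces[[best_model]] %||%
    rec_surfaces[[best_cand]]
  save_grid(best_surface$grid, "best_surface")

  ## stage: corridors --------------------------------------------------------
  corridors <- NULL
  if (isTRUE(cfg$corridors)) {
    patches <- lapply(areas, function(ar)
      pts$cells[pts$area == ar, , drop = FALSE])
    corridors <- map_corridors(best_surface, pts$cells,
                               focal_patches = patches, labels = pts$labels)
    save_grid(corridors$path_count, "lcp_path_count")
    save_grid(corridors$current_individuals, "current_individuals")
    if (!is.null(corridors$current_patches))
      save_grid(corridors$current_patches, "current_patches")
    save_grid(corridors$divergence, "high_current_no_lcp")
    write_paths_geojson(best_surface, corridors$paths,
                        file.path(out_dir, "lcp_paths.geojson"))
    manifest$files[["lcp_paths"]] <- "lcp_paths.geojson"
  }

  manifest$selected_values <- lapply(opt_values, function(v) v)
  manifest$reconciliation_winner <- best_cand
  manifest$best_model <- best_model
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(landscape = land, points = pts, genetic = genetic,
                 geographic = geographic, traces = traces,
                 opt_values = opt_values, opt_modes = opt_modes,
                 univariate_tables = uni_tables,
                 multivariate_tables = multi_tables,
                 reconciliation = rec, best_candidate = best_cand,
                 multivariate_table_full = multi_full$table,
                 best_surface = best_surface, corridors = corridors,
                 manifest = manifest, out_dir = out_dir))
}

# Compose a multivariate surface from per-feature optimized values + modes.
compose_from_values <- function(land, feat_names, road_names, values, modes,
                                buffered_classes = character(0),
                                include = NULL) {
  use <- if (is.null(include)) feat_names else intersect(feat_names, include)
  feats <- lapply(use, function(fn)
    list(layer = land$layers[[fn]], role = modes[[fn]],
         value = if (modes[[fn]] == "barrier") values[[fn]] else 1))
  road_spec <- NULL
  if (length(road_names))
    road_spec <- list(road_layers = land$layers[road_names],
                      barrier_values = unlist(values[road_names]),
                      buffered_classes = buffered_classes)
  compose_multivariate_surface(feats, road_spec)
}

# Fit the preset multivariate model set (plus null) and rank it.
fit_multivariate_set <- function(land, feat_names, road_names, values, modes,
                                 genetic, geographic, cells, cfg) {
  labels <- dist_labels(genetic)
  have_lidar <- "lidar_veg" %in% names(land$layers)
  presets <- c("all_barriers", "natural_barriers", "natural_facilitators",
               "all_facilitators", "linear_facilitators", "landcover",
               "development_roads", "global")
  fits <- list(); surfaces <- list()
  all_avail <- c(feat_names,
                 intersect(c("powerline", "railroad", "lidar_veg"),
                           names(land$layers)))
  values <- utils::modifyList(
    stats::setNames(lapply(all_avail, function(f) 1), all_avail), values)
  modes <- utils::modifyList(
    stats::setNames(lapply(all_avail, function(f) "facilitator"), all_avail),
    modes)
  for (ps in presets) {
    spec <- multivariate_preset(ps, with_lidar = have_lidar)
    barr <- intersect(spec$barriers, all_avail)
    fac <- intersect(spec$facilitators, all_avail)
    if (!length(barr) && !length(fac) && !spec$roads) next
    use_modes <- modes
    for (b in barr) use_modes[[b]] <- "barrier"
    for (f in fac) use_modes[[f]] <- "facilitator"
    rn <- if (spec$roads) road_names else character(0)
    variants <- if (spec$roads && length(rn))
      list(buffered = rn, barrier_only = character(0)) else
      list(plain = character(0))
    for (vn in names(variants)) {
      nm <- if (length(variants) > 1) paste(ps, vn, sep = "_") else ps
      surf <- tryCatch(
        compose_from_values(land, c(barr, fac), rn, values, use_modes,
                            buffered_classes = variants[[vn]]),
        error = function(e) NULL)
      if (is.null(surf)) next
      cd <- cost_distance_matrix(surf, cells, labels = labels)
      if (!is.null(cd$disconnected_pairs)) next
      fits[[nm]] <- mlpe_fit(genetic, cd$distances, name = nm)
      surfaces[[nm]] <- surf
    }
  }
  fits[["null"]] <- mlpe_fit(genetic, geographic, name = "null")
  list(table = rank_models(fits), surfaces = surfaces, fits = fits)
}
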