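# Full-run orchestration: simulate or ingest reporter matrices, normalize,
# call MR per condition, cluster trajectories and match them across
# conditions, run stagewise DE, and combine everything with set logic.
# All stage outputs are written as TSV plus one JSON manifest; a rerun with
# the same configuration is byte-identical.

#' Read a pipeline run configuration
#'
#' The configuration is a YAML file with either a `simulation` block
#' (arguments to [sim_config()]) or an `inputs` block (`design` path and
#' `matrices`, a named map multiplex id -> reporter TSV path), plus optional
#' `thresholds` (`alpha_mr`, `alpha_de`, `fc_log2`), `clustering` (`k`,
#' `seed`, `n_restarts`), `reference`, and `channel_normalize` (logical,
#' default `TRUE`; `FALSE` runs the bridge correction alone, for inputs
#' whose channels are already on a common loading scale).
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

default_thresholds <- function(cfg) {
  th <- cfg$thresholds
  list(alpha_mr = th$alpha_mr %||% 0.05,
       alpha_de = th$alpha_de %||% 0.05,
       fc_log2 = th$fc_log2 %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes every stage in order: data acquisition (simulation or TSV
#' ingest), channel + bridge normalization, MR calling per condition, the
#' MR Venn partition and vehicle-only exclusion, trajectory clustering of
#' the untreated MR set and of the vehicle-corrected TMX set with cluster
#' matching, stagewise DE, DE/MR intersections and the highly regulated
#' list. Any stage failure aborts with the stage name and cause.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   YAML file.
#' @param out_dir Output directory for result tables and the manifest.
#' @return Invisibly, a list with all in-memory results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- default_thresholds(config)
  cl_cfg <- config$clustering
  k <- cl_cfg$k %||% 5
  cl_seed <- cl_cfg$seed %||% 17
  n_restarts <- cl_cfg$n_restarts %||% 50
  reference <- config$reference %||% "M"
  manifest <- list(package = "bridgeTMT",
                   version = as.character(utils::packageVersion("bridgeTMT")),
                   thresholds = th,
                   clustering = list(k = k, seed = cl_seed,
                                     n_restarts = n_restarts),
                   reference = reference,
                   stages = list())

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    acquired <- run_stage("simulate", {
      sc <- do.call(sim_config, config$simulation)
      truth <- generate_ground_truth(sc)
      sim <- simulate_multiplexes(truth, sc)
      write_simulation(sim, file.path(out_dir, "simulated"))
      sim
    })
    matrices <- acquired$matrices
    design <- acquired$design
    truth <- acquired$truth
    manifest$seed <- config$simulation$seed %||% 1
  } else if (!is.null(config$inputs)) {
    acquired <- run_stage("ingest", {
      paths <- config$inputs$matrices
      missing <- unlist(paths)[!file.exists(unlist(paths))]
      if (length(missing)) {
        stop("input matrix path does not exist: ",
             paste(missing, collapse = ", "))
      }
      if (!file.exists(config$inputs$design)) {
        stop("design path does not exist: ", config$inputs$design)
      }
      design <- read_design(config$inputs$design)
      matrices <- lapply(names(paths), function(mx) {
        read_reporter_matrix(paths[[mx]], design, mx)
      })
      names(matrices) <- names(paths)
      list(matrices = matrices, design = design)
    })
    matrices <- acquired$matrices
    design <- acquired$design
  } else {
    stop("pipeline stage 'config' failed: need a 'simulation' or 'inputs' block")
  }
  manifest$stages$input <- list(
    n_proteins = vapply(matrices, function(m) nrow(m$intensities), integer(1)))

  # --- normalization ------------------------------------------------------
  # channel_normalize: false runs bridge correction only, for inputs whose
  # channels are already on a common loading scale
  do_channel <- config$channel_normalize %||% TRUE
  bridged <- run_stage("normalize", {
    if (do_channel) {
      normalize_experiment(matrices, design, reference)
    } else {
      bridge_correct(matrices, design, reference)
    }
  })
  manifest$channel_normalize <- do_channel
  write_result_table(
    data.frame(protein_id = rownames(bridged$log2), bridged$log2,
               check.names = FALSE),
    file.path(out_dir, "bridged_log2.tsv"))
  manifest$stages$normalize <- list(
    n_retained = nrow(bridged$log2),
    n_dropped_missing_bridge = length(bridged$dropped))

  # --- longitudinal MR per condition --------------------------------------
  mr <- run_stage("longitudinal_mr", {
    lapply(stats::setNames(conditions(), conditions()), function(co) {
      call_mr(bridged, co, alpha = th$alpha_mr,
              fc_threshold_log2 = th$fc_log2)
    })
  })
  for (co in names(mr)) {
    write_result_table(mr[[co]], file.path(out_dir, paste0("mr_", co, ".tsv")))
  }
  mr_sets <- lapply(mr, function(m) m$protein_id[m$is_mr])
  manifest$stages$mr <- lapply(mr_sets, length)

  # --- set logic: venn + vehicle-only exclusion ---------------------------
  venn <- run_stage("mr_venn", {
    mr_venn(mr_sets$untreated, mr_sets$vehicle, mr_sets$tmx)
  })
  cluster_input <- exclude_vehicle_only(venn)
  write_result_table(
    data.frame(region = names(venn$sizes), size = as.integer(venn$sizes),
               members = vapply(venn$regions, paste, character(1),
                                collapse = ";")),
    file.path(out_dir, "mr_venn.tsv"))
  write_result_table(data.frame(protein_id = cluster_input),
                     file.path(out_dir, "tmx_cluster_input.tsv"))
  manifest$stages$venn <- as.list(venn$sizes)
  manifest$stages$tmx_cluster_input <- length(cluster_input)

  # --- trajectory clustering ----------------------------------------------
  models <- run_stage("clustering", {
    out <- list()
    sets <- list(untreated = mr_sets$untreated, tmx = cluster_input)
    for (nm in names(sets)) {
      ids <- sets[[nm]]
      if (length(ids) >= k) {
        traj <- build_trajectories(bridged, ids,
                                   if (nm == "tmx") "tmx" else "untreated")
        if (nrow(unique(traj)) >= k) {
          out[[nm]] <- kmeans_cluster(traj, k = k, seed = cl_seed,
                                      n_restarts = n_restarts)
        }
      }
    }
    out
  })
  for (nm in names(models)) {
    write_result_table(
      data.frame(protein_id = names(models[[nm]]$assignments),
                 cluster = as.integer(models[[nm]]$assignments)),
      file.path(out_dir, paste0("clusters_", nm, ".tsv")))
  }
  cluster_match <- NULL
  if (all(c("untreated", "tmx") %in% names(models))) {
    cluster_match <- run_stage("cluster_match", {
      match_clusters(models$untreated, models$tmx)
    })
    write_result_table(cluster_match$overlap,
                       file.path(out_dir, "cluster_overlap.tsv"))
  }
  manifest$stages$clustering <- lapply(models, function(m) {
    list(k = m$k, sizes = m$sizes, inertia = m$inertia)
  })

  # --- stagewise DE -------------------------------------------------------
  de <- run_stage("stagewise_de", {
    lapply(stats::setNames(stages(), stages()), function(tp) {
      stage_de(bridged, tp, alpha = th$alpha_de,
               fc_threshold_log2 = th$fc_log2)
    })
  })
  for (tp in names(de)) {
    write_result_table(de[[tp]], file.path(out_dir, paste0("de_", tp, ".tsv")))
  }
  de_all <- do.call(rbind, de)
  de_union <- sort(unique(de_all$protein_id[de_all$is_de]))
  manifest$stages$de <- c(
    lapply(de, function(d) sum(d$is_de)),
    list(union = length(de_union)))

  # --- DE x MR set analysis -----------------------------------------------
  sets_out <- run_stage("set_analysis", {
    list(de_mr = de_mr_intersections(de_union, mr_sets$untreated,
                                     mr_sets$tmx),
         highly = highly_regulated(de_all, min_stages = 2))
  })
  write_result_table(
    data.frame(set = names(sets_out$de_mr$sizes),
               size = as.integer(sets_out$de_mr$sizes),
               members = vapply(sets_out$de_mr[names(sets_out$de_mr$sizes)],
                                paste, character(1), collapse = ";")),
    file.path(out_dir, "de_mr_sets.tsv"))
  write_result_table(sets_out$highly,
                     file.path(out_dir, "highly_regulated.tsv"))
  manifest$stages$set_analysis <- list(
    de_mr_sizes = as.list(sets_out$de_mr$sizes),
    n_highly_regulated = nrow(sets_out$highly))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bridged = bridged, mr = mr, mr_sets = mr_sets, venn = venn,
                 cluster_input = cluster_input, models = models,
                 cluster_match = cluster_match, de = de,
                 de_union = de_union, sets = sets_out, truth = truth,
                 manifest = manifest))
}
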