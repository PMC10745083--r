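default_config <- function() {
  list(
    seed = 1,
    log_level = "info",
    simulate = list(n_major = 2, leafs_per_major = 2, leaf_shape_voxels = c(4, 4, 4),
                    n_classes = 3, pattern_sparsity = 0.5, class_effect = 2,
                    smoothness_scale = 10, n_per_cell = 3, noise_sd = 0.2),
    data = list(normalization = "none", detection_limit_quantile = 0),
    estimator = list(kind = "el", per_major = TRUE,
                     sigma_x = c(100, 400, 1600, 6400),
                     sigma_c = c(0.01, 0.1, 1),
                     alpha = c(0, 0.25, 0.5, 0.75, 1)),
    connectome = list(variant = "normalized", mode = "structure"),
    # mask threshold scaled to the synthetic block brain (adjacent leaf
    # blocks sit 100 um apart); for atlas-scale data use the 1500 um default
    # of distal_mask()
    nmf = list(enabled = TRUE, q = 3, q_grid = numeric(0), lambda = 0.002,
               replicates = 8, match_threshold = 0.3, top_k = 15,
               mask_threshold_um = 150, holdout_fraction = 0.2, n_repeats = 3)
  )
}

check_config_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad) > 0) {
    stop_mesoconn("unknown config key(s): ",
                  paste0(path, bad, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) stop_mesoconn("config key ", path, k, " must be a section")
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(cfg)
}

#' Read and validate a pipeline configuration
#'
#' YAML file with the sections `simulate`, `data`, `estimator`, `connectome`,
#' `nmf` plus top-level `seed` and `log_level`. Unknown keys are rejected;
#' omitted keys take package defaults, so the resolved configuration
#' round-trips without loss.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  if (!file.exists(path)) stop_mesoconn("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_config_keys(user, ref)
  cfg <- modifyList(ref, user)
  cfg$nmf$q_grid <- as.numeric(unlist(cfg$nmf$q_grid))  # [] parses as list()
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_mesoconn("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

log_msg <- function(level, cfg, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[cfg$log_level %||% "info"]]) {
    message("[", level, "] ", ...)
  }
}

# prepend a config-hash comment to a text file written by a stage
stamp_file <- function(path, hash) {
  lines <- readLines(path, warn = FALSE)
  writeLines(c(paste0("# config_hash: ", hash), lines), path)
  invisible(path)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' simulate -> normalize/regionalize -> select and evaluate the estimator ->
#' build the class-specific connectivity tensor -> factor the wild-type
#' matrix into stable archetypes. All outputs are deterministic given the
#' configuration and seed; every text artifact is stamped with the hash of
#' the resolved configuration, and `provenance.json` records the
#' configuration, hash and seeds.
#'
#' @param config a configuration list from [read_config()], or a path to a
#'   YAML configuration file.
#' @param out_dir output directory.
#' @param seed optional seed override.
#' @return (invisibly) a list with the dataset, fitted model, evaluation
#'   report, tensor and stability result, plus the artifact directory.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    modifyList(default_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfg_path)
  hash <- unname(md5sum(cfg_path))

  sim <- cfg$simulate
  d <- pipeline_stage("simulate", {
    ont <- make_brain(sim$n_major, sim$leafs_per_major, sim$leaf_shape_voxels,
                      seed = cfg$seed)
    gt <- sample_ground_truth(ont, n_classes = sim$n_classes,
                              pattern_sparsity = sim$pattern_sparsity,
                              class_effect = sim$class_effect,
                              smoothness_scale = sim$smoothness_scale,
                              seed = cfg$seed)
    simulate_experiments(gt, n_per_cell = sim$n_per_cell,
                         noise_sd = sim$noise_sd, seed = cfg$seed + 1)
  })
  log_msg("info", cfg, "simulated ", nrow(d$experiments), " experiments")

  d <- pipeline_stage("regionalize", {
    out <- if (cfg$data$normalization != "none") {
      normalize_dataset(d, cfg$data$normalization)
    } else d
    write_dataset(out, file.path(out_dir, "dataset"), volumes = FALSE)
    stamp_file(file.path(out_dir, "dataset", "manifest.tsv"), hash)
    stamp_file(file.path(out_dir, "dataset", "regionalized.tsv"), hash)
    out
  })
  detection <- if (cfg$data$detection_limit_quantile > 0) {
    fit_detection_limit(d, cfg$data$detection_limit_quantile)
  } else 0

  est <- cfg$estimator
  model <- pipeline_stage("fit", {
    num <- function(x) as.numeric(unlist(x))  # YAML sequences may parse as lists
    grid <- switch(est$kind,
                   nnls = data.frame(sigma_x = NA_real_),
                   nw = data.frame(sigma_x = num(est$sigma_x)),
                   cre_nw = data.frame(sigma_x = num(est$sigma_x)),
                   el = expand.grid(sigma_x = num(est$sigma_x),
                                    sigma_c = num(est$sigma_c),
                                    alpha = num(est$alpha)))
    select_hyperparameters(est$kind, d, grid, per_major = est$per_major,
                           detection_limit = detection)
  })
  report <- pipeline_stage("evaluate", {
    rep <- loocv_weighted_loss(model, d, detection_limit = detection)
    write_evaluation_report(rep, file.path(out_dir, "evaluation.tsv"),
                            file.path(out_dir, "evaluation.json"))
    stamp_file(file.path(out_dir, "evaluation.tsv"), hash)
    rep
  })
  log_msg("info", cfg, "overall weighted LOOCV loss: ",
          format(report$overall, digits = 5))

  tensor <- pipeline_stage("build-connectome", {
    tens <- connectivity_tensor(model, d, mode = cfg$connectome$mode)
    tens <- normalize_connectivity(tens, variant = cfg$connectome$variant)
    write_connectivity(tens, out_dir)
    stamp_file(file.path(out_dir, "connectivity_long.tsv"), hash)
    tens
  })

  stability <- NULL
  if (isTRUE(cfg$nmf$enabled)) {
    stability <- pipeline_stage("nmf", {
      Cwt <- tensor$values["wt", , ]
      M <- distal_mask(d$ontology, cfg$nmf$mask_threshold_um) & !is.na(Cwt)
      q <- cfg$nmf$q
      if (length(cfg$nmf$q_grid) > 0) {
        q <- select_rank(Cwt, M, q_grid = as.numeric(unlist(cfg$nmf$q_grid)),
                         holdout_fraction = cfg$nmf$holdout_fraction,
                         n_repeats = cfg$nmf$n_repeats, seed = cfg$seed,
                         lambda = cfg$nmf$lambda)
      }
      fit <- masked_sparse_nmf(Cwt, M, q = q, lambda = cfg$nmf$lambda,
                               seed = cfg$seed)
      stab <- stability_archetypes(Cwt, M, q = q, lambda = cfg$nmf$lambda,
                                   n_replicates = cfg$nmf$replicates,
                                   match_threshold = cfg$nmf$match_threshold,
                                   top_k = cfg$nmf$top_k, seed = cfg$seed)
      utils::write.csv(fit$W, file.path(out_dir, "W.csv"))
      utils::write.csv(fit$H, file.path(out_dir, "H.csv"))
      write.table(data.frame(iteration = seq_along(fit$objective_trace),
                             objective = fit$objective_trace),
                  file.path(out_dir, "objective_trace.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      stamp_file(file.path(out_dir, "objective_trace.tsv"), hash)
      jsonlite::write_json(list(config_hash = hash, q = as.integer(q),
                                lambda = cfg$nmf$lambda,
                                n_replicates = cfg$nmf$replicates,
                                frequency = as.list(stab$frequency),
                                archetypes = as.data.frame(stab$archetypes)),
                           file.path(out_dir, "stability.json"),
                           auto_unbox = TRUE, digits = NA)
      stab
    })
  }

  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            package_version = as.character(utils::packageVersion("mesoconn")),
                            config = cfg),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = d, model = model, evaluation = report,
                 tensor = tensor, stability = stability, dir = out_dir,
                 config_hash = hash))
}

# thin command-line front-end over the pipeline (see inst/cli/mesoconn.R)
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mesoconn.R run --out <dir> [--config <yaml>] [--seed <int>]"
  if (length(args) == 0 || args[1] != "run") {
    message(usage)
    return(invisible(1L))
  }
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out <- get_opt("--out")
  if (is.null(out)) stop_mesoconn(usage)
  seed <- get_opt("--seed")
  run_pipeline(config = get_opt("--config"), out_dir = out,
               seed = if (!is.null(seed)) as.integer(seed))
  invisible(0L)
}
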