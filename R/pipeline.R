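# End-to-end orchestration: regulator enrichment per source, candidate path
# enumeration, the four IP stages, ensemble confidences, consensus
# extraction, and the optional evaluation and bifurcation stages, with a
# manifest recording configuration, seed, and objective values.

#' Pipeline parameters with study defaults
#'
#' All defaults follow the published method where a published value exists:
#' regulator enrichment at `alpha = 0.05`; source-target paths with up to 3
#' intermediate proteins (five interactions in total) and the 50%
#' iterative-deepening coverage stop; hit-source and source-source paths
#' with up to 1 intermediate; receptor-source paths with up to 4;
#' consensus confidence 0.75; bifurcation enrichment FDR 0.1.
#'
#' @param alpha regulator enrichment threshold
#' @param universe gene universe size for enrichment (NULL: the network's
#'   gene/mRNA node count)
#' @param max_intermediates source-target intermediate bound
#' @param coverage_stop iterative-deepening stop fraction
#' @param max_hit_intermediates,max_source_intermediates,max_receptor_intermediates
#'   auxiliary path bounds
#' @param conf_threshold consensus confidence threshold
#' @param bifurcation_fdr BH FDR for module-regulator enrichment
#' @return named list of parameters
#' @export
pipeline_params <- function(alpha = 0.05, universe = NULL,
                            max_intermediates = 3, coverage_stop = 0.5,
                            max_hit_intermediates = 1,
                            max_source_intermediates = 1,
                            max_receptor_intermediates = 4,
                            conf_threshold = 0.75, bifurcation_fdr = 0.1) {
  list(alpha = alpha, universe = universe,
       max_intermediates = max_intermediates, coverage_stop = coverage_stop,
       max_hit_intermediates = max_hit_intermediates,
       max_source_intermediates = max_source_intermediates,
       max_receptor_intermediates = max_receptor_intermediates,
       conf_threshold = conf_threshold, bifurcation_fdr = bifurcation_fdr)
}

#' Run enrichment, path enumeration, the IP, and ensemble aggregation
#'
#' The in-memory core of the pipeline: selects candidate regulators per
#' source, enumerates all four candidate path classes, builds and solves the
#' integer program (stages 1-4), and aggregates the solution pool into
#' confidences.
#'
#' @param net a [background_network()]
#' @param ev an [evidence_set()]
#' @param params see [pipeline_params()]
#' @param pool_size stage-3 solution pool size
#' @param seed forwarded to the solver (the solve itself is deterministic)
#' @return list with `regulators` (per source), `enrichment` (per-source
#'   tables), `paths`, `model` (stage optima recorded), `solutions`,
#'   `ensemble`
#' @export
infer_subnetwork_ensemble <- function(net, ev, params = pipeline_params(),
                                      pool_size = 1000, seed = 1) {
  universe <- if (is.null(params$universe)) length(gene_nodes(net)) else params$universe
  regulators <- list(); enrichment <- list(); st_paths <- list()
  for (s in ev$sources) {
    tg <- ev$targets_by_source[[s]]
    if (!length(tg)) next
    sel <- select_candidate_regulators(tg, ev$regulator_binding,
                                       ev$stress_bound_regulators,
                                       universe = universe, alpha = params$alpha)
    regulators[[s]] <- sel$selected
    enrichment[[s]] <- sel$table
    if (length(sel$selected))
      st_paths <- c(st_paths, build_source_target_paths(
        net, s, tg, sel$selected, ev$regulator_binding,
        max_intermediates = params$max_intermediates,
        coverage_stop = params$coverage_stop))
  }
  aux <- build_auxiliary_paths(
    net, ev,
    max_hit_intermediates = params$max_hit_intermediates,
    max_source_intermediates = params$max_source_intermediates,
    max_receptor_intermediates = params$max_receptor_intermediates)
  paths <- c(st_paths, aux)
  model <- build_ip(paths, net, ev)
  solved <- solve_ip(model, pool_size = pool_size, seed = seed)
  ensemble <- compute_confidences(solved$solutions)
  list(regulators = regulators, enrichment = enrichment, paths = paths,
       model = solved$model, solutions = solved$solutions, ensemble = ensemble)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized fields: `edge_file`, `node_file`, `evidence_dir`, `out_dir`,
#' `seed`, `pool_size`, every [pipeline_params()] name, and optionally
#' `positives_file`, `negatives_file`, `excluded_file`, `clusters_file`,
#' `n_permutations`, `permutation_pool_size`.
#'
#' @param file YAML path
#' @return configuration list
#' @export
read_pipeline_config <- function(file) yaml::read_yaml(file)

#' Run the full inference pipeline from a configuration
#'
#' Executes enrichment, path enumeration, IP stages 1-4, ensemble
#' aggregation, and consensus extraction; when label files are configured it
#' adds the precision-recall evaluation with the candidate baseline (and the
#' permuted baseline if `n_permutations > 0`), and when a cluster file is
#' configured it adds bifurcation-point ranking. All stage outputs and a
#' manifest (configuration, seed, objective values, timings) are written to
#' `out_dir`.
#'
#' @param config list as from [read_pipeline_config()], or a YAML path
#' @return invisibly, the in-memory results list (see
#'   [infer_subnetwork_ensemble()], plus `consensus`, optional `evaluation`
#'   and `bifurcation`, and `manifest`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t0 <- proc.time()[["elapsed"]]
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  pool_size <- config$pool_size %||% 1000
  par_names <- names(formals(pipeline_params))
  params <- do.call(pipeline_params, config[intersect(names(config), par_names)])

  net <- load_background_network(config$edge_file, config$node_file)
  ev <- load_evidence_set(config$evidence_dir)
  report <- validate_evidence(net, ev)
  if (nrow(report)) {
    utils::write.table(report, file.path(out_dir, "validation_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (any(startsWith(report$category, "missing_")))
      stop("evidence validation failed; see validation_report.tsv")
    warning("evidence validation produced ", nrow(report), " note(s)")
  }

  timings <- numeric()
  tick <- function(label) {
    now <- proc.time()[["elapsed"]]
    timings[[label]] <<- round(now - t0 - sum(timings), 3)
  }

  res <- infer_subnetwork_ensemble(net, ev, params = params,
                                   pool_size = pool_size, seed = seed)
  tick("inference")

  enr_dir <- file.path(out_dir, "enrichment")
  dir.create(enr_dir, showWarnings = FALSE)
  for (s in names(res$enrichment))
    write_enrichment_table(res$enrichment[[s]],
                           file.path(enr_dir, paste0(s, ".tsv")))
  write_paths(res$paths, file.path(out_dir, "paths.tsv"))
  write_solutions(res$solutions, file.path(out_dir, "solutions.json"))
  write_confidences(res$ensemble, file.path(out_dir, "confidences.tsv"))

  consensus <- consensus_subnetwork(res$ensemble, params$conf_threshold)
  writeLines(consensus$nodes, file.path(out_dir, "consensus_nodes.txt"))
  export_sif(net, file.path(out_dir, "consensus.sif"),
             edge_ids = consensus$edges$edge_id)
  res$consensus <- consensus
  tick("outputs")

  if (!is.null(config$positives_file)) {
    labels <- label_set(
      positives = .read_list(config$positives_file),
      negatives = if (!is.null(config$negatives_file))
        .read_list(config$negatives_file) else character(),
      excluded = if (!is.null(config$excluded_file))
        .read_list(config$excluded_file) else character())
    pr <- precision_recall(res$ensemble$node_confidence, labels)
    utils::write.table(pr, file.path(out_dir, "pr_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cb <- candidate_baseline(res$paths, labels, net)
    res$evaluation <- list(pr = pr, candidate = cb)
    n_perms <- config$n_permutations %||% 0
    if (n_perms > 0) {
      perm_conf <- permuted_baseline(net, ev, n_perms = n_perms,
                                     pool_size = config$permutation_pool_size %||% 100,
                                     seed = seed, params = params)
      perm_pr <- precision_recall(perm_conf, labels)
      utils::write.table(perm_pr, file.path(out_dir, "pr_curve_permuted.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$evaluation$permuted <- perm_pr
    }
    tick("evaluation")
  }

  if (!is.null(config$clusters_file)) {
    cl <- utils::read.delim(config$clusters_file, stringsAsFactors = FALSE)
    cluster_map <- stats::setNames(cl$cluster, cl$gene)
    subnet <- extract_module_paths(res$ensemble, res$paths, cluster_map,
                                   ev$regulator_binding,
                                   universe = params$universe %||% length(gene_nodes(net)),
                                   conf_threshold = params$conf_threshold,
                                   fdr = params$bifurcation_fdr)
    ranking <- rank_bifurcation_points(subnet)
    utils::write.table(ranking, file.path(out_dir, "bifurcation_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$bifurcation <- list(subnetwork = subnet, ranking = ranking)
    tick("bifurcation")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("subnetIP")),
    seed = seed, pool_size = pool_size, params = params,
    objectives = list(max_connections = res$model$max_connections,
                      max_hits = res$model$max_hits,
                      min_nodes = res$model$min_nodes,
                      pool_found = length(res$solutions)),
    consensus = list(threshold = params$conf_threshold,
                     n_nodes = length(consensus$nodes),
                     n_edges = nrow(consensus$edges),
                     n_paths = length(consensus$paths)),
    timings_s = as.list(timings)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
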