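# Module-annotated consensus paths and information-gain-ratio ranking of
# bifurcation points: nodes whose outgoing paths cleanly separate induced
# from repressed downstream gene modules.
#
# The count C(T) is a TOTAL bit count (|T| times the entropy of the cluster
# mixture), while the split information S(n) is the plain entropy of the
# partition proportions (bits per target). The ratio B(n) = I(n)/S(n)
# therefore scales with the number of downstream targets, favouring nodes
# with few, cleanly split outgoing partitions and many targets.

#' Extract the module-annotated consensus path subnetwork
#'
#' Keeps consensus source-target paths (confidence at or above
#' `conf_threshold`) whose terminal regulator is enriched (hypergeometric
#' upper tail, Benjamini-Hochberg FDR at most `fdr` across all regulator x
#' cluster tests) for the cluster of the terminal target; targets outside
#' every cluster are removed. Each protein node on a retained path is
#' labeled with the clusters of its downstream retained regulators.
#'
#' @param ens an `ip_ensemble`
#' @param paths the candidate path list the ensemble was solved from
#' @param cluster_map named character vector: target gene/mRNA -> cluster
#'   (`"induced"` or `"repressed"`)
#' @param regulator_binding named list: regulator -> bound genes
#' @param universe gene universe size for the enrichment tests
#' @param conf_threshold consensus confidence threshold (default 0.75)
#' @param fdr BH FDR threshold for regulator-cluster enrichment (default 0.1)
#' @return object of class `module_subnetwork`: retained paths (with a
#'   `cluster` tag), per-node label sets, the enrichment table, and the
#'   target cluster assignment
#' @export
extract_module_paths <- function(ens, paths, cluster_map, regulator_binding,
                                 universe, conf_threshold = 0.75, fdr = 0.1) {
  cluster_map <- cluster_map[!is.na(cluster_map)]
  clusters <- sort(unique(cluster_map))
  path_ids <- vapply(paths, `[[`, "", "path_id")
  consensus_ids <- names(ens$path_confidence)[ens$path_confidence >= conf_threshold]
  st <- paths[path_ids %in% consensus_ids &
                vapply(paths, `[[`, "", "class") == "source_target"]

  regs <- sort(unique(vapply(st, `[[`, "", "regulator")))
  tests <- list()
  for (r in intersect(regs, names(regulator_binding))) {
    bound <- unique(regulator_binding[[r]])
    for (cl in clusters) {
      cl_genes <- names(cluster_map)[cluster_map == cl]
      ov <- length(intersect(bound, cl_genes))
      p <- if (length(bound) && length(cl_genes))
        hypergeom_tail_p(ov, length(bound), length(cl_genes), universe)
      else 1
      tests[[length(tests) + 1]] <- data.frame(
        regulator = r, cluster = cl, overlap = ov, bound = length(bound),
        cluster_size = length(cl_genes), p = p, stringsAsFactors = FALSE)
    }
  }
  enrichment <- if (length(tests)) do.call(rbind, tests)
  else data.frame(regulator = character(), cluster = character(),
                  overlap = integer(), bound = integer(),
                  cluster_size = integer(), p = numeric())
  enrichment$q <- if (nrow(enrichment)) bh_fdr(enrichment$p) else numeric()
  enrichment$enriched <- enrichment$q <= fdr

  retained <- list()
  for (p in st) {
    tgt <- p$terminus
    if (!tgt %in% names(cluster_map)) next
    cl <- cluster_map[[tgt]]
    ok <- any(enrichment$enriched & enrichment$regulator == p$regulator &
                enrichment$cluster == cl)
    if (!ok) next
    p$cluster <- cl
    retained[[length(retained) + 1]] <- p
  }
  if (!length(retained))
    message("no cluster-enriched consensus source-target paths; module subnetwork is empty")

  node_labels <- list()
  for (p in retained) {
    prots <- p$nodes[seq_len(length(p$nodes) - 1L)]
    for (n in prots)
      node_labels[[n]] <- sort(unique(c(node_labels[[n]], p$cluster)))
  }
  structure(list(paths = retained, node_labels = node_labels,
                 cluster_map = cluster_map, enrichment = enrichment,
                 conf_threshold = conf_threshold, fdr = fdr),
            class = "module_subnetwork")
}

#' @export
print.module_subnetwork <- function(x, ...) {
  cat(sprintf("module_subnetwork: %d retained paths over %d labeled nodes (%d enriched regulator-cluster pairs)\n",
              length(x$paths), length(x$node_labels), sum(x$enrichment$enriched)))
  invisible(x)
}

# targets downstream of n along retained paths, with their clusters
.downstream_targets <- function(subnet, n) {
  tg <- character()
  for (p in subnet$paths) {
    k <- match(n, p$nodes)
    if (!is.na(k) && k < length(p$nodes)) tg <- c(tg, p$terminus)
  }
  sort(unique(tg))
}

#' Partition a node's downstream targets by reachable child combination
#'
#' For each target downstream of `n`, the set of `n`'s children (immediate
#' successors along retained paths) through which the target is reachable is
#' computed; targets sharing an identical child set form one partition.
#'
#' @param subnet a `module_subnetwork`
#' @param n node with at least one retained outgoing path
#' @return named list of character vectors: partition key (comma-joined
#'   child set) -> targets
#' @export
partition_by_children <- function(subnet, n) {
  child_sets <- list()
  for (p in subnet$paths) {
    k <- match(n, p$nodes)
    if (is.na(k) || k >= length(p$nodes)) next
    child <- p$nodes[[k + 1L]]
    t <- p$terminus
    child_sets[[t]] <- sort(unique(c(child_sets[[t]], child)))
  }
  if (!length(child_sets)) stop("node ", n, " has no retained outgoing path")
  keys <- vapply(child_sets, paste, "", collapse = ",")
  targets <- names(child_sets)
  out <- lapply(split(targets, keys), sort)
  out[order(names(out))]
}

#' Total bits needed to encode cluster membership of a target set
#'
#' `C(T) = sum_c -|T^c| log2(|T^c| / |T|)`; an empty set costs 0 bits and a
#' pure set (one cluster) also costs 0.
#'
#' @param clusters character vector: the cluster of each target (one cluster
#'   per target; `NA` is an error)
#' @return bits (non-negative)
#' @export
count_bits <- function(clusters) {
  if (!length(clusters)) return(0)
  if (anyNA(clusters)) stop("every target must carry exactly one cluster label")
  n <- length(clusters)
  counts <- table(clusters)
  sum(vapply(counts, function(k) -k * log2(k / n), numeric(1)))
}

#' Information-gain-ratio bifurcation score of a node
#'
#' `I(n) = C(T(n)) - sum_i C(P_i(n))` is the total bits saved by the child
#' partitioning; `S(n)` is the entropy of the partition size proportions
#' (bits per target); `B(n) = I(n) / S(n)`. `B` is defined only when the
#' node lies upstream of both clusters and has more than one partition.
#'
#' @param subnet a `module_subnetwork`
#' @param n candidate node
#' @return object of class `bifurcation_result` with `node`, `targets`,
#'   `partitions`, `C`, `I`, `S`, `B` (NA when undefined, with `reason`)
#' @export
bifurcation_score <- function(subnet, n) {
  targets <- .downstream_targets(subnet, n)
  if (!length(targets)) stop("node ", n, " has no downstream targets")
  cl <- subnet$cluster_map[targets]
  partitions <- partition_by_children(subnet, n)
  C_total <- count_bits(cl)
  C_parts <- vapply(partitions, function(tg) count_bits(subnet$cluster_map[tg]),
                    numeric(1))
  I <- C_total - sum(C_parts)
  sizes <- vapply(partitions, length, 0L)
  props <- sizes / sum(sizes)
  S <- -sum(props * log2(props))
  both <- length(unique(cl)) >= 2
  reason <- NULL
  B <- NA_real_
  if (!both) reason <- "single cluster downstream"
  else if (S == 0) reason <- "single partition (split information 0)"
  else B <- I / S
  structure(list(node = n, targets = targets, clusters = cl,
                 partitions = partitions, C = C_total, I = I, S = S, B = B,
                 reason = reason),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("bifurcation_result %s: |T|=%d partitions=%d C=%.3f I=%.3f S=%.3f B=%s\n",
              x$node, length(x$targets), length(x$partitions), x$C, x$I, x$S,
              ifelse(is.na(x$B), paste0("NA (", x$reason, ")"), sprintf("%.3f", x$B))))
  invisible(x)
}

#' Rank candidate bifurcation points
#'
#' Candidates are nodes upstream of at least one target in each cluster;
#' nodes with undefined scores (single partition) are excluded from the
#' ranking but listed. Ranking is by decreasing `B`, ties broken by node id.
#'
#' @param subnet a `module_subnetwork`
#' @return data.frame `node  n_targets  n_partitions  C  I  S  B  rank`
#'   (excluded candidates carry NA rank)
#' @export
rank_bifurcation_points <- function(subnet) {
  nodes <- sort(names(subnet$node_labels))
  cand <- nodes[vapply(nodes, function(n)
    length(subnet$node_labels[[n]]) >= 2, TRUE)]
  if (!length(cand))
    return(data.frame(node = character(), n_targets = integer(),
                      n_partitions = integer(), C = numeric(), I = numeric(),
                      S = numeric(), B = numeric(), rank = integer()))
  rows <- lapply(cand, function(n) {
    r <- bifurcation_score(subnet, n)
    data.frame(node = n, n_targets = length(r$targets),
               n_partitions = length(r$partitions),
               C = r$C, I = r$I, S = r$S, B = r$B, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ranked <- !is.na(out$B)
  ord <- order(-out$B[ranked], out$node[ranked])
  out$rank <- NA_integer_
  out$rank[ranked][ord] <- seq_len(sum(ranked))
  out[order(is.na(out$rank), out$rank, out$node), , drop = FALSE]
}
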