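# Seed-deterministic synthetic study generator: a background network with
# heavy-tailed degree structure, a planted true signaling subnetwork
# (sources -> kinase cascades -> TF/RBP regulators -> bound target genes,
# plus receptor chains), and partial-coverage hit annotations. Every other
# module is testable against the planted truth without any downloads.
#
# Defaults emulate the statistical shape of the real study inputs at desk
# scale: a few hundred proteins with preferential-attachment degrees, a
# modest TF/RBP layer with cluster-biased regulons (induced vs repressed
# modules), a handful of interrogated sources each explained by short
# kinase cascades, and evidence hits drawn from the planted interior nodes.

#' Generate a random background network with a regulatory layer
#'
#' Protein-protein structure comes from a preferential-attachment graph
#' (heavy-tailed degrees, so hub effects in permuted baselines are
#' exercised); each protein edge is directed (kinase-substrate) with
#' probability `directed_fraction`, otherwise undirected (protein-protein).
#' A designated TF/RBP subset binds gene/mRNA nodes with cluster-biased
#' regulons: genes are split into induced / repressed / unassigned modules
#' and each regulator draws `tf_cluster_affinity` of its regulon from its
#' own module.
#'
#' @param n_proteins,n_genes node counts (defaults 200, 120)
#' @param n_tfs number of TF/RBP regulators (default 14)
#' @param mean_degree target mean protein degree (default 4)
#' @param directed_fraction probability a protein edge is directed (default 0.5)
#' @param rbp_fraction fraction of regulators acting on mRNA
#'   (protein-RNA edges; default 0.2)
#' @param cluster_fractions fractions of genes in the induced and repressed
#'   modules (default 0.4 each; the rest are unassigned)
#' @param tf_cluster_affinity fraction of a regulon drawn from the
#'   regulator's own module (default 0.85)
#' @param binding_range regulon size range (default 8 to 20 genes)
#' @param seed integer seed; identical seeds give identical networks
#' @return a [background_network()] with attributes `tf_nodes` (regulator
#'   ids) and `cluster_map` (named vector gene -> `"induced"`/`"repressed"`)
#' @export
generate_background <- function(n_proteins = 200, n_genes = 120, n_tfs = 14,
                                mean_degree = 4, directed_fraction = 0.5,
                                rbp_fraction = 0.2,
                                cluster_fractions = c(induced = 0.4, repressed = 0.4),
                                tf_cluster_affinity = 0.85,
                                binding_range = c(8, 20),
                                seed = 1) {
  stopifnot(n_proteins > 2, n_genes > 2, n_tfs >= 1, mean_degree > 0,
            directed_fraction >= 0, directed_fraction <= 1)
  set.seed(seed)
  prot <- sprintf("P%03d", seq_len(n_proteins))
  genes <- sprintf("G%03d", seq_len(n_genes))

  g <- igraph::sample_pa(n_proteins, m = max(1L, round(mean_degree / 2)),
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- prot[el[, 1]]; b <- prot[el[, 2]]
  directed <- stats::runif(nrow(el)) < directed_fraction
  flip <- directed & stats::runif(nrow(el)) < 0.5
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  prot_edges <- data.frame(node_a = a, node_b = b, directed = directed,
                           class = ifelse(directed, "kinase-substrate", "protein-protein"),
                           stringsAsFactors = FALSE)

  tfs <- sort(sample(prot, n_tfs))
  is_rbp <- stats::setNames(stats::runif(n_tfs) < rbp_fraction, tfs)
  n_ind <- round(cluster_fractions[["induced"]] * n_genes)
  n_rep <- round(cluster_fractions[["repressed"]] * n_genes)
  shuffled <- sample(genes)
  cluster_map <- stats::setNames(
    c(rep("induced", n_ind), rep("repressed", n_rep)),
    shuffled[seq_len(n_ind + n_rep)])
  tf_cluster <- stats::setNames(
    rep_len(c("induced", "repressed"), n_tfs)[sample.int(n_tfs)], tfs)

  reg_edges <- do.call(rbind, lapply(tfs, function(tf) {
    size <- sample(binding_range[[1]]:binding_range[[2]], 1)
    own <- names(cluster_map)[cluster_map == tf_cluster[[tf]]]
    other <- setdiff(genes, own)
    n_own <- min(round(tf_cluster_affinity * size), length(own))
    bound <- c(sample(own, n_own), sample(other, min(size - n_own, length(other))))
    data.frame(node_a = tf, node_b = unique(bound), directed = TRUE,
               class = if (is_rbp[[tf]]) "protein-RNA" else "protein-DNA",
               stringsAsFactors = FALSE)
  }))

  nodes <- data.frame(node = c(prot, genes),
                      kind = c(rep("protein", n_proteins),
                               rep("gene_or_mrna", n_genes)),
                      stringsAsFactors = FALSE)
  net <- background_network(nodes, rbind(prot_edges, reg_edges))
  attr(net, "tf_nodes") <- tfs
  attr(net, "cluster_map") <- cluster_map
  net
}

#' Plant a true subnetwork and matching evidence in a background network
#'
#' Selects sources, plants directed kinase cascades from each source to
#' `paths_per_source` regulators (reusing existing edges where possible,
#' adding directed kinase-substrate edges otherwise; all routes of one
#' source share one length drawn from `path_length_range`, counted in
#' edges of the source-to-regulator segment), plants one short receptor
#' chain per receptor, sets each source's targets to the genes bound by its
#' planted regulators plus a `target_noise` fraction of spurious random
#' genes, and marks `hit_coverage` of the planted interior nodes as fitness
#' or phospho hits (sources and regulators are never hits).
#'
#' @param net a network from [generate_background()]
#' @param n_sources number of sources (default 5)
#' @param paths_per_source planted routes per source (default 2)
#' @param path_length_range range of segment lengths in edges (default 2:3,
#'   i.e. 1-2 intermediate kinases)
#' @param hit_coverage fraction of planted interior nodes annotated as hits
#'   (default 1)
#' @param target_noise fraction of each target set that is spurious
#'   (default 0; 1 replaces the set with random genes of equal size)
#' @param n_receptors receptor chains to plant (default 1)
#' @param seed integer seed
#' @return list with `net` (the network including any added planted edges,
#'   attributes preserved), `evidence` (an [evidence_set()]), `truth`
#'   (planted nodes, routes, regulators per source, receptor chains), and
#'   `labels` (a [label_set()]: planted proteins positive, all other
#'   proteins negative)
#' @export
plant_truth_and_evidence <- function(net, n_sources = 5, paths_per_source = 2,
                                     path_length_range = c(2, 3),
                                     hit_coverage = 1, target_noise = 0,
                                     n_receptors = 1, seed = 1) {
  set.seed(seed)
  tfs <- attr(net, "tf_nodes")
  if (is.null(tfs) || !length(tfs))
    stop("network has no TF/RBP layer; generate it with generate_background()")
  binding <- network_binding_map(net)
  prot <- protein_nodes(net)
  genes <- gene_nodes(net)
  pool <- setdiff(prot, tfs)
  sources <- sort(sample(pool, n_sources))
  reserved <- c(sources, tfs)

  existing <- paste(net$edges$node_a, net$edges$node_b)
  und_pairs <- with(net$edges[!net$edges$directed, ],
                    paste(node_a, node_b))
  new_edges <- list()
  # connect u -> v with a directed interaction: reuse a forward directed
  # edge or add a kinase-substrate edge. A pair already joined by an
  # undirected edge cannot take a directed one (the network forbids mixed
  # directedness), so such a step fails and the route is resampled: planted
  # cascades are always fully directed and never contend with other paths
  # for an undirected edge's orientation.
  connect <- function(u, v) {
    key <- paste(min(u, v), max(u, v))
    if (key %in% und_pairs) return(FALSE)
    if (!paste(u, v) %in% existing) {
      new_edges[[length(new_edges) + 1]] <<- data.frame(
        node_a = u, node_b = v, directed = TRUE, class = "kinase-substrate",
        stringsAsFactors = FALSE)
      existing <<- c(existing, paste(u, v))
    }
    TRUE
  }
  plant_route <- function(from, to, n_edges, max_tries = 25L) {
    n_mid <- n_edges - 1L
    for (try in seq_len(max_tries)) {
      saved_edges <- new_edges; saved_existing <- existing
      mids <- if (n_mid > 0)
        sample(setdiff(pool, c(reserved, from, to)), n_mid)
      else character()
      route <- c(from, mids, to)
      ok <- TRUE
      for (k in seq_len(length(route) - 1L)) {
        if (!connect(route[[k]], route[[k + 1L]])) { ok <- FALSE; break }
      }
      if (ok) return(route)
      new_edges <<- saved_edges; existing <<- saved_existing
    }
    stop("could not plant a fully directed route from ", from, " to ", to)
  }

  routes <- list(); regs_by_source <- list()
  for (s in sources) {
    L <- if (length(path_length_range) == 1) path_length_range
         else sample(seq(path_length_range[[1]], path_length_range[[2]]), 1)
    regs <- sample(tfs, min(paths_per_source, length(tfs)))
    regs_by_source[[s]] <- sort(regs)
    for (f in regs) routes[[length(routes) + 1]] <- plant_route(s, f, L)
  }

  receptor_chains <- list()
  receptors <- data.frame(receptor = character(), source = character(),
                          stringsAsFactors = FALSE)
  if (n_receptors > 0) {
    used <- unique(unlist(routes, use.names = FALSE))
    rec_pool <- setdiff(pool, c(used, reserved))
    recs <- sample(rec_pool, n_receptors)
    for (r in recs) {
      s <- sample(sources, 1)
      chain <- plant_route(r, s, 2L)
      receptor_chains[[length(receptor_chains) + 1]] <- chain
      receptors <- rbind(receptors,
                         data.frame(receptor = r, source = s, stringsAsFactors = FALSE))
    }
  }

  if (length(new_edges)) {
    net2 <- background_network(net$nodes,
                               rbind(net$edges[, c("node_a", "node_b", "directed", "class")],
                                     do.call(rbind, new_edges)))
    attr(net2, "tf_nodes") <- attr(net, "tf_nodes")
    attr(net2, "cluster_map") <- attr(net, "cluster_map")
    net <- net2
  }

  # target_noise is the fraction of each target set that is spurious:
  # that many clean targets are displaced by random other genes, so the
  # set size is preserved and noise = 1 means full replacement
  targets_by_source <- list()
  for (s in sources) {
    clean <- sort(unique(unlist(binding[regs_by_source[[s]]], use.names = FALSE)))
    if (target_noise > 0) {
      n_spur <- min(round(target_noise * length(clean)),
                    length(setdiff(genes, clean)))
      kept <- if (n_spur < length(clean))
        sample(clean, length(clean) - n_spur) else character()
      spurious <- sample(setdiff(genes, clean), n_spur)
      tg <- sort(c(kept, spurious))
    } else tg <- clean
    targets_by_source[[s]] <- tg
  }

  all_route_nodes <- unique(unlist(c(routes, receptor_chains), use.names = FALSE))
  interior <- setdiff(all_route_nodes, c(sources, tfs, receptors$receptor))
  n_hits <- round(hit_coverage * length(interior))
  hit_sel <- if (n_hits > 0) sample(interior, n_hits) else character()
  n_fit <- ceiling(length(hit_sel) / 2)
  fitness_hits <- sort(hit_sel[seq_len(n_fit)])
  phospho_hits <- sort(setdiff(hit_sel, fitness_hits))

  planted <- sort(unique(c(sources, unlist(regs_by_source, use.names = FALSE),
                           interior, receptors$receptor)))
  truth <- list(nodes = planted, routes = routes,
                regulators_by_source = regs_by_source,
                receptor_chains = receptor_chains,
                hit_coverage = hit_coverage, target_noise = target_noise)
  labels <- label_set(positives = planted,
                      negatives = setdiff(prot, planted))
  evidence <- evidence_set(sources = sources,
                           targets_by_source = targets_by_source,
                           fitness_hits = fitness_hits,
                           phospho_hits = phospho_hits,
                           receptors = receptors,
                           regulator_binding = binding,
                           stress_bound_regulators = character())
  list(net = net, evidence = evidence, truth = truth, labels = labels)
}

#' Generate a complete synthetic study (background plus planted truth)
#'
#' @param seed integer seed driving both the background and the planting
#' @param ... parameters forwarded to [generate_background()] and
#'   [plant_truth_and_evidence()] (matched by name)
#' @return as [plant_truth_and_evidence()], plus `cluster_map`
#' @export
generate_study <- function(seed = 1, ...) {
  dots <- list(...)
  bg_formals <- names(formals(generate_background))
  pl_formals <- setdiff(names(formals(plant_truth_and_evidence)), c("net", "seed"))
  net <- do.call(generate_background,
                 c(list(seed = seed), dots[names(dots) %in% bg_formals]))
  out <- do.call(plant_truth_and_evidence,
                 c(list(net = net, seed = seed + 1L),
                   dots[names(dots) %in% pl_formals]))
  out$cluster_map <- attr(out$net, "cluster_map")
  out
}

#' Write a self-contained synthetic fixture directory
#'
#' Emits the network tables, all evidence TSVs, the gene module table, and
#' the planted truth as JSON; the directory round-trips through the package
#' loaders and supports a full pipeline run.
#'
#' @param net a [background_network()]
#' @param ev an [evidence_set()]
#' @param truth planted-truth list from [plant_truth_and_evidence()]
#' @param dir output directory (created if absent)
#' @export
write_fixture <- function(net, ev, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_background_network(net, file.path(dir, "edges.tsv"),
                           file.path(dir, "nodes.tsv"))
  write_evidence_set(ev, dir)
  cm <- attr(net, "cluster_map")
  if (!is.null(cm))
    utils::write.table(data.frame(gene = names(cm), cluster = cm),
                       file.path(dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
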