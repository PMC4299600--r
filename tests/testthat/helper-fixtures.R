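# Shared fixtures: tiny hand-built networks and a random small-instance
# generator used by the property and oracle tests.

# Chain S1 -> M1 -> F1 with regulator F1 binding G1, G2; one undirected
# edge H1 -- S1 for a fitness hit.
tiny_network <- function() {
  nodes <- data.frame(
    node = c("S1", "M1", "F1", "G1", "G2", "H1"),
    kind = c("protein", "protein", "protein", "gene_or_mrna", "gene_or_mrna", "protein"))
  edges <- data.frame(
    node_a = c("S1", "M1", "F1", "F1", "H1"),
    node_b = c("M1", "F1", "G1", "G2", "S1"),
    directed = c(1, 1, 1, 1, 0),
    class = c("kinase-substrate", "kinase-substrate", "protein-DNA",
              "protein-DNA", "protein-protein"))
  background_network(nodes, edges)
}

tiny_evidence <- function(net = tiny_network()) {
  evidence_set(
    sources = "S1",
    targets_by_source = list(S1 = c("G1", "G2")),
    fitness_hits = "H1",
    regulator_binding = list(F1 = c("G1", "G2")))
}

# random mixed-direction protein network with a small regulatory layer;
# used for path-enumeration and IP oracle property tests
random_small_network <- function(n_prot = 8, n_genes = 3, p_edge = 0.35,
                                 directed_frac = 0.5, seed = 1) {
  set.seed(seed)
  prot <- sprintf("P%02d", seq_len(n_prot))
  genes <- sprintf("G%02d", seq_len(n_genes))
  rows <- list()
  for (i in seq_len(n_prot - 1)) for (j in seq.int(i + 1, n_prot)) {
    if (stats::runif(1) > p_edge) next
    dird <- stats::runif(1) < directed_frac
    a <- prot[[i]]; b <- prot[[j]]
    if (dird && stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
    rows[[length(rows) + 1]] <- data.frame(
      node_a = a, node_b = b, directed = dird,
      class = if (dird) "kinase-substrate" else "protein-protein")
  }
  tfs <- sample(prot, min(2, n_prot))
  for (tf in tfs) for (g in sample(genes, sample.int(n_genes, 1))) {
    rows[[length(rows) + 1]] <- data.frame(
      node_a = tf, node_b = g, directed = TRUE, class = "protein-DNA")
  }
  edges <- unique(do.call(rbind, rows))
  nodes <- data.frame(node = c(prot, genes),
                      kind = c(rep("protein", n_prot), rep("gene_or_mrna", n_genes)))
  net <- background_network(nodes, edges)
  attr(net, "tf_nodes") <- sort(tfs)
  net
}

# random small IP instance: enumerate candidate paths on a random network
# for randomly chosen evidence, then subsample at most max_paths paths
# (keeping receptor pairs out so build_ip never rejects)
random_ip_instance <- function(seed, max_paths = 12) {
  set.seed(seed)
  net <- random_small_network(n_prot = sample(5:8, 1), n_genes = 2,
                              p_edge = 0.45, seed = seed + 1000)
  prot <- protein_nodes(net)
  binding <- network_binding_map(net)
  tfs <- names(binding)
  if (!length(tfs)) return(NULL)
  sources <- sample(setdiff(prot, tfs), min(2, length(setdiff(prot, tfs))))
  if (!length(sources)) return(NULL)
  targets <- lapply(stats::setNames(sources, sources), function(s)
    unique(unlist(binding, use.names = FALSE)))
  hits <- sample(setdiff(prot, sources), min(2, length(setdiff(prot, sources))))
  ev <- evidence_set(sources = sources, targets_by_source = targets,
                     fitness_hits = hits[1],
                     phospho_hits = if (length(hits) > 1) hits[2] else character(),
                     regulator_binding = binding)
  paths <- list()
  for (s in sources) {
    paths <- c(paths, suppressWarnings(build_source_target_paths(
      net, s, targets[[s]], tfs, binding, max_intermediates = 2)))
  }
  paths <- c(paths, build_auxiliary_paths(net, ev))
  if (!length(paths)) return(NULL)
  if (length(paths) > max_paths) {
    # keep a deterministic subsample; mandatory coverage is whatever survives
    paths <- paths[sort(sample(seq_along(paths), max_paths))]
  }
  suppressWarnings(model <- build_ip(paths, net, ev))
  list(net = net, ev = ev, paths = paths, model = model)
}

# hub-and-spoke network: degree-1 spoke proteins can reach the TF layer only
# through a few hub proteins, so any degree-matched permuted evidence routes
# its paths through the hubs while specific spokes are rarely drawn
hub_spoke_fixture <- function(n_spokes = 60, n_hubs = 3, n_tfs = 4,
                              n_genes = 30, seed = 1) {
  set.seed(seed)
  spokes <- sprintf("P%02d", seq_len(n_spokes))
  hubs <- sprintf("H%d", seq_len(n_hubs))
  tfs <- sprintf("T%d", seq_len(n_tfs))
  genes <- sprintf("G%02d", seq_len(n_genes))
  edges <- rbind(
    data.frame(node_a = spokes, node_b = sample(hubs, n_spokes, replace = TRUE),
               directed = 1, class = "kinase-substrate"),
    expand.grid(node_a = hubs, node_b = tfs, stringsAsFactors = FALSE) |>
      transform(directed = 1, class = "kinase-substrate"),
    do.call(rbind, lapply(tfs, function(tf)
      data.frame(node_a = tf, node_b = sample(genes, 8),
                 directed = 1, class = "protein-DNA")))
  )
  nodes <- data.frame(
    node = c(spokes, hubs, tfs, genes),
    kind = c(rep("protein", n_spokes + n_hubs + n_tfs),
             rep("gene_or_mrna", n_genes)))
  net <- background_network(nodes, edges)
  binding <- network_binding_map(net)
  sources <- sample(spokes, 3)
  targets <- lapply(stats::setNames(sources, sources), function(s)
    unique(unlist(binding[sample(tfs, 2)], use.names = FALSE)))
  ev <- evidence_set(sources = sources, targets_by_source = targets,
                     regulator_binding = binding)
  list(net = net, ev = ev, hubs = hubs, sources = sources)
}
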