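# Background interaction network and experimental evidence containers.
#
# A gene may be represented by two nodes: one for the protein and one for the
# DNA/mRNA that is regulated ("gene_or_mrna" kind). Gene/mRNA nodes are
# terminal targets: they never carry outgoing edges, so undirected edges may
# not touch them. Undirected edges are stored once under a canonical key
# (lexicographically smaller node first); the traversal direction of an
# undirected edge is inferred per solution by the IP, never stored on the
# network itself.

NODE_KINDS <- c("protein", "gene_or_mrna")
EDGE_CLASSES <- c("protein-protein", "kinase-substrate", "protein-DNA", "protein-RNA")

#' Construct a background interaction network
#'
#' @param nodes data.frame with columns `node` (identifier) and `kind`
#'   (`"protein"` or `"gene_or_mrna"`).
#' @param edges data.frame with columns `node_a`, `node_b`, `directed`
#'   (logical or 0/1) and `class` (one of `"protein-protein"`,
#'   `"kinase-substrate"`, `"protein-DNA"`, `"protein-RNA"`). Directed edges
#'   run `node_a -> node_b`; undirected edges are canonicalized so that
#'   `node_a < node_b` and duplicate `(b, a)` presentations collapse.
#'
#' @return An object of class `background_network` with components `nodes`,
#'   `edges` (with an `edge_id` column: `"A>B"` for directed, `"A--B"` for
#'   undirected) and a traversal arc index used by the path enumerator.
#' @export
background_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("node", "kind") %in% names(nodes)),
            all(c("node_a", "node_b", "directed", "class") %in% names(edges)))
  nodes$node <- as.character(nodes$node)
  nodes$kind <- as.character(nodes$kind)
  if (anyDuplicated(nodes$node))
    stop("duplicate node identifiers in node table")
  bad_kind <- setdiff(unique(nodes$kind), NODE_KINDS)
  if (length(bad_kind))
    stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "))

  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  edges$directed <- as.logical(as.integer(as.logical(edges$directed)))
  edges$class <- as.character(edges$class)
  bad_class <- setdiff(unique(edges$class), EDGE_CLASSES)
  if (length(bad_class))
    stop("unknown interaction class(es): ", paste(bad_class, collapse = ", "))

  unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$node)
  if (length(unknown)) {
    offender <- edges[edges$node_a %in% unknown | edges$node_b %in% unknown, , drop = FALSE][1, ]
    stop(sprintf("edge (%s, %s) references undeclared node(s): %s",
                 offender$node_a, offender$node_b,
                 paste(unknown, collapse = ", ")))
  }
  if (any(edges$node_a == edges$node_b))
    stop("self-loops are not allowed")

  # canonicalize undirected records
  flip <- !edges$directed & edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  edges <- unique(edges)

  pair_key <- ifelse(edges$node_a < edges$node_b,
                     paste(edges$node_a, edges$node_b, sep = "\r"),
                     paste(edges$node_b, edges$node_a, sep = "\r"))
  mixed <- tapply(edges$directed, pair_key, function(d) any(d) && !all(d))
  if (any(mixed)) {
    bad <- sub("\r", ", ", names(mixed)[mixed][1])
    stop(sprintf("conflicting directedness for node pair (%s)", bad))
  }
  dup_und <- duplicated(pair_key) & !edges$directed
  if (any(dup_und))
    stop("conflicting duplicate undirected records for pair (",
         sub("\r", ", ", pair_key[dup_und][1]), ")")

  kind <- stats::setNames(nodes$kind, nodes$node)
  gene_out <- edges$directed & kind[edges$node_a] == "gene_or_mrna"
  gene_und <- !edges$directed & (kind[edges$node_a] == "gene_or_mrna" |
                                   kind[edges$node_b] == "gene_or_mrna")
  if (any(gene_out))
    stop("gene/mRNA node has an outgoing edge: ",
         edges$node_a[gene_out][1])
  if (any(gene_und))
    stop("undirected edge touches a gene/mRNA node (would give it an outgoing edge)")

  edges$edge_id <- ifelse(edges$directed,
                          paste0(edges$node_a, ">", edges$node_b),
                          paste0(edges$node_a, "--", edges$node_b))
  edges <- edges[order(edges$edge_id), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL

  net <- structure(list(nodes = nodes, edges = edges), class = "background_network")
  net$arcs <- .build_arcs(net)
  net
}

# Traversal arcs: directed edges one arc; undirected edges two arcs.
# `forward` marks traversal in the canonical (stored) orientation.
.build_arcs <- function(net) {
  e <- net$edges
  d <- e[e$directed, , drop = FALSE]
  u <- e[!e$directed, , drop = FALSE]
  arcs <- data.frame(
    from = c(d$node_a, u$node_a, u$node_b),
    to = c(d$node_b, u$node_b, u$node_a),
    edge_id = c(d$edge_id, u$edge_id, u$edge_id),
    undirected = c(rep(FALSE, nrow(d)), rep(TRUE, 2 * nrow(u))),
    forward = c(rep(TRUE, nrow(d) + nrow(u)), rep(FALSE, nrow(u))),
    stringsAsFactors = FALSE
  )
  arcs <- arcs[order(arcs$from, arcs$to, arcs$edge_id), , drop = FALSE]
  rownames(arcs) <- NULL
  split(arcs, factor(arcs$from, levels = sort(net$nodes$node)), drop = FALSE)
}

#' @export
print.background_network <- function(x, ...) {
  nd <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  cat(sprintf("background_network: %d proteins, %d gene/mRNA nodes; %d directed + %d undirected edges\n",
              nd[["protein"]], nd[["gene_or_mrna"]],
              sum(x$edges$directed), sum(!x$edges$directed)))
  invisible(x)
}

#' Node kinds as a named vector
#' @param net a `background_network`
#' @return named character vector node -> kind
#' @export
node_kinds <- function(net) stats::setNames(net$nodes$kind, net$nodes$node)

#' Protein nodes of a network
#' @param net a `background_network`
#' @export
protein_nodes <- function(net) net$nodes$node[net$nodes$kind == "protein"]

#' Gene/mRNA nodes of a network
#' @param net a `background_network`
#' @export
gene_nodes <- function(net) net$nodes$node[net$nodes$kind == "gene_or_mrna"]

#' Total degree of every protein node
#'
#' Counts incident edges of any class or orientation.
#' @param net a `background_network`
#' @return named integer vector over protein nodes
#' @export
protein_degrees <- function(net) {
  prot <- protein_nodes(net)
  ends <- c(net$edges$node_a, net$edges$node_b)
  deg <- table(factor(ends, levels = prot))
  stats::setNames(as.integer(deg), prot)
}

#' Regulator binding map implied by the network's regulatory edges
#'
#' @param net a `background_network`
#' @return named list: regulator protein -> character vector of bound
#'   gene/mRNA nodes (protein-DNA and protein-RNA edges).
#' @export
network_binding_map <- function(net) {
  e <- net$edges
  reg <- e[e$class %in% c("protein-DNA", "protein-RNA"), , drop = FALSE]
  if (!nrow(reg)) return(list())
  lapply(split(reg$node_b, reg$node_a), unique)
}

#' Load a background network from TSV tables
#'
#' The edge table has header `node_a  node_b  directed  class` (`directed` is
#' 1/0); the node table has header `node  kind`.
#'
#' @param edge_file,node_file paths to the TSV files
#' @return a validated [background_network()]
#' @export
load_background_network <- function(edge_file, node_file) {
  edges <- utils::read.delim(edge_file, stringsAsFactors = FALSE, colClasses = "character")
  nodes <- utils::read.delim(node_file, stringsAsFactors = FALSE, colClasses = "character")
  edges$directed <- as.integer(edges$directed)
  background_network(nodes, edges)
}

#' Write a background network as TSV tables
#' @param net a `background_network`
#' @param edge_file,node_file output paths
#' @export
write_background_network <- function(net, edge_file, node_file) {
  e <- net$edges[, c("node_a", "node_b", "directed", "class")]
  e$directed <- as.integer(e$directed)
  utils::write.table(e, edge_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes, node_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edge_file, node_file))
}

#' Construct an evidence set
#'
#' @param sources character vector of source proteins (profiled regulator
#'   mutants).
#' @param targets_by_source named list mapping each source to its dysregulated
#'   gene/mRNA targets.
#' @param fitness_hits,phospho_hits character vectors of protein nodes.
#' @param receptors data.frame with columns `receptor`, `source`: each
#'   membrane receptor paired with the downstream source it must reach.
#' @param regulator_binding named list: TF/RBP protein -> bound gene/mRNA
#'   nodes.
#' @param stress_bound_regulators TF/RBPs included as candidates regardless of
#'   enrichment (known to bind targets under the stress condition).
#' @return an object of class `evidence_set`
#' @export
evidence_set <- function(sources,
                         targets_by_source,
                         fitness_hits = character(),
                         phospho_hits = character(),
                         receptors = data.frame(receptor = character(), source = character()),
                         regulator_binding = list(),
                         stress_bound_regulators = character()) {
  sources <- as.character(sources)
  if (!all(sources %in% names(targets_by_source)))
    stop("every source needs an entry in targets_by_source")
  receptors <- as.data.frame(receptors, stringsAsFactors = FALSE)
  if (nrow(receptors) && !all(receptors$source %in% sources))
    stop("receptors may only be paired with declared sources")
  structure(list(
    sources = sources,
    targets_by_source = lapply(targets_by_source, as.character)[sources],
    fitness_hits = as.character(fitness_hits),
    phospho_hits = as.character(phospho_hits),
    receptors = receptors,
    regulator_binding = lapply(regulator_binding, as.character),
    stress_bound_regulators = as.character(stress_bound_regulators)
  ), class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("evidence_set: %d sources, %d fitness hits, %d phospho hits, %d receptor pairs, %d regulators with binding data\n",
              length(x$sources), length(x$fitness_hits), length(x$phospho_hits),
              nrow(x$receptors), length(x$regulator_binding)))
  invisible(x)
}

#' Validate an evidence set against a background network
#'
#' Reporting operation: it never errors. The report lists evidence nodes
#' absent from the network, sources with empty target sets, and targets
#' without any incident regulatory edge. An empty report means the evidence is
#' usable as-is.
#'
#' @param net a `background_network`
#' @param ev an `evidence_set`
#' @return data.frame with columns `category`, `item`, `message`; zero rows
#'   when valid.
#' @export
validate_evidence <- function(net, ev) {
  rows <- list()
  add <- function(category, item, message) {
    rows[[length(rows) + 1]] <<- data.frame(category = category, item = item,
                                            message = message, stringsAsFactors = FALSE)
  }
  prot <- protein_nodes(net)
  genes <- gene_nodes(net)
  for (s in setdiff(ev$sources, prot))
    add("missing_source", s, "source not a protein node of the network")
  for (f in setdiff(ev$fitness_hits, prot))
    add("missing_fitness_hit", f, "fitness hit not a protein node of the network")
  for (h in setdiff(ev$phospho_hits, prot))
    add("missing_phospho_hit", h, "phospho hit not a protein node of the network")
  for (r in setdiff(ev$receptors$receptor, prot))
    add("missing_receptor", r, "receptor not a protein node of the network")
  for (s in ev$sources) {
    tg <- ev$targets_by_source[[s]]
    if (!length(tg)) add("empty_target_set", s, "source has an empty target set")
    for (t in setdiff(tg, genes))
      add("missing_target", t, sprintf("target of %s not a gene/mRNA node", s))
  }
  bound <- unique(unlist(network_binding_map(net), use.names = FALSE))
  all_targets <- unique(unlist(ev$targets_by_source, use.names = FALSE))
  for (t in setdiff(intersect(all_targets, genes), bound))
    add("unbound_target", t, "target has no incident regulatory edge")
  if (!length(rows))
    return(data.frame(category = character(), item = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# --- evidence TSV round trip -------------------------------------------------

.read_list <- function(file) {
  if (!file.exists(file) || file.size(file) == 0) return(character())
  x <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")[[1]]
  x[nzchar(x)]
}

.read_pairs <- function(file, names) {
  if (!file.exists(file) || file.size(file) == 0)
    return(stats::setNames(data.frame(character(), character(), stringsAsFactors = FALSE), names))
  x <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  stats::setNames(x[, 1:2], names)
}

#' Load an evidence set from a directory of TSV files
#'
#' Expected files (single-column lists unless noted): `sources.tsv`,
#' `fitness_hits.tsv`, `phospho_hits.tsv`, `stress_bound_regulators.tsv`, and
#' two-column tables `source_targets.tsv` (source, target),
#' `receptors.tsv` (receptor, source), `regulator_binding.tsv`
#' (regulator, target). Missing optional files yield empty sets.
#'
#' @param dir directory containing the TSV files
#' @return an `evidence_set`
#' @export
load_evidence_set <- function(dir) {
  st <- .read_pairs(file.path(dir, "source_targets.tsv"), c("source", "target"))
  sources <- .read_list(file.path(dir, "sources.tsv"))
  tbs <- lapply(stats::setNames(sources, sources),
                function(s) unique(st$target[st$source == s]))
  rb <- .read_pairs(file.path(dir, "regulator_binding.tsv"), c("regulator", "target"))
  evidence_set(
    sources = sources,
    targets_by_source = tbs,
    fitness_hits = .read_list(file.path(dir, "fitness_hits.tsv")),
    phospho_hits = .read_list(file.path(dir, "phospho_hits.tsv")),
    receptors = .read_pairs(file.path(dir, "receptors.tsv"), c("receptor", "source")),
    regulator_binding = lapply(split(rb$target, rb$regulator), unique),
    stress_bound_regulators = .read_list(file.path(dir, "stress_bound_regulators.tsv"))
  )
}

#' Write an evidence set as TSV files
#' @param ev an `evidence_set`
#' @param dir output directory (created if absent)
#' @export
write_evidence_set <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- function(x, file) writeLines(x, file.path(dir, file))
  wp <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  wl(ev$sources, "sources.tsv")
  wl(ev$fitness_hits, "fitness_hits.tsv")
  wl(ev$phospho_hits, "phospho_hits.tsv")
  wl(ev$stress_bound_regulators, "stress_bound_regulators.tsv")
  st <- do.call(rbind, lapply(ev$sources, function(s)
    if (length(ev$targets_by_source[[s]]))
      data.frame(source = s, target = ev$targets_by_source[[s]], stringsAsFactors = FALSE)))
  if (is.null(st)) st <- data.frame(source = character(), target = character())
  wp(st, "source_targets.tsv")
  wp(ev$receptors, "receptors.tsv")
  rb <- do.call(rbind, lapply(names(ev$regulator_binding), function(r)
    if (length(ev$regulator_binding[[r]]))
      data.frame(regulator = r, target = ev$regulator_binding[[r]], stringsAsFactors = FALSE)))
  if (is.null(rb)) rb <- data.frame(regulator = character(), target = character())
  wp(rb, "regulator_binding.tsv")
  invisible(dir)
}

# --- exports -----------------------------------------------------------------

#' Export a network (or consensus subgraph) in SIF format
#'
#' @param net a `background_network`
#' @param file output path
#' @param edge_ids optional subset of edge ids to export
#' @export
export_sif <- function(net, file, edge_ids = NULL) {
  e <- net$edges
  if (!is.null(edge_ids)) e <- e[e$edge_id %in% edge_ids, , drop = FALSE]
  sif <- data.frame(node_a = e$node_a, relation = e$class, node_b = e$node_b)
  utils::write.table(sif, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Export a network (or consensus subgraph) as GraphML
#'
#' @inheritParams export_sif
#' @export
export_graphml <- function(net, file, edge_ids = NULL) {
  e <- net$edges
  if (!is.null(edge_ids)) e <- e[e$edge_id %in% edge_ids, , drop = FALSE]
  keep <- unique(c(e$node_a, e$node_b))
  nodes <- net$nodes[net$nodes$node %in% keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$node_a, to = e$node_b,
                   class = e$class, directed = e$directed),
    directed = TRUE,
    vertices = data.frame(name = nodes$node, kind = nodes$kind)
  )
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
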