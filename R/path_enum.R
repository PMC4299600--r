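# Enumeration of the four classes of directed, acyclic candidate paths that
# are the raw material of the integer program:
#   source_target   source -> ... -> TF/RBP -> target gene/mRNA
#   hit_source      fitness hit -> ... -> source      (<= 1 intermediate)
#   source_source   source_i -> ... -> source_j       (<= 1 intermediate)
#   receptor_source receptor -> ... -> source         (<= 4 intermediates)
#
# Every path is simple, traverses directed edges forward only, and records
# the traversal orientation it requires for each undirected edge. Gene/mRNA
# nodes cannot be interior nodes (they have no outgoing edges). Paths are
# emitted in lexicographic node-sequence order, which makes every downstream
# stage deterministic.

.new_path <- function(class, nodes, edges, dir, regulator = NA_character_) {
  list(path_id = paste0(class, ":", paste(nodes, collapse = ",")),
       class = class, nodes = nodes, edges = edges, dir = dir,
       origin = nodes[[1]], terminus = nodes[[length(nodes)]],
       regulator = regulator)
}

#' Enumerate bounded simple paths from an origin to a set of termini
#'
#' Depth-first search over the mixed directed/undirected network: directed
#' edges are traversed forward only; each undirected edge traversal is
#' annotated with the orientation the path requires. A path may pass through
#' a terminus on its way to another (interior visits are allowed); gene/mRNA
#' nodes are terminal by construction.
#'
#' @param net a [background_network()]
#' @param origin start node
#' @param termini character vector of admissible end nodes
#' @param max_edges maximum number of edges per path (>= 1)
#' @param class path class tag recorded on the results
#' @return list of candidate paths (possibly empty), each a list with
#'   `path_id`, `class`, `nodes`, `edges`, `dir` (named vector: undirected
#'   edge id -> `"u>v"` traversal), `origin`, `terminus`.
#' @export
enumerate_bounded_paths <- function(net, origin, termini, max_edges,
                                    class = "generic") {
  stopifnot(max_edges >= 1)
  if (!origin %in% net$nodes$node) stop("origin not in network: ", origin)
  missing_t <- setdiff(termini, net$nodes$node)
  if (length(missing_t)) stop("termini not in network: ", paste(missing_t, collapse = ", "))
  out <- list()
  arcs <- net$arcs
  visited <- stats::setNames(logical(nrow(net$nodes)), net$nodes$node)

  recurse <- function(node, nodes, edges, dir) {
    if (length(edges) >= max_edges) return()
    nb <- arcs[[node]]
    if (is.null(nb) || !nrow(nb)) return()
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$to[[k]]
      if (visited[[nxt]]) next
      e_id <- nb$edge_id[[k]]
      ndir <- dir
      if (nb$undirected[[k]]) ndir[[e_id]] <- paste0(node, ">", nxt)
      nnodes <- c(nodes, nxt)
      nedges <- c(edges, e_id)
      if (nxt %in% termini)
        out[[length(out) + 1]] <<- .new_path(class, nnodes, nedges, ndir)
      visited[[nxt]] <<- TRUE
      recurse(nxt, nnodes, nedges, ndir)
      visited[[nxt]] <<- FALSE
    }
  }
  visited[[origin]] <- TRUE
  recurse(origin, origin, character(), stats::setNames(character(), character()))
  out
}

#' Build candidate source-target paths by iterative deepening
#'
#' Paths run from the source through at most `max_intermediates` intermediate
#' proteins to a candidate TF/RBP (a segment of at most
#' `max_intermediates + 1` interactions), then one terminal regulatory edge
#' to a bound target gene, for a total of up to `max_intermediates + 2`
#' interactions. Deepening over segment length stops at the smallest depth at
#' which at least `coverage_stop` of the source's candidate regulators are
#' reached (a regulator counts as reached when at least one simple path to it
#' exists within the current depth), or at the maximum depth. A source that is
#' itself a candidate regulator is reached at depth 0 and may emit
#' single-edge source-to-target paths.
#'
#' @param net a [background_network()]
#' @param source source protein
#' @param targets the source's dysregulated targets `T(s)`
#' @param regulators candidate regulators from [select_candidate_regulators()]
#' @param regulator_binding named list: regulator -> bound genes
#' @param max_intermediates maximum intermediate proteins between source and
#'   regulator (default 3, i.e. five interactions in total)
#' @param coverage_stop deepening stop fraction (default 0.5)
#' @return list of `source_target` candidate paths (lexicographic order);
#'   empty, with a warning, when no regulator is reachable.
#' @export
build_source_target_paths <- function(net, source, targets, regulators,
                                      regulator_binding,
                                      max_intermediates = 3,
                                      coverage_stop = 0.5) {
  regulators <- sort(unique(regulators))
  if (!length(regulators)) {
    warning("source ", source, ": no candidate regulators; no paths built")
    return(list())
  }
  seg_max <- max_intermediates + 1
  segs <- enumerate_bounded_paths(net, source, regulators, seg_max, class = "segment")
  # depth at which each regulator is first reached
  first_depth <- rep(Inf, length(regulators))
  names(first_depth) <- regulators
  if (source %in% regulators) first_depth[[source]] <- 0
  for (p in segs) {
    d <- length(p$edges)
    if (d < first_depth[[p$terminus]]) first_depth[[p$terminus]] <- d
  }
  depth_stop <- seg_max
  for (d in 0:seg_max) {
    if (mean(first_depth <= d) >= coverage_stop) { depth_stop <- d; break }
  }
  if (all(is.infinite(first_depth))) {
    warning("source ", source, ": no candidate regulator reachable within ",
            seg_max, " interactions")
    return(list())
  }

  binding <- network_binding_map(net)
  out <- list()
  extend <- function(seg_nodes, seg_edges, seg_dir, reg) {
    reachable <- intersect(intersect(regulator_binding[[reg]], targets),
                           binding[[reg]])
    for (g in sort(reachable)) {
      if (g %in% seg_nodes) next
      eid <- net$edges$edge_id[net$edges$node_a == reg & net$edges$node_b == g &
                                 net$edges$directed]
      p <- .new_path("source_target", c(seg_nodes, g), c(seg_edges, eid[[1]]),
                     seg_dir, regulator = reg)
      out[[length(out) + 1]] <<- p
    }
  }
  if (source %in% regulators && depth_stop >= 0)
    extend(source, character(), stats::setNames(character(), character()), source)
  for (p in segs) {
    if (length(p$edges) <= depth_stop) extend(p$nodes, p$edges, p$dir, p$terminus)
  }
  out[order(vapply(out, `[[`, "", "path_id"))]
}

#' Build hit-source, source-source, and receptor-source candidate paths
#'
#' Hit-source paths connect every fitness-contribution hit to every source
#' with at most `max_hit_intermediates` intermediates; source-source paths
#' connect every ordered source pair with at most
#' `max_source_intermediates` intermediates; receptor-source paths connect
#' each declared receptor to its paired source with at most
#' `max_receptor_intermediates` intermediates.
#'
#' @param net a [background_network()]
#' @param ev an [evidence_set()]
#' @param max_hit_intermediates,max_source_intermediates,max_receptor_intermediates
#'   class-specific intermediate bounds (defaults 1, 1, 4)
#' @return list of candidate paths, ordered by class then node sequence
#' @export
build_auxiliary_paths <- function(net, ev,
                                  max_hit_intermediates = 1,
                                  max_source_intermediates = 1,
                                  max_receptor_intermediates = 4) {
  out <- list()
  emit <- function(paths, class) {
    for (p in paths) {
      p$class <- class
      p$path_id <- paste0(class, ":", paste(p$nodes, collapse = ","))
      out[[length(out) + 1]] <<- p
    }
  }
  present <- function(x) x[x %in% net$nodes$node]
  for (f in sort(present(setdiff(ev$fitness_hits, character())))) {
    for (s in sort(present(setdiff(ev$sources, f)))) {
      emit(enumerate_bounded_paths(net, f, s, max_hit_intermediates + 1), "hit_source")
    }
  }
  src <- sort(present(ev$sources))
  for (si in src) for (sj in setdiff(src, si)) {
    emit(enumerate_bounded_paths(net, si, sj, max_source_intermediates + 1), "source_source")
  }
  if (nrow(ev$receptors)) {
    rs <- ev$receptors[order(ev$receptors$receptor, ev$receptors$source), , drop = FALSE]
    for (k in seq_len(nrow(rs))) {
      if (!rs$receptor[[k]] %in% net$nodes$node) next
      emit(enumerate_bounded_paths(net, rs$receptor[[k]], rs$source[[k]],
                                   max_receptor_intermediates + 1), "receptor_source")
    }
  }
  cls <- vapply(out, `[[`, "", "class")
  ids <- vapply(out, `[[`, "", "path_id")
  out[order(cls, ids)]
}

#' Reconstruct a candidate path from its node sequence
#'
#' Resolves consecutive node pairs against the network's edges (a directed
#' edge forward, else the undirected edge with the traversal orientation
#' recorded).
#'
#' @param net a [background_network()]
#' @param nodes node sequence
#' @param class path class tag
#' @return a candidate path
#' @export
path_from_nodes <- function(net, nodes, class = "generic") {
  stopifnot(length(nodes) >= 2)
  edges <- character(length(nodes) - 1)
  dir <- stats::setNames(character(), character())
  e <- net$edges
  for (k in seq_len(length(nodes) - 1)) {
    u <- nodes[[k]]; v <- nodes[[k + 1]]
    hit_d <- e$edge_id[e$directed & e$node_a == u & e$node_b == v]
    if (length(hit_d)) { edges[[k]] <- hit_d[[1]]; next }
    a <- min(u, v); b <- max(u, v)
    hit_u <- e$edge_id[!e$directed & e$node_a == a & e$node_b == b]
    if (!length(hit_u)) stop(sprintf("no traversable edge %s -> %s", u, v))
    edges[[k]] <- hit_u[[1]]
    dir[[hit_u[[1]]]] <- paste0(u, ">", v)
  }
  reg <- if (class == "source_target") nodes[[length(nodes) - 1]] else NA_character_
  .new_path(class, nodes, edges, dir, regulator = reg)
}

#' Serialize candidate paths as TSV
#'
#' Columns: `path_id  class  origin  terminus  node_sequence` (comma-joined);
#' edge ids and undirected-edge orientations are recoverable from the network
#' plus the sequence via [path_from_nodes()].
#'
#' @param paths list of candidate paths
#' @param file output path
#' @export
write_paths <- function(paths, file) {
  df <- data.frame(
    path_id = vapply(paths, `[[`, "", "path_id"),
    class = vapply(paths, `[[`, "", "class"),
    origin = vapply(paths, `[[`, "", "origin"),
    terminus = vapply(paths, `[[`, "", "terminus"),
    node_sequence = vapply(paths, function(p) paste(p$nodes, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Load candidate paths from TSV written by [write_paths()]
#' @param net the background network used to resolve edges
#' @param file TSV path
#' @return list of candidate paths
#' @export
read_paths <- function(net, file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(k)
    path_from_nodes(net, strsplit(df$node_sequence[[k]], ",", fixed = TRUE)[[1]],
                    class = df$class[[k]]))
}
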