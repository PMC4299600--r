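# Independent brute-force oracle: enumerate every subset of candidate paths,
# keep the feasible ones (mandatory coverage + consistent undirected-edge
# orientations), and compute the lexicographic optimum
# (max connections, max hits, min nodes) plus the set of optimal node sets.
# Shares only the model's *data* (paths, groups, pairs, hits), none of the
# solver's search machinery; subsets are enumerated with bitmasks.

brute_force_lexicographic <- function(model) {
  nP <- length(model$paths)
  stopifnot(nP <= 16)
  pow2 <- 2^(seq_len(nP) - 1)
  mask_of <- function(idx) sum(pow2[idx])
  grp_masks <- vapply(model$groups, function(g) mask_of(g$cand), numeric(1))
  pair_masks <- vapply(model$pairs, function(p) mask_of(p$cand), numeric(1))
  # pairwise orientation conflicts
  conflict <- numeric(nP)
  if (nP >= 2) {
    for (i in seq_len(nP - 1)) for (j in seq.int(i + 1, nP)) {
      shared <- intersect(model$pund[[i]], model$pund[[j]])
      if (!length(shared)) next
      oi <- model$porient[[i]][match(shared, model$pund[[i]])]
      oj <- model$porient[[j]][match(shared, model$pund[[j]])]
      if (any(oi != oj)) {
        conflict[i] <- conflict[i] + pow2[j]
        conflict[j] <- conflict[j] + pow2[i]
      }
    }
  }
  node_in <- lapply(model$pnodes, function(x) x)
  best <- NULL
  best_sets <- list()
  for (mask in 0:(2^nP - 1)) {
    if (length(grp_masks) && any(bitwAnd(mask, grp_masks) == 0)) next
    sel <- which(bitwAnd(mask, pow2) > 0)
    if (any(bitwAnd(mask, conflict[sel]) > 0)) next
    nodes <- unique(unlist(node_in[sel], use.names = FALSE))
    v <- c(sum(bitwAnd(mask, pair_masks) > 0),
           sum(model$hit_idx %in% nodes),
           -length(nodes))
    if (is.null(best) || v[1] > best[1] ||
        (v[1] == best[1] && v[2] > best[2]) ||
        (v[1] == best[1] && v[2] == best[2] && v[3] > best[3])) {
      best <- v
      best_sets <- list()
    }
    if (identical(v, best)) {
      ns <- sort(nodes)
      best_sets[[paste(ns, collapse = ",")]] <- ns
    }
  }
  if (is.null(best)) return(NULL)
  list(max_connections = as.integer(best[1]),
       max_hits = as.integer(best[2]),
       min_nodes = as.integer(-best[3]),
       node_sets = best_sets[order(names(best_sets))])
}

# exhaustive simple-path oracle on a mixed graph via igraph (undirected
# edges expanded to arc pairs)
igraph_simple_paths <- function(net, origin, termini, max_edges) {
  e <- net$edges
  d <- e[e$directed, c("node_a", "node_b")]
  u <- e[!e$directed, c("node_a", "node_b")]
  arcs <- rbind(d, u, stats::setNames(u[, 2:1], names(u)))
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = net$nodes$node)
  out <- character()
  for (t in intersect(termini, net$nodes$node)) {
    if (t == origin) next
    sp <- igraph::all_simple_paths(g, from = origin, to = t, cutoff = max_edges)
    out <- c(out, vapply(sp, function(p) paste(names(p), collapse = ","), ""))
  }
  sort(unique(out))
}

# solver-side optimal node sets, as the same canonical key list
solver_node_sets <- function(model) {
  solved <- solve_ip(model, pool_size = 1e9)
  sets <- lapply(solved$solutions, function(s) sort(match(s$nodes, model$nodes)))
  keys <- vapply(sets, paste, "", collapse = ",")
  out <- sets[!duplicated(keys)]
  out[order(vapply(out, paste, "", collapse = ","))]
}
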