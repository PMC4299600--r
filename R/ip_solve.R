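# Exact lexicographic solver for the path-selection integer program.
#
# At every optimum the edge, node, and connection indicators are determined
# by the selected paths, so the program reduces to a search over path subsets
# and orientations of the undirected edges:
#
#   stages 1-2  With a full orientation of the undirected edges fixed,
#               selecting every orientation-compatible path simultaneously
#               maximizes both the connection count and the hit count, so the
#               optima are found by branch-and-bound over the orientations of
#               the conflicted undirected edges only (edges traversed in both
#               orientations by different candidate paths).
#   stage 3     Depth-first branch-and-bound over "requirements": each
#               mandatory pair group, each connection pair, and each hit node
#               in turn either is already satisfied, or branches over its
#               orientation-compatible candidate paths (optional requirements
#               also branch on skipping). Leaves must reproduce the frozen
#               connection and hit optima; the node count is bounded from
#               below by the current node set plus forced additions. All
#               optimal node sets are enumerated (up to pool_size).
#   stage 4     Per solution, the node set is fixed and the number of
#               selected paths is maximized by searching orientations of the
#               undirected edges used by the within-node-set paths.
#
# The search is fully deterministic: candidates are tried in ascending path
# order and ties resolve lexicographically, so identical inputs give
# identical pools for any seed.

# Shared incremental state over paths killed/revived by orientation choices.
.conflicted_edges <- function(model, path_set = seq_along(model$paths)) {
  nU <- length(model$und_edges)
  if (!nU) return(integer())
  seen <- matrix(FALSE, nU, 2)
  for (i in path_set) {
    pu <- model$pund[[i]]
    po <- model$porient[[i]]
    for (k in seq_along(pu)) seen[pu[[k]], po[[k]] + 1L] <- TRUE
  }
  which(seen[, 1] & seen[, 2])
}

# Paths requiring each orientation of each undirected edge, as a list
# indexed [[u]][[bit + 1]].
.edge_requirers <- function(model, path_set = seq_along(model$paths)) {
  nU <- length(model$und_edges)
  req <- lapply(seq_len(max(nU, 1)), function(u) list(integer(), integer()))
  for (i in path_set) {
    pu <- model$pund[[i]]
    po <- model$porient[[i]]
    for (k in seq_along(pu)) {
      slot <- po[[k]] + 1L
      req[[pu[[k]]]][[slot]] <- c(req[[pu[[k]]]][[slot]], i)
    }
  }
  req
}

# Stage 1/2 engine: maximize #connected pairs (objective = "conn") or #hits
# subject to the frozen connection count (objective = "hits"), over full
# orientations. Returns the optimum, or stops if no orientation leaves every
# mandatory group satisfiable.
.orientation_optimum <- function(model, objective = c("conn", "hits"),
                                 conn_target = NULL) {
  objective <- match.arg(objective)
  nP <- length(model$paths)
  if (!nP) {
    if (length(model$groups)) stop("infeasible: mandatory pairs but no candidate paths")
    return(0L)
  }
  conflicted <- .conflicted_edges(model)
  requirers <- .edge_requirers(model)

  alive <- rep(TRUE, nP)
  grp_alive <- vapply(model$groups, function(g) length(g$cand), 0L)
  pair_cand <- lapply(model$pairs, `[[`, "cand")
  path2grp <- vector("list", nP)
  for (gi in seq_along(model$groups))
    for (i in model$groups[[gi]]$cand) path2grp[[i]] <- c(path2grp[[i]], gi)
  path2pair <- vector("list", nP)
  for (qi in seq_along(pair_cand))
    for (i in pair_cand[[qi]]) path2pair[[i]] <- c(path2pair[[i]], qi)
  pair_alive <- vapply(pair_cand, length, 0L)

  # pre-assign unconflicted edges: kill nothing (paths agree); conflicted
  # edges are branched below.
  best <- -1L
  n_pairs <- length(model$pairs)

  hits_value <- function() {
    if (!length(model$hit_idx)) return(0L)
    nodes <- unique(unlist(model$pnodes[alive], use.names = FALSE))
    sum(model$hit_idx %in% nodes)
  }

  kill <- function(ids) {
    killed <- ids[alive[ids]]
    alive[killed] <<- FALSE
    for (i in killed) {
      for (gi in path2grp[[i]]) grp_alive[gi] <<- grp_alive[gi] - 1L
      for (qi in path2pair[[i]]) pair_alive[qi] <<- pair_alive[qi] - 1L
    }
    killed
  }
  revive <- function(killed) {
    alive[killed] <<- TRUE
    for (i in killed) {
      for (gi in path2grp[[i]]) grp_alive[gi] <<- grp_alive[gi] + 1L
      for (qi in path2pair[[i]]) pair_alive[qi] <<- pair_alive[qi] + 1L
    }
  }

  n_expand <- 0L
  recurse <- function(k) {
    n_expand <<- n_expand + 1L
    if (n_expand %% 100000L == 0L)
      message("orientation search: ", n_expand, " expansions")
    if (length(model$groups) && any(grp_alive == 0L)) return()
    conn_ub <- sum(pair_alive > 0L)
    if (objective == "conn") {
      if (conn_ub <= best) return()
    } else {
      if (conn_ub < conn_target) return()
      if (hits_value() <= best) return()
    }
    if (k > length(conflicted)) {
      if (objective == "conn") best <<- max(best, conn_ub)
      else if (conn_ub == conn_target) best <<- max(best, hits_value())
      return()
    }
    u <- conflicted[[k]]
    for (bit in c(1L, 0L)) {
      killed <- kill(requirers[[u]][[(1L - bit) + 1L]])
      recurse(k + 1L)
      revive(killed)
    }
  }
  recurse(1L)
  if (best < 0L) stop("infeasible: no orientation satisfies every mandatory pair")
  as.integer(best)
}

#' Stage 1: maximize connections between hits and sources
#'
#' Maximizes the number of connected fitness-hit/source and source/source
#' pairs; the optimum is recorded on the model and frozen as an equality for
#' the later stages.
#'
#' @param model an `ip_model` from [build_ip()]
#' @return the model with `max_connections` recorded
#' @export
solve_stage_max_connections <- function(model) {
  model$max_connections <- .orientation_optimum(model, "conn")
  model
}

#' Stage 2: maximize inclusion of fitness and phospho hits
#'
#' Maximizes the number of hit proteins appearing in relevant paths, subject
#' to the stage-1 connection optimum; the optimum is recorded and frozen.
#'
#' @param model an `ip_model` with `max_connections` recorded
#' @return the model with `max_hits` recorded
#' @export
solve_stage_max_hits <- function(model) {
  if (is.na(model$max_connections))
    stop("solve_stage_max_connections must run first")
  if (!length(model$hit_idx)) {
    model$max_hits <- 0L
    return(model)
  }
  model$max_hits <- .orientation_optimum(model, "hits",
                                         conn_target = model$max_connections)
  model
}

# Stage 3 core: exact minimum-node search, implemented in C++ (src/stage3.cpp)
# as a depth-first enumeration over requirements (mandatory pair groups in
# build_ip order, then connection pairs, then hit nodes) with
# orientation-driven candidate elimination, admissible node lower bounds,
# unit propagation of single-candidate groups, exact dominance pruning of
# skip branches, and memoization of identical search states. mode "value"
# returns the minimal node count; mode "pool" enumerates distinct optimal
# node sets (up to pool_size) with one representative selection each.
.flatten_model <- function(model) {
  csr <- function(lst) {
    lens <- vapply(lst, length, 0L)
    list(off = c(0L, cumsum(lens)),
         dat = as.integer(unlist(lst, use.names = FALSE)) - 1L)
  }
  pn <- csr(model$pnodes)
  pu <- csr(model$pund)
  po <- as.integer(unlist(model$porient, use.names = FALSE))
  grp_cand <- lapply(model$groups, `[[`, "cand")
  g <- csr(grp_cand)
  g_ends <- unlist(lapply(model$groups, function(gr) {
    first <- model$pnodes[[gr$cand[[1]]]]
    ends <- c(first[[1]], first[[length(first)]])
    if (ends[[1]] == ends[[2]]) ends[[2]] <- 0L
    ends - 1L
  }), use.names = FALSE)
  pair_cand <- lapply(model$pairs, `[[`, "cand")
  q <- csr(pair_cand)
  hit_cand <- lapply(model$hit_idx, function(h)
    which(vapply(model$pnodes, function(x) h %in% x, TRUE)))
  h <- csr(hit_cand)
  p2g <- vector("list", length(model$paths))
  for (gi in seq_along(grp_cand))
    for (i in grp_cand[[gi]]) p2g[[i]] <- c(p2g[[i]], gi)
  p2q <- vector("list", length(model$paths))
  for (qi in seq_along(pair_cand))
    for (i in pair_cand[[qi]]) p2q[[i]] <- c(p2q[[i]], qi)
  pg <- csr(p2g)
  pq <- csr(p2q)
  # requirements: groups (order = group index), pairs with candidates (by
  # key), hits with candidates (hit order)
  pair_pos <- which(vapply(pair_cand, length, 0L) > 0L)
  pair_pos <- pair_pos[order(vapply(model$pairs[pair_pos], `[[`, "", "key"))]
  hit_pos <- which(vapply(hit_cand, length, 0L) > 0L)
  list(
    nP = length(model$paths), nN = length(model$nodes),
    nU = length(model$und_edges), nG = length(model$groups),
    nQ = length(model$pairs), nH = length(model$hit_idx),
    pn_off = pn$off, pn = pn$dat,
    pu_off = pu$off, pu = pu$dat, po = po,
    g_off = g$off, g_cand = g$dat, g_ends = as.integer(g_ends),
    q_off = q$off, q_cand = q$dat,
    hit_node = as.integer(model$hit_idx) - 1L,
    h_off = h$off, h_cand = h$dat,
    p2g_off = pg$off, p2g = pg$dat,
    p2q_off = pq$off, p2q = pq$dat,
    req_type = c(rep(0L, length(model$groups)),
                 rep(1L, length(pair_pos)),
                 rep(2L, length(hit_pos))),
    req_id = c(seq_along(model$groups) - 1L, pair_pos - 1L, hit_pos - 1L)
  )
}

.stage3_search <- function(model, conn_target, hits_target,
                           mode = c("value", "pool"),
                           best_nodes = Inf, pool_size = Inf) {
  mode <- match.arg(mode)
  flat <- .flatten_model(model)
  res <- .stage3_cpp(flat, as.integer(conn_target), as.integer(hits_target),
                     if (mode == "value") 0L else 1L,
                     as.numeric(best_nodes), as.numeric(pool_size))
  if (mode == "value") return(as.integer(res$min_nodes))
  lapply(seq_along(res$sel), function(k) {
    orient <- res$orient[[k]]
    orient[orient < 0L] <- NA_integer_
    list(sel = res$sel[[k]], orient = orient)
  })
}

#' Stage 3: minimize total nodes and enumerate the solution pool
#'
#' Minimizes the number of relevant nodes subject to the stage-1/2 freezes,
#' then enumerates distinct optimal solutions (distinct relevant-node sets)
#' up to `pool_size`. Enumeration order is deterministic; `seed` is accepted
#' for interface stability and does not alter the result.
#'
#' @param model an `ip_model` with `max_connections` and `max_hits` recorded
#' @param pool_size maximum number of solutions to return (default 1000)
#' @param seed unused; the enumeration is deterministic
#' @return list of `ip_solution` objects, all with the minimal node count;
#'   the model with `min_nodes` recorded is attached as
#'   `attr(, "model")`.
#' @export
solve_stage_min_nodes_pool <- function(model, pool_size = 1000, seed = NULL) {
  if (is.na(model$max_connections) || is.na(model$max_hits))
    stop("stages 1 and 2 must run first")
  if (!length(model$paths)) {
    model$min_nodes <- 0L
    sol <- .make_solution(model, integer(), integer())
    out <- list(sol)
    attr(out, "model") <- model
    return(out)
  }
  min_nodes <- .stage3_search(model, model$max_connections, model$max_hits,
                              mode = "value")
  model$min_nodes <- as.integer(min_nodes)
  raw <- .stage3_search(model, model$max_connections, model$max_hits,
                        mode = "pool", best_nodes = min_nodes,
                        pool_size = pool_size)
  if (length(raw) < pool_size)
    message(sprintf("solution pool exhausted: %d distinct optimal node sets (pool_size %d)",
                    length(raw), pool_size))
  out <- lapply(raw, function(rw) .make_solution(model, rw$sel, rw$orient))
  attr(out, "model") <- model
  out
}

#' Stage 4: maximize the number of paths within a solution's node set
#'
#' Fixes the solution's relevant nodes and selects as many candidate paths as
#' the node set and a consistent orientation of its undirected edges allow,
#' preserving the stage-1/2 freezes and mandatory pair coverage. The node set
#' never changes; the path set becomes maximal.
#'
#' @param model an `ip_model` with all three stage optima recorded
#' @param sol an `ip_solution` from [solve_stage_min_nodes_pool()]
#' @return the augmented `ip_solution`
#' @export
solve_stage_max_paths <- function(model, sol) {
  node_set <- match(sol$nodes, model$nodes)
  inside <- which(vapply(model$pnodes, function(pn) all(pn %in% node_set), TRUE))
  if (!length(inside)) return(sol)
  requirers <- .edge_requirers(model, inside)
  branch_edges <- .conflicted_edges(model, inside)
  # the node set (eq17) is fixed but directions are not: unconflicted edges
  # keep their single used orientation, conflicted ones are branched
  used_und <- sort(unique(unlist(model$pund[inside], use.names = FALSE)))
  fixed_orient <- rep(NA_integer_, max(length(model$und_edges), 1))
  for (u in setdiff(used_und, branch_edges))
    fixed_orient[[u]] <- if (length(requirers[[u]][[2]]) > 0) 1L else 0L

  admissible <- function(orient) {
    keep <- inside[vapply(inside, function(i) {
      pu <- model$pund[[i]]; po <- model$porient[[i]]
      all(vapply(seq_along(pu), function(k) {
        v <- orient[[pu[[k]]]]
        is.na(v) || v == po[[k]]
      }, TRUE))
    }, TRUE)]
    # constraints: groups covered, freezes reproduced, node set fully used
    for (g in model$groups) if (!any(g$cand %in% keep)) return(NULL)
    conn <- sum(vapply(model$pairs, function(pr) any(pr$cand %in% keep), TRUE))
    if (conn != model$max_connections) return(NULL)
    nodes <- unique(unlist(model$pnodes[keep], use.names = FALSE))
    if (length(nodes) != length(node_set)) return(NULL)
    if (sum(model$hit_idx %in% nodes) != model$max_hits) return(NULL)
    keep
  }

  best_keep <- NULL
  if (length(branch_edges) > 20L) {
    warning("stage 4: too many conflicted undirected edges (",
            length(branch_edges), "); keeping the input solution's orientation")
    for (u in branch_edges) {
      eid <- model$und_edges[[u]]
      fixed_orient[[u]] <- if (eid %in% names(sol$directions))
        .canonical_bit(eid, sol$directions[[eid]]) else 1L
    }
    branch_edges <- integer()
  }
  assign_rec <- function(k, orient) {
    if (k > length(branch_edges)) {
      keep <- admissible(orient)
      if (!is.null(keep) &&
          (is.null(best_keep) || length(keep) > length(best_keep)))
        best_keep <<- list(keep = keep, orient = orient)
      return()
    }
    for (bit in c(1L, 0L)) {
      orient[[branch_edges[[k]]]] <- bit
      assign_rec(k + 1L, orient)
    }
  }
  assign_rec(1L, fixed_orient)
  if (is.null(best_keep)) return(sol)  # input solution already maximal
  out <- .make_solution(model, best_keep$keep, best_keep$orient)
  out
}

#' Solve all four stages and return the solution ensemble inputs
#'
#' Convenience wrapper running stages 1-4 in the fixed order
#' (connections, hits, minimum nodes, maximum paths).
#'
#' @param model an `ip_model`
#' @param pool_size stage-3 pool size
#' @param seed accepted for interface stability; the solve is deterministic
#' @return list with `model` (stage optima recorded) and `solutions` (the
#'   stage-4-augmented pool)
#' @export
solve_ip <- function(model, pool_size = 1000, seed = NULL) {
  model <- solve_stage_max_connections(model)
  model <- solve_stage_max_hits(model)
  sols <- solve_stage_min_nodes_pool(model, pool_size = pool_size, seed = seed)
  model <- attr(sols, "model")
  sols <- lapply(sols, function(s) solve_stage_max_paths(model, s))
  list(model = model, solutions = sols)
}
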