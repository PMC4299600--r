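# Integer-program model over candidate paths.
#
# Binary variables: sigma_p (path selected), x_e (edge relevant), d_e
# (inferred direction of an undirected edge; 1 = canonical orientation, i.e.
# from the lexicographically smaller endpoint to the larger), y_n (node
# relevant), and c_ij (pair connected) for every fitness-hit/source pair and
# every unordered source pair. Constraints:
#   eq1  each source-target pair with candidate paths gets >= 1 selected path
#   eq2  each receptor-source pair gets >= 1 selected path
#   eq3/4, eq5/6  c_ij is exactly the indicator that some pair path is selected
#   eq7/8  x_e = 1 iff some selected path uses e
#   eq9/10 y_n = 1 iff some relevant edge touches n
#   eq11  all selected paths agree with the inferred direction of every
#         undirected edge they traverse
# Stage freezes (eq13: sum c = max_connections; eq15: sum of hit y =
# max_hits; eq17: y fixed per solution) are added by the solver stages.
#
# At any optimum, x, y, and c are determined by sigma through eq3-eq10, so
# the solver searches over path selections and orientations only; the checker
# re-evaluates every equation family directly from sets.

.canonical_bit <- function(edge_id, dir_string) {
  # 1 when the traversal orientation matches the canonical key order "a--b"
  ab <- strsplit(edge_id, "--", fixed = TRUE)[[1]]
  as.integer(identical(dir_string, paste0(ab[[1]], ">", ab[[2]])))
}

#' Build the integer-program model from candidate paths
#'
#' Source-target pairs receive a covering constraint only when at least one
#' candidate path was enumerated for them; declared receptor-source pairs
#' must have at least one candidate path, otherwise building fails (the
#' infeasibility is detectable before solving).
#'
#' @param paths list of candidate paths (see [build_source_target_paths()],
#'   [build_auxiliary_paths()])
#' @param net a [background_network()]
#' @param ev an [evidence_set()]
#' @return an object of class `ip_model` carrying the variable universe, the
#'   mandatory path groups, the connection pairs, the hit node set, and a
#'   constraint registry tagged by equation number. Stage optima
#'   (`max_connections`, `max_hits`, `min_nodes`) are `NA` until solved.
#' @export
build_ip <- function(paths, net, ev) {
  path_ids <- vapply(paths, `[[`, "", "path_id")
  if (anyDuplicated(path_ids)) stop("duplicate candidate path ids")
  nP <- length(paths)
  cls <- vapply(paths, `[[`, "", "class")

  nodes_u <- sort(unique(unlist(lapply(paths, `[[`, "nodes"), use.names = FALSE)))
  edges_u <- sort(unique(unlist(lapply(paths, `[[`, "edges"), use.names = FALSE)))
  und_u <- edges_u[grepl("--", edges_u, fixed = TRUE)]
  node_idx <- stats::setNames(seq_along(nodes_u), nodes_u)
  edge_idx <- stats::setNames(seq_along(edges_u), edges_u)
  und_idx <- stats::setNames(seq_along(und_u), und_u)

  pnodes <- lapply(paths, function(p) unname(node_idx[p$nodes]))
  pedges <- lapply(paths, function(p) unname(edge_idx[p$edges]))
  pund <- lapply(paths, function(p) unname(und_idx[names(p$dir)]))
  porient <- lapply(paths, function(p) {
    if (!length(p$dir)) return(integer())
    vapply(seq_along(p$dir), function(k)
      .canonical_bit(names(p$dir)[[k]], p$dir[[k]]), integer(1))
  })

  origin <- vapply(paths, `[[`, "", "origin")
  terminus <- vapply(paths, `[[`, "", "terminus")

  group_of <- function(class, type) {
    sel <- which(cls == class)
    if (!length(sel)) return(list())
    keys <- paste(origin[sel], terminus[sel], sep = "|")
    lapply(split(sel, keys), function(cand)
      list(type = type, key = paste(origin[cand[[1]]], terminus[cand[[1]]], sep = "|"),
           cand = sort(cand)))
  }
  groups <- c(group_of("source_target", "source_target"),
              group_of("receptor_source", "receptor_source"))

  if (nrow(ev$receptors)) {
    for (k in seq_len(nrow(ev$receptors))) {
      key <- paste(ev$receptors$receptor[[k]], ev$receptors$source[[k]], sep = "|")
      if (!key %in% names(groups))
        stop("receptor-source pair (", sub("\\|", ", ", key),
             ") has no candidate path; the program would be infeasible")
    }
  }

  # connection pairs: every hit-source pair and every unordered source pair
  pairs <- list()
  hs_sel <- which(cls == "hit_source")
  hs_keys <- if (length(hs_sel)) paste(origin[hs_sel], terminus[hs_sel], sep = "|") else character()
  for (f in sort(unique(ev$fitness_hits))) for (s in sort(setdiff(ev$sources, f))) {
    key <- paste(f, s, sep = "|")
    pairs[[paste0("hs:", key)]] <- list(type = "hit_source", key = key,
                                        cand = sort(hs_sel[hs_keys == key]))
  }
  ss_sel <- which(cls == "source_source")
  ss_keys <- if (length(ss_sel))
    vapply(ss_sel, function(i) paste(sort(c(origin[[i]], terminus[[i]])), collapse = "|"), "")
  else character()
  src <- sort(unique(ev$sources))
  if (length(src) >= 2) {
    cmb <- utils::combn(src, 2)
    for (k in seq_len(ncol(cmb))) {
      key <- paste(cmb[, k], collapse = "|")
      pairs[[paste0("ss:", key)]] <- list(type = "source_source", key = key,
                                          cand = sort(ss_sel[ss_keys == key]))
    }
  }

  hit_nodes <- sort(intersect(unique(c(ev$fitness_hits, ev$phospho_hits)), nodes_u))

  groups <- groups[order(vapply(groups, function(g) length(g$cand), 0L),
                         vapply(groups, `[[`, "", "key"))]

  registry <- .constraint_registry(paths, groups, pairs, nodes_u, edges_u, pnodes, pedges)

  structure(list(
    paths = paths, path_ids = path_ids, classes = cls,
    nodes = nodes_u, edges = edges_u, und_edges = und_u,
    pnodes = pnodes, pedges = pedges, pund = pund, porient = porient,
    groups = groups, pairs = pairs,
    hit_nodes = hit_nodes, hit_idx = unname(node_idx[hit_nodes]),
    registry = registry,
    max_connections = NA_integer_, max_hits = NA_integer_, min_nodes = NA_integer_
  ), class = "ip_model")
}

.constraint_registry <- function(paths, groups, pairs, nodes_u, edges_u, pnodes, pedges) {
  rows <- list()
  add <- function(eq, ids) {
    if (length(ids))
      rows[[length(rows) + 1]] <<- data.frame(eq = eq, id = ids, stringsAsFactors = FALSE)
  }
  gt <- vapply(groups, `[[`, "", "type")
  gk <- vapply(groups, `[[`, "", "key")
  add(1L, gk[gt == "source_target"])
  add(2L, gk[gt == "receptor_source"])
  pt <- vapply(pairs, `[[`, "", "type")
  pk <- vapply(pairs, `[[`, "", "key")
  add(3L, pk[pt == "hit_source"])
  for (i in which(pt == "hit_source"))
    add(4L, paste(pk[[i]], pairs[[i]]$cand, sep = "#"))
  add(5L, pk[pt == "source_source"])
  for (i in which(pt == "source_source"))
    add(6L, paste(pk[[i]], pairs[[i]]$cand, sep = "#"))
  for (i in seq_along(paths))
    add(7L, paste(i, edges_u[pedges[[i]]], sep = "#"))
  add(8L, edges_u)
  add(9L, paste(rep(edges_u, each = 2), c("a", "b"), sep = "#"))
  add(10L, nodes_u)
  for (i in seq_along(paths)) {
    und <- names(paths[[i]]$dir)
    add(11L, if (length(und)) paste(i, und, sep = "#") else character())
  }
  if (!length(rows))
    return(data.frame(eq = integer(), id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ip_model <- function(x, ...) {
  cat(sprintf("ip_model: %d paths, %d edges (%d undirected), %d nodes, %d mandatory pair groups, %d connection pairs, %d hit nodes\n",
              length(x$paths), length(x$edges), length(x$und_edges),
              length(x$nodes), length(x$groups), length(x$pairs),
              length(x$hit_nodes)))
  cat(sprintf("  constraints: %s\n",
              paste(sprintf("eq%d:%d", sort(unique(x$registry$eq)),
                            as.integer(table(x$registry$eq))), collapse = " ")))
  if (!is.na(x$max_connections))
    cat(sprintf("  stage optima: connections=%d hits=%s nodes=%s\n",
                x$max_connections,
                ifelse(is.na(x$max_hits), "?", x$max_hits),
                ifelse(is.na(x$min_nodes), "?", x$min_nodes)))
  invisible(x)
}

# Solution constructor used by the solver stages.
.make_solution <- function(model, sel_idx, orientations) {
  sel_idx <- sort(sel_idx)
  nodes <- sort(unique(unlist(model$pnodes[sel_idx], use.names = FALSE)))
  edges <- sort(unique(unlist(model$pedges[sel_idx], use.names = FALSE)))
  und_used <- sort(unique(unlist(model$pund[sel_idx], use.names = FALSE)))
  dirs <- character()
  for (u in und_used) {
    eid <- model$und_edges[[u]]
    ab <- strsplit(eid, "--", fixed = TRUE)[[1]]
    dirs[[eid]] <- if (orientations[[u]] == 1L) paste0(ab[[1]], ">", ab[[2]])
                   else paste0(ab[[2]], ">", ab[[1]])
  }
  conn <- sum(vapply(model$pairs, function(pr) any(pr$cand %in% sel_idx), TRUE))
  hits <- sum(model$hit_idx %in% nodes)
  structure(list(
    path_idx = sel_idx,
    paths = model$path_ids[sel_idx],
    nodes = model$nodes[nodes],
    edges = model$edges[edges],
    directions = dirs,
    objectives = list(connections = as.integer(conn), hits = as.integer(hits),
                      n_nodes = length(nodes), n_paths = length(sel_idx))
  ), class = "ip_solution")
}

#' @export
print.ip_solution <- function(x, ...) {
  o <- x$objectives
  cat(sprintf("ip_solution: %d paths, %d nodes, %d edges (connections=%d, hits=%d)\n",
              o$n_paths, o$n_nodes, length(x$edges), o$connections, o$hits))
  invisible(x)
}

#' Independently verify a solution against the IP constraints
#'
#' Re-evaluates equation families 1-11 plus the recorded stage-freeze
#' equalities directly from the path definitions and the solution's sets,
#' without touching the solver.
#'
#' @param model an `ip_model` (stage optima checked only when recorded)
#' @param sol an `ip_solution`
#' @return list with `pass` (logical) and `violations` (data.frame `eq`,
#'   `detail`)
#' @export
check_solution <- function(model, sol) {
  v <- list()
  bad <- function(eq, detail)
    v[[length(v) + 1]] <<- data.frame(eq = eq, detail = detail, stringsAsFactors = FALSE)
  sel <- sol$path_idx

  for (g in model$groups) {
    if (!any(g$cand %in% sel))
      bad(if (g$type == "source_target") 1L else 2L,
          paste("pair", g$key, "has no selected path"))
  }

  # eq3-6: connection indicators are derived; verify the recorded count (eq13)
  conn <- sum(vapply(model$pairs, function(pr) any(pr$cand %in% sel), TRUE))
  if (!is.na(model$max_connections) && conn != model$max_connections)
    bad(13L, sprintf("connections %d != frozen max_connections %d",
                     conn, model$max_connections))

  exp_edges <- sort(unique(unlist(model$pedges[sel], use.names = FALSE)))
  got_edges <- sort(match(sol$edges, model$edges))
  if (!identical(exp_edges, got_edges)) {
    extra <- setdiff(got_edges, exp_edges)
    miss <- setdiff(exp_edges, got_edges)
    if (length(miss))
      bad(7L, paste("edges of a selected path not relevant:",
                    paste(model$edges[miss], collapse = ",")))
    if (length(extra))
      bad(8L, paste("relevant edge in no selected path:",
                    paste(model$edges[extra], collapse = ",")))
  }

  exp_nodes <- sort(unique(unlist(model$pnodes[sel], use.names = FALSE)))
  got_nodes <- sort(match(sol$nodes, model$nodes))
  if (!identical(exp_nodes, got_nodes)) {
    miss <- setdiff(exp_nodes, got_nodes)
    extra <- setdiff(got_nodes, exp_nodes)
    if (length(miss))
      bad(9L, paste("endpoint of a relevant edge not relevant:",
                    paste(model$nodes[miss], collapse = ",")))
    if (length(extra))
      bad(10L, paste("relevant node touched by no relevant edge:",
                     paste(model$nodes[extra], collapse = ",")))
  }

  for (i in sel) {
    p <- model$paths[[i]]
    for (eid in names(p$dir)) {
      want <- p$dir[[eid]]
      got <- if (eid %in% names(sol$directions)) sol$directions[[eid]] else NA_character_
      if (is.na(got) || !identical(got, want))
        bad(11L, sprintf("path %s needs %s but edge %s is oriented %s",
                         p$path_id, want, eid,
                         if (is.na(got)) "unset" else got))
    }
  }

  hits <- sum(model$hit_nodes %in% sol$nodes)
  if (!is.na(model$max_hits) && hits != model$max_hits)
    bad(15L, sprintf("hits %d != frozen max_hits %d", hits, model$max_hits))
  if (!is.na(model$min_nodes) && length(sol$nodes) != model$min_nodes)
    bad(17L, sprintf("node count %d != stage-3 optimum %d",
                     length(sol$nodes), model$min_nodes))

  violations <- if (length(v)) do.call(rbind, v)
  else data.frame(eq = integer(), detail = character(), stringsAsFactors = FALSE)
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Export the integer program in LP text format (debugging aid)
#'
#' Writes the model's variables and equation families 1-11 in standard LP
#' text syntax with the stage-3 node-minimization objective.
#'
#' @param model an `ip_model`
#' @param file output path
#' @export
write_lp <- function(model, file) {
  sv <- function(i) paste0("s_", i)
  xv <- function(e) paste0("x_", gsub("[^A-Za-z0-9]", "_", model$edges[[e]]))
  dv <- function(u) paste0("d_", gsub("[^A-Za-z0-9]", "_", model$und_edges[[u]]))
  yv <- function(n) paste0("y_", gsub("[^A-Za-z0-9]", "_", model$nodes[[n]]))
  cv <- function(k) paste0("c_", gsub("[^A-Za-z0-9]", "_", k))
  ln <- c("Minimize", paste(" obj:", paste(vapply(seq_along(model$nodes), yv, ""),
                                           collapse = " + ")), "Subject To")
  for (g in model$groups)
    ln <- c(ln, paste0(" ", paste(vapply(g$cand, sv, ""), collapse = " + "), " >= 1"))
  for (nm in names(model$pairs)) {
    pr <- model$pairs[[nm]]
    if (length(pr$cand)) {
      ln <- c(ln, paste0(" ", cv(pr$key), " - ",
                         paste(vapply(pr$cand, sv, ""), collapse = " - "), " <= 0"))
      for (i in pr$cand)
        ln <- c(ln, paste0(" ", cv(pr$key), " - ", sv(i), " >= 0"))
    } else ln <- c(ln, paste0(" ", cv(pr$key), " = 0"))
  }
  for (i in seq_along(model$paths)) {
    for (e in model$pedges[[i]])
      ln <- c(ln, paste0(" ", sv(i), " - ", xv(e), " <= 0"))
  }
  for (e in seq_along(model$edges)) {
    users <- which(vapply(model$pedges, function(pe) e %in% pe, TRUE))
    ln <- c(ln, paste0(" ", xv(e), " - ",
                       paste(vapply(users, sv, ""), collapse = " - "), " <= 0"))
  }
  for (e in seq_along(model$edges)) {
    ends <- match(strsplit(model$edges[[e]], ">|--")[[1]], model$nodes)
    for (n in ends)
      ln <- c(ln, paste0(" ", xv(e), " - ", yv(n), " <= 0"))
  }
  for (n in seq_along(model$nodes)) {
    touch <- which(vapply(seq_along(model$edges), function(e)
      n %in% match(strsplit(model$edges[[e]], ">|--")[[1]], model$nodes), TRUE))
    ln <- c(ln, paste0(" ", yv(n), " - ",
                       paste(vapply(touch, xv, ""), collapse = " - "), " <= 0"))
  }
  for (i in seq_along(model$paths)) {
    pu <- model$pund[[i]]
    po <- model$porient[[i]]
    for (k in seq_along(pu)) {
      if (po[[k]] == 1L)
        ln <- c(ln, paste0(" ", sv(i), " - ", dv(pu[[k]]), " <= 0"))
      else
        ln <- c(ln, paste0(" ", sv(i), " + ", dv(pu[[k]]), " <= 1"))
    }
  }
  vars <- c(vapply(seq_along(model$paths), sv, ""),
            vapply(seq_along(model$edges), xv, ""),
            vapply(seq_along(model$und_edges), dv, ""),
            vapply(seq_along(model$nodes), yv, ""),
            vapply(names(model$pairs), function(nm) cv(model$pairs[[nm]]$key), ""))
  ln <- c(ln, "Binary", paste0(" ", unique(vars)), "End")
  writeLines(ln, file)
  invisible(file)
}
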