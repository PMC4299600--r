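# Aggregation of the solution pool into per-element confidence values and
# thresholded consensus subnetworks. The confidence of a node, edge, or path
# is its frequency across the ensemble of equally optimal solutions.

#' Compute element confidences across a solution pool
#'
#' @param solutions non-empty list of `ip_solution` objects
#' @return an object of class `ip_ensemble` with `node_confidence`,
#'   `edge_confidence`, `path_confidence` (named numeric vectors over the
#'   union of elements ever selected), `edge_direction` (majority traversal
#'   orientation of each undirected edge with its frequency among solutions
#'   using the edge), and `n_solutions`.
#' @export
compute_confidences <- function(solutions) {
  if (!length(solutions)) stop("empty solution pool")
  n <- length(solutions)
  freq <- function(field) {
    tab <- table(unlist(lapply(solutions, `[[`, field), use.names = FALSE))
    nm <- if (is.null(names(tab))) character() else names(tab)
    sort(stats::setNames(as.numeric(tab) / n, nm), decreasing = TRUE)
  }
  node_confidence <- freq("nodes")
  edge_confidence <- freq("edges")
  path_confidence <- freq("paths")

  # majority orientation of undirected edges, counted over the solutions
  # that use the edge (confidence itself ignores orientation)
  dir_votes <- list()
  for (s in solutions) {
    for (eid in names(s$directions)) {
      dir_votes[[eid]] <- c(dir_votes[[eid]], s$directions[[eid]])
    }
  }
  edge_direction <- do.call(rbind, c(list(
    data.frame(edge_id = character(), majority_direction = character(),
               direction_frequency = numeric(), stringsAsFactors = FALSE)),
    lapply(names(dir_votes), function(eid) {
      tab <- sort(table(dir_votes[[eid]]), decreasing = TRUE)
      data.frame(edge_id = eid, majority_direction = names(tab)[[1]],
                 direction_frequency = as.numeric(tab[[1]]) / sum(tab),
                 stringsAsFactors = FALSE)
    })))
  structure(list(node_confidence = node_confidence,
                 edge_confidence = edge_confidence,
                 path_confidence = path_confidence,
                 edge_direction = edge_direction,
                 n_solutions = n),
            class = "ip_ensemble")
}

#' @export
print.ip_ensemble <- function(x, ...) {
  cat(sprintf("ip_ensemble: %d solutions; %d nodes, %d edges, %d paths ever selected\n",
              x$n_solutions, length(x$node_confidence),
              length(x$edge_confidence), length(x$path_confidence)))
  invisible(x)
}

#' Extract the consensus subnetwork at a confidence threshold
#'
#' Keeps nodes, edges, and paths whose confidence is at least `threshold`;
#' edges additionally require both endpoints to be kept.
#'
#' @param ens an `ip_ensemble`
#' @param threshold confidence threshold in (0, 1\] (default 0.75)
#' @return list with `nodes` (character), `edges` (data.frame `edge_id`,
#'   `confidence`, `majority_direction`), `paths` (character path ids), and
#'   `threshold`
#' @export
consensus_subnetwork <- function(ens, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  nodes <- sort(names(ens$node_confidence)[ens$node_confidence >= threshold])
  eids <- names(ens$edge_confidence)[ens$edge_confidence >= threshold]
  ends <- strsplit(eids, ">|--")
  keep <- vapply(ends, function(ab) all(ab %in% nodes), TRUE)
  eids <- sort(eids[keep])
  dirs <- ens$edge_direction$majority_direction[match(eids, ens$edge_direction$edge_id)]
  list(nodes = nodes,
       edges = data.frame(edge_id = eids,
                          confidence = as.numeric(ens$edge_confidence[eids]),
                          majority_direction = ifelse(is.na(dirs), eids, dirs),
                          stringsAsFactors = FALSE),
       paths = sort(names(ens$path_confidence)[ens$path_confidence >= threshold]),
       threshold = threshold)
}

#' Write ensemble confidence tables as TSV
#'
#' One row per element: `element_type  element_id  confidence
#' majority_direction` (direction only for undirected edges).
#'
#' @param ens an `ip_ensemble`
#' @param file output path
#' @export
write_confidences <- function(ens, file) {
  md <- function(ids) {
    out <- ens$edge_direction$majority_direction[match(ids, ens$edge_direction$edge_id)]
    ifelse(is.na(out), "", out)
  }
  df <- rbind(
    data.frame(element_type = "node", element_id = names(ens$node_confidence),
               confidence = as.numeric(ens$node_confidence),
               majority_direction = "", stringsAsFactors = FALSE),
    data.frame(element_type = "edge", element_id = names(ens$edge_confidence),
               confidence = as.numeric(ens$edge_confidence),
               majority_direction = md(names(ens$edge_confidence)),
               stringsAsFactors = FALSE),
    data.frame(element_type = "path", element_id = names(ens$path_confidence),
               confidence = as.numeric(ens$path_confidence),
               majority_direction = "", stringsAsFactors = FALSE)
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize a solution pool as JSON
#' @param solutions list of `ip_solution`
#' @param file output path
#' @export
write_solutions <- function(solutions, file) {
  jsonlite::write_json(lapply(solutions, function(s) list(
    objective = s$objectives, nodes = s$nodes, edges = s$edges,
    paths = s$paths, directions = as.list(s$directions)
  )), file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
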