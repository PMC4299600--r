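# Precision-recall assessment of node confidences against curated labels,
# with the candidate-set baseline and the degree-preserving permuted
# baseline.

#' Construct a label set for precision-recall scoring
#'
#' @param positives,negatives disjoint character vectors of protein nodes
#' @param excluded nodes removed from scoring entirely (typically the
#'   experimental hits, so predictive accuracy is not inflated by inputs)
#' @return object of class `label_set`
#' @export
label_set <- function(positives, negatives, excluded = character()) {
  positives <- setdiff(unique(as.character(positives)), excluded)
  negatives <- setdiff(unique(as.character(negatives)), excluded)
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap")
  structure(list(positives = positives, negatives = negatives,
                 excluded = unique(as.character(excluded))),
            class = "label_set")
}

#' Precision-recall curve over node confidences
#'
#' At each distinct confidence threshold, the predicted set is every scored
#' node with confidence at or above the threshold; precision is computed over
#' labeled predictions only, and unlabeled nodes are ignored.
#'
#' @param node_confidence named numeric vector (nodes absent from the vector
#'   score 0)
#' @param labels a [label_set()] with at least one positive after exclusion
#' @return data.frame `threshold  precision  recall  n_predicted`, one row
#'   per distinct confidence value, in decreasing threshold order
#' @export
precision_recall <- function(node_confidence, labels) {
  if (!length(labels$positives)) stop("no positives to score")
  scored <- c(labels$positives, labels$negatives)
  conf <- stats::setNames(rep(0, length(scored)), scored)
  known <- intersect(names(node_confidence), scored)
  conf[known] <- node_confidence[known]
  thresholds <- sort(unique(conf), decreasing = TRUE)
  out <- lapply(thresholds, function(tau) {
    pred <- names(conf)[conf >= tau]
    tp <- length(intersect(pred, labels$positives))
    labeled <- length(pred)  # scored nodes only, all labeled by construction
    data.frame(threshold = tau,
               precision = if (labeled) tp / labeled else NA_real_,
               recall = tp / length(labels$positives),
               n_predicted = labeled)
  })
  do.call(rbind, out)
}

#' Precision and recall of the candidate-path baseline
#'
#' Treats every protein node appearing in any candidate path as predicted
#' with confidence 1 and returns the single resulting precision-recall
#' point.
#'
#' @param candidate_paths list of candidate paths
#' @param labels a [label_set()]
#' @param net optional [background_network()]; when supplied, gene/mRNA
#'   nodes are removed from the predicted set
#' @return list with `precision` (NA when no labeled node is predicted),
#'   `recall`, and `n_predicted`
#' @export
candidate_baseline <- function(candidate_paths, labels, net = NULL) {
  pred <- unique(unlist(lapply(candidate_paths, `[[`, "nodes"), use.names = FALSE))
  if (!is.null(net)) pred <- intersect(pred, protein_nodes(net))
  pred <- setdiff(pred, labels$excluded)
  tp <- length(intersect(pred, labels$positives))
  labeled <- length(intersect(pred, c(labels$positives, labels$negatives)))
  list(precision = if (labeled) tp / labeled else NA_real_,
       recall = if (length(labels$positives)) tp / length(labels$positives) else NA_real_,
       n_predicted = length(pred))
}

# logarithmic degree bins: 1, 2-3, 4-7, 8-15, ...
.degree_bin <- function(deg) ifelse(deg <= 0, -1L, floor(log2(pmax(deg, 1))))

# sample `n` proteins from `pool` whose degree bin is `bin`, widening the bin
# symmetrically when it holds fewer than n candidates
.sample_bin <- function(bin, n, pool_bins, exclude = character()) {
  width <- 0L
  repeat {
    cand <- names(pool_bins)[abs(pool_bins - bin) <= width]
    cand <- setdiff(cand, exclude)
    if (length(cand) >= n) break
    width <- width + 1L
    if (width > 64L) stop("cannot satisfy degree bin ", bin)
  }
  if (width > 0L)
    message(sprintf("degree bin %d widened by %d to draw %d node(s)", bin, width, n))
  sample(cand, n)
}

#' Draw a degree-matched permuted evidence set
#'
#' Permuted sources, fitness hits, and phospho hits are drawn from the
#' network's proteins matching the real sets in size and in degree
#' distribution (logarithmic degree bins; a bin is widened when it holds too
#' few candidates). Permuted receptors are random proteins, equal in number
#' to the real receptor pairs, each paired with a random permuted source.
#' Permuted targets are uniform draws of `|T(s)|` gene/mRNA nodes per
#' source. Regulator binding and stress-bound regulator annotations are
#' background knowledge and stay unchanged.
#'
#' @param net a [background_network()]
#' @param ev the real [evidence_set()]
#' @param seed integer seed; the same seed reproduces the same permutation
#' @return a permuted `evidence_set`
#' @export
permute_inputs <- function(net, ev, seed) {
  set.seed(seed)
  deg <- protein_degrees(net)
  bins <- .degree_bin(deg)
  genes <- gene_nodes(net)

  draw_matched <- function(real) {
    real <- intersect(real, names(bins))
    if (!length(real)) return(character())
    want <- table(.degree_bin(deg[real]))
    out <- character()
    for (b in names(want))
      out <- c(out, .sample_bin(as.integer(b), as.integer(want[[b]]), bins,
                                exclude = out))
    sort(out)
  }

  p_sources <- draw_matched(ev$sources)
  p_fitness <- draw_matched(ev$fitness_hits)
  p_phospho <- draw_matched(ev$phospho_hits)
  p_targets <- lapply(stats::setNames(p_sources, p_sources), function(s) character())
  real_sizes <- vapply(ev$targets_by_source, length, 0L)
  for (k in seq_along(p_sources))
    p_targets[[k]] <- sort(sample(genes, min(real_sizes[[k]], length(genes))))
  n_rec <- nrow(ev$receptors)
  p_receptors <- if (n_rec && length(p_sources))
    data.frame(receptor = sample(setdiff(protein_nodes(net), p_sources), n_rec),
               source = sample(p_sources, n_rec, replace = TRUE),
               stringsAsFactors = FALSE)
  else data.frame(receptor = character(), source = character())
  evidence_set(sources = p_sources, targets_by_source = p_targets,
               fitness_hits = p_fitness, phospho_hits = p_phospho,
               receptors = p_receptors,
               regulator_binding = ev$regulator_binding,
               stress_bound_regulators = ev$stress_bound_regulators)
}

#' Permuted-baseline node confidences
#'
#' Runs the full inference pipeline (regulator enrichment, path enumeration,
#' the four IP stages, ensemble confidence) on `n_perms` degree-matched
#' permutations of the evidence and returns each node's confidence averaged
#' over the permutation ensembles. A permuted instance whose receptor pairs
#' cannot be connected is re-run without receptor pairs (its source-target
#' constraints already drop with enumeration, consistent with the
#' enumeration-gated covering policy).
#'
#' @param net a [background_network()]
#' @param ev the real [evidence_set()]
#' @param n_perms number of permutations (>= 1)
#' @param pool_size stage-3 pool size per permutation
#' @param seed master seed; per-permutation seeds are derived from it
#' @param params pipeline parameters, see [pipeline_params()]
#' @return named numeric vector: average confidence per node over all
#'   permutation ensembles (nodes never selected average 0)
#' @export
permuted_baseline <- function(net, ev, n_perms = 20, pool_size = 100,
                              seed = 1, params = pipeline_params()) {
  stopifnot(n_perms >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_perms)
  acc <- numeric()
  for (k in seq_len(n_perms)) {
    evp <- permute_inputs(net, ev, sub_seeds[[k]])
    conf <- tryCatch({
      res <- infer_subnetwork_ensemble(net, evp, params = params,
                                       pool_size = pool_size,
                                       seed = sub_seeds[[k]])
      res$ensemble$node_confidence
    }, error = function(e) {
      evp$receptors <- evp$receptors[0, , drop = FALSE]
      res <- tryCatch(infer_subnetwork_ensemble(net, evp, params = params,
                                                pool_size = pool_size,
                                                seed = sub_seeds[[k]]),
                      error = function(e2) NULL)
      if (is.null(res)) stats::setNames(numeric(), character())
      else res$ensemble$node_confidence
    })
    for (n in names(conf)) {
      cur <- if (n %in% names(acc)) acc[[n]] else 0
      acc[[n]] <- cur + conf[[n]]
    }
  }
  sort(acc / n_perms, decreasing = TRUE)
}
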