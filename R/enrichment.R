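# Hypergeometric enrichment statistics: candidate TF/RBP selection per source,
# pairwise overlap of mutant target sets, and Benjamini-Hochberg FDR.

#' Inclusive upper-tail hypergeometric probability
#'
#' Probability of observing `overlap` or more shared elements between a set of
#' size `set_a_size` and a random draw of `set_b_size` elements from a
#' universe of `universe` elements: `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, set_a_size, set_b_size)`. The tail is
#' inclusive, so `overlap = 0` always gives 1.
#'
#' @param overlap observed overlap count
#' @param set_a_size,set_b_size sizes of the two sets
#' @param universe universe size
#' @return a probability in \[0, 1\]
#' @export
hypergeom_tail_p <- function(overlap, set_a_size, set_b_size, universe) {
  if (any(c(overlap, set_a_size, set_b_size, universe) < 0))
    stop("counts must be non-negative")
  if (set_a_size > universe || set_b_size > universe)
    stop("set sizes cannot exceed the universe")
  if (overlap > min(set_a_size, set_b_size))
    stop("overlap cannot exceed the smaller set")
  if (overlap == 0) return(1)
  stats::phyper(overlap - 1, set_a_size, universe - set_a_size, set_b_size,
                lower.tail = FALSE)
}

#' Select candidate transcription factors / RNA-binding proteins for a source
#'
#' A regulator becomes a candidate for a source when its bound targets are
#' significantly enriched (inclusive upper-tail hypergeometric, `p < alpha`)
#' with the source's dysregulated targets, or when it is listed as binding
#' targets under the stress condition (`stress_bound`), in which case it is
#' included regardless of enrichment.
#'
#' @param source_targets gene/mRNA targets of the source (non-empty)
#' @param regulator_binding named list: regulator -> bound genes
#' @param stress_bound regulators included unconditionally
#' @param universe number of genes in the enrichment universe
#' @param alpha significance threshold (default 0.05)
#' @return list with `selected` (sorted regulator ids) and `table`, a
#'   data.frame of per-regulator statistics
#'   (`regulator overlap k n N p selected`).
#' @export
select_candidate_regulators <- function(source_targets, regulator_binding,
                                        stress_bound = character(),
                                        universe, alpha = 0.05) {
  source_targets <- unique(as.character(source_targets))
  if (!length(source_targets)) stop("enrichment undefined for an empty target set")
  regs <- sort(unique(c(names(regulator_binding), stress_bound)))
  if (!length(regs))
    return(list(selected = character(),
                table = data.frame(regulator = character(), overlap = integer(),
                                   k = integer(), n = integer(), N = integer(),
                                   p = numeric(), selected = logical())))
  tab <- do.call(rbind, lapply(regs, function(r) {
    bound <- unique(regulator_binding[[r]])
    ov <- length(intersect(bound, source_targets))
    p <- if (length(bound))
      hypergeom_tail_p(ov, length(bound), length(source_targets), universe)
    else 1
    data.frame(regulator = r, overlap = ov, k = length(bound),
               n = length(source_targets), N = universe, p = p,
               stringsAsFactors = FALSE)
  }))
  tab$selected <- tab$p < alpha | tab$regulator %in% stress_bound
  list(selected = tab$regulator[tab$selected], table = tab)
}

#' Pairwise overlap of per-source target sets
#'
#' For every unordered source pair, the overlap fraction
#' `|A intersect B| / min(|A|, |B|)` (the fraction of the smaller set shared)
#' and the inclusive upper-tail hypergeometric p-value of the overlap.
#'
#' @param targets_by_source named list of target sets (>= 2 sources)
#' @param universe universe size for the hypergeometric test
#' @return list of two symmetric matrices, `fraction` and `p_value`, with the
#'   sources as dimnames. Diagonals are 1 and the tail p of full self-overlap.
#' @export
pairwise_target_overlap <- function(targets_by_source, universe) {
  src <- names(targets_by_source)
  if (length(src) < 2) stop("need at least two sources")
  n <- length(src)
  fraction <- matrix(NA_real_, n, n, dimnames = list(src, src))
  p_value <- matrix(NA_real_, n, n, dimnames = list(src, src))
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- unique(targets_by_source[[i]])
      b <- unique(targets_by_source[[j]])
      ov <- length(intersect(a, b))
      fr <- if (min(length(a), length(b)) == 0) 0 else ov / min(length(a), length(b))
      p <- hypergeom_tail_p(ov, length(a), length(b), universe)
      fraction[i, j] <- fraction[j, i] <- fr
      p_value[i, j] <- p_value[j, i] <- p
    }
  }
  list(fraction = fraction, p_value = p_value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure with cumulative-minimum monotonicity
#' enforcement; output order matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return numeric vector of q-values
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Write an enrichment table as TSV
#' @param table the `table` component of [select_candidate_regulators()]
#' @param file output path
#' @export
write_enrichment_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
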