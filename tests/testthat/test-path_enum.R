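test_that("bounded enumeration finds exactly the expected toy paths", {
  nodes <- data.frame(node = c("A", "B", "C", "D"), kind = rep("protein", 4))
  edges <- data.frame(
    node_a = c("A", "B", "A", "D"),
    node_b = c("B", "C", "D", "C"),
    directed = c(1, 1, 0, 1),
    class = c("kinase-substrate", "kinase-substrate", "protein-protein",
              "kinase-substrate"))
  net <- background_network(nodes, edges)

  p1 <- enumerate_bounded_paths(net, "A", "C", max_edges = 2)
  expect_length(p1, 2)
  seqs <- vapply(p1, function(p) paste(p$nodes, collapse = ","), "")
  expect_setequal(seqs, c("A,B,C", "A,D,C"))
  und <- p1[[which(seqs == "A,D,C")]]
  expect_equal(unname(und$dir["A--D"]), "A>D")

  # chain-only sub-network: exactly one path
  chain <- background_network(nodes[1:3, ], edges[1:2, ])
  p2 <- enumerate_bounded_paths(chain, "A", "C", max_edges = 2)
  expect_length(p2, 1)
  expect_equal(p2[[1]]$nodes, c("A", "B", "C"))

  # origin without outgoing or undirected incident edges
  p3 <- enumerate_bounded_paths(chain, "C", "A", max_edges = 3)
  expect_length(p3, 0)
})

test_that("enumeration equals the exhaustive igraph oracle on random graphs", {
  for (seed in 1:25) {
    net <- random_small_network(n_prot = sample(4:7, 1), n_genes = 2,
                                p_edge = 0.5, seed = seed)
    prot <- protein_nodes(net)
    origin <- prot[[1]]
    termini <- prot[-1][seq_len(min(2, length(prot) - 1))]
    max_edges <- sample(2:4, 1)
    mine <- enumerate_bounded_paths(net, origin, termini, max_edges)
    mine_seq <- sort(vapply(mine, function(p) paste(p$nodes, collapse = ","), ""))
    oracle <- igraph_simple_paths(net, origin, termini, max_edges)
    # gene nodes are dead ends in both representations, so protein-only
    # termini keep the comparison exact
    expect_equal(mine_seq, oracle,
                 label = paste("seed", seed))
  }
})

test_that("increasing the edge bound never removes a path", {
  net <- random_small_network(n_prot = 7, n_genes = 2, p_edge = 0.5, seed = 99)
  prot <- protein_nodes(net)
  shorter <- enumerate_bounded_paths(net, prot[[1]], prot[5:6], 2)
  longer <- enumerate_bounded_paths(net, prot[[1]], prot[5:6], 4)
  ids <- function(x) vapply(x, `[[`, "", "path_id")
  expect_true(all(ids(shorter) %in% ids(longer)))
})

test_that("iterative deepening stops at 50% regulator coverage", {
  # four regulators: two adjacent to the source (depth 1), two only at
  # depth 3; the deepening must stop after depth 1
  nodes <- data.frame(
    node = c("S", "R1", "R2", "R3", "R4", "m1", "m2", "n1", "n2",
             "g1", "g2", "g3", "g4"),
    kind = c(rep("protein", 9), rep("gene_or_mrna", 4)))
  edges <- data.frame(
    node_a = c("S", "S", "S", "m1", "m2", "S", "n1", "n2",
               "R1", "R2", "R3", "R4"),
    node_b = c("R1", "R2", "m1", "m2", "R3", "n1", "n2", "R4",
               "g1", "g2", "g3", "g4"),
    directed = 1,
    class = c(rep("kinase-substrate", 8), rep("protein-DNA", 4)))
  net <- background_network(nodes, edges)
  binding <- list(R1 = "g1", R2 = "g2", R3 = "g3", R4 = "g4")
  paths <- build_source_target_paths(net, "S", paste0("g", 1:4),
                                     regulators = paste0("R", 1:4),
                                     regulator_binding = binding)
  regs <- unique(vapply(paths, `[[`, "", "regulator"))
  expect_setequal(regs, c("R1", "R2"))
  expect_true(all(vapply(paths, function(p) length(p$edges), 0L) == 2))
})

test_that("a source that is itself a regulator emits single-edge paths", {
  nodes <- data.frame(node = c("S", "g1"), kind = c("protein", "gene_or_mrna"))
  edges <- data.frame(node_a = "S", node_b = "g1", directed = 1,
                      class = "protein-DNA")
  net <- background_network(nodes, edges)
  paths <- build_source_target_paths(net, "S", "g1", regulators = "S",
                                     regulator_binding = list(S = "g1"))
  expect_length(paths, 1)
  expect_equal(paths[[1]]$nodes, c("S", "g1"))
  expect_equal(length(paths[[1]]$edges), 1)
})

test_that("unreachable regulators give an empty result with a warning", {
  net <- tiny_network()
  expect_warning(
    out <- build_source_target_paths(net, "H1", "G1", regulators = "F1",
                                     regulator_binding = list(F1 = "G1"),
                                     max_intermediates = 0),
    "no candidate regulator reachable")
  expect_length(out, 0)
})

test_that("auxiliary path classes respect their intermediate bounds", {
  net <- tiny_network()
  ev <- tiny_evidence()
  aux <- build_auxiliary_paths(net, ev)
  hs <- Filter(function(p) p$class == "hit_source", aux)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$nodes, c("H1", "S1"))
  expect_equal(unname(hs[[1]]$dir["H1--S1"]), "H1>S1")

  # hit three steps from the source: no hit-source path
  nodes <- data.frame(node = c("F", "a", "b", "S"), kind = rep("protein", 4))
  edges <- data.frame(node_a = c("F", "a", "b"), node_b = c("a", "b", "S"),
                      directed = 1, class = "kinase-substrate")
  far <- background_network(nodes, edges)
  ev_far <- evidence_set(sources = "S", targets_by_source = list(S = character()),
                         fitness_hits = "F")
  aux_far <- build_auxiliary_paths(far, ev_far)
  expect_length(Filter(function(p) p$class == "hit_source", aux_far), 0)

  # receptor chain with exactly four intermediates
  nodes_r <- data.frame(node = c("r", "a", "b", "c", "d", "S"),
                        kind = rep("protein", 6))
  edges_r <- data.frame(node_a = c("r", "a", "b", "c", "d"),
                        node_b = c("a", "b", "c", "d", "S"),
                        directed = 1, class = "kinase-substrate")
  net_r <- background_network(nodes_r, edges_r)
  ev_r <- evidence_set(sources = "S", targets_by_source = list(S = character()),
                       receptors = data.frame(receptor = "r", source = "S"))
  aux_r <- build_auxiliary_paths(net_r, ev_r)
  rs <- Filter(function(p) p$class == "receptor_source", aux_r)
  expect_length(rs, 1)
  expect_equal(length(rs[[1]]$edges), 5)
})

test_that("paths round-trip through the TSV serialization", {
  net <- tiny_network()
  ev <- tiny_evidence()
  paths <- c(build_source_target_paths(net, "S1", c("G1", "G2"), "F1",
                                       ev$regulator_binding),
             build_auxiliary_paths(net, ev))
  f <- tempfile()
  write_paths(paths, f)
  back <- read_paths(net, f)
  expect_equal(vapply(back, `[[`, "", "path_id"),
               vapply(paths, `[[`, "", "path_id"))
  expect_equal(lapply(back, `[[`, "dir"), lapply(paths, `[[`, "dir"))
})
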