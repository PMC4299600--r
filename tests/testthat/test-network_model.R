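test_that("construction classifies directed and undirected edges", {
  net <- background_network(
    data.frame(node = c("A", "B", "G"),
               kind = c("protein", "protein", "gene_or_mrna")),
    data.frame(node_a = c("A", "B"), node_b = c("B", "G"),
               directed = c(1, 1),
               class = c("kinase-substrate", "protein-DNA")))
  expect_equal(sum(net$edges$directed), 2)
  expect_equal(sum(!net$edges$directed), 0)
  expect_setequal(net$edges$edge_id, c("A>B", "B>G"))
})

test_that("undirected duplicates collapse to one canonical record", {
  net <- background_network(
    data.frame(node = c("A", "B"), kind = c("protein", "protein")),
    data.frame(node_a = c("A", "B"), node_b = c("B", "A"),
               directed = c(0, 0),
               class = c("protein-protein", "protein-protein")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$edge_id, "A--B")
})

test_that("loading rejects invalid structures with informative errors", {
  nodes <- data.frame(node = c("A", "B"), kind = c("protein", "protein"))
  expect_error(background_network(nodes,
    data.frame(node_a = "A", node_b = "X", directed = 1,
               class = "kinase-substrate")), "A, X|X")
  expect_error(background_network(nodes,
    data.frame(node_a = c("A", "A"), node_b = c("B", "B"),
               directed = c(1, 0),
               class = c("kinase-substrate", "protein-protein"))),
    "conflicting directedness")
  expect_error(background_network(nodes,
    data.frame(node_a = "A", node_b = "A", directed = 0,
               class = "protein-protein")), "self-loop")
  expect_error(background_network(
    data.frame(node = c("A", "G"), kind = c("protein", "gene_or_mrna")),
    data.frame(node_a = "G", node_b = "A", directed = 1,
               class = "kinase-substrate")), "outgoing")
  expect_error(background_network(
    data.frame(node = c("A", "G"), kind = c("protein", "gene_or_mrna")),
    data.frame(node_a = "A", node_b = "G", directed = 0,
               class = "protein-protein")), "gene/mRNA")
  expect_error(background_network(nodes,
    data.frame(node_a = "A", node_b = "B", directed = 1,
               class = "mystery")), "unknown interaction class")
})

test_that("write then load round-trips a nontrivial network", {
  net <- generate_background(n_proteins = 40, n_genes = 20, n_tfs = 4, seed = 7)
  ef <- tempfile(); nf <- tempfile()
  write_background_network(net, ef, nf)
  net2 <- load_background_network(ef, nf)
  expect_equal(net$nodes, net2$nodes)
  expect_equal(net$edges, net2$edges)
})

test_that("loading is invariant to row order and undirected presentation", {
  nodes <- data.frame(node = c("A", "B", "C"), kind = rep("protein", 3))
  e1 <- data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                   directed = c(0, 1),
                   class = c("protein-protein", "kinase-substrate"))
  e2 <- e1[2:1, ]
  e2$node_a[[2]] <- "B"; e2$node_b[[2]] <- "A"  # flipped undirected row
  n1 <- background_network(nodes, e1)
  n2 <- background_network(nodes, e2)
  expect_equal(n1$edges, n2$edges)
})

test_that("validate_evidence reports problems without erroring", {
  net <- tiny_network()
  expect_equal(nrow(validate_evidence(net, tiny_evidence())), 0)

  ev_empty <- evidence_set(sources = "S1", targets_by_source = list(S1 = character()))
  rep1 <- validate_evidence(net, ev_empty)
  expect_true(any(rep1$category == "empty_target_set" & rep1$item == "S1"))

  ev_missing <- evidence_set(sources = "S1",
                             targets_by_source = list(S1 = "G1"),
                             fitness_hits = "NOPE")
  rep2 <- validate_evidence(net, ev_missing)
  expect_true(any(rep2$category == "missing_fitness_hit" & rep2$item == "NOPE"))
})

test_that("evidence sets round-trip through their TSV directory format", {
  ev <- evidence_set(
    sources = c("S1", "S2"),
    targets_by_source = list(S1 = c("G1", "G2"), S2 = "G2"),
    fitness_hits = "F1", phospho_hits = c("H1", "H2"),
    receptors = data.frame(receptor = "R1", source = "S1"),
    regulator_binding = list(T1 = c("G1", "G2"), T2 = "G2"),
    stress_bound_regulators = "T2")
  dir <- tempfile(); write_evidence_set(ev, dir)
  ev2 <- load_evidence_set(dir)
  expect_equal(ev$sources, ev2$sources)
  expect_equal(ev$targets_by_source, ev2$targets_by_source)
  expect_equal(ev$fitness_hits, ev2$fitness_hits)
  expect_equal(ev$phospho_hits, ev2$phospho_hits)
  expect_equal(ev$receptors, ev2$receptors, ignore_attr = TRUE)
  expect_equal(ev$regulator_binding, ev2$regulator_binding)
  expect_equal(ev$stress_bound_regulators, ev2$stress_bound_regulators)
})

test_that("SIF and GraphML exports cover the requested edge subset", {
  net <- tiny_network()
  sif <- tempfile(fileext = ".sif")
  export_sif(net, sif, edge_ids = c("S1>M1", "M1>F1"))
  lines <- readLines(sif)
  expect_length(lines, 2)
  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  expect_true(file.size(gml) > 0)
  expect_match(readLines(gml, n = 2)[2], "graphml", fixed = TRUE)
})
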