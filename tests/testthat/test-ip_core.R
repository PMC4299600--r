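# a linear three-node instance used across the model-shape checks
linear_model <- function() {
  nodes <- data.frame(node = c("S", "F", "g"),
                      kind = c("protein", "protein", "gene_or_mrna"))
  edges <- data.frame(node_a = c("S", "F"), node_b = c("F", "g"),
                      directed = 1,
                      class = c("kinase-substrate", "protein-DNA"))
  net <- background_network(nodes, edges)
  ev <- evidence_set(sources = "S", targets_by_source = list(S = "g"),
                     regulator_binding = list(F = "g"))
  paths <- build_source_target_paths(net, "S", "g", "F", ev$regulator_binding)
  list(net = net, ev = ev, paths = paths,
       model = build_ip(paths, net, ev))
}

test_that("the constraint registry matches the hand-counted template", {
  m <- linear_model()$model
  expect_length(m$paths, 1)
  expect_length(m$edges, 2)
  expect_length(m$nodes, 3)
  counts <- table(m$registry$eq)
  expect_equal(unname(counts[["1"]]), 1)   # one source-target pair
  expect_equal(unname(counts[["7"]]), 2)   # path has two edges
  expect_equal(unname(counts[["8"]]), 2)   # one per edge variable
  expect_equal(unname(counts[["9"]]), 4)   # two endpoints per edge
  expect_equal(unname(counts[["10"]]), 3)  # one per node
  expect_false("11" %in% names(counts))    # no undirected edges
})

test_that("an empty model is trivially feasible", {
  net <- tiny_network()
  ev <- evidence_set(sources = "S1", targets_by_source = list(S1 = character()))
  model <- build_ip(list(), net, ev)
  solved <- solve_ip(model, pool_size = 5)
  expect_equal(solved$model$max_connections, 0L)
  expect_equal(solved$model$max_hits, 0L)
  expect_equal(solved$model$min_nodes, 0L)
  expect_length(solved$solutions, 1)
  expect_length(solved$solutions[[1]]$nodes, 0)
})

test_that("a declared receptor pair without candidate paths fails the build", {
  net <- tiny_network()
  ev <- evidence_set(sources = "S1", targets_by_source = list(S1 = "G1"),
                     receptors = data.frame(receptor = "M1", source = "S1"),
                     regulator_binding = list(F1 = "G1"))
  paths <- build_source_target_paths(net, "S1", "G1", "F1", ev$regulator_binding)
  expect_error(build_ip(paths, net, ev), "receptor-source pair")
})

test_that("antiparallel use of one undirected edge is forbidden", {
  nodes <- data.frame(node = c("A", "B"), kind = rep("protein", 2))
  edges <- data.frame(node_a = "A", node_b = "B", directed = 0,
                      class = "protein-protein")
  net <- background_network(nodes, edges)
  p_ab <- path_from_nodes(net, c("A", "B"), class = "hit_source")
  p_ba <- path_from_nodes(net, c("B", "A"), class = "hit_source")
  ev <- evidence_set(sources = c("A", "B"),
                     targets_by_source = list(A = character(), B = character()),
                     fitness_hits = character())
  model <- build_ip(list(p_ab, p_ba), net, ev)
  sol_bad <- structure(list(path_idx = 1:2, paths = model$path_ids,
                            nodes = c("A", "B"), edges = "A--B",
                            directions = c("A--B" = "A>B"),
                            objectives = list()), class = "ip_solution")
  chk <- check_solution(model, sol_bad)
  expect_false(chk$pass)
  expect_true(11 %in% chk$violations$eq)
})

test_that("stage optima and pools match brute force on random instances", {
  tested <- 0
  for (seed in 1:60) {
    inst <- random_ip_instance(seed)
    if (is.null(inst)) next
    oracle <- brute_force_lexicographic(inst$model)
    if (is.null(oracle)) {
      # orientation conflicts between mandatory groups: the solver must
      # agree that the program is infeasible
      expect_error(solve_ip(inst$model, pool_size = 10), "infeasible")
      next
    }
    solved <- solve_ip(inst$model, pool_size = 1e9)
    expect_equal(solved$model$max_connections, oracle$max_connections,
                 label = paste("connections, seed", seed))
    expect_equal(solved$model$max_hits, oracle$max_hits,
                 label = paste("hits, seed", seed))
    expect_equal(solved$model$min_nodes, oracle$min_nodes,
                 label = paste("min nodes, seed", seed))
    sets <- solver_node_sets(inst$model)
    expect_equal(unname(sets), unname(oracle$node_sets),
                 label = paste("optimal node sets, seed", seed))
    tested <- tested + 1
    if (tested >= 20) break
  }
  expect_gte(tested, 10)
})

test_that("node-disjoint equal-cost alternatives both enter the pool", {
  nodes <- data.frame(node = c("S", "M1", "M2", "F", "g"),
                      kind = c(rep("protein", 4), "gene_or_mrna"))
  edges <- data.frame(node_a = c("S", "S", "M1", "M2", "F"),
                      node_b = c("M1", "M2", "F", "F", "g"),
                      directed = 1,
                      class = c(rep("kinase-substrate", 4), "protein-DNA"))
  net <- background_network(nodes, edges)
  ev <- evidence_set(sources = "S", targets_by_source = list(S = "g"),
                     regulator_binding = list(F = "g"))
  paths <- build_source_target_paths(net, "S", "g", "F", ev$regulator_binding)
  expect_length(paths, 2)
  solved <- solve_ip(build_ip(paths, net, ev), pool_size = 10)
  expect_length(solved$solutions, 2)
  node_sets <- lapply(solved$solutions, `[[`, "nodes")
  expect_setequal(vapply(node_sets, paste, "", collapse = ","),
                  c("F,M1,S,g", "F,M2,S,g"))
})

test_that("a shared hub beats private intermediates at stage 3", {
  # two sources can reach F through one shared hub or two private nodes
  nodes <- data.frame(
    node = c("S1", "S2", "hub", "p1", "p2", "F", "g"),
    kind = c(rep("protein", 6), "gene_or_mrna"))
  edges <- data.frame(
    node_a = c("S1", "S2", "hub", "S1", "S2", "p1", "p2", "F"),
    node_b = c("hub", "hub", "F", "p1", "p2", "F", "F", "g"),
    directed = 1,
    class = c(rep("kinase-substrate", 7), "protein-DNA"))
  net <- background_network(nodes, edges)
  ev <- evidence_set(sources = c("S1", "S2"),
                     targets_by_source = list(S1 = "g", S2 = "g"),
                     regulator_binding = list(F = "g"))
  paths <- c(build_source_target_paths(net, "S1", "g", "F", ev$regulator_binding),
             build_source_target_paths(net, "S2", "g", "F", ev$regulator_binding))
  solved <- solve_ip(build_ip(paths, net, ev), pool_size = 10)
  expect_length(solved$solutions, 1)
  expect_true("hub" %in% solved$solutions[[1]]$nodes)
  expect_false(any(c("p1", "p2") %in% solved$solutions[[1]]$nodes))
})

test_that("stage 4 adds parallel paths without changing the node set", {
  # a phospho hit on M forces the long route at stage 2; stage 4 must then
  # add the short route (same node set) as a second relevant path
  nodes <- data.frame(node = c("S", "M", "F", "g"),
                      kind = c(rep("protein", 3), "gene_or_mrna"))
  edges <- data.frame(node_a = c("S", "M", "S", "F"),
                      node_b = c("M", "F", "F", "g"),
                      directed = 1,
                      class = c("kinase-substrate", "kinase-substrate",
                                "kinase-substrate", "protein-DNA"))
  net <- background_network(nodes, edges)
  ev <- evidence_set(sources = "S", targets_by_source = list(S = "g"),
                     phospho_hits = "M",
                     regulator_binding = list(F = "g"))
  paths <- list(path_from_nodes(net, c("S", "M", "F", "g"), "source_target"),
                path_from_nodes(net, c("S", "F", "g"), "source_target"))
  solved <- solve_ip(build_ip(paths, net, ev), pool_size = 5)
  expect_length(solved$solutions, 1)
  s <- solved$solutions[[1]]
  expect_setequal(s$nodes, c("S", "M", "F", "g"))
  expect_equal(s$objectives$n_paths, 2)
  expect_setequal(s$paths, vapply(paths, `[[`, "", "path_id"))
})

test_that("pools are reproducible for identical inputs", {
  inst <- random_ip_instance(7)
  s1 <- solve_ip(inst$model, pool_size = 50, seed = 1)
  s2 <- solve_ip(inst$model, pool_size = 50, seed = 1)
  expect_identical(lapply(s1$solutions, `[[`, "nodes"),
                   lapply(s2$solutions, `[[`, "nodes"))
  expect_identical(lapply(s1$solutions, `[[`, "paths"),
                   lapply(s2$solutions, `[[`, "paths"))
})

test_that("check_solution certifies solver output and flags violations", {
  m <- linear_model()
  solved <- solve_ip(m$model, pool_size = 3)
  for (s in solved$solutions) {
    chk <- check_solution(solved$model, s)
    expect_true(chk$pass)
    expect_equal(nrow(chk$violations), 0)
  }
  empty <- structure(list(path_idx = integer(), paths = character(),
                          nodes = character(), edges = character(),
                          directions = character(), objectives = list()),
                     class = "ip_solution")
  chk2 <- check_solution(solved$model, empty)
  expect_false(chk2$pass)
  expect_true(1 %in% chk2$violations$eq)
})

test_that("the LP export writes a syntactically plausible model", {
  m <- linear_model()
  f <- tempfile(fileext = ".lp")
  write_lp(m$model, f)
  txt <- readLines(f)
  expect_equal(txt[[1]], "Minimize")
  expect_true(any(txt == "Subject To"))
  expect_true(any(txt == "Binary"))
  expect_true(any(grepl(">= 1", txt, fixed = TRUE)))
})
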