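# hand-built module subnetwork: node n with children a and b; a leads to
# induced targets, b to repressed targets
toy_subnet <- function(cluster_map = c(t1 = "induced", t2 = "induced",
                                       t3 = "repressed", t4 = "repressed"),
                       seqs = list(c("n", "a", "r1", "t1"),
                                   c("n", "a", "r1", "t2"),
                                   c("n", "b", "r2", "t3"),
                                   c("n", "b", "r2", "t4"))) {
  paths <- lapply(seqs, function(s) {
    cl <- cluster_map[[s[[length(s)]]]]
    list(path_id = paste0("source_target:", paste(s, collapse = ",")),
         class = "source_target", nodes = s, regulator = s[[length(s) - 1]],
         terminus = s[[length(s)]], cluster = cl)
  })
  labels <- list()
  for (p in paths) {
    for (nd in p$nodes[-length(p$nodes)])
      labels[[nd]] <- sort(unique(c(labels[[nd]], p$cluster)))
  }
  structure(list(paths = paths, node_labels = labels,
                 cluster_map = cluster_map,
                 enrichment = data.frame(), conf_threshold = 0.75, fdr = 0.1),
            class = "module_subnetwork")
}

test_that("count_bits matches the stated total-bit formula", {
  expect_equal(count_bits(character()), 0)
  expect_equal(count_bits(rep("induced", 5)), 0)
  expect_equal(count_bits(c("induced", "induced", "repressed", "repressed")), 4)
  expect_equal(count_bits(c(rep("induced", 3), "repressed")),
               -3 * log2(3 / 4) - 1 * log2(1 / 4), tolerance = 1e-12)
  # cross-check: |T| times the binary entropy of the mixture
  expect_equal(count_bits(c(rep("induced", 3), "repressed")),
               4 * (-(0.75) * log2(0.75) - 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_error(count_bits(c("induced", NA)), "cluster")
})

test_that("targets partition by their reachable child combination", {
  sub <- toy_subnet(
    cluster_map = c(t1 = "induced", t2 = "repressed", t3 = "induced"),
    seqs = list(c("n", "a", "r1", "t1"),
                c("n", "b", "r2", "t2"),
                c("n", "a", "r3", "t3"),
                c("n", "b", "r4", "t3")))
  parts <- partition_by_children(sub, "n")
  expect_length(parts, 3)
  expect_equal(parts[["a"]], "t1")
  expect_equal(parts[["b"]], "t2")
  expect_equal(parts[["a,b"]], "t3")

  # single child: one partition holding all targets
  sub1 <- toy_subnet(cluster_map = c(t1 = "induced", t2 = "repressed"),
                     seqs = list(c("n", "a", "r1", "t1"),
                                 c("n", "a", "r1", "t2")))
  parts1 <- partition_by_children(sub1, "n")
  expect_length(parts1, 1)
  expect_setequal(parts1[[1]], c("t1", "t2"))

  # tree topology: partitions equal the children's target sets
  tree <- toy_subnet()
  pt <- partition_by_children(tree, "n")
  expect_equal(pt[["a"]], c("t1", "t2"))
  expect_equal(pt[["b"]], c("t3", "t4"))
  expect_error(partition_by_children(tree, "t1"), "no retained outgoing")
})

test_that("the pure 2+2 split gives C=4, I=4, S=1, B=4", {
  res <- bifurcation_score(toy_subnet(), "n")
  expect_equal(res$C, 4)
  expect_equal(res$I, 4)
  expect_equal(res$S, 1)
  expect_equal(res$B, 4)
})

test_that("the score is invariant under swapping cluster labels", {
  swap <- c(induced = "repressed", repressed = "induced")
  sub <- toy_subnet()
  swapped_map <- stats::setNames(unname(swap[sub$cluster_map]),
                                 names(sub$cluster_map))
  sub_sw <- toy_subnet(cluster_map = swapped_map)
  expect_equal(bifurcation_score(sub_sw, "n")$B, bifurcation_score(sub, "n")$B)
})

test_that("duplicating every target doubles C and I but not S, so B doubles", {
  base <- toy_subnet()
  dup_map <- c(base$cluster_map,
               stats::setNames(base$cluster_map, paste0(names(base$cluster_map), "x")))
  dup_seqs <- list(c("n", "a", "r1", "t1"), c("n", "a", "r1", "t2"),
                   c("n", "b", "r2", "t3"), c("n", "b", "r2", "t4"),
                   c("n", "a", "r1", "t1x"), c("n", "a", "r1", "t2x"),
                   c("n", "b", "r2", "t3x"), c("n", "b", "r2", "t4x"))
  dup <- toy_subnet(cluster_map = dup_map, seqs = dup_seqs)
  b0 <- bifurcation_score(base, "n")
  b1 <- bifurcation_score(dup, "n")
  expect_equal(b1$C, 2 * b0$C)
  expect_equal(b1$I, 2 * b0$I)
  expect_equal(b1$S, b0$S)
  expect_equal(b1$B, 2 * b0$B)
})

test_that("unpurifying partitions give I = 0 and single partitions are excluded", {
  # each child reaches one induced and one repressed target: partitions have
  # the same mixture as the full set, so no bits are saved
  sub <- toy_subnet(cluster_map = c(t1 = "induced", t2 = "repressed",
                                    t3 = "induced", t4 = "repressed"),
                    seqs = list(c("n", "a", "r1", "t1"),
                                c("n", "a", "r1", "t2"),
                                c("n", "b", "r2", "t3"),
                                c("n", "b", "r2", "t4")))
  res <- bifurcation_score(sub, "n")
  expect_equal(res$I, 0)
  expect_equal(res$B, 0)

  single <- toy_subnet(cluster_map = c(t1 = "induced", t2 = "repressed"),
                       seqs = list(c("n", "a", "r1", "t1"),
                                   c("n", "a", "r1", "t2")))
  res1 <- bifurcation_score(single, "n")
  expect_true(is.na(res1$B))
  ranking <- rank_bifurcation_points(single)
  expect_true(all(is.na(ranking$rank[ranking$node == "n"])))
})

test_that("information gain is non-negative on random module subnetworks", {
  for (seed in 1:20) {
    set.seed(seed)
    n_t <- sample(3:8, 1)
    tg <- paste0("t", seq_len(n_t))
    cm <- stats::setNames(sample(c("induced", "repressed"), n_t, replace = TRUE), tg)
    children <- paste0("c", 1:2)
    seqs <- lapply(tg, function(t)
      c("n", sample(children, 1), paste0("r", sample(1:2, 1)), t))
    # ensure at least one target reachable via each child
    sub <- toy_subnet(cluster_map = cm, seqs = seqs)
    res <- bifurcation_score(sub, "n")
    expect_gte(res$I, -1e-9)
  }
})

test_that("ranking orders candidates by B with deterministic ties", {
  # n1 splits cleanly (high B); n2 does not purify (B = 0)
  seqs <- list(c("n1", "a", "r1", "t1"), c("n1", "a", "r1", "t2"),
               c("n1", "b", "r2", "t3"), c("n1", "b", "r2", "t4"),
               c("n2", "c", "r1", "t1"), c("n2", "c", "r1", "t3"),
               c("n2", "d", "r1", "t2"), c("n2", "d", "r2", "t4"))
  sub <- toy_subnet(seqs = seqs)
  rk <- rank_bifurcation_points(sub)
  expect_equal(rk$node[which(rk$rank == 1)], "n1")
  expect_true(rk$B[rk$node == "n1"] > rk$B[rk$node == "n2"])
})

test_that("module path extraction honors confidence and enrichment gates", {
  # regulator rI binds induced genes (enriched); rX binds a mixed bag and is
  # not enriched for either cluster at FDR 0.1
  genes <- paste0("g", 1:40)
  cluster_map <- stats::setNames(c(rep("induced", 15), rep("repressed", 15)),
                                 genes[1:30])
  binding <- list(rI = genes[1:10],            # purely induced
                  rR = genes[16:25],           # purely repressed
                  rX = genes[c(1, 16, 31:38)]) # mostly unclustered
  paths <- list(
    list(path_id = "source_target:s,rI,g1", class = "source_target",
         nodes = c("s", "rI", "g1"), regulator = "rI", terminus = "g1",
         origin = "s", edges = c("s>rI", "rI>g1"), dir = character()),
    list(path_id = "source_target:s,rR,g16", class = "source_target",
         nodes = c("s", "rR", "g16"), regulator = "rR", terminus = "g16",
         origin = "s", edges = c("s>rR", "rR>g16"), dir = character()),
    list(path_id = "source_target:s,rX,g31", class = "source_target",
         nodes = c("s", "rX", "g31"), regulator = "rX", terminus = "g31",
         origin = "s", edges = c("s>rX", "rX>g31"), dir = character()),
    list(path_id = "source_target:s,rI,g2", class = "source_target",
         nodes = c("s", "rI", "g2"), regulator = "rI", terminus = "g2",
         origin = "s", edges = c("s>rI", "rI>g2"), dir = character()))
  ens <- structure(list(
    path_confidence = c("source_target:s,rI,g1" = 1,
                        "source_target:s,rR,g16" = 0.8,
                        "source_target:s,rX,g31" = 1,
                        "source_target:s,rI,g2" = 0.6),
    node_confidence = numeric(), edge_confidence = numeric(),
    edge_direction = data.frame(), n_solutions = 10), class = "ip_ensemble")
  sub <- extract_module_paths(ens, paths, cluster_map, binding,
                              universe = 40, conf_threshold = 0.75, fdr = 0.1)
  kept <- vapply(sub$paths, `[[`, "", "path_id")
  # g2 path dropped by confidence; g31 dropped (unclustered target); rI/rR kept
  expect_setequal(kept, c("source_target:s,rI,g1", "source_target:s,rR,g16"))
  # the shared upstream node s is labeled with both clusters
  expect_setequal(sub$node_labels[["s"]], c("induced", "repressed"))
  expect_true(all(c("rI", "rR") %in% sub$enrichment$regulator[sub$enrichment$enriched]))
})
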