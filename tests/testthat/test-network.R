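toy_sets <- function() {
  list(c1 = c("t1", "t2"), c2 = c("t2", "t3"))
}

test_that("network construction counts nodes and edges correctly", {
  net <- build_network(toy_sets())
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 4L)
  empty <- build_network(stats::setNames(list(), character(0)))
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)
  # empty-set compounds become zero-degree nodes, not dropped
  net2 <- build_network(list(c1 = c("t1"), c7 = character(0)))
  expect_true("c7" %in% net2$nodes$id)
  expect_error(build_network(list(c1 = "x", c1 = "y")), "uniquely named")
  expect_error(build_network(list(c1 = "c2", c2 = "t1")), "both")
})

test_that("degree summary ranks, ties by id, and reports extremes", {
  net <- build_network(toy_sets())
  deg <- degree_summary(net)
  got <- stats::setNames(deg$degree, deg$node)
  expect_equal(got[c("c1", "c2", "t1", "t2", "t3")],
               c(c1 = 2L, c2 = 2L, t1 = 1L, t2 = 2L, t3 = 1L))
  # ranked descending, ties broken by node id
  expect_equal(deg$node[1:3], c("c1", "c2", "t2"))
  star <- build_network(list(c1 = paste0("t", 1:10)))
  expect_equal(attr(degree_summary(star), "max_degree"), 10L)
  lone <- build_network(list(c1 = character(0)))
  d <- degree_summary(lone)
  expect_equal(d$degree, 0L)
  expect_equal(attr(d, "zero_degree_compounds"), "c1")
})

test_that("degree sums and bipartiteness hold on random networks", {
  set.seed(51)
  for (i in 1:50) {
    nc <- sample(1:6, 1); nt <- sample(1:8, 1)
    sets <- lapply(seq_len(nc), function(j) {
      k <- sample(0:nt, 1)
      if (k == 0) character(0) else sample(paste0("t", 1:nt), k)
    })
    names(sets) <- paste0("c", seq_len(nc))
    net <- build_network(sets)
    expect_equal(nrow(net$edges), sum(lengths(sets)))
    deg <- degree_summary(net)
    cdeg <- sum(deg$degree[deg$type == "compound"])
    tdeg <- sum(deg$degree[deg$type == "target"])
    expect_equal(cdeg, nrow(net$edges))
    expect_equal(tdeg, nrow(net$edges))
    g <- as_igraph(net)
    expect_true(igraph::is_bipartite(g))
  }
})

test_that("clustering separates planted archetypes and ignores input order", {
  set.seed(52)
  n_bits <- 512L
  arch <- matrix(rand_bits(3 * n_bits, 0.15), 3, n_bits)
  fp <- do.call(rbind, lapply(1:30, function(i) {
    a <- (i - 1) %% 3 + 1
    ctnpharm:::.flip_bits(arch[a, ], 0.02)
  }))
  rownames(fp) <- sprintf("cmp%02d", 1:30)
  truth <- rep(1:3, 10)
  part <- cluster_compounds(fp, cut = 0.4)
  expect_equal(length(part$clusters), 3L)
  # clusters coincide with the planted labels
  for (cl in part$clusters) {
    expect_equal(length(unique(truth[match(cl, rownames(fp))])), 1L)
  }
  # permutation invariance
  perm <- sample(30)
  part2 <- cluster_compounds(fp[perm, , drop = FALSE], cut = 0.4)
  expect_equal(part2$assignment[names(part$assignment)], part$assignment)
  # degenerate cases
  one <- cluster_compounds(fp[1, , drop = FALSE], cut = 0.4)
  expect_equal(length(one$clusters), 1L)
  two_same <- rbind(a = arch[1, ], b = arch[1, ], far = arch[2, ])
  expect_equal(length(cluster_compounds(two_same, cut = 0.2)$clusters), 2L)
})

test_that("SIF and GraphML exports round-trip node and edge sets", {
  net <- build_network(c(toy_sets(), list(c7 = character(0))))
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(net, sif)
  expect_equal(length(readLines(sif)), 5L)  # 4 edges + 1 lone node
  back <- read_sif(sif)
  expect_setequal(paste(back$edges$compound, back$edges$target),
                  paste(net$edges$compound, net$edges$target))
  expect_setequal(back$nodes$id, net$nodes$id)
  write_graphml(net, gml)
  back2 <- read_graphml(gml)
  expect_setequal(paste(back2$edges$compound, back2$edges$target),
                  paste(net$edges$compound, net$edges$target))
  expect_equal(back2$nodes[order(back2$nodes$id), c("id", "type")],
               net$nodes[order(net$nodes$id), c("id", "type")],
               ignore_attr = TRUE)
  # empty network still writes valid files
  empty <- build_network(stats::setNames(list(), character(0)))
  write_sif(empty, sif); write_graphml(empty, gml)
  expect_equal(nrow(read_sif(sif)$edges), 0L)
  expect_equal(nrow(read_graphml(gml)$edges), 0L)
})

test_that("random networks round-trip through both formats", {
  set.seed(53)
  for (i in 1:100) {
    nc <- sample(1:5, 1); nt <- sample(1:6, 1)
    sets <- lapply(seq_len(nc), function(j) {
      k <- sample(0:nt, 1)
      if (k == 0) character(0) else sample(paste0("g", 1:nt), k)
    })
    names(sets) <- paste0("c", seq_len(nc))
    net <- build_network(sets)
    sif <- withr::local_tempfile(fileext = ".sif")
    gml <- withr::local_tempfile(fileext = ".graphml")
    write_sif(net, sif); write_graphml(net, gml)
    for (back in list(read_sif(sif), read_graphml(gml))) {
      expect_setequal(back$nodes$id, net$nodes$id)
      expect_setequal(paste(back$edges$compound, back$edges$target),
                      paste(net$edges$compound, net$edges$target))
    }
  }
})
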