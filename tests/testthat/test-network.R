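test_that("pearson correlation matches the covariance formula and guards input", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 4)
  expect_equal(pearson_cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_cor(x, x), 1.0)
  expect_equal(pearson_cor(x, -x), -1.0)
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(pearson_cor(a, b), oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)),
               class = "dielcross_undefined_cor_error")
  expect_error(pearson_cor(1:2, 1:2), class = "dielcross_argument_error")
})

test_that("build_network cleans edges, keeps isolated pathway nodes, scores PCC", {
  toy <- toy_network_inputs()
  net <- build_network(toy$pathway, toy$interactions,
                       expression = toy$expression, pcc_threshold = 0.5)
  # 5 records: 1 self loop, 1 duplicate unordered pair -> 3 edges
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$log$n_self_loops, 1L)
  expect_equal(net$log$n_duplicates, 1L)
  expect_equal(net$log$n_input, 5L)
  # pathway gene p3 has no interactions but stays as an isolated node
  expect_true("p3" %in% net$nodes$gene_id)
  expect_setequal(net$nodes$gene_id, c("p1", "p2", "p3", "x1", "x2"))
  # every edge endpoint is a node
  expect_true(all(c(net$edges$gene_a, net$edges$gene_b) %in%
                    net$nodes$gene_id))
  # PCC: p1 ~ x1 strongly positive, p1 ~ x2 strongly negative,
  # p2 is constant -> undefined, stays NA and never high_pcc
  e <- net$edges
  expect_gt(e$pcc[e$gene_a == "p1" & e$gene_b == "x1"], 0.5)
  expect_lt(e$pcc[e$gene_a == "p1" & e$gene_b == "x2"], -0.5)
  expect_true(is.na(e$pcc[e$gene_a == "p2" | e$gene_b == "p2"]))
  expect_identical(e$high_pcc, !is.na(e$pcc) & e$pcc > 0.5)
  # a threshold of 1 admits no flagged edge
  net1 <- build_network(toy$pathway, toy$interactions,
                        expression = toy$expression, pcc_threshold = 1)
  expect_equal(sum(net1$edges$high_pcc), 0L)
  # rebuilding with identical inputs is pure
  expect_identical(net, build_network(toy$pathway, toy$interactions,
                                      expression = toy$expression,
                                      pcc_threshold = 0.5))
  expect_error(build_network(character(0), toy$interactions),
               class = "dielcross_argument_error")
  bad <- toy$interactions; bad$confidence[1] <- 1.5
  expect_error(build_network(toy$pathway, bad),
               class = "dielcross_validation_error")
})

test_that("synthetic planted-correlation edges are flagged high-PCC", {
  cfg <- sim_config(seed = 51)
  gi <- generate_interactions(cfg, n_pathway_genes = 11, n_partners = 69,
                              planted_pcc = 0.9, frac_planted = 0.4)
  net <- build_network(unique(gi$interactions$gene_a), gi$interactions,
                       expression = gi$expression, pcc_threshold = 0.5)
  expect_equal(nrow(net$edges), 69L)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  tkey <- paste(gi$truth$gene_a, gi$truth$gene_b)
  planted <- gi$truth$planted[match(key, tkey)]
  expect_true(all(net$edges$high_pcc[planted]))
  expect_lt(mean(net$edges$high_pcc[!planted]), 0.2)
})

test_that("regulator overlays append directed edges and add missing targets", {
  toy <- toy_network_inputs()
  net <- build_network(toy$pathway, toy$interactions)
  # 11 genes bound by the factor, one of them also a direct target
  reg <- data.frame(
    regulator = "TF1",
    target = c("x1", "x2", paste0("new", 1:9), "x1"),
    relation = c(rep("bound", 11), "direct_target"),
    stringsAsFactors = FALSE)
  net2 <- overlay_regulator(net, reg)
  expect_equal(nrow(net2$regulators), 12L)
  expect_true(all(c("TF1", "new1", "new9") %in% net2$nodes$gene_id))
  expect_equal(net2$log$n_regulator_added_nodes, 10L)  # TF1 + new1..new9
  # empty overlay is the identity
  expect_identical(overlay_regulator(net, empty_reg <- data.frame(
    regulator = character(0), target = character(0),
    relation = character(0), stringsAsFactors = FALSE)), net)
  # duplicates collapse with a warning
  expect_warning(net3 <- overlay_regulator(net, rbind(reg, reg[1, ])),
                 "duplicate")
  expect_equal(nrow(net3$regulators), 12L)
  expect_error(overlay_regulator(net, data.frame(
    regulator = "TF1", target = "x1", relation = "activates",
    stringsAsFactors = FALSE)), class = "dielcross_format_error")
})

test_that("SIF export writes typed interaction lines and attribute tables", {
  toy <- toy_network_inputs()
  net <- build_network(toy$pathway, toy$interactions,
                       expression = toy$expression)
  net <- overlay_regulator(net, data.frame(
    regulator = "TF1", target = "x1", relation = "bound",
    stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir, "sif")
  sif <- readLines(paths[1])
  expect_equal(sum(grepl("\tinteracts\t", sif)), nrow(net$edges))
  expect_equal(sum(grepl("\tbound\t", sif)), 1L)
  nodes <- read.delim(paths[2])
  expect_equal(nrow(nodes), nrow(net$nodes))
  edges <- read.delim(paths[3])
  expect_equal(nrow(edges), nrow(net$edges))
  expect_error(export_network(net, dir, "gexf"),
               class = "dielcross_argument_error")
})

test_that("GraphML round trip is lossless and byte-identical", {
  cfg <- sim_config(seed = 61)
  gi <- generate_interactions(cfg, n_pathway_genes = 4, n_partners = 12)
  labels <- data.frame(gene_id = c("pathway_01", "partner_001"),
                       drought_class = c("up", "down"),
                       stringsAsFactors = FALSE)
  net <- build_network(unique(gi$interactions$gene_a), gi$interactions,
                       expression = gi$expression, labels = labels,
                       bins = c(pathway_01 = "carbohydrate metabolism"),
                       characterized = "pathway_02")
  net <- overlay_regulator(net, data.frame(
    regulator = "TF1", target = c("pathway_01", "pathway_03"),
    relation = c("bound", "regulated_up"), stringsAsFactors = FALSE))
  dir <- withr::local_tempdir()
  p1 <- export_network(net, dir, "graphml", name = "n1")
  imported <- import_network_graphml(p1)
  expect_equal(imported$nodes, net$nodes)
  expect_equal(imported$edges[c("gene_a", "gene_b", "confidence", "pcc",
                                "high_pcc")],
               net$edges[c("gene_a", "gene_b", "confidence", "pcc",
                           "high_pcc")])
  expect_equal(imported$regulators, net$regulators)
  expect_equal(imported$pcc_threshold, net$pcc_threshold)
  p2 <- export_network(imported, dir, "graphml", name = "n2")
  expect_identical(readLines(p1), readLines(p2))
})
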