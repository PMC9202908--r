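mk_de <- function(ids, classes, lfc = 0, q = 1) {
  de_result(data.frame(feature_id = ids, class = classes, base_mean = 10,
                       log2fc = lfc, p = q, q = q, detected = TRUE,
                       flag = ""))
}

test_that("miRNA edge building restricts, deduplicates and logs", {
  tt <- data.frame(miRNA_id = c("mi1", "mi1", "mi2", "mi1", ""),
                   target_id = c("g1", "g2", "g1", "g1", "g9"))
  expect_message(ed <- build_mirna_edges(c("mi1"), c("g1"), tt),
                 "malformed")
  expect_equal(nrow(ed), 2)                      # duplicate row collapsed
  expect_true(all(ed$src == "mi1"))
  ed2 <- build_mirna_edges(c("mi1"), c("g1"), tt[1:4, ],
                           de_targets_only = TRUE)
  expect_equal(ed2$dst, "g1")
  expect_equal(nrow(build_mirna_edges(character(0), "g1", tt[1:4, ])), 0)
})

test_that("merge_network unions typed edges and rejects collisions", {
  me <- data.frame(src = "mi1", dst = "g1", etype = "mirna_target")
  pp <- data.frame(lnc_id = "l1", mrna_id = "g1", r = 0.95)
  ppi <- data.frame(src = "g1", dst = "l1")   # same pair, different type
  de <- mk_de(c("mi1", "g1", "l1"), c("miRNA", "mRNA", "lncRNA"),
              lfc = c(1, -2, 2), q = c(0.01, 0.01, 0.5))
  net <- merge_network(me, pp, ppi, de = de)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)   # type-distinct parallel edges kept
  expect_setequal(net$edges$etype, c("mirna_target", "lnc_coexpr", "ppi"))
  expect_equal(net$nodes$de_direction[net$nodes$id == "g1"], "down")
  expect_equal(net$nodes$de_direction[net$nodes$id == "l1"], "none")
  # merging a network with itself is idempotent
  again <- reg_network(net$nodes, rbind(net$edges, net$edges))
  expect_identical(again, net)
  # conflicting classes for one id collide
  expect_error(reg_network(
    data.frame(id = c("x", "x"), class = c("mRNA", "miRNA"),
               de_direction = "none"),
    data.frame(src = character(), dst = character(),
               etype = character())), "collision")
  # empty merge is a valid empty network
  e <- merge_network()
  expect_equal(nrow(e$nodes), 0)
  expect_equal(nrow(e$edges), 0)
})

test_that("degree ranking is total, deterministic and hand-checkable", {
  leaves <- paste0("g", sprintf("%02d", 1:10))
  me <- data.frame(src = "mi_hub", dst = leaves, etype = "mirna_target")
  de <- mk_de(c("mi_hub", leaves), c("miRNA", rep("mRNA", 10)))
  net <- merge_network(me, de = de)
  dr <- degree_ranking(net, top_n = 20)
  expect_equal(dr$node_id[1], "mi_hub")
  expect_equal(dr$degree[1], 10)
  expect_equal(dr$out_degree[1], 10)
  expect_true(all(dr$degree[-1] == 1))
  expect_equal(dr$node_id[-1], leaves)    # ties broken lexicographically
  expect_equal(nrow(dr), 11)              # top_n beyond node count -> all
  # synthetic hub miRNA ranks first in a generated network
  cfg <- simulation_config(seed = 23, n_mrna = 100, n_lnc = 10,
                           n_mir = 15, n_modules = 0)
  ann <- generate_annotation(cfg)
  gen <- generate_counts(cfg, ann)
  tp <- generate_targets_and_pathways(cfg, ann, gen$de_truth)
  mir_ids <- ann$feature_id[ann$class == "miRNA"]
  ed <- build_mirna_edges(mir_ids, NULL, tp$targets)
  full <- merge_network(ed, de = mk_de(c(mir_ids,
                                         unique(tp$targets$target_id)),
                                       c(rep("miRNA", length(mir_ids)),
                                         rep("mRNA",
                                             length(unique(tp$targets$target_id))))))
  expect_equal(degree_ranking(full, 1)$node_id, tp$hub_mirna)
})

test_that("module subnetwork keeps selected-module edges plus miRNAs", {
  nodes <- data.frame(
    id = c("mi1", "g1", "g2", "g3", "l1"),
    class = c("miRNA", "mRNA", "mRNA", "mRNA", "lncRNA"),
    de_direction = "none")
  edges <- data.frame(
    src = c("mi1", "l1", "mi1"),
    dst = c("g1", "g2", "g3"),
    etype = c("mirna_target", "lnc_coexpr", "mirna_target"))
  net <- reg_network(nodes, edges)
  labels <- c(g1 = "blue", g2 = "blue", g3 = "brown", l1 = "turquoise")
  sub <- extract_module_subnetwork(net, labels, c("blue"))
  expect_setequal(sub$network$nodes$id, c("mi1", "g1", "l1", "g2"))
  expect_equal(nrow(sub$network$edges), 2)
  # two selected modules with no cross edges -> two components
  sub2 <- extract_module_subnetwork(net, labels, c("blue", "brown"))
  expect_gte(sub2$components$n_components, 2)
  expect_error(extract_module_subnetwork(net, labels, "chartreuse"),
               "unknown module")
  # selecting every module keeps everything; selecting none empties
  all_sub <- extract_module_subnetwork(net, labels,
                                       unique(labels))$network
  expect_equal(nrow(all_sub$edges), nrow(net$edges))
  none <- extract_module_subnetwork(net, labels, character(0))$network
  expect_equal(nrow(none$edges), 0)
})

test_that("component counts agree with a BFS oracle on random graphs", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    ids <- paste0("n", seq_len(n))
    ne <- sample(0:(n + 2), 1)
    if (ne > 0) {
      pairs <- t(replicate(ne, sample(ids, 2)))
      edges <- data.frame(src = pairs[, 1], dst = pairs[, 2],
                          etype = "ppi")
    } else {
      edges <- data.frame(src = character(), dst = character(),
                          etype = character())
    }
    net <- reg_network(data.frame(id = ids, class = "protein",
                                  de_direction = "none"), edges)
    expect_equal(network_components(net)$n_components,
                 bfs_components_oracle(ids, net$edges$src, net$edges$dst))
  }
})

test_that("graph exports round-trip and SIF has one line per edge", {
  nodes <- data.frame(id = c("mi1", "g1", "l1"),
                      class = c("miRNA", "mRNA", "lncRNA"),
                      de_direction = c("up", "down", "none"))
  edges <- data.frame(src = c("mi1", "l1"), dst = c("g1", "g1"),
                      etype = c("mirna_target", "lnc_coexpr"))
  net <- reg_network(nodes, edges)
  d <- withr::local_tempdir()
  export_graph(net, file.path(d, "n.graphml"), "graphml")
  back <- read_graphml(file.path(d, "n.graphml"))
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges, net$edges)
  export_graph(net, file.path(d, "n.sif"), "sif")
  expect_equal(length(readLines(file.path(d, "n.sif"))), nrow(net$edges))
  export_graph(net, file.path(d, "n.tsv"), "tsv")
  tsv <- utils::read.table(file.path(d, "n.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(tsv), nrow(net$edges))
  expect_error(export_graph(net, file.path(d, "x"), "gexf"))
  # empty network still exports valid files
  empty <- merge_network()
  export_graph(empty, file.path(d, "e.sif"), "sif")
  expect_equal(length(readLines(file.path(d, "e.sif"))), 0)
  export_graph(empty, file.path(d, "e.graphml"), "graphml")
  expect_equal(nrow(read_graphml(file.path(d, "e.graphml"))$nodes), 0)
})
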