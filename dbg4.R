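suppressMessages(library(tadscope))
cfg <- simulation_config(seed = 2)
ann <- generate_annotation(cfg)
gen <- generate_counts(cfg, ann)
tp <- generate_targets_and_pathways(cfg, ann, gen$de_truth)
ed <- build_mirna_edges(ann$feature_id[ann$class=="miRNA"], NULL, tp$targets)
de <- paired_nb_test(gen$cm)
net <- merge_network(ed, de = de, class_of = gen$cm$class_of)
print(head(degree_ranking(net, 6)))
cat("hub:", tp$hub_mirna, "\n")
deg <- table(tp$targets$miRNA_id)
cat("max out degree:", max(deg), " hub deg:", deg[tp$hub_mirna], "\n")
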