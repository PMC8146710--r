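#!/usr/bin/env Rscript
# Step 5: build the prophage-prophage homology network from simulated
# all-vs-all ORF hits with planted gene-content clusters, tier annotation
# confidence, flag remnant candidates, and draw a k-word dotplot for a
# syntenic pair.

suppressPackageStartupMessages(library(srpcensus))

calls <- utils::read.delim("results/prophage_calls.tsv")
cfg <- sim_config()
hs <- simulate_homology_hits(calls$prophage_id, cfg, seed = 20260925L)

pairs <- filter_homologs(hs$hits, known_prophages = calls$prophage_id)
message(sprintf("%d hits -> %d undirected homolog pairs (%d internal)",
                nrow(hs$hits), nrow(pairs), sum(pairs$internal)))

g <- build_prophage_graph(pairs, nodes = calls[, c("prophage_id",
                                                   "strain_id",
                                                   "virfam_label")])
nodes <- graph_node_table(g)
nodes$remnant_candidate <- classify_remnant(nodes$virfam_label,
                                            nodes$homolog_pairs)
write_tsv_plain(nodes, "results/homology_nodes.tsv")
write_tsv_plain(link_table(g, calls), "results/homology_links.tsv")

n_sig <- sum(igraph::E(g)$edge_class == "significant")
message(sprintf("graph: %d nodes, %d edges (%d significant, >= 10 shared ORF pairs)",
                igraph::vcount(g), igraph::ecount(g), n_sig))
message(sprintf("%d prophages with >= 10 homologous pairs (%.0f%%)",
                sum(nodes$homolog_pairs >= 10),
                100 * mean(nodes$homolog_pairs >= 10)))

conf <- annotate_confidence(hs$hits$evalue, hs$hits$aln_length)
message(sprintf("annotation confidence: %d high, %d low",
                sum(conf == "high"), sum(conf == "low")))

ann <- c("phage terminase large subunit", "integrase", "portal protein",
         "major capsid protein", "tail fiber protein",
         "hypothetical protein", "hypothetical protein", "DNA primase")
kc <- keyword_census(ann)
message(sprintf("keyword census demo: %d lifecycle, %d structural, %.0f%% hypothetical",
                sum(kc$lifecycle), sum(kc$structural),
                100 * kc$hypothetical_fraction))

# dotplot of a repeat-implanted pair: shared 400 bp cassette
set.seed(9)
core <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
s1 <- paste0(flank(300), core, flank(300))
s2 <- paste0(flank(150), core, flank(450))
dp <- dotplot(s1, s2, word_size = 12)
write_tsv_plain(dp, "results/dotplot_matches.tsv")
message(sprintf("dotplot: %d matched %d-mers along the shared cassette",
                nrow(dp), 12))
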