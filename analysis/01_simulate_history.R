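#!/usr/bin/env Rscript
# Simulate a synthetic duplication history on a toy genome, write the
# SEDEF-style alignment table it emits plus the true copy-number track
# and a CNV table with a planted degree effect, then rebuild the SD
# network from the table alone and check it against the event-log oracle.

suppressMessages(library(sdnet))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
set.seed(1)

hist <- simulate_duplication_history(
  n_chroms = 4, chrom_len = 5e5, n_events = 250,
  source_mode = "preferential", len_range = c(1e3, 1e4), seed = 101)

write_sd_table(hist$alignments, "results/synthetic/sd_table.tsv")
message(nrow(hist$alignments), " alignments emitted by ",
        nrow(hist$events), " duplication events (",
        nrow(hist$alignments) - nrow(hist$events), " secondary)")

# rebuild the network from the written table, as for real data
alns <- read_sd_alignments("results/synthetic/sd_table.tsv", "sedef")
net <- sd_network_from_alignments(alns, min_identity = 0,
                                  autosomes_only = FALSE)
print(net)
write_sd_network(net, "results/synthetic/network")

gt <- ground_truth_network(hist)
stopifnot(igraph::isomorphic(igraph::simplify(net$graph), gt$graph))
message("network is isomorphic to the event-log ground truth")

# true copy number per region and a CNV table with a planted trend
cn <- region_copy_number(hist, net$nodes)
write.table(cbind(net$nodes[, c("chrom", "start", "end", "region_id")],
                  copy_number = round(cn, 3)),
            "results/synthetic/copy_number.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cnvs <- simulate_cnv_table(net$nodes, n_cnvs = 3000, degree_effect = 1.0,
                           n_chroms = 4, chrom_len = 5e5, seed = 102)
write.table(cnvs, "results/synthetic/cnvs.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
message("wrote results/synthetic/{sd_table.tsv,network,copy_number.bed,cnvs.bed}")
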