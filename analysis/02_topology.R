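#!/usr/bin/env Rscript
# Topological characterisation of the SD network built in step 01:
# component spectrum, edges-per-size scaling, giant-component statistics,
# label-propagation modules, and edge classes.

suppressMessages(library(sdnet))
dir.create("results/topology", recursive = TRUE, showWarnings = FALSE)

net <- read_sd_network("results/synthetic/network")
sp <- component_spectrum(net)

write.table(data.frame(N = sp$sizes, E = sp$edges),
            "results/topology/components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
dens <- log_binned_density(sp$sizes)
write.table(dens, "results/topology/size_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(length(sp$sizes), " components; largest ", sp$sizes[1], " nodes")
if (nrow(sp$mean_edges_by_size) >= 3) {
  es <- estimate_f_regression(sp$mean_edges_by_size)
  message(sprintf("E(N) ~ N^%.2f  (regression f-hat = %.2f)", es$slope,
                  es$f))
}

gc <- giant_component_stats(net)
message(sprintf("giant component: %d nodes, %d edges, C = %.3f, l = %.2f",
                gc$n_nodes, gc$n_edges, gc$clustering, gc$path_length))

mods <- detect_modules(net, seed = 11)
message(length(unique(mods)), " label-propagation modules")
cls <- edge_class_fractions(net)
message(sprintf("intrachromosomal edges: %.0f%%; tandem: %.0f%%",
                100 * cls$intra_fraction, 100 * cls$tandem_fraction))

summary <- data.frame(
  nodes = nrow(net$nodes), edges = igraph::ecount(net$graph),
  components = length(sp$sizes), gc_nodes = gc$n_nodes,
  gc_edges = gc$n_edges, gc_clustering = gc$clustering,
  gc_path_length = gc$path_length, modules = length(unique(mods)),
  intra_fraction = cls$intra_fraction,
  tandem_fraction = cls$tandem_fraction)
write.table(summary, "results/topology/summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
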