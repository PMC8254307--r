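#!/usr/bin/env Rscript
# Integration profile for the real human data. Runs only when the two
# input files are supplied (they are large downloads and are not bundled):
#
#   data/genomicSuperDups.txt[.gz]  - UCSC GRCh38 genomicSuperDups dump
#   data/sv_callset.vcf[.gz]        - 1000 Genomes phase-3 integrated SV
#                                     callset (or a BED+MAC table
#                                     data/cnvs_mac.bed)
#
# Reproduces, on the real network: node/edge/component counts, the
# giant-component statistics, the E(N) exponent and f_reg, the ABC and
# motif-count estimates of delta and t, the giant-component p-value,
# the CNV fraction table, and the region-length random forest.

suppressMessages(library(sdnet))

sd_file <- Sys.glob(c("data/genomicSuperDups.txt",
                      "data/genomicSuperDups.txt.gz"))[1]
if (is.na(sd_file)) {
  message("data/genomicSuperDups.txt not found; skipping the human profile")
  quit(save = "no")
}
dir.create("results/human", recursive = TRUE, showWarnings = FALSE)

alns <- read_sd_alignments(sd_file, "ucsc")
alns <- filter_alignments(alns)          # >= 1 kb, >= 90%, autosomes
message(nrow(alns), " autosomal alignments")
net <- sd_network_from_alignments(alns)
print(net)
write_sd_network(net, "results/human/network")

sp <- component_spectrum(net)
gc <- giant_component_stats(net)
es <- estimate_f_regression(sp$mean_edges_by_size)
message(sprintf(
  "%d components; GC %d nodes / %d edges; C=%.2f l=%.2f; E(N)~N^%.2f (f_reg=%.2f)",
  length(sp$sizes), gc$n_nodes, gc$n_edges, gc$clustering,
  gc$path_length, es$slope, es$f))

abc <- abc_delta(sp$sizes, f = round(es$f, 2), prior = c(5e-5, 9e-4),
                 n_sims = 5000, tolerance = 0.2, target_nodes = 6656,
                 seed = 7)
print(abc)

fit <- minimize_loss(motif_counts(net), seed = 8)
message(sprintf("loss fit: f=%.2f delta=%.2g t=%.0f (loss %.3f)",
                fit$f, fit$delta, fit$t, fit$loss))

pooled <- pool_simulations(growth_params("pcm", delta = abc$estimate,
                                         f = round(es$f, 2),
                                         target_nodes = 6656, seed = 9),
                           n_reps = 500)
message(sprintf("GC p-value: %.2f",
                giant_component_pvalue(gc$n_nodes, pooled$biggest)))

cnv_file <- Sys.glob(c("data/sv_callset.vcf", "data/sv_callset.vcf.gz",
                       "data/cnvs_mac.bed"))[1]
if (!is.na(cnv_file)) {
  dialect <- if (grepl("\\.bed$", cnv_file)) "bed_mac" else "vcf"
  cnvs <- read_cnvs(cnv_file, dialect)
  tab <- overlap_fraction_table(net$nodes, cnvs)
  write.table(tab, "results/human/cnv_fractions.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  print(tab, row.names = FALSE, digits = 3)
}

cn_file <- Sys.glob("data/copy_number.bed")[1]
cn <- if (!is.na(cn_file)) read.table(cn_file, sep = "\t")$V5 else NULL
features <- extract_region_features(net, copy_number = cn)
fit_len <- fit_length_model(features, seed = 10)
message(sprintf("region-length RF: 10-fold R2 = %.2f", fit_len$r_squared))
pv <- permutation_importance_pvalues(features, n_perm = 1000, seed = 11)
write.table(pv, "results/human/length_importance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
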