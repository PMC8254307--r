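#!/usr/bin/env Rscript
# What drives duplicated-region length? Random-forest regression of
# region length on untrimmed-network features with permutation
# importance p-values, on the synthetic network from step 01.

suppressMessages(library(sdnet))
dir.create("results/length_model", recursive = TRUE, showWarnings = FALSE)

net <- read_sd_network("results/synthetic/network")
cn <- read.table("results/synthetic/copy_number.bed", sep = "\t")
stopifnot(nrow(cn) == nrow(net$nodes))
features <- extract_region_features(net, copy_number = cn$V5)
message(nrow(features), " regions x ", ncol(features) - 1, " features")

fit <- fit_length_model(features, n_folds = 10, seed = 21)
message(sprintf("10-fold cross-validated R2 = %.2f", fit$r_squared))

pv <- permutation_importance_pvalues(features, n_perm = 200,
                                     n_trees = 300, seed = 22)
pv <- pv[order(pv$p_value), ]
write.table(pv, "results/length_model/importance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(pv, row.names = FALSE, digits = 3)
jsonlite::write_json(list(r_squared = fit$r_squared,
                          per_fold = fit$per_fold,
                          n_perm = 200, alpha = 0.01),
                     "results/length_model/metrics.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
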