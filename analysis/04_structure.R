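#!/usr/bin/env Rscript
# Population structure: PCA, ancestry classification against the simulated
# truth labels, pairwise Weir-Cockerham FST and Mantel isolation-by-distance.

suppressPackageStartupMessages(library(fragpop))

ds <- read_genotypes("results/genotypes_clean.csv", "dart_csv", orient_minor = FALSE)
meta <- utils::read.csv("results/sample_meta.csv")
ds <- attach_metadata(ds, meta[meta$sample_id %in% ds$sample_ids, ])

pca <- run_pca(ds, 2)
utils::write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                            site = ds$sample_meta$site,
                            ancestry = ds$sample_meta$ancestry),
                 "results/pca_scores.csv", row.names = FALSE)
cat(sprintf("PCA: axis 1 explains %.1f%%, axis 2 %.1f%%\n",
            100 * pca$explained[1], 100 * pca$explained[2]))

fst <- pairwise_fst(ds)
utils::write.csv(as.data.frame(fst), "results/fst_matrix.csv")
cat("pairwise FST (upper corner):\n")
print(round(fst[1:4, 1:4], 3))

km <- tapply(ds$sample_meta$river_km, ds$sample_meta$site, unique)
km <- km[rownames(fst)]
geo <- abs(outer(km, km, "-"))
mt <- mantel_test(fst, geo, n_perm = 999, seed = 1)
cat(sprintf("isolation by distance: Mantel r = %.2f, p = %.3f\n", mt$r, mt$p))
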