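#!/usr/bin/env Rscript
# Heterozygosity and inbreeding: individual PHt, per-group Ho/He/FIS on a
# fixed locus panel, the upstream-downstream diversity gradient, and
# effective inbreeding of each site against the most diverse site.

suppressPackageStartupMessages(library(fragpop))

ds <- read_genotypes("results/genotypes_clean.csv", "dart_csv", orient_minor = FALSE)
meta <- utils::read.csv("results/sample_meta.csv")
ds <- attach_metadata(ds, meta[meta$sample_id %in% ds$sample_ids, ])

pht <- individual_pht(ds)
utils::write.csv(pht, "results/individual_pht.csv", row.names = FALSE)

div <- diversity_table(ds, make_groupings(ds), min_n = 11)
utils::write.csv(div, "results/diversity.csv", row.names = FALSE)
print(div[, c("group", "n", "Ho", "He", "Fis")], digits = 3)

m <- het_distance_model(pht, ds$sample_meta$river_km)
cat(sprintf("PHt vs river distance: slope %.2e per km, p = %.3g, r2 = %.3f\n",
            m$slope, m$p_value, m$r2))

a <- group_anova(pht$pht, ds$sample_meta$site)
cat(sprintf("PHt differs among sites: ANOVA p = %.3g\n", a$anova$`Pr(>F)`[1]))

site_rows <- div[!grepl("\\.", div$group) & div$group != "all", ]
ref <- max(site_rows$He)
fe <- data.frame(site = site_rows$group, He = site_rows$He,
                 Fe = suppressWarnings(effective_inbreeding(site_rows$He, ref)))
utils::write.csv(fe, "results/effective_inbreeding.csv", row.names = FALSE)
cat("Fe per site (reference = most diverse site):\n")
print(fe, digits = 3)
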