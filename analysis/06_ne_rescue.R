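#!/usr/bin/env Rscript
# LD-based effective sizes over the standard monitoring groupings
# (site-by-cohort, cohort pooled, site pooled, all; with/without admixed),
# life-history adjustments, and the genetic-rescue migrant calculator.

suppressPackageStartupMessages(library(fragpop))

ds <- read_genotypes("results/genotypes_thinned.csv", "dart_csv", orient_minor = FALSE)
meta <- utils::read.csv("results/sample_meta.csv")
ds <- attach_metadata(ds, meta[meta$sample_id %in% ds$sample_ids, ])

ne <- ne_scan(ds, make_groupings(ds), ldne_config(pcrit = 0.01), min_n = 11)
life <- life_history(23, 3)
fin <- is.finite(ne$ne_hat)
ne$nb_adj <- NA_real_
ne$nb_adj[fin] <- adjust_nb(ne$ne_hat[fin], life$nb_ne_ratio)$nb_adj
write_ne_table(ne, "results/ne_estimates.csv")
print(ne[, c("label", "n", "ne_hat", "nb_adj")], digits = 4)
cat(sprintf("skipped groups (< 11 samples): %s\n",
            paste(attr(ne, "skipped"), collapse = "; ")))

pooled <- ne$ne_hat[ne$label %in% c("all", "all.no_admixed")]
per_site <- ne$ne_hat[ne$label %in% c("S5", "S8", "S8.no_admixed", "S9",
                                      "S9.no_admixed")]
cat(sprintf("pooled-all Ne = %.1f vs per-site (downstream) min %.1f: %s\n",
            pooled[1], min(per_site, na.rm = TRUE),
            if (pooled[1] < min(per_site, na.rm = TRUE))
              "pooling diverged demes collapses the estimate" else
              "no pooling bias visible"))

fe <- utils::read.csv("results/effective_inbreeding.csv")
site_ne <- ne[match(fe$site, sub("\\.no_admixed$", "", ne$label)), ]
keep <- fe$Fe > 0.1 & is.finite(site_ne$nb_adj)
plan <- rescue_plan(fe$site[keep], fe$Fe[keep], site_ne$nb_adj[keep],
                    Fe_target = 0.1)
utils::write.csv(plan, "results/rescue_plan.csv", row.names = FALSE)
cat("genetic-rescue plan (target Fe < 0.1):\n")
print(plan, digits = 3)
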