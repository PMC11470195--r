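# shared fixture builders; everything is generated in code under fixed seeds

# truncated-Beta allele frequencies matching the simulator's ancestral model
fixture_freqs <- function(L, seed = 1) {
  withr::with_seed(seed, fragpop:::.rtrunc_beta(
    L, list(shape1 = 0.5, shape2 = 0.5, lower = 0.05, upper = 0.95)))
}

# iid Hardy-Weinberg genotypes from given allele frequencies
hwe_genotypes <- function(n, p, seed = 1) {
  withr::with_seed(seed,
    vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n)))
}

hwe_dataset <- function(n, L, seed = 1, sample_meta = NULL) {
  p <- fixture_freqs(L, seed)
  genotype_dataset(hwe_genotypes(n, p, seed + 1), sprintf("h%03d", seq_len(n)),
                   sample_meta = sample_meta)
}

# a child of two parental dosage vectors (Mendelian, unlinked loci)
mate <- function(g1, g2) {
  stats::rbinom(length(g1), 1L, g1 / 2) + stats::rbinom(length(g2), 1L, g2 / 2)
}

# pedigree fixture: planted full-sib families on an unrelated background.
# family_sizes: children per family (each family has its own parent pair,
# parents drawn fresh from the allele frequencies and not included).
pedigree_dataset <- function(family_sizes, n_unrelated, L = 1000, seed = 1,
                             error_rate = 0) {
  p <- fixture_freqs(L, seed)
  withr::with_seed(seed + 1, {
    rows <- list(); fam_id <- integer()
    for (f in seq_along(family_sizes)) {
      pa <- stats::rbinom(L, 2L, p); pb <- stats::rbinom(L, 2L, p)
      for (k in seq_len(family_sizes[f])) {
        rows[[length(rows) + 1L]] <- mate(pa, pb)
        fam_id <- c(fam_id, f)
      }
    }
    for (k in seq_len(n_unrelated)) {
      rows[[length(rows) + 1L]] <- stats::rbinom(L, 2L, p)
      fam_id <- c(fam_id, 0L)
    }
    G <- do.call(rbind, rows)
    if (error_rate > 0) {
      flip <- which(stats::runif(length(G)) < error_rate)
      G[flip] <- sample(0:2, length(flip), replace = TRUE)
    }
    ds <- genotype_dataset(G, sprintf("p%03d", seq_len(nrow(G))))
    attr(ds, "family") <- fam_id
    ds
  })
}

# tiny hand-built dataset used across io/qc tests
toy_dataset <- function() {
  dos <- rbind(a1 = c(0L, 1L, 2L, 1L),
               a2 = c(1L, 1L, 0L, NA),
               a3 = c(2L, 0L, 1L, 0L))
  lm <- data.frame(locus_id = paste0("L", 1:4), tag_id = paste0("t", c(1, 1, 2, 3)),
                   chrom = c("1", "1", "2", NA), pos = c(100L, 5000L, 200L, NA),
                   mean_depth = c(10, 20, 3, 30),
                   reproducibility = c(1, 0.99, 1, 0.9))
  sm <- data.frame(sample_id = c("a1", "a2", "a3"), site = c("S1", "S2", "S2"),
                   river_km = c(0, 5, 5), capture_year = c(2020L, 2021L, 2021L))
  genotype_dataset(dos, c("a1", "a2", "a3"), locus_meta = lm, sample_meta = sm)
}

# minimal VCF text with one triallelic record among five
toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT", "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T", ".", "PASS", ".", "GT", "0/1", "0/1", "0/0", sep = "\t"),
    paste("1", "300", "v3", "G", "A,T", ".", "PASS", ".", "GT", "0/1", "0/2", "1/1", sep = "\t"),
    paste("2", "100", "v4", "T", "C", ".", "PASS", ".", "GT", "1/1", "./.", "0/0", sep = "\t"),
    paste("2", "250", "v5", "A", "C", ".", "PASS", ".", "GT", "0/0", "0/0", "0/1", sep = "\t")),
    path)
  path
}
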