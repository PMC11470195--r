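test_that("excess-het test matches the exact binomial tail", {
  r <- excess_het_test(50, 50, 0.05)
  expect_equal(r$p_value, 0.5^50)
  expect_true(r$flagged)
  expect_gt(excess_het_test(25, 50, 0.05)$p_value, 0.5)
  expect_false(excess_het_test(25, 50, 0.05)$flagged)
  expect_equal(excess_het_test(0, 50, 0.05)$p_value, 1)
  expect_error(excess_het_test(5, 0), "called_count")
})

test_that("filter chain drops loci stage by stage with a faithful report", {
  # 10 loci: 2 with depth 3, 1 with reproducibility 0.9 -> 7 survive stages 1-2
  G <- hwe_genotypes(12, fixture_freqs(10, seed = 3), seed = 11)
  lm <- data.frame(locus_id = sprintf("L%02d", 1:10),
                   mean_depth = c(3, 3, rep(20, 8)),
                   reproducibility = c(1, 1, 0.9, rep(0.99, 7)))
  ds <- genotype_dataset(G, sprintf("i%02d", 1:12), locus_meta = lm)
  res <- apply_qc(ds, qc_config(one_per_tag = FALSE), seed = 1)
  st <- res$report$stages
  expect_equal(st$depth$n_after, 8)
  expect_equal(st$reproducibility$n_after, 7)
  expect_setequal(st$depth$dropped, c("L01", "L02"))
  expect_equal(st$reproducibility$dropped, "L03")
  expect_equal(ncol(res$ds$dosages), 7)
  # counts monotone non-increasing through the chain
  locus_counts <- vapply(st[vapply(st, function(s) s$what == "loci", TRUE)],
                         function(s) s$n_after, numeric(1))
  expect_true(all(diff(locus_counts) <= 0))
})

test_that("a clean dataset passes unchanged and the chain is idempotent", {
  ds <- hwe_dataset(15, 25, seed = 5)
  res <- apply_qc(ds, qc_config(), seed = 2)
  expect_identical(res$ds$dosages, ds$dosages)
  drops <- vapply(res$report$stages, function(s) length(s$dropped), integer(1))
  expect_true(all(drops == 0))
  twice <- apply_qc(res$ds, qc_config(), seed = 2)
  expect_identical(twice$ds$dosages, res$ds$dosages)
})

test_that("one SNP per tag is kept, deterministically under a seed", {
  ds <- toy_dataset()  # L1 and L2 share tag t1
  r1 <- apply_qc(ds, qc_config(depth_min = 0, reproducibility_min = 0,
                               locus_missing_max = 1), seed = 7)
  kept <- r1$ds$locus_meta$locus_id
  expect_equal(sum(kept %in% c("L1", "L2")), 1L)
  r2 <- apply_qc(ds, qc_config(depth_min = 0, reproducibility_min = 0,
                               locus_missing_max = 1), seed = 7)
  expect_identical(r2$ds$locus_meta$locus_id, kept)
  # MAC filter is only active when configured
  expect_error(apply_qc(genotype_dataset(matrix(1L, 6, 2)),
                        qc_config(mac_min = 20)), "all loci")
})

test_that("excess-het filter removes a planted always-het artefact locus", {
  G <- hwe_genotypes(40, fixture_freqs(30, seed = 6), seed = 13)
  G <- cbind(G, matrix(1L, 40, 1))   # collapsed-paralog signature
  ds <- genotype_dataset(G, sprintf("i%02d", 1:40))
  res <- apply_qc(ds, qc_config(one_per_tag = FALSE), seed = 1)
  expect_equal(res$report$stages$excess_het$dropped, "L0031")
})

test_that("distance thinning keeps one locus per window", {
  pos <- c(1000L, 10000L, 49000L, 60000L, 120000L)
  lm <- data.frame(locus_id = paste0("L", 1:5), chrom = "1", pos = pos)
  ds <- genotype_dataset(hwe_genotypes(8, rep(0.4, 5), seed = 2),
                         sprintf("i%d", 1:8), locus_meta = lm)
  th <- thin_by_distance(ds, 50000L, seed = 3)
  expect_equal(ncol(th$dosages), 3L)  # windows [0,50k) [50k,100k) [100k,150k)
  w <- floor(th$locus_meta$pos / 50000)
  expect_equal(sort(w), 0:2)
  expect_identical(thin_by_distance(ds, 50000L, seed = 3)$locus_meta$locus_id,
                   th$locus_meta$locus_id)
  # unplaced loci removed; same-window loci collapse to one
  ds2 <- toy_dataset()  # L1/L2 share chrom-1 window 0; L3 on chrom 2; L4 unplaced
  th2 <- thin_by_distance(ds2, 50000L, seed = 1)
  expect_equal(ncol(th2$dosages), 2L)
  expect_true("L3" %in% th2$locus_meta$locus_id)
  expect_false("L4" %in% th2$locus_meta$locus_id)
})

test_that("LD decays with physical distance on linked genotypes", {
  pos <- sort(sample(withr::with_seed(8, sample.int(3e5, 70))))
  ds <- sim_linked_genotypes(60, positions = pos, decay_bp = 20000, seed = 2)
  ld <- ld_decay(ds, max_dist_bp = 2e5, bin_bp = 40000)
  expect_gt(nrow(ld$bins), 2)
  # monotone non-increasing trend (rank correlation of bin mean vs distance)
  expect_lt(stats::cor(ld$bins$bin_mid, ld$bins$mean_r2, method = "spearman"), 0)
  expect_gt(ld$bins$mean_r2[1], utils::tail(ld$bins$mean_r2, 1))
  # a duplicated locus at distance ~0 shows near-complete LD
  dup <- ds
  dup$dosages[, 2] <- dup$dosages[, 1]
  dup$locus_meta$pos[2] <- dup$locus_meta$pos[1] + 1L
  ld2 <- ld_decay(dup, max_dist_bp = 2e5, bin_bp = 40000)
  expect_gt(ld2$bins$mean_r2[1], 0.2)
  # unlinked loci across chromosomes sit at background
  un <- hwe_dataset(80, 40, seed = 12)
  un$locus_meta$chrom <- rep(c("1", "2"), each = 20)
  un$locus_meta$pos <- rep(seq(1e4, 2e5, length.out = 20), 2)
  ld3 <- ld_decay(un, max_dist_bp = 2e5, bin_bp = 1e5)
  expect_lt(max(ld3$bins$mean_r2), 3 * ld3$background$mean_r2 + 0.05)
  expect_error(ld_decay(hwe_dataset(10, 5, seed = 1)), "placed")
})
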