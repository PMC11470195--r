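# two diverged populations drawn directly from perturbed allele frequencies
two_pop_dataset <- function(n_per = 40, L = 300, fst = 0.1, seed = 1) {
  p0 <- fixture_freqs(L, seed)
  withr::with_seed(seed + 1, {
    # Balding-Nichols style divergence: per-pop freqs ~ Beta around p0
    a <- (1 - fst) / fst
    p1 <- stats::rbeta(L, p0 * a, (1 - p0) * a)
    p2 <- stats::rbeta(L, p0 * a, (1 - p0) * a)
    G <- rbind(vapply(p1, function(pp) stats::rbinom(n_per, 2L, pp), integer(n_per)),
               vapply(p2, function(pp) stats::rbinom(n_per, 2L, pp), integer(n_per)))
    sm <- data.frame(sample_id = sprintf("s%03d", seq_len(2 * n_per)),
                     site = rep(c("A", "B"), each = n_per))
    list(ds = genotype_dataset(G, sm$sample_id, sample_meta = sm),
         p1 = p1, p2 = p2)
  })
}

test_that("PCA separates diverged populations on the first axis", {
  tp <- two_pop_dataset(n_per = 40, L = 300, fst = 0.1, seed = 7)
  pca <- run_pca(tp$ds, 2)
  grp <- tp$ds$sample_meta$site
  s1 <- pca$scores[grp == "A", 1]; s2 <- pca$scores[grp == "B", 1]
  pooled_sd <- sqrt((stats::var(s1) + stats::var(s2)) / 2)
  expect_gt(abs(mean(s1) - mean(s2)), 4 * pooled_sd)
  # a duplicated individual lands on identical coordinates
  dup <- tp$ds
  dup$dosages[2, ] <- dup$dosages[1, ]
  p2 <- run_pca(dup, 2)
  expect_equal(p2$scores[1, ], p2$scores[2, ], tolerance = 1e-9)
  expect_error(run_pca(genotype_dataset(matrix(1L, 5, 4)), 2), "constant")
})

test_that("no PCA axis separates random halves of a panmictic sample", {
  reject <- vapply(1:20, function(s) {
    ds <- hwe_dataset(40, 150, seed = 200 + s)
    pca <- run_pca(ds, 2)
    half <- rep(c(TRUE, FALSE), 20)
    min(stats::t.test(pca$scores[half, 1], pca$scores[!half, 1])$p.value,
        stats::t.test(pca$scores[half, 2], pca$scores[!half, 2])$p.value) < 0.01
  }, logical(1))
  expect_lte(mean(reject), 0.05)
})

test_that("ancestry classification recovers F1s between diverged populations", {
  hits <- vapply(1:20, function(s) {
    tp <- two_pop_dataset(n_per = 30, L = 400, fst = 0.08, seed = 300 + s)
    withr::with_seed(s, {
      f1 <- t(vapply(1:10, function(i)
        stats::rbinom(400, 1L, tp$p1) + stats::rbinom(400, 1L, tp$p2),
        integer(400)))
    })
    G <- rbind(tp$ds$dosages, f1)
    ids <- c(tp$ds$sample_ids, sprintf("f%02d", 1:10))
    ds <- genotype_dataset(G, ids)
    pca <- run_pca(ds, 2)
    site <- tp$ds$sample_meta$site
    lab <- classify_ancestry(pca, source_ids = ids[which(site == "B")],
                             local_ids = ids[which(site == "A")], axis = 1)
    mean(lab[sprintf("f%02d", 1:10)] == "admixed")
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.9)
})

test_that("ancestry labels are orientation-invariant and pure sets stay pure", {
  tp <- two_pop_dataset(n_per = 30, L = 400, fst = 0.1, seed = 401)
  pca <- run_pca(tp$ds, 2)
  site <- tp$ds$sample_meta$site
  ids <- tp$ds$sample_ids
  lab <- classify_ancestry(pca, ids[site == "B"], ids[site == "A"], axis = 1)
  expect_false(any(lab[ids[site == "A"]] == "source"))
  expect_lt(mean(lab == "admixed"), 0.1)
  flipped <- pca
  flipped$scores[, 1] <- -flipped$scores[, 1]
  lab2 <- classify_ancestry(flipped, ids[site == "B"], ids[site == "A"], axis = 1)
  expect_identical(lab, lab2, ignore_attr = TRUE)
  # overlapping references are refused
  expect_error(classify_ancestry(pca, ids[site == "A"][1:15],
                                 ids[site == "A"][16:30], axis = 1), "overlap")
})

test_that("Weir-Cockerham FST is null within and calibrated between demes", {
  # one panmictic population split into two labelled halves
  ds <- hwe_dataset(200, 400, seed = 500,
                    sample_meta = data.frame(
                      sample_id = sprintf("h%03d", 1:200),
                      site = rep(c("X", "Y"), 100)))
  f <- pairwise_fst(ds)
  expect_lt(abs(attr(f, "raw")["X", "Y"]), 0.01)
  expect_equal(diag(f), c(X = 0, Y = 0))
  # identical dosage matrices as two sites: exactly zero after flooring
  G <- hwe_genotypes(30, fixture_freqs(100, 501), seed = 502)
  ds2 <- genotype_dataset(rbind(G, G), sprintf("d%03d", 1:60),
                          sample_meta = data.frame(
                            sample_id = sprintf("d%03d", 1:60),
                            site = rep(c("A", "B"), each = 30)))
  expect_equal(pairwise_fst(ds2)["A", "B"], 0)
  # drift closed form: demes of size Ne isolated t generations
  fst_hat <- vapply(1:4, function(s) {
    cfg <- sim_config(deme_sizes = c(50, 50), n_loci = 500, n_generations = 30,
                      sampling = data.frame(deme = c(1, 2), generation = 30,
                                            n = c(40, 40)), seed = 510 + s)
    pairwise_fst(simulate_metapop(cfg)$ds)["S1", "S2"]
  }, numeric(1))
  expected <- 1 - (1 - 1 / 100)^30
  expect_lt(abs(mean(fst_hat) - expected), 0.05)
})

test_that("Mantel test has the right fixed points and matches vegan", {
  d <- as.matrix(stats::dist(withr::with_seed(600, matrix(stats::rnorm(16), 8))))
  expect_equal(mantel_test(d, d, n_perm = 99)$r, 1)
  expect_equal(mantel_test(d, -d, n_perm = 99)$r, -1)
  expect_error(mantel_test(d, matrix(1, 8, 8)), "constant")
  d2 <- as.matrix(stats::dist(withr::with_seed(601, matrix(stats::rnorm(16), 8))))
  ours <- mantel_test(d, d2, n_perm = 999, seed = 3)
  skip_if_not_installed("vegan")
  veg <- vegan::mantel(d, d2, permutations = 999)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
})
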