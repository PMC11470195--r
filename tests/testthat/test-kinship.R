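test_that("relatedness separates full sibs, parent-offspring and unrelateds", {
  ds <- pedigree_dataset(family_sizes = c(6), n_unrelated = 24, L = 1000,
                         seed = 11)
  fam <- attr(ds, "family")
  pr <- pairwise_relatedness(ds)
  i1 <- match(pr$id1, ds$sample_ids); i2 <- match(pr$id2, ds$sample_ids)
  sib <- fam[i1] == 1 & fam[i2] == 1
  unrel <- fam[i1] == 0 & fam[i2] == 0
  expect_gt(mean(pr$r_hat[sib]), 0.4); expect_lt(mean(pr$r_hat[sib]), 0.6)
  expect_gt(mean(pr$r_hat[unrel]), -0.1); expect_lt(mean(pr$r_hat[unrel]), 0.1)
  # parent-offspring pairs: build children of known parents explicitly
  p <- fixture_freqs(1000, seed = 12)
  withr::with_seed(13, {
    par1 <- stats::rbinom(1000, 2L, p); par2 <- stats::rbinom(1000, 2L, p)
    kid <- mate(par1, par2)
  })
  ds2 <- genotype_dataset(rbind(par1, par2, kid,
                                hwe_genotypes(20, p, seed = 14)),
                          c("par1", "par2", "kid", sprintf("u%02d", 1:20)))
  pr2 <- pairwise_relatedness(ds2)
  po <- pr2[pr2$id1 %in% c("par1", "par2") & pr2$id2 == "kid", ]
  expect_true(all(po$r_hat > 0.4 & po$r_hat < 0.6))
  # identical genotypes mismatch at no locus
  dup <- genotype_dataset(rbind(a = par1, b = par1), c("a", "b"))
  expect_equal(pairwise_relatedness(dup, min_loci = 10)$mismatch_rate, 0)
})

test_that("duplicate detection tolerates 1% genotyping error, not sibship", {
  found_dup <- logical(10); grouped_sib <- logical(10)
  for (s in 1:10) {
    ds <- pedigree_dataset(family_sizes = c(2), n_unrelated = 18, L = 1000,
                           seed = 100 + s)
    # plant a re-genotyped copy of the first individual with 1% error
    g <- ds$dosages[1, ]
    withr::with_seed(200 + s, {
      flip <- which(stats::runif(1000) < 0.01)
      g[flip] <- sample(0:2, length(flip), replace = TRUE)
    })
    ds2 <- genotype_dataset(rbind(ds$dosages, recap = g),
                            c(ds$sample_ids, "recap"))
    dups <- find_duplicates(pairwise_relatedness(ds2))
    found_dup[s] <- any(vapply(dups, function(gr)
      all(c("p001", "recap") %in% gr), logical(1)))
    grouped_sib[s] <- any(vapply(dups, function(gr)
      all(c("p001", "p002") %in% gr), logical(1)))
  }
  expect_true(all(found_dup))
  expect_false(any(grouped_sib))
  expect_equal(find_duplicates(data.frame(id1 = character(), id2 = character(),
                                          r_hat = numeric(),
                                          mismatch_rate = numeric())), list())
})

test_that("sib clustering recovers planted families and avoids false ones", {
  recovered <- logical(20); clean_runs <- logical(20); merged <- logical(20)
  for (s in 1:20) {
    ds <- pedigree_dataset(family_sizes = c(5), n_unrelated = 50, L = 1000,
                           seed = 300 + s)
    fam <- sib_clusters(pairwise_relatedness(ds))
    planted <- ds$sample_ids[attr(ds, "family") == 1]
    sizes <- table(fam$family[fam$sample_id %in% planted])
    recovered[s] <- length(sizes) == 1 && max(sizes) >= 4
    # pure unrelateds should yield nothing
    un <- pedigree_dataset(family_sizes = integer(), n_unrelated = 40,
                           L = 1000, seed = 400 + s)
    clean_runs[s] <- nrow(sib_clusters(pairwise_relatedness(un))) == 0
    # two disjoint families must not merge
    two <- pedigree_dataset(family_sizes = c(4, 4), n_unrelated = 20,
                            L = 1000, seed = 500 + s)
    f2 <- sib_clusters(pairwise_relatedness(two))
    fa <- unique(f2$family[f2$sample_id %in% two$sample_ids[attr(two, "family") == 1]])
    fb <- unique(f2$family[f2$sample_id %in% two$sample_ids[attr(two, "family") == 2]])
    merged[s] <- length(intersect(fa, fb)) > 0
  }
  expect_gte(mean(recovered), 0.9)
  expect_gte(mean(clean_runs), 0.9)
  expect_lte(mean(merged), 0.1)
})

test_that("family output is invariant to sample order", {
  ds <- pedigree_dataset(family_sizes = c(4, 3), n_unrelated = 15, L = 800,
                         seed = 601)
  fam1 <- sib_clusters(pairwise_relatedness(ds))
  perm <- withr::with_seed(602, sample(nrow(ds$dosages)))
  ds2 <- subset_genotypes(ds, samples = perm)
  fam2 <- sib_clusters(pairwise_relatedness(ds2))
  key <- function(f) sort(vapply(split(f$sample_id, f$family),
                                 function(v) paste(sort(v), collapse = "+"), ""))
  expect_equal(unname(key(fam1)), unname(key(fam2)))
})

test_that("cross-site family edges summarize dispersal evidence", {
  fam <- data.frame(family = c(1, 1, 1, 2, 2),
                    sample_id = paste0("x", 1:5),
                    site = c("A", "A", "B", "C", "C"),
                    cohort = c("2020", "2020", "2021", "2019", "2019"))
  class(fam) <- c("sib_families", "data.frame")
  conn <- family_connectivity(fam)
  expect_equal(nrow(conn$edges), 1)
  expect_equal(conn$edges$site_a, "A"); expect_equal(conn$edges$site_b, "B")
  expect_equal(conn$families$n_sites, c(2, 1))
  expect_equal(conn$families$cohorts[1], "2020+2021")
  # all single-site families: no edges
  fam$site <- "A"
  expect_equal(nrow(family_connectivity(fam)$edges), 0)
})
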