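test_that("composite r2 matches hand-computed values", {
  # x = y: Delta = 3/4 - 2*0.25 = 0.25, r2 = 1 at p = q = 0.5
  r <- pair_r2(c(0, 1, 1, 2), c(0, 1, 1, 2))
  expect_equal(r$delta, 0.25)
  expect_equal(r$r2, 1)
  expect_equal(r$S_pair, 4L)
  # perfect repulsion is equally complete LD
  expect_equal(pair_r2(c(0, 1, 1, 2), c(2, 1, 1, 0))$r2, 1)
  # missing data restrict to jointly called individuals
  r2 <- pair_r2(c(0, 1, 1, 2, NA), c(0, 1, 1, 2, 1))
  expect_equal(r2$S_pair, 4L)
  expect_equal(r2$r2, 1)
  expect_warning(rm <- pair_r2(c(0, 0, 0, 0), c(0, 1, 2, 1)), "monomorphic")
  expect_true(is.na(rm$r2))
  expect_error(pair_r2(c(0, NA), c(NA, 1)), "jointly called")
})

test_that("matrix r2 agrees with the scalar path under missing data", {
  ds <- hwe_dataset(25, 12, seed = 51)
  ds$dosages[cbind(sample(25, 10, TRUE), sample(12, 10, TRUE))] <- NA
  m <- fragpop:::.pair_r2_matrix(ds$dosages)
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    sc <- suppressWarnings(pair_r2(ds$dosages[, pair[1]], ds$dosages[, pair[2]]))
    expect_equal(m$r2[pair[1], pair[2]], sc$r2, tolerance = 1e-12)
    expect_equal(m$S[pair[1], pair[2]], sc$S_pair)
  }
})

test_that("drift relation inverts to the closed-form estimate", {
  # (1/3 + sqrt(1/9 - 2.76*0.01)) / 0.02
  expect_equal(fragpop:::.ne_from_drift(0.01, 60), 31.1158, tolerance = 1e-4)
  expect_equal(fragpop:::.ne_from_drift(0, 60), Inf)
  expect_equal(fragpop:::.ne_from_drift(-0.001, 60), Inf)
  # small-sample branch uses the S < 30 constants
  expect_equal(fragpop:::.ne_from_drift(0.01, 20),
               (0.308 + sqrt(0.308^2 - 2.08 * 0.01)) / 0.02, tolerance = 1e-10)
})

test_that("sampling-only LD matches the finite-sample expectation", {
  # iid HWE genotypes = random-mating population far larger than the sample
  S <- 100
  p <- fixture_freqs(50, seed = 61)
  G <- hwe_genotypes(S, p, seed = 62)
  m <- fragpop:::.pair_r2_matrix(G)
  r2 <- m$r2[upper.tri(m$r2)]
  expect_gt(sum(!is.na(r2)), 1000)
  expected <- 1 / S + 3.19 / S^2
  expect_lt(abs(mean(r2, na.rm = TRUE) / expected - 1), 0.10)
})

test_that("the estimator does not hallucinate drift in a huge population", {
  # samples from an effectively infinite population should give huge Ne
  est <- vapply(1:5, function(s) {
    ds <- hwe_dataset(50, 400, seed = 70 + s)
    estimate_ne(ds, label = "big")$ne_hat
  }, numeric(1))
  expect_gt(stats::median(est), 1000)
})

test_that("a clone group yields a flagged degenerate estimate", {
  G <- matrix(rep(c(0L, 1L, 2L, 1L), each = 10), 10, 4)
  ds <- genotype_dataset(G, paste0("c", 1:10))
  expect_warning(est <- estimate_ne(ds, label = "clones"), "degenerate")
  expect_true(est$degenerate)
  expect_true(is.na(est$ne_hat))
})

test_that("pcrit screening only removes rare-allele loci", {
  ds <- hwe_dataset(40, 60, seed = 81)
  ds$dosages[, 1] <- c(1L, rep(0L, 39))          # maf 1/80 = 0.0125
  e0 <- estimate_ne(ds, cfg = ldne_config(pcrit = 0), label = "p0")
  e1 <- estimate_ne(ds, cfg = ldne_config(pcrit = 0.02), label = "p1")
  expect_lte(e1$n_loci, e0$n_loci)
  expect_lte(e1$n_pairs, e0$n_pairs)
  expect_equal(e0$n_loci - e1$n_loci, 1L)
})

test_that("jackknife CI brackets the point estimate and tightens with loci", {
  cfg <- sim_config(deme_sizes = 60, n_loci = 400, n_generations = 12,
                    sampling = data.frame(deme = 1, generation = 12, n = 30),
                    seed = 91)
  out <- simulate_metapop(cfg)
  est <- estimate_ne(out$ds, label = "d", ci = TRUE)
  expect_true(est$ci_low <= est$ne_hat && est$ne_hat <= est$ci_high)
  # doubling the locus count should not widen the interval (median over reps)
  widths <- t(vapply(1:8, function(s) {
    cfgS <- sim_config(deme_sizes = 60, n_loci = 400, n_generations = 12,
                       sampling = data.frame(deme = 1, generation = 12, n = 30),
                       seed = 100 + s)
    o <- simulate_metapop(cfgS)
    full <- jackknife_ci(o$ds)
    half <- jackknife_ci(subset_genotypes(o$ds, loci = 1:200))
    c(full = diff(pmin(full, 1e6)), half = diff(pmin(half, 1e6)))
  }, numeric(2)))
  expect_lte(stats::median(widths[, "full"]), stats::median(widths[, "half"]))
  expect_warning(jackknife_ci(subset_genotypes(out$ds, samples = 1:4)),
                 "smaller than 5")
})

test_that("ne_scan emits one row per grouping and skips small groups", {
  cfg <- sim_config(deme_sizes = c(50, 50), n_loci = 300, n_generations = 10,
                    sampling = data.frame(deme = c(1, 2), generation = 10,
                                          n = c(20, 20)), seed = 111)
  out <- simulate_metapop(cfg)
  sm <- out$ds$sample_meta
  tab <- ne_scan(out$ds, list(S1 = sm$site == "S1", S2 = sm$site == "S2",
                              pooled = rep(TRUE, nrow(sm)),
                              tiny = seq_len(3)), min_n = 11)
  expect_equal(tab$label, c("S1", "S2", "pooled"))
  expect_match(attr(tab, "skipped"), "tiny")
  expect_true(all(tab$n_pairs > 0))
})
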