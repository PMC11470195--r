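test_that("heterozygosity decays at the closed-form drift rate", {
  rates <- vapply(1:3, function(s) {
    cfg <- sim_config(deme_sizes = 100, n_loci = 800, n_generations = 200,
                      seed = 700 + s)
    he <- simulate_metapop(cfg)$truth$he_trajectory[, 1]
    t <- seq_along(he) - 1
    -unname(stats::coef(stats::lm(log(he) ~ t))[2])
  }, numeric(1))
  expect_lt(abs(mean(rates) / (1 / 200) - 1), 0.15)
})

test_that("divergence between isolated demes matches the drift closed form", {
  # reuses the FST fixture logic: truth trajectories, not the estimator
  cfg <- sim_config(deme_sizes = c(50, 50), n_loci = 600, n_generations = 30,
                    sampling = data.frame(deme = c(1, 2), generation = 30,
                                          n = c(40, 40)), seed = 710)
  out <- simulate_metapop(cfg)
  fst <- pairwise_fst(out$ds)["S1", "S2"]
  expected <- 1 - (1 - 1 / 100)^30
  expect_lt(abs(fst - expected), 0.08)
})

test_that("allele-frequency trajectories are martingales", {
  drift <- vapply(1:200, function(s) {
    cfg <- sim_config(deme_sizes = 50, n_loci = 40, n_generations = 8,
                      seed = 800 + s)
    out <- simulate_metapop(cfg)
    mean(colMeans(out$ds$dosages) / 2) - mean(out$truth$init_freq)
  }, numeric(1))
  expect_gt(stats::t.test(drift)$p.value, 0.01)
})

test_that("identity migration equals independent single demes in law", {
  he2 <- vapply(1:20, function(s) {
    cfg <- sim_config(deme_sizes = c(30, 30), n_loci = 200, n_generations = 10,
                      seed = 900 + s)
    simulate_metapop(cfg)$truth$he_trajectory[11, 1]
  }, numeric(1))
  he1 <- vapply(1:20, function(s) {
    cfg <- sim_config(deme_sizes = 30, n_loci = 200, n_generations = 10,
                      seed = 950 + s)
    simulate_metapop(cfg)$truth$he_trajectory[11, 1]
  }, numeric(1))
  expect_gt(stats::ks.test(he2, he1)$p.value, 0.01)
})

test_that("runs are deterministic under a fixed seed and error on bad config", {
  cfg <- sim_config(deme_sizes = c(20, 20), n_loci = 50, n_generations = 5,
                    sampling = data.frame(deme = 1, generation = 5, n = 10),
                    seed = 42)
  a <- simulate_metapop(cfg); b <- simulate_metapop(cfg)
  expect_identical(a$ds$dosages, b$ds$dosages)
  expect_identical(a$truth$he_trajectory, b$truth$he_trajectory)
  expect_error(sim_config(deme_sizes = c(10, 10),
                          migration = matrix(1, 2, 2)), "row-stochastic")
  expect_error(sim_config(deme_sizes = 10,
                          translocations = data.frame(generation = 1, dest = 1,
                                                      count = 2)), "source_pop")
})

test_that("the study-like preset carries the monitoring signature", {
  seeds <- 1:20
  he_upstream_lower <- logical(20); pooled_smaller <- logical(20)
  f1_pht <- numeric(); local_pht_mean <- numeric(); source_he <- numeric()
  for (i in seeds) {
    out <- make_study_like(seed = 1000 + i, n_loci = 1000)
    sm <- out$ds$sample_meta
    he <- function(s) pop_heterozygosity(out$ds, sm$site == s, label = s)$He
    he_upstream_lower[i] <- he("S2") < he("S8")
    est <- function(sel, lab) suppressWarnings(
      estimate_ne(out$ds, sel, label = lab)$ne_hat)
    per_site <- c(est(sm$site == "S5", "S5"), est(sm$site == "S8", "S8"),
                  est(sm$site == "S9", "S9"))
    pooled <- est(rep(TRUE, nrow(sm)), "all")
    pooled_smaller[i] <- pooled < min(per_site)
    pht <- individual_pht(out$ds)$pht
    f1 <- out$truth$samples$anc_fraction == 0.5  # true F1s, not backcrosses
    loc <- out$truth$samples$anc_fraction == 0
    f1_pht <- c(f1_pht, pht[f1])
    local_pht_mean <- c(local_pht_mean, mean(pht[loc]))
    source_he <- c(source_he, out$truth$source_he)
  }
  expect_gte(mean(he_upstream_lower), 0.9)
  expect_gte(mean(pooled_smaller), 0.9)
  # F1 heterozygosity exceeds both parental-population means (pooled over
  # seeds: individual F1s are rare, as in real monitoring)
  expect_gt(length(f1_pht), 5)
  expect_gt(mean(f1_pht), mean(local_pht_mean))
  expect_gt(mean(f1_pht), mean(source_he))
})

test_that("disabling translocation leaves no admixed ancestry", {
  out <- make_study_like(seed = 77, n_loci = 300, translocation = FALSE)
  expect_false(any(out$ds$sample_meta$ancestry == "admixed"))
  expect_false(any(out$truth$samples$anc_fraction > 0))
  # with translocation enabled, admixed F1s appear in late cohorts
  out2 <- make_study_like(seed = 77, n_loci = 300, translocation = TRUE)
  adm <- out2$ds$sample_meta$ancestry == "admixed"
  if (any(adm))
    expect_true(all(out2$ds$sample_meta$cohort[adm] %in% c("2021", "2022")))
})

test_that("sampled metadata is coherent: lengths, ages, cohorts, truth", {
  out <- make_study_like(seed = 5, n_loci = 200)
  sm <- out$ds$sample_meta
  expect_true(all(sm$total_length_mm > 0))
  expect_true(all(sm$site %in% paste0("S", 1:9)))
  expect_true(all(!is.na(sm$age_class)))
  juv <- sm$cohort != "adult"
  # surveys run in April, before the spawning season, so the cohort rule
  # subtracts one extra year
  rederived <- assign_cohort(sm$age_class[juv], sm$capture_year[juv],
                             capture_month = 4)
  expect_gt(mean(rederived == sm$cohort[juv]), 0.8)  # noise blurs bin edges
  expect_identical(out$truth$samples$sample_id, out$ds$sample_ids)
  expect_true(all(out$truth$samples$parent_deme1 %in% 1:9))
})
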