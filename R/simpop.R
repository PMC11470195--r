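#' Configuration for the Wright-Fisher metapopulation simulator
#'
#' Discrete non-overlapping generations; each deme of constant census size
#' produces its next generation by drawing, per offspring, two parents whose
#' demes follow the row of the migration matrix and transmitting one allele
#' per locus from each parent. Loci are unlinked, selectively neutral, and
#' start from shared ancestral frequencies drawn from a truncated Beta. A
#' divergent, more diverse source population can evolve alongside the
#' metapopulation and supply translocated individuals; offspring of one
#' local and one source parent are the F1 admixed class.
#'
#' @param deme_sizes integer vector of per-deme census (= effective) sizes.
#' @param n_loci number of unlinked biallelic loci.
#' @param n_generations number of structured generations simulated.
#' @param migration row-stochastic matrix; `migration[d, s]` is the
#'   probability that a parent of a deme-`d` offspring comes from deme `s`.
#'   Default: no migration (identity).
#' @param init_freq list `(shape1, shape2, lower, upper)` of the truncated
#'   Beta ancestral-frequency model.
#' @param stem optional list `(size, generations)`: a shared bottleneck phase
#'   run before the metapopulation splits, so all demes inherit correlated
#'   drift (lowered diversity) from a common recent ancestor.
#' @param source_pop optional list `(size, generations)`: a large population
#'   evolved independently from the same ancestral frequencies, retaining
#'   more diversity than the bottlenecked demes.
#' @param translocations data.frame with columns `generation`, `dest`
#'   (deme index), `count`: individuals moved from the source population
#'   into `dest` at the start of that generation (they join the breeding
#'   pool).
#' @param sampling data.frame with columns `deme`, `generation`, `n`: a
#'   cohort sample of `n` juveniles born in that deme at that generation.
#'   Sampled juveniles are drawn as additional offspring of the same parent
#'   pool (the realistic monitoring design: a cohort is far larger than the
#'   breeding population, so sampled fish are siblings/cousins of, not
#'   identical to, the individuals that carry the deme forward).
#' @param seed integer seed; the run is fully deterministic given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(deme_sizes, n_loci = 3000L, n_generations = 20L,
                       migration = NULL,
                       init_freq = list(shape1 = 0.5, shape2 = 0.5,
                                        lower = 0.05, upper = 0.95),
                       stem = NULL, source_pop = NULL, translocations = NULL,
                       sampling = NULL, seed = 1L) {
  deme_sizes <- as.integer(deme_sizes)
  stopifnot(all(deme_sizes >= 2), n_loci >= 1, n_generations >= 1)
  k <- length(deme_sizes)
  if (is.null(migration)) migration <- diag(k)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == k) || any(abs(rowSums(migration) - 1) > 1e-8))
    stop("migration must be a row-stochastic ", k, "x", k, " matrix")
  if (!is.null(translocations)) {
    stopifnot(all(c("generation", "dest", "count") %in% names(translocations)))
    if (is.null(source_pop)) stop("translocations need a source_pop")
  }
  if (!is.null(sampling))
    stopifnot(all(c("deme", "generation", "n") %in% names(sampling)))
  structure(list(deme_sizes = deme_sizes, n_loci = as.integer(n_loci),
                 n_generations = as.integer(n_generations),
                 migration = migration, init_freq = init_freq, stem = stem,
                 source_pop = source_pop, translocations = translocations,
                 sampling = sampling, seed = as.integer(seed)),
            class = "sim_config")
}

.rtrunc_beta <- function(n, m) {
  lo <- stats::pbeta(m$lower, m$shape1, m$shape2)
  hi <- stats::pbeta(m$upper, m$shape1, m$shape2)
  stats::qbeta(stats::runif(n, lo, hi), m$shape1, m$shape2)
}

# Mendelian transmission: one allele from each parent dosage matrix
.transmit <- function(P1, P2) {
  n <- nrow(P1); L <- ncol(P1)
  matrix((stats::runif(n * L) < P1 / 2) + (stats::runif(n * L) < P2 / 2),
         n, L)
}

# one Wright-Fisher generation inside a single pool:
# geno (N x L), anc (ancestry fraction per row) -> n offspring
.wf_offspring <- function(geno, anc, n) {
  N <- nrow(geno)
  i1 <- sample.int(N, n, replace = TRUE)
  i2 <- sample.int(N, n, replace = TRUE)
  child <- .transmit(geno[i1, , drop = FALSE], geno[i2, , drop = FALSE])
  list(geno = child, anc = (anc[i1] + anc[i2]) / 2, p1 = i1, p2 = i2)
}

.mean_he <- function(geno) {
  p <- colMeans(geno) / 2
  mean(2 * p * (1 - p))
}

#' Run the metapopulation simulation
#'
#' @param cfg a [sim_config()].
#' @return list with `ds` (a [genotype_dataset()] of the sampled individuals;
#'   empty sampling gives a dataset of the final generation of deme 1) and
#'   `truth` (`sim_truth`: the config, per-sample ancestry fraction and
#'   parent demes, per-deme expected-heterozygosity trajectory, source-pop
#'   heterozygosity, translocation log).
#' @export
simulate_metapop <- function(cfg) {
  set.seed(cfg$seed)
  k <- length(cfg$deme_sizes); L <- cfg$n_loci
  f0 <- .rtrunc_beta(L, cfg$init_freq)

  draw_pop <- function(n, f)
    matrix(stats::rbinom(n * L, 2L, rep(f, each = n)), n, L)

  # optional shared bottleneck stem
  founder_pool <- NULL
  if (!is.null(cfg$stem)) {
    stem <- draw_pop(cfg$stem$size, f0)
    for (g in seq_len(cfg$stem$generations))
      stem <- .wf_offspring(stem, numeric(nrow(stem)), cfg$stem$size)$geno
    founder_pool <- stem
  }
  init_deme <- function(n) {
    if (is.null(founder_pool)) return(draw_pop(n, f0))
    founder_pool[sample.int(nrow(founder_pool), n, replace = TRUE), , drop = FALSE]
  }
  demes <- lapply(cfg$deme_sizes, init_deme)
  ancs <- lapply(cfg$deme_sizes, numeric)      # source-ancestry fraction

  src <- NULL
  if (!is.null(cfg$source_pop)) {
    src <- draw_pop(cfg$source_pop$size, f0)
    for (g in seq_len(cfg$source_pop$generations %||% 0))
      src <- .wf_offspring(src, numeric(nrow(src)), cfg$source_pop$size)$geno
  }

  he_traj <- matrix(NA_real_, cfg$n_generations + 1L, k)
  he_traj[1, ] <- vapply(demes, .mean_he, numeric(1))
  samples <- list(); sample_truth <- list(); trans_log <- list()

  for (g in seq_len(cfg$n_generations)) {
    # translocations scheduled for this generation join the breeding pools
    if (!is.null(cfg$translocations)) {
      ev <- cfg$translocations[cfg$translocations$generation == g, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        d <- ev$dest[e]; cnt <- ev$count[e]
        pick <- sample.int(nrow(src), cnt)
        demes[[d]] <- rbind(demes[[d]], src[pick, , drop = FALSE])
        ancs[[d]] <- c(ancs[[d]], rep(1, cnt))
        trans_log[[length(trans_log) + 1L]] <-
          data.frame(generation = g, dest = d, count = cnt)
      }
    }
    new_demes <- vector("list", k); new_ancs <- vector("list", k)
    for (d in seq_len(k)) {
      n <- cfg$deme_sizes[d]
      n_samp <- 0L
      if (!is.null(cfg$sampling)) {
        ev <- cfg$sampling[cfg$sampling$generation == g & cfg$sampling$deme == d, ,
                           drop = FALSE]
        n_samp <- sum(ev$n)
      }
      n_tot <- n + n_samp
      pd1 <- sample.int(k, n_tot, replace = TRUE, prob = cfg$migration[d, ])
      pd2 <- sample.int(k, n_tot, replace = TRUE, prob = cfg$migration[d, ])
      P1 <- matrix(0L, n_tot, L); P2 <- matrix(0L, n_tot, L)
      a1 <- numeric(n_tot); a2 <- numeric(n_tot)
      for (s in unique(c(pd1, pd2))) {
        w1 <- which(pd1 == s)
        if (length(w1)) {
          i <- sample.int(nrow(demes[[s]]), length(w1), replace = TRUE)
          P1[w1, ] <- demes[[s]][i, , drop = FALSE]; a1[w1] <- ancs[[s]][i]
        }
        w2 <- which(pd2 == s)
        if (length(w2)) {
          i <- sample.int(nrow(demes[[s]]), length(w2), replace = TRUE)
          P2[w2, ] <- demes[[s]][i, , drop = FALSE]; a2[w2] <- ancs[[s]][i]
        }
      }
      child <- .transmit(P1, P2)
      child_anc <- (a1 + a2) / 2
      new_demes[[d]] <- child[seq_len(n), , drop = FALSE]
      new_ancs[[d]] <- child_anc[seq_len(n)]
      if (n_samp > 0) {
        pick <- n + seq_len(n_samp)
        samples[[length(samples) + 1L]] <- child[pick, , drop = FALSE]
        sample_truth[[length(sample_truth) + 1L]] <- data.frame(
          deme = d, birth_gen = g, anc_fraction = child_anc[pick],
          parent_deme1 = pd1[pick], parent_deme2 = pd2[pick])
      }
    }
    if (!is.null(src))
      src <- .wf_offspring(src, numeric(nrow(src)), nrow(src))$geno
    demes <- new_demes; ancs <- new_ancs
    he_traj[g + 1L, ] <- vapply(demes, .mean_he, numeric(1))
  }

  if (length(samples)) {
    geno <- do.call(rbind, samples)
    truth_tab <- do.call(rbind, sample_truth)
  } else {
    geno <- demes[[1]]
    truth_tab <- data.frame(deme = 1L, birth_gen = cfg$n_generations,
                            anc_fraction = ancs[[1]],
                            parent_deme1 = NA_integer_,
                            parent_deme2 = NA_integer_)
  }
  ids <- sprintf("ind%04d", seq_len(nrow(geno)))
  truth_tab$sample_id <- ids
  truth_tab$ancestry <- ifelse(truth_tab$anc_fraction == 0, "local",
                        ifelse(truth_tab$anc_fraction == 1, "source", "admixed"))
  sm <- data.frame(sample_id = ids,
                   site = paste0("S", truth_tab$deme),
                   cohort = truth_tab$birth_gen,
                   ancestry = truth_tab$ancestry)
  ds <- genotype_dataset(geno, ids, sample_meta = sm,
                         provenance = sprintf("simulate_metapop(seed=%d)", cfg$seed))
  truth <- structure(list(config = cfg, samples = truth_tab,
                          he_trajectory = he_traj,
                          source_he = if (!is.null(src)) .mean_he(src) else NA_real_,
                          init_freq = f0,
                          translocation_log = if (length(trans_log))
                            do.call(rbind, trans_log) else NULL),
                     class = "sim_truth")
  list(ds = ds, truth = truth)
}

#' Genotypes with block-wise physical linkage (test fixture generator)
#'
#' Draws pairs of haplotypes from a Markov chain along the chromosome whose
#' allele correlation decays as exp(-distance / decay_bp), giving r-squared
#' that falls off with physical distance — the pattern LD-decay screening is
#' meant to detect. Used to exercise [ld_decay()]; the main simulator keeps
#' loci unlinked.
#'
#' @param n_ind number of individuals.
#' @param positions sorted bp positions of the loci.
#' @param chrom chromosome label.
#' @param decay_bp correlation length in bp.
#' @param seed RNG seed.
#' @return a [genotype_dataset()] with placed loci.
#' @export
sim_linked_genotypes <- function(n_ind, positions, chrom = "1",
                                 decay_bp = 20000, seed = 1L) {
  set.seed(seed)
  L <- length(positions)
  hap <- function() {
    h <- integer(L)
    h[1] <- stats::rbinom(1, 1, 0.5)
    if (L > 1) {
      rho <- exp(-diff(positions) / decay_bp)
      flip <- stats::rbinom(L - 1, 1, (1 - rho) / 2)
      for (l in 2:L) h[l] <- if (flip[l - 1]) 1L - h[l - 1] else h[l - 1]
    }
    h
  }
  geno <- t(vapply(seq_len(n_ind), function(i) hap() + hap(), integer(L)))
  lm <- data.frame(locus_id = sprintf("%s_%d", chrom, positions),
                   chrom = chrom, pos = positions)
  genotype_dataset(geno, sprintf("ind%03d", seq_len(n_ind)), locus_meta = lm)
}

#' Study-like preset: nine riverine demes, barriers, translocation
#'
#' A ready-made configuration emulating a fragmented river population
#' monitored by cohort sampling: nine linearly ordered demes with a
#' small-upstream / large-downstream effective-size ladder, stepping-stone
#' migration interrupted by barriers (downstream-biased where present), a
#' shared recent bottleneck that lowers diversity relative to a large
#' divergent source population (expected-heterozygosity ratio around 1.4),
#' translocations from the source into two downstream demes in the last two
#' generations (producing F1 admixed offspring), and per-deme cohort
#' sampling over the final six generations plus an older adult draw.
#' Sampled fish carry capture years, river distances and Gompertz-generated
#' lengths so the full pipeline (QC, diversity, structure, kinship, Ne,
#' growth) can run end to end against known truth.
#'
#' @param seed integer seed.
#' @param n_loci number of loci (default 3000).
#' @param translocation enable the translocation events (default TRUE).
#' @return list `(ds, truth)` as from [simulate_metapop()], with length,
#'   capture-year and river-distance metadata attached and ~1% missing
#'   genotypes.
#' @export
make_study_like <- function(seed = 1L, n_loci = 3000L, translocation = TRUE) {
  sizes <- c(20L, 15L, 18L, 8L, 30L, 15L, 25L, 130L, 60L)
  k <- 9
  mig <- diag(k)
  connect <- function(m, from, to, rate) {
    m[to, from] <- m[to, from] + rate     # parents of `to` offspring from `from`
    m
  }
  # barrier pattern along the river: 1|>2 ?>3 1|>4 ?>5 <>6 <>7 ?>8 <>9
  mig <- connect(mig, 1, 2, 0.03)   # downstream only over the barrier
  mig <- connect(mig, 2, 3, 0.015)  # occasional
  mig <- connect(mig, 3, 4, 0.03)
  mig <- connect(mig, 4, 5, 0.015)
  mig <- connect(mig, 5, 6, 0.03); mig <- connect(mig, 6, 5, 0.03)
  mig <- connect(mig, 6, 7, 0.03); mig <- connect(mig, 7, 6, 0.03)
  mig <- connect(mig, 7, 8, 0.015)
  mig <- connect(mig, 8, 9, 0.03); mig <- connect(mig, 9, 8, 0.03)
  diag(mig) <- 0
  diag(mig) <- 1 - rowSums(mig)

  G <- 15L                                  # structured generations
  cohort_gens <- (G - 5L):G                 # cohorts 2017..2022
  gen_year <- function(g) 2017L + (g - (G - 5L))
  samp <- rbind(
    data.frame(deme = 1, generation = G - 2L, n = 3),
    data.frame(deme = 2, generation = (G - 4L):(G - 2L), n = c(24, 25, 35)),
    data.frame(deme = 3, generation = G - 2L, n = 33),
    data.frame(deme = 4, generation = G - 2L, n = 7),
    data.frame(deme = 5, generation = (G - 3L):(G - 2L), n = c(7, 12)),
    data.frame(deme = 6, generation = c(G - 2L, G), n = c(3, 5)),
    data.frame(deme = 8, generation = (G - 4L):G, n = c(6, 6, 47, 3, 23)),
    data.frame(deme = 9, generation = (G - 2L):G, n = c(4, 3, 1)),
    # adults: an older generation, pooled as the adult group
    data.frame(deme = c(2, 5, 8, 9), generation = G - 7L, n = c(7, 18, 14, 17)))
  trans <- if (translocation)
    data.frame(generation = c(G - 2L, G - 1L), dest = c(8L, 8L),
               count = c(3L, 3L)) else NULL
  cfg <- sim_config(deme_sizes = sizes, n_loci = n_loci, n_generations = G,
                    migration = mig,
                    stem = list(size = 50L, generations = 22L),
                    source_pop = list(size = 400L, generations = 30L),
                    translocations = trans, sampling = samp, seed = seed)
  out <- simulate_metapop(cfg)
  ds <- out$ds; truth <- out$truth

  # cohort years, capture metadata and river distances
  bg <- truth$samples$birth_gen
  cohort <- ifelse(bg >= min(cohort_gens), as.character(gen_year(bg)), "adult")
  river_km <- c(0, 5.4, 11.8, 33.9, 55.1, 63.7, 77.3, 92.1, 102.9)
  juv <- cohort != "adult"
  set.seed(seed + 1L)
  # juveniles are encountered at 0.5-2.5 years, but no later than the final
  # survey year; adults are older fish surveyed in the final year
  n_s <- length(cohort)
  age <- rep(10.5, n_s)
  birth <- suppressWarnings(as.integer(cohort))
  age[juv] <- sample(c(0.5, 1.5, 2.5), sum(juv), replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
  age[juv] <- pmin(age[juv], 2023L - birth[juv] - 0.5)
  capture_year <- rep(2023L, n_s)
  capture_year[juv] <- birth[juv] + age[juv] + 0.5
  cohort_offset <- stats::rnorm(length(unique(cohort)), 0, 6)
  names(cohort_offset) <- unique(cohort)
  len <- gompertz_length(age, 400, 2.3, 0.65) +
    cohort_offset[cohort] + stats::rnorm(nrow(ds$dosages), 0, 8)
  sm <- ds$sample_meta
  sm$cohort <- cohort
  sm$capture_year <- capture_year
  sm$capture_date <- sprintf("%d-04-15", capture_year)  # autumn surveys
  sm$total_length_mm <- round(pmax(len, 40), 1)
  sm$river_km <- river_km[truth$samples$deme]
  sm$age_class <- assign_age(sm$total_length_mm, sm$capture_year)
  ds$sample_meta <- sm

  # locus metadata: map, tags, depth, reproducibility + ~1% missing calls
  L <- ncol(ds$dosages)
  new_tag <- stats::rbinom(L, 1, 0.95); new_tag[1] <- 1
  lm <- data.frame(locus_id = sprintf("L%05d", seq_len(L)),
                   tag_id = sprintf("tag%05d", cumsum(new_tag)),
                   chrom = as.character(sample.int(24, L, replace = TRUE)),
                   pos = sample.int(4e7, L, replace = TRUE),
                   mean_depth = round(stats::rgamma(L, shape = 8, scale = 2.5), 1),
                   reproducibility = round(pmin(1, 1 - stats::rbeta(L, 0.5, 40)), 4))
  miss <- matrix(stats::runif(length(ds$dosages)) < 0.01, nrow(ds$dosages))
  ds$dosages[miss] <- NA_integer_
  lm$call_rate <- round(colMeans(!is.na(ds$dosages)), 4)
  ds$locus_meta <- .complete_locus_meta(lm, lm$locus_id, L)
  colnames(ds$dosages) <- lm$locus_id
  ds <- .log_op(ds, sprintf("make_study_like(seed=%d): 9 demes, %d loci", seed, L))
  truth$samples$cohort <- cohort
  list(ds = ds, truth = truth)
}

#' Write simulation truth as JSON
#' @param truth a `sim_truth` from [simulate_metapop()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  x <- list(deme_sizes = truth$config$deme_sizes,
            n_loci = truth$config$n_loci,
            n_generations = truth$config$n_generations,
            migration = truth$config$migration,
            seed = truth$config$seed,
            samples = truth$samples,
            he_trajectory = truth$he_trajectory,
            source_he = truth$source_he,
            translocations = truth$translocation_log)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
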