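#' Configuration for the LD-based effective-size estimator
#'
#' @param pcrit minimum within-group minor-allele frequency for a locus to
#'   enter the computation (default 0.01, screening rare alleles that inflate
#'   r-squared).
#' @param mating_model only `"random"` is supported.
#' @param ci_method only `"jackknife_samples"` (delete-one individual).
#' @param min_pair_S smallest joint call count for a locus pair to be used.
#' @return A list of class `ldne_config`.
#' @export
ldne_config <- function(pcrit = 0.01, mating_model = "random",
                        ci_method = "jackknife_samples", min_pair_S = 10L) {
  stopifnot(pcrit >= 0, pcrit < 0.5,
            identical(mating_model, "random"),
            identical(ci_method, "jackknife_samples"))
  structure(list(pcrit = pcrit, mating_model = mating_model,
                 ci_method = ci_method, min_pair_S = as.integer(min_pair_S)),
            class = "ldne_config")
}

#' Burrows composite-LD r-squared for one locus pair
#'
#' The composite (Burrows) disequilibrium is computable from unphased diploid
#' dosages: over the S individuals called at both loci,
#' Delta = (1/S) * sum(x*y)/2 - 2*p*q, with p, q the allele frequencies of
#' the two loci among those individuals; r2 = Delta^2 / (p(1-p) q(1-q)).
#'
#' @param x,y dosage vectors (0/1/2/NA) of the two loci over the same
#'   individuals.
#' @return list with `r2`, `S_pair` (joint call count) and `delta`; `r2` is
#'   `NA` (with a warning) if either locus is monomorphic among the jointly
#'   called individuals.
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  S <- sum(ok)
  if (S < 2) stop("pair_r2 needs at least two jointly called individuals")
  x <- x[ok]; y <- y[ok]
  p <- mean(x) / 2; q <- mean(y) / 2
  if (p %in% c(0, 1) || q %in% c(0, 1)) {
    warning("monomorphic locus in pair; r2 undefined")
    return(list(r2 = NA_real_, S_pair = S, delta = NA_real_))
  }
  delta <- sum(x * y) / (2 * S) - 2 * p * q
  list(r2 = delta^2 / (p * (1 - p) * q * (1 - q)), S_pair = S, delta = delta)
}

# All-pairs composite r2 via crossproducts; handles missing data exactly
# (per-pair allele frequencies over jointly called individuals).
# Returns L x L matrices r2 and S (joint call counts); diagonal is NA.
.pair_r2_matrix <- function(dos) {
  M <- !is.na(dos)
  storage.mode(M) <- "double"
  X <- dos; X[is.na(X)] <- 0; storage.mode(X) <- "double"
  S <- crossprod(M)                   # joint call counts
  Sxy <- crossprod(X)                 # sum x_j x_k over jointly called
  Sx <- crossprod(X, M)               # Sx[j,k] = sum of x_j over ind called at both
  P <- Sx / (2 * S)                   # per-pair freq of locus j (rows)
  Q <- t(P)                           # per-pair freq of locus k (cols)
  D <- Sxy / (2 * S) - 2 * P * Q
  denom <- P * (1 - P) * Q * (1 - Q)
  r2 <- D^2 / denom
  r2[denom <= 0 | S < 2] <- NA_real_
  diag(r2) <- NA_real_
  list(r2 = r2, S = S)
}

# sampling expectation of r2 under random mating (Waples-style correction)
.e_r2_sample <- function(S) {
  ifelse(S >= 30, 1 / S + 3.19 / S^2, 0.0018 + 0.907 / S + 4.44 / S^2)
}

# invert the drift relation r2_drift -> Ne
.ne_from_drift <- function(r2_drift, S) {
  if (is.na(r2_drift) || r2_drift <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2_drift
    if (disc < 0) return(Inf)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- 0.308^2 - 2.08 * r2_drift
    if (disc < 0) return(Inf)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

# weighted mean r2, weighted harmonic mean S and drift signal for a group's
# dosage submatrix, after within-group pcrit screening
.group_r2_stats <- function(dos, cfg) {
  called <- colSums(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  use <- called >= 2 & !is.na(maf) & maf > 0 & maf >= cfg$pcrit
  if (sum(use) < 2)
    return(list(ok = FALSE, n_loci = sum(use)))
  m <- .pair_r2_matrix(dos[, use, drop = FALSE])
  ut <- upper.tri(m$r2)
  r2 <- m$r2[ut]; S <- m$S[ut]
  keep <- !is.na(r2) & S >= cfg$min_pair_S
  r2 <- r2[keep]; S <- S[keep]
  if (!length(r2)) return(list(ok = FALSE, n_loci = sum(use)))
  w <- S
  r2_mean <- sum(w * r2) / sum(w)
  S_harm <- sum(w) / sum(w / S)
  e_r2 <- .e_r2_sample(S_harm)
  # the sampling expectation is calibrated to the bias-corrected Burrows
  # composite (Delta scaled by S/(S-1)); rescale the plain mean to match
  r2_corr <- r2_mean * (S_harm / (S_harm - 1))^2
  list(ok = TRUE, n_loci = sum(use), n_pairs = length(r2),
       r2_mean = r2_mean, S_harmonic = S_harm,
       r2_expected = e_r2, r2_drift = r2_corr - e_r2)
}

#' Single-sample LD-based effective size estimate
#'
#' Screens loci whose minor-allele frequency within the analysis group falls
#' below `pcrit`, scores every remaining locus pair with the Burrows
#' composite r-squared, subtracts the finite-sample expectation
#' (1/S + 3.19/S^2 for S >= 30, else 0.0018 + 0.907/S + 4.44/S^2, with S the
#' weighted harmonic-mean joint call count), and inverts the drift relation
#' to obtain the effective-size estimate. Non-positive drift signal yields an
#' infinite estimate (no detectable drift LD).
#'
#' @param ds a [genotype_dataset()].
#' @param group sample selector (see [subset_genotypes()]); `NULL` = all.
#' @param cfg an [ldne_config()].
#' @param label group label carried into the result.
#' @param ci compute the delete-one-individual jackknife CI? (needs >= 5
#'   individuals; see [jackknife_ci()]).
#' @return An object of class `ne_estimate`: `label`, `n` (group size),
#'   `ne_hat`, `ci_low`, `ci_high`, `n_pairs`, `n_loci`, `S_harmonic`,
#'   `r2_mean`, `r2_expected_sampling`, `r2_drift`, and `degenerate` flag.
#' @export
estimate_ne <- function(ds, group = NULL, cfg = ldne_config(), label = "all",
                        ci = FALSE) {
  idx <- .resolve_selector(group, ds$sample_ids, ds$sample_meta, "sample")
  if (length(idx) < 4) stop("group '", label, "' has fewer than 4 individuals")
  dos <- ds$dosages[idx, , drop = FALSE]
  clones <- nrow(unique(dos)) == 1
  st <- if (clones) list(ok = FALSE, n_loci = 0L) else .group_r2_stats(dos, cfg)
  if (!st$ok) {
    warning("group '", label, "' has <2 usable polymorphic loci; ",
            "estimate is degenerate")
    return(structure(list(label = label, n = length(idx), ne_hat = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          n_pairs = 0L, n_loci = st$n_loci,
                          S_harmonic = NA_real_, r2_mean = NA_real_,
                          r2_expected_sampling = NA_real_,
                          r2_drift = NA_real_, degenerate = TRUE),
                     class = "ne_estimate"))
  }
  ne <- .ne_from_drift(st$r2_drift, st$S_harmonic)
  out <- structure(list(label = label, n = length(idx), ne_hat = ne,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_pairs = st$n_pairs, n_loci = st$n_loci,
                        S_harmonic = st$S_harmonic, r2_mean = st$r2_mean,
                        r2_expected_sampling = st$r2_expected,
                        r2_drift = st$r2_drift, degenerate = FALSE),
                   class = "ne_estimate")
  if (ci) {
    bounds <- jackknife_ci(ds, group = idx, cfg = cfg)
    out$ci_low <- bounds[1]; out$ci_high <- bounds[2]
  }
  out
}

#' @exportS3Method base::print
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne estimate [%s]: n=%d, Ne=%s (CI %s-%s), %d pairs, mean r2=%.5g\n",
              x$label, x$n, format(round(x$ne_hat, 1)),
              format(round(x$ci_low, 1)), format(round(x$ci_high, 1)),
              x$n_pairs, x$r2_mean))
  invisible(x)
}

#' Delete-one-individual jackknife CI for the LD-based estimate
#'
#' Recomputes the drift signal r2_drift leaving out one individual at a time,
#' forms the jackknife variance, builds a 95% normal-theory interval on
#' r2_drift (truncated below at 0), and maps it through the drift relation.
#' An interval reaching non-positive drift gives an infinite upper bound.
#'
#' @inheritParams estimate_ne
#' @return numeric `c(ci_low, ci_high)` on the Ne scale; `NA`s when the group
#'   is smaller than 5.
#' @export
jackknife_ci <- function(ds, group = NULL, cfg = ldne_config()) {
  idx <- .resolve_selector(group, ds$sample_ids, ds$sample_meta, "sample")
  n <- length(idx)
  if (n < 5) {
    warning("jackknife CI undefined for groups smaller than 5")
    return(c(NA_real_, NA_real_))
  }
  dos <- ds$dosages[idx, , drop = FALSE]
  full <- .group_r2_stats(dos, cfg)
  if (!full$ok) return(c(NA_real_, NA_real_))
  theta <- vapply(seq_len(n), function(i) {
    st <- .group_r2_stats(dos[-i, , drop = FALSE], cfg)
    if (st$ok) st$r2_drift else NA_real_
  }, numeric(1))
  theta <- theta[!is.na(theta)]
  m <- length(theta)
  if (m < 3) return(c(NA_real_, NA_real_))
  v <- (m - 1) / m * sum((theta - mean(theta))^2)
  half <- 1.96 * sqrt(v)
  lo_drift <- max(0, full$r2_drift - half)
  hi_drift <- full$r2_drift + half
  S <- full$S_harmonic
  ci_low <- .ne_from_drift(hi_drift, S)     # larger drift -> smaller Ne
  ci_high <- if (lo_drift <= 0) Inf else .ne_from_drift(lo_drift, S)
  c(ci_low, ci_high)
}

#' Estimate Ne over a set of named groupings
#'
#' @param ds a [genotype_dataset()].
#' @param groupings named list of sample selectors (see [subset_genotypes()]).
#' @param cfg an [ldne_config()].
#' @param min_n groups smaller than this are skipped (logged in the result's
#'   `skipped` attribute); default 11 — monitoring groups need more than 10
#'   samples for a usable estimate.
#' @param ci compute jackknife CIs.
#' @return data.frame with one row per estimated group: label, n, ne_hat,
#'   ci_low, ci_high, n_pairs, n_loci, S_harmonic, r2_mean, r2_drift.
#' @export
ne_scan <- function(ds, groupings, cfg = ldne_config(), min_n = 11L,
                    ci = FALSE) {
  stopifnot(is.list(groupings), !is.null(names(groupings)))
  rows <- list(); skipped <- character()
  for (nm in names(groupings)) {
    idx <- tryCatch(
      .resolve_selector(groupings[[nm]], ds$sample_ids, ds$sample_meta, "sample"),
      error = function(e) integer())
    if (length(idx) < min_n) {
      skipped <- c(skipped, sprintf("%s (n=%d)", nm, length(idx)))
      next
    }
    est <- suppressWarnings(estimate_ne(ds, idx, cfg, label = nm, ci = ci))
    rows[[nm]] <- data.frame(label = nm, n = est$n, ne_hat = est$ne_hat,
                             ci_low = est$ci_low, ci_high = est$ci_high,
                             n_pairs = est$n_pairs, n_loci = est$n_loci,
                             S_harmonic = est$S_harmonic,
                             r2_mean = est$r2_mean, r2_drift = est$r2_drift)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), n = integer(), ne_hat = numeric(),
               ci_low = numeric(), ci_high = numeric(), n_pairs = integer(),
               n_loci = integer(), S_harmonic = numeric(),
               r2_mean = numeric(), r2_drift = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Build the standard monitoring groupings from sample metadata
#'
#' Produces the four grouping families used for cohort-based monitoring:
#' per site-by-cohort, per cohort (sites pooled), per site (cohorts pooled),
#' and all samples. Groups containing admixed-ancestry individuals are
#' emitted twice, with and without them, so mixture-LD bias can be read
#' directly off paired rows.
#'
#' @param ds a [genotype_dataset()] whose `sample_meta` carries `site`,
#'   `cohort` and `ancestry`.
#' @param admixed_variants emit with/without-admixed paired groups?
#' @return named list of integer sample selectors for [ne_scan()].
#' @export
make_groupings <- function(ds, admixed_variants = TRUE) {
  sm <- ds$sample_meta
  adm <- !is.na(sm$ancestry) & sm$ancestry %in% c("admixed", "source")
  g <- list()
  add <- function(name, idx) {
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return()
    if (admixed_variants && any(adm[idx])) {
      g[[paste0(name, ".no_admixed")]] <<- idx[!adm[idx]]
      g[[paste0(name, ".with_admixed")]] <<- idx
    } else g[[name]] <<- idx
  }
  site <- as.character(sm$site); coh <- as.character(sm$cohort)
  for (s in sort(unique(stats::na.omit(site))))
    for (k in sort(unique(stats::na.omit(coh[site == s]))))
      add(paste0(s, ".", k), which(site == s & coh == k))
  for (k in sort(unique(stats::na.omit(coh))))
    add(paste0("all_sites.", k), which(coh == k))
  for (s in sort(unique(stats::na.omit(site))))
    add(s, which(site == s))
  add("all", seq_len(nrow(sm)))
  g
}

#' Write an Ne-estimate table as CSV
#' @param tab data.frame from [ne_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ne_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
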