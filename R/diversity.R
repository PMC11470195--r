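#' Individual heterozygosity (PHt)
#'
#' Proportion of heterozygous sites among each individual's non-missing loci.
#'
#' @param ds a [genotype_dataset()].
#' @return data.frame: sample_id, pht, n_called. Individuals with zero called
#'   loci get `NA` pht (with a warning).
#' @export
individual_pht <- function(ds) {
  if (!nrow(ds$dosages) || !ncol(ds$dosages)) stop("dataset is empty")
  n_called <- rowSums(!is.na(ds$dosages))
  het <- rowSums(ds$dosages == 1L, na.rm = TRUE)
  pht <- ifelse(n_called > 0, het / n_called, NA_real_)
  if (any(n_called == 0))
    warning(sum(n_called == 0), " individual(s) with zero called loci")
  data.frame(sample_id = ds$sample_ids, pht = pht, n_called = n_called)
}

#' Population heterozygosity summary for one group
#'
#' Per locus within the group: Ho is the heterozygote fraction among called
#' individuals; He = 2p(1-p) with p the allele frequency among called
#' genotypes (uncorrected, so printed group-level Fe arithmetic is exact; set
#' `small_sample_correction = TRUE` for the 2n/(2n-1) variant); FIS is
#' 1 - Ho/He over loci with He > 0. The summary reports means and SDs across
#' the locus panel of `ds` — supply a fixed panel so groups are comparable.
#'
#' @param ds a [genotype_dataset()] restricted to the comparison locus panel.
#' @param group sample selector (>= 2 individuals); `NULL` = all.
#' @param label group label.
#' @param small_sample_correction apply the 2n/(2n-1) factor to He.
#' @return one-row data.frame: group, n, Ho, sd_Ho, He, sd_He, Fis, sd_Fis.
#' @export
pop_heterozygosity <- function(ds, group = NULL, label = "all",
                               small_sample_correction = FALSE) {
  idx <- .resolve_selector(group, ds$sample_ids, ds$sample_meta, "sample")
  if (length(idx) < 2) stop("group '", label, "' needs at least 2 individuals")
  dos <- ds$dosages[idx, , drop = FALSE]
  called <- colSums(!is.na(dos))
  het <- colSums(dos == 1L, na.rm = TRUE)
  ho <- ifelse(called > 0, het / called, NA_real_)
  p <- ifelse(called > 0, colSums(dos, na.rm = TRUE) / (2 * called), NA_real_)
  he <- 2 * p * (1 - p)
  if (small_sample_correction)
    he <- he * ifelse(called > 0, 2 * called / (2 * called - 1), NA_real_)
  fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  data.frame(group = label, n = length(idx),
             Ho = mean(ho, na.rm = TRUE), sd_Ho = stats::sd(ho, na.rm = TRUE),
             He = mean(he, na.rm = TRUE), sd_He = stats::sd(he, na.rm = TRUE),
             Fis = mean(fis, na.rm = TRUE), sd_Fis = stats::sd(fis, na.rm = TRUE))
}

#' Effective inbreeding relative to an outbred reference
#'
#' Fe = 1 - He_inbred / He_outbred. May be negative when the focal group is
#' more diverse than the reference (returned as-is, with a warning).
#'
#' @param He_inbred expected heterozygosity of the focal (inbred) group.
#' @param He_outbred expected heterozygosity of the outbred reference (> 0).
#' @return Fe.
#' @export
effective_inbreeding <- function(He_inbred, He_outbred) {
  if (any(He_outbred <= 0)) stop("He_outbred must be positive")
  fe <- 1 - He_inbred / He_outbred
  if (any(fe < 0))
    warning("negative Fe: focal group more diverse than the reference")
  fe
}

#' Linear model of individual heterozygosity on river distance
#'
#' Ordinary least squares of PHt on stream distance, the standard
#' upstream-to-downstream diversity-gradient test.
#'
#' @param pht data.frame from [individual_pht()].
#' @param river_km numeric distance (km) per sample, aligned with `pht`.
#' @return list: slope, intercept, p_value (t-test on slope), r2, n.
#' @export
het_distance_model <- function(pht, river_km) {
  ok <- !is.na(pht$pht) & !is.na(river_km)
  if (sum(ok) < 3) stop("need at least 3 samples with both values")
  if (stats::sd(river_km[ok]) == 0) stop("river_km is constant; model degenerate")
  fit <- stats::lm(pht$pht[ok] ~ river_km[ok])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = sm$coefficients[2, 4],
       r2 = sm$r.squared, n = sum(ok))
}

#' Fixed-effects ANOVA with Tukey HSD and nested-model comparison
#'
#' Fits `values ~ f1` (or `~ f1 * f2` / `~ f1 + f2`), returns the ANOVA
#' table, Tukey honest-significant-difference pairwise comparisons, and —
#' when two factors are supplied — nested-model F-tests for the ladder
#' f1, f1 + f2, f1 + f2 + f1:f2.
#'
#' @param values numeric response per sample.
#' @param f1 first grouping factor.
#' @param f2 optional second factor.
#' @param interaction include the interaction term (refused, with a message,
#'   when some cell of the two-way design is empty).
#' @return list: anova (data.frame), tukey (list of matrices), and, with two
#'   factors, `ladder` (data.frame of nested-model comparisons).
#' @export
group_anova <- function(values, f1, f2 = NULL, interaction = !is.null(f2)) {
  f1 <- factor(f1)
  if (nlevels(f1) < 2) stop("need at least 2 groups")
  if (min(table(f1)) < 2) stop("every group needs at least 2 members")
  dat <- data.frame(y = values, f1 = f1)
  if (is.null(f2)) {
    fit <- stats::aov(y ~ f1, data = dat)
    return(list(anova = as.data.frame(summary(fit)[[1]]),
                tukey = lapply(stats::TukeyHSD(fit), identity)))
  }
  dat$f2 <- factor(f2)
  use_int <- interaction
  if (use_int && any(table(dat$f1, dat$f2) == 0)) {
    message("empty cells in the two-way design; interaction term skipped")
    use_int <- FALSE
  }
  m1 <- stats::lm(y ~ f1, data = dat)
  m2 <- stats::lm(y ~ f2, data = dat)
  m12 <- stats::lm(y ~ f1 + f2, data = dat)
  fits <- list(f1 = m1, f2 = m2, `f1+f2` = m12)
  cmp <- list(stats::anova(m1, m12), stats::anova(m2, m12))
  labels <- c("f1 -> f1+f2", "f2 -> f1+f2")
  if (use_int) {
    mint <- stats::lm(y ~ f1 * f2, data = dat)
    fits$`f1*f2` <- mint
    cmp <- c(cmp, list(stats::anova(m12, mint)))
    labels <- c(labels, "f1+f2 -> f1*f2")
  }
  ladder <- data.frame(
    comparison = labels,
    F = vapply(cmp, function(a) a$F[2], numeric(1)),
    p_value = vapply(cmp, function(a) a$`Pr(>F)`[2], numeric(1)),
    adj_r2_larger = vapply(cmp, function(a) NA_real_, numeric(1)))
  ladder$adj_r2_larger <- vapply(
    c(list(m12, m12), if (use_int) list(fits$`f1*f2`)),
    function(m) summary(m)$adj.r.squared, numeric(1))
  aovfit <- stats::aov(y ~ f1, data = dat)
  list(anova = as.data.frame(summary(aovfit)[[1]]),
       tukey = lapply(stats::TukeyHSD(aovfit), identity),
       ladder = ladder,
       adj_r2 = vapply(fits, function(m) summary(m)$adj.r.squared, numeric(1)))
}

#' Diversity summaries for a list of groups
#'
#' @param ds a [genotype_dataset()] restricted to a fixed locus panel.
#' @param groupings named list of sample selectors.
#' @param min_n skip groups smaller than this.
#' @return data.frame with one [pop_heterozygosity()] row per group.
#' @export
diversity_table <- function(ds, groupings, min_n = 2L) {
  rows <- list()
  for (nm in names(groupings)) {
    idx <- tryCatch(
      .resolve_selector(groupings[[nm]], ds$sample_ids, ds$sample_meta, "sample"),
      error = function(e) integer())
    if (length(idx) < min_n) next
    rows[[nm]] <- pop_heterozygosity(ds, idx, label = nm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
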