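#' Quality-control configuration
#'
#' Defaults follow standard practice for reduced-representation SNP data from
#' small wild populations: per-locus mean read depth in [6, 50], tag
#' reproducibility at least 95%, at most 10% missing calls per locus and 20%
#' per individual, removal of loci whose heterozygote excess over 0.5 is
#' significant (a paralog/technical-artefact signature), one random SNP per
#' sequencing tag, and optional minor-allele-count screening used only for
#' sibship subsets.
#'
#' @param depth_min,depth_max admissible range of per-locus mean read depth.
#' @param reproducibility_min minimum tag reproducibility (strict `<` drops).
#' @param locus_missing_max maximum fraction of missing calls per locus.
#' @param individual_missing_max maximum fraction of missing calls per sample.
#' @param excess_het_alpha family-wise alpha for the excess-heterozygosity test.
#' @param excess_het_correction `"bonferroni"` or `"fdr"`.
#' @param one_per_tag keep one random SNP per `tag_id`?
#' @param thin_window_bp window used by [thin_by_distance()].
#' @param mac_min minimum minor-allele count (0 disables; 2 for sibship data).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(depth_min = 6, depth_max = 50, reproducibility_min = 0.95,
                      locus_missing_max = 0.10, individual_missing_max = 0.20,
                      excess_het_alpha = 0.05,
                      excess_het_correction = c("bonferroni", "fdr"),
                      one_per_tag = TRUE, thin_window_bp = 50000L,
                      mac_min = 0L) {
  excess_het_correction <- match.arg(excess_het_correction)
  stopifnot(depth_min < depth_max,
            locus_missing_max >= 0, locus_missing_max <= 1,
            individual_missing_max >= 0, individual_missing_max <= 1,
            reproducibility_min >= 0, reproducibility_min <= 1)
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 reproducibility_min = reproducibility_min,
                 locus_missing_max = locus_missing_max,
                 individual_missing_max = individual_missing_max,
                 excess_het_alpha = excess_het_alpha,
                 excess_het_correction = excess_het_correction,
                 one_per_tag = one_per_tag,
                 thin_window_bp = as.integer(thin_window_bp),
                 mac_min = as.integer(mac_min)),
            class = "qc_config")
}

#' Exact one-sided test for heterozygote excess over 0.5
#'
#' Under the null that each called genotype is heterozygous with probability
#' 0.5, the p-value is the exact binomial upper tail
#' P(X >= het_count), X ~ Binomial(called_count, 0.5). Loci with
#' significantly more heterozygotes than half their calls are classic
#' collapsed-paralog artefacts.
#'
#' @param het_count number of heterozygous calls at the locus.
#' @param called_count number of non-missing calls.
#' @param alpha per-test significance threshold (after any multiple-testing
#'   correction applied by the caller).
#' @return list with `p_value` and logical `flagged`.
#' @export
excess_het_test <- function(het_count, called_count, alpha = 0.05) {
  if (any(called_count < 1)) stop("called_count must be >= 1")
  if (any(het_count < 0 | het_count > called_count))
    stop("het_count must lie in [0, called_count]")
  p <- stats::pbinom(het_count - 1, called_count, 0.5, lower.tail = FALSE)
  list(p_value = p, flagged = p < alpha)
}

#' Apply the full locus/individual QC chain
#'
#' Filters are applied in fixed order: depth, reproducibility, locus
#' missingness, individual missingness, excess heterozygosity, one SNP per
#' tag (random within tag, seeded), minor-allele count. Stages whose metadata
#' are entirely absent (e.g. no depth column) pass all loci through. The
#' chain is idempotent: re-applying it to its own output drops nothing.
#'
#' @param ds a [genotype_dataset()].
#' @param cfg a [qc_config()].
#' @param seed integer seed controlling the random one-per-tag draw.
#' @return list with elements `ds` (filtered dataset) and `report`
#'   (`filter_report`: per-stage before/after counts and dropped ids).
#' @export
apply_qc <- function(ds, cfg = qc_config(), seed = 1L) {
  report <- list(seed = seed, stages = list())
  note <- function(stage, what, dropped_ids, n_before, n_after) {
    report$stages[[stage]] <<- list(what = what, n_before = n_before,
                                    n_after = n_after,
                                    dropped = dropped_ids)
  }
  lm <- ds$locus_meta
  keep <- rep(TRUE, ncol(ds$dosages))

  stage_drop <- function(stage, bad) {
    n_before <- sum(keep)
    drop <- keep & bad
    keep[drop] <<- FALSE
    note(stage, "loci", lm$locus_id[drop], n_before, sum(keep))
  }

  depth_bad <- !is.na(lm$mean_depth) &
    (lm$mean_depth < cfg$depth_min | lm$mean_depth > cfg$depth_max)
  stage_drop("depth", depth_bad)
  rep_bad <- !is.na(lm$reproducibility) & lm$reproducibility < cfg$reproducibility_min
  stage_drop("reproducibility", rep_bad)

  miss_loc <- colMeans(is.na(ds$dosages))
  stage_drop("locus_missing", miss_loc > cfg$locus_missing_max)

  # individual missingness, computed on the loci that survive so far
  n_before_ind <- nrow(ds$dosages)
  miss_ind <- rowMeans(is.na(ds$dosages[, keep, drop = FALSE]))
  ind_keep <- miss_ind <= cfg$individual_missing_max
  note("individual_missing", "individuals", ds$sample_ids[!ind_keep],
       n_before_ind, sum(ind_keep))

  sub <- ds$dosages[ind_keep, , drop = FALSE]
  het <- colSums(sub == 1L, na.rm = TRUE)
  called <- colSums(!is.na(sub))
  testable <- keep & called >= 1
  p <- rep(NA_real_, length(keep))
  p[testable] <- excess_het_test(het[testable], called[testable], 1)$p_value
  m <- sum(testable)
  flagged <- rep(FALSE, length(keep))
  if (m > 0) {
    if (cfg$excess_het_correction == "bonferroni") {
      flagged[testable] <- p[testable] < cfg$excess_het_alpha / m
    } else {
      flagged[testable] <- stats::p.adjust(p[testable], "fdr") < cfg$excess_het_alpha
    }
  }
  stage_drop("excess_het", flagged)

  if (isTRUE(cfg$one_per_tag) && !all(is.na(lm$tag_id))) {
    n_before <- sum(keep)
    idx <- which(keep)
    tag <- lm$tag_id[idx]
    tag[is.na(tag)] <- paste0(".untagged", seq_along(tag[is.na(tag)]))
    keep_in_tag <- withr_seed(seed, {
      split_idx <- split(idx, tag)
      vapply(split_idx, function(v)
        if (length(v) == 1L) v else sample(v, 1L), integer(1))
    })
    drop <- setdiff(idx, keep_in_tag)
    keep[drop] <- FALSE
    note("one_per_tag", "loci", lm$locus_id[drop], n_before, sum(keep))
  } else {
    note("one_per_tag", "loci", character(), sum(keep), sum(keep))
  }

  if (cfg$mac_min > 0) {
    mac <- pmin(colSums(sub, na.rm = TRUE), 2 * called - colSums(sub, na.rm = TRUE))
    stage_drop("mac", mac < cfg$mac_min)
  } else {
    note("mac", "loci", character(), sum(keep), sum(keep))
  }

  if (!any(keep)) {
    err <- simpleError("apply_qc removed all loci")
    err$report <- structure(report, class = "filter_report")
    stop(err)
  }
  out <- subset_genotypes(ds, samples = which(ind_keep), loci = which(keep))
  out <- .log_op(out, sprintf("apply_qc: %d/%d loci, %d/%d individuals retained (seed %d)",
                              sum(keep), length(keep), sum(ind_keep),
                              n_before_ind, seed))
  list(ds = out, report = structure(report, class = "filter_report"))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("QC filter report (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-20s %s: %d -> %d (%d dropped)\n", nm, s$what,
                s$n_before, s$n_after, length(s$dropped)))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report a `filter_report` from [apply_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' LD decay with physical distance
#'
#' For every pair of mapped loci on the same chromosome within `max_dist_bp`,
#' computes the composite-LD r-squared ([pair_r2()]) and bins it by physical
#' distance. The background level is the mean r-squared of a random sample of
#' cross-chromosome pairs, which carry no physical linkage.
#'
#' @param ds a [genotype_dataset()].
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @param n_background number of cross-chromosome pairs sampled for the
#'   background level.
#' @param seed seed for the background sample.
#' @return list with `bins` (data.frame: bin_start, bin_mid, n_pairs, mean_r2)
#'   and `background` (list: mean_r2, n_pairs).
#' @export
ld_decay <- function(ds, max_dist_bp = 200000L, bin_bp = 10000L,
                     n_background = 500L, seed = 1L) {
  lm <- ds$locus_meta
  placed <- which(!is.na(lm$chrom) & !is.na(lm$pos))
  if (length(placed) < 2) stop("ld_decay needs at least two placed loci")
  r2m <- .pair_r2_matrix(ds$dosages)$r2
  chrom <- lm$chrom[placed]; pos <- lm$pos[placed]
  rows <- list()
  for (ch in unique(chrom)) {
    i <- placed[chrom == ch]
    if (length(i) < 2) next
    cmb <- utils::combn(seq_along(i), 2)
    d <- abs(pos[chrom == ch][cmb[1, ]] - pos[chrom == ch][cmb[2, ]])
    ok <- d <= max_dist_bp
    if (!any(ok)) next
    rows[[ch]] <- data.frame(dist = d[ok],
                             r2 = r2m[cbind(i[cmb[1, ok]], i[cmb[2, ok]])])
  }
  within <- do.call(rbind, rows)
  if (is.null(within)) stop("no same-chromosome pairs within max_dist_bp")
  within <- within[!is.na(within$r2), , drop = FALSE]
  bin <- floor(within$dist / bin_bp)
  agg <- stats::aggregate(within$r2, list(bin = bin), mean)
  n <- stats::aggregate(within$r2, list(bin = bin), length)
  bins <- data.frame(bin_start = agg$bin * bin_bp,
                     bin_mid = (agg$bin + 0.5) * bin_bp,
                     n_pairs = n$x, mean_r2 = agg$x)
  bg <- withr_seed(seed, {
    cross <- which(outer(chrom, chrom, "!="), arr.ind = TRUE)
    cross <- cross[cross[, 1] < cross[, 2], , drop = FALSE]
    if (nrow(cross) == 0) {
      list(mean_r2 = NA_real_, n_pairs = 0L)
    } else {
      pick <- cross[sample(nrow(cross), min(n_background, nrow(cross))), , drop = FALSE]
      v <- r2m[cbind(placed[pick[, 1]], placed[pick[, 2]])]
      list(mean_r2 = mean(v, na.rm = TRUE), n_pairs = sum(!is.na(v)))
    }
  })
  list(bins = bins, background = bg)
}

#' Thin mapped loci by distance windows
#'
#' Removes unmapped loci, then keeps one random locus (seeded) per
#' non-overlapping window of `window_bp` anchored at position 0 on each
#' chromosome.
#'
#' @param ds a [genotype_dataset()].
#' @param window_bp window width in bp.
#' @param seed seed for the random within-window choice.
#' @return The thinned dataset.
#' @export
thin_by_distance <- function(ds, window_bp = 50000L, seed = 1L) {
  lm <- ds$locus_meta
  placed <- which(!is.na(lm$chrom) & !is.na(lm$pos))
  if (!length(placed)) stop("thin_by_distance needs placed loci")
  win <- paste(lm$chrom[placed], floor(lm$pos[placed] / window_bp), sep = ":")
  keep <- withr_seed(seed, {
    vapply(split(placed, win), function(v)
      if (length(v) == 1L) v else sample(v, 1L), integer(1))
  })
  out <- subset_genotypes(ds, loci = sort(unname(keep)))
  .log_op(out, sprintf("thin_by_distance: window %d bp, %d -> %d loci (seed %d)",
                       window_bp, ncol(ds$dosages), length(keep), seed))
}
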