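#' Pipeline configuration
#'
#' Bundles every stage's settings into one declarative object. All
#' scientific thresholds default to the monitoring protocol's values and are
#' individually overridable.
#'
#' @param qc a [qc_config()].
#' @param ldne an [ldne_config()].
#' @param life a [life_history()].
#' @param rules an [age_rules()].
#' @param fe_target target effective inbreeding for the rescue plan.
#' @param min_group_n minimum group size for Ne estimation (default 11).
#' @param outbred_he expected heterozygosity of the outbred reference
#'   population; `NULL` uses the most diverse site in the data.
#' @param pca_axis PCA axis used for ancestry classification.
#' @param thin_window_bp window for physical-linkage thinning before Ne /
#'   kinship stages.
#' @param seed integer seed used by every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_config(), ldne = ldne_config(),
                            life = life_history(), rules = age_rules(),
                            fe_target = 0.1, min_group_n = 11L,
                            outbred_he = NULL, pca_axis = 2L,
                            thin_window_bp = 50000L, seed = 1L) {
  structure(list(qc = qc, ldne = ldne, life = life, rules = rules,
                 fe_target = fe_target, min_group_n = as.integer(min_group_n),
                 outbred_he = outbred_he, pca_axis = as.integer(pca_axis),
                 thin_window_bp = as.integer(thin_window_bp),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full monitoring pipeline
#'
#' Fixed stage order: QC filtering; individual and group heterozygosity with
#' effective inbreeding; PCA structure and ancestry counts; relatedness,
#' duplicates and sib families with cross-site connectivity; physical
#' thinning followed by the LD-based Ne scan over the standard groupings
#' with life-history adjustments; the genetic-rescue plan; the growth model
#' ladder. Outputs are written as CSV/JSON under `outdir` when given, and
#' the whole report is returned. Identical config + seed gives identical
#' outputs.
#'
#' @param ds a [genotype_dataset()] with sample metadata attached (site,
#'   cohort or capture data, lengths for the growth stage).
#' @param cfg a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @return list of class `pipeline_report` with elements `qc_report`,
#'   `diversity`, `fe`, `pca`, `ancestry_counts`, `duplicates`, `families`,
#'   `connectivity`, `ne`, `rescue`, `growth`.
#' @export
run_pipeline <- function(ds, cfg = pipeline_config(), outdir = NULL) {
  stage <- "qc"
  report <- list()
  res <- tryCatch({
    qc <- apply_qc(ds, cfg$qc, seed = cfg$seed)
    report$qc_report <- qc$report
    clean <- qc$ds

    stage <- "diversity"
    pht <- individual_pht(clean)
    groupings <- make_groupings(clean)
    div <- diversity_table(clean, groupings, min_n = max(2L, cfg$min_group_n))
    he_ref <- cfg$outbred_he
    site_rows <- div[!grepl("\\.", div$group) & div$group != "all", , drop = FALSE]
    if (is.null(he_ref)) he_ref <- max(site_rows$He)
    fe <- data.frame(group = site_rows$group, He = site_rows$He,
                     Fe = suppressWarnings(effective_inbreeding(site_rows$He, he_ref)))
    report$diversity <- div
    report$pht <- pht
    report$fe <- fe

    stage <- "structure"
    pca <- run_pca(clean, n_components = max(2L, cfg$pca_axis))
    anc <- clean$sample_meta$ancestry
    report$pca <- pca
    if (all(c("local", "source") %in% anc)) {
      lab <- classify_ancestry(
        pca, source_ids = clean$sample_ids[anc == "source"],
        local_ids = clean$sample_ids[anc == "local"], axis = cfg$pca_axis)
      report$ancestry_labels <- lab
      report$ancestry_counts <- table(lab)
    } else {
      report$ancestry_counts <- table(anc)
    }

    stage <- "kinship"
    lm <- clean$locus_meta
    thinned <- if (any(!is.na(lm$chrom) & !is.na(lm$pos)))
      thin_by_distance(clean, cfg$thin_window_bp, seed = cfg$seed) else clean
    pairs <- pairwise_relatedness(thinned)
    dup <- find_duplicates(pairs)
    fam <- sib_clusters(pairs, sample_meta = thinned$sample_meta)
    report$duplicates <- dup
    report$families <- fam
    report$connectivity <- family_connectivity(fam)

    stage <- "ne"
    ne <- ne_scan(thinned, make_groupings(thinned), cfg$ldne,
                  min_n = cfg$min_group_n)
    ratio <- cfg$life$nb_ne_ratio
    finite <- is.finite(ne$ne_hat) & ne$ne_hat > 0
    ne$nb_adj <- NA_real_; ne$ne_adj <- NA_real_
    if (any(finite)) {
      adj <- adjust_nb(ne$ne_hat[finite], ratio)
      ne$nb_adj[finite] <- adj$nb_adj
      ne$ne_adj[finite] <- adj$ne_adj
    }
    report$ne <- ne

    stage <- "rescue"
    site_ne <- ne[ne$label %in% c(fe$group,
                                  paste0(fe$group, ".no_admixed")), , drop = FALSE]
    site_ne$site <- sub("\\.no_admixed$", "", site_ne$label)
    m <- match(fe$group, site_ne$site)
    nb_site <- site_ne$nb_adj[m]
    keep <- !is.na(nb_site) & is.finite(nb_site) & fe$Fe > 0
    report$rescue <- rescue_plan(fe$group[keep], fe$Fe[keep],
                                 nb_site[keep], cfg$fe_target)

    stage <- "growth"
    sm <- clean$sample_meta
    if (!all(is.na(sm$total_length_mm))) {
      age_mid <- c("YOY" = 0.5, "1-2YO" = 1.5, "2-3YO" = 2.5)
      cls <- sm$age_class
      if (all(is.na(cls)))
        cls <- assign_age(sm$total_length_mm, sm$capture_year, cfg$rules)
      juv <- !is.na(cls) & cls != "adult" & !is.na(sm$total_length_mm)
      if (sum(juv) >= 4 && length(unique(cls[juv])) >= 2) {
        gm <- fit_gompertz(sm$total_length_mm[juv], age_mid[cls[juv]])
        lad <- tryCatch(
          growth_model_ladder(gm$residuals[!is.na(gm$residuals)],
                              sm$site[juv], sm$cohort[juv], pht$pht[juv]),
          error = function(e) NULL)
        report$growth <- list(model = gm[c("b1", "b2", "b3")], ladder = lad)
      } else {
        report$growth <- list(model = NULL, ladder = NULL,
                              note = "insufficient age spread for a growth fit")
      }
    }
    report
  }, error = function(e) {
    e$message <- sprintf("pipeline failed at stage '%s': %s", stage, e$message)
    e$partial <- report
    stop(e)
  })

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_filter_report(res$qc_report, file.path(outdir, "qc_report.json"))
    utils::write.csv(res$diversity, file.path(outdir, "diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(res$fe, file.path(outdir, "effective_inbreeding.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(res$pca$scores),
                                res$pca$scores),
                     file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    write_ne_table(res$ne, file.path(outdir, "ne_estimates.csv"))
    utils::write.csv(res$rescue, file.path(outdir, "rescue_plan.csv"),
                     row.names = FALSE)
    if (nrow(res$families))
      utils::write.csv(res$families, file.path(outdir, "sib_families.csv"),
                       row.names = FALSE)
  }
  structure(res, class = "pipeline_report")
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("Monitoring pipeline report\n")
  cat(sprintf("  diversity groups : %d\n", nrow(x$diversity)))
  cat(sprintf("  Fe per site      : %s\n",
              paste(sprintf("%s=%.3f", x$fe$group, x$fe$Fe), collapse = ", ")))
  cat(sprintf("  ancestry counts  : %s\n",
              paste(names(x$ancestry_counts), x$ancestry_counts,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  sib families     : %d (%d duplicates)\n",
              length(unique(x$families$family)), length(x$duplicates)))
  cat(sprintf("  Ne groups        : %d\n", nrow(x$ne)))
  cat(sprintf("  rescue sites     : %d\n", nrow(x$rescue)))
  invisible(x)
}
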