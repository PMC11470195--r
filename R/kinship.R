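#' Pairwise relatedness and genotype mismatch
#'
#' Moment-based (Queller-Goodnight) relatedness for every pair of
#' individuals, using allele frequencies estimated from the whole dataset,
#' together with the raw genotype mismatch rate (fraction of jointly called
#' loci with differing genotypes). The estimate is symmetrized (mean of the
#' two directed ratios). Expected values: ~0.5 for full sibs and
#' parent-offspring, ~0 for unrelateds.
#'
#' This is a declared surrogate for full-likelihood sibship reconstruction:
#' it supports the same downstream summaries (duplicate detection, full-sib
#' clusters, cross-site family edges) and is validated against pedigree
#' simulations, but does not model genotyping error or half-sib structure.
#'
#' @param ds a [genotype_dataset()].
#' @param min_loci pairs with fewer jointly called loci are flagged
#'   low-confidence (column `low_confidence`).
#' @return data.frame: id1, id2, r_hat, mismatch_rate, n_joint,
#'   low_confidence.
#' @export
pairwise_relatedness <- function(ds, min_loci = 50L) {
  G <- ds$dosages
  n <- nrow(G)
  if (n < 2) stop("need at least two individuals")
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  G <- G[, poly, drop = FALSE]; p <- p[poly]
  q <- 1 - p
  M <- !is.na(G); storage.mode(M) <- "double"
  X <- G; X[is.na(X)] <- 0; storage.mode(X) <- "double"
  H <- (2 - G) * M; H[is.na(H)] <- 0; storage.mode(H) <- "double"
  # similarity term: 0.5 * sum over loci of (gx*gy + (2-gx)*(2-gy))
  Sim <- 0.5 * (tcrossprod(X) + tcrossprod(H))
  # expectation term sum over jointly called loci of (gx*p + (2-gx)*q)
  P <- sweep(X, 2, p, "*") + sweep(H, 2, q, "*")
  C <- tcrossprod(P, M)                  # C[x, y]
  # denominator: sum over jointly called loci of (1 + I(gx hom) - (gx p + (2-gx) q))
  Hom <- (G != 1L) * M; Hom[is.na(Hom)] <- 0; storage.mode(Hom) <- "double"
  D <- tcrossprod(M + Hom, M) - C
  num <- Sim - C
  Rdir <- num / D                        # directed estimate, focal = row
  r_hat_m <- (Rdir + t(Rdir)) / 2
  # mismatch: jointly called loci with equal dosage
  eq <- matrix(0, n, n)
  for (d in 0:2) {
    I <- (G == d) * M; I[is.na(I)] <- 0; storage.mode(I) <- "double"
    eq <- eq + tcrossprod(I)
  }
  joint <- tcrossprod(M)
  mm <- 1 - eq / joint
  ut <- which(upper.tri(r_hat_m), arr.ind = TRUE)
  out <- data.frame(id1 = ds$sample_ids[ut[, 1]],
                    id2 = ds$sample_ids[ut[, 2]],
                    r_hat = r_hat_m[ut],
                    mismatch_rate = mm[ut],
                    n_joint = joint[ut])
  out$low_confidence <- out$n_joint < min_loci
  out
}

# connected components over sample ids from an edge list
.components <- function(ids, edge1, edge2) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(edge1)) {
    a <- find(match(edge1[k], ids)); b <- find(match(edge2[k], ids))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(ids), find, numeric(1))
  split(ids, roots)
}

#' Detect duplicate (recaptured) individuals
#'
#' Samples whose genotype mismatch rate is at most `mismatch_max` are linked;
#' connected components of two or more samples are reported as recapture
#' groups. The default threshold (2%) comfortably absorbs per-genotype error
#' around 1% while staying far below the mismatch rate of full sibs.
#'
#' @param pairs data.frame from [pairwise_relatedness()].
#' @param mismatch_max maximum mismatch rate for a duplicate link.
#' @return list of character vectors (one per recapture group).
#' @export
find_duplicates <- function(pairs, mismatch_max = 0.02) {
  if (!nrow(pairs)) return(list())
  e <- pairs[pairs$mismatch_rate <= mismatch_max, , drop = FALSE]
  if (!nrow(e)) return(list())
  ids <- sort(unique(c(e$id1, e$id2)))
  comp <- .components(ids, e$id1, e$id2)
  unname(comp[lengths(comp) >= 2])
}

#' Cluster samples into full-sib-like families
#'
#' Links pairs with relatedness of at least `r_min` and reports single-linkage
#' components of two or more samples as families. Run after duplicates have
#' been collapsed.
#'
#' @param pairs data.frame from [pairwise_relatedness()].
#' @param r_min minimum relatedness for a sib edge (default 0.35, midway
#'   between the full-sib expectation 0.5 and the half-sib 0.25).
#' @param sample_meta optional sample metadata (site, cohort) used to
#'   annotate families.
#' @return data.frame of class `sib_families`: family, sample_id, site,
#'   cohort. Empty when no family is found.
#' @export
sib_clusters <- function(pairs, r_min = 0.35, sample_meta = NULL) {
  empty <- data.frame(family = integer(), sample_id = character(),
                      site = character(), cohort = character())
  if (!nrow(pairs)) return(structure(empty, class = c("sib_families", "data.frame")))
  e <- pairs[pairs$r_hat >= r_min, , drop = FALSE]
  if (!nrow(e)) return(structure(empty, class = c("sib_families", "data.frame")))
  ids <- sort(unique(c(e$id1, e$id2)))
  comp <- .components(ids, e$id1, e$id2)
  comp <- comp[lengths(comp) >= 2]
  comp <- comp[order(-lengths(comp), vapply(comp, min, character(1)))]
  out <- do.call(rbind, lapply(seq_along(comp), function(i)
    data.frame(family = i, sample_id = sort(comp[[i]]))))
  if (is.null(out)) return(structure(empty, class = c("sib_families", "data.frame")))
  if (!is.null(sample_meta)) {
    idx <- match(out$sample_id, sample_meta$sample_id)
    out$site <- as.character(sample_meta$site[idx])
    out$cohort <- as.character(sample_meta$cohort[idx])
  } else {
    out$site <- NA_character_; out$cohort <- NA_character_
  }
  rownames(out) <- NULL
  structure(out, class = c("sib_families", "data.frame"))
}

#' Cross-site connectivity evidence from sib families
#'
#' Families whose members were sampled at more than one site are dispersal
#' evidence. Returns per-site-pair counts of spanning families and the
#' per-family site and cohort spans.
#'
#' @param families a `sib_families` data.frame from [sib_clusters()].
#' @return list: `edges` (data.frame site_a, site_b, n_families) and
#'   `families` (data.frame family, n, n_sites, sites, cohorts).
#' @export
family_connectivity <- function(families) {
  if (!nrow(families))
    return(list(edges = data.frame(site_a = character(), site_b = character(),
                                   n_families = integer()),
                families = data.frame(family = integer(), n = integer(),
                                      n_sites = integer(), sites = character(),
                                      cohorts = character())))
  per <- lapply(split(families, families$family), function(f) {
    sites <- sort(unique(stats::na.omit(f$site)))
    data.frame(family = f$family[1], n = nrow(f), n_sites = length(sites),
               sites = paste(sites, collapse = "+"),
               cohorts = paste(sort(unique(stats::na.omit(f$cohort))),
                               collapse = "+"))
  })
  fam <- do.call(rbind, per)
  rownames(fam) <- NULL
  edges <- list()
  for (f in split(families, families$family)) {
    sites <- sort(unique(stats::na.omit(f$site)))
    if (length(sites) < 2) next
    cmb <- utils::combn(sites, 2)
    for (k in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, k], cmb[2, k], sep = "|")
      edges[[key]] <- (if (is.null(edges[[key]])) 0L else edges[[key]]) + 1L
    }
  }
  ed <- if (length(edges)) {
    parts <- strsplit(names(edges), "|", fixed = TRUE)
    data.frame(site_a = vapply(parts, `[`, "", 1),
               site_b = vapply(parts, `[`, "", 2),
               n_families = unlist(edges, use.names = FALSE))
  } else data.frame(site_a = character(), site_b = character(),
                    n_families = integer())
  list(edges = ed, families = fam)
}
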