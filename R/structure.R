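#' PCA of genotype dosages
#'
#' Missing dosages are mean-imputed per locus, columns are centered, and the
#' covariance eigendecomposition is taken (the standard shortcut for
#' principal-coordinate analysis of SNP genotypes). Component signs are fixed
#' by making each component's largest-magnitude loading positive, so results
#' are deterministic.
#'
#' @param ds a [genotype_dataset()].
#' @param n_components number of axes to return.
#' @return list of class `pca_result`: `scores` (individuals x components,
#'   rownames = sample ids), `explained` (variance fractions), `loadings`.
#' @export
run_pca <- function(ds, n_components = 2L) {
  X <- ds$dosages
  if (nrow(X) < 2 || ncol(X) < 2) stop("PCA needs >= 2 individuals and loci")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < 1e-12)) stop("constant genotype matrix; PCA degenerate")
  pc <- stats::prcomp(X, center = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ds$sample_ids
  structure(list(scores = scores,
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 loadings = load),
            class = "pca_result")
}

#' Classify ancestry from a PCA axis
#'
#' Uses reference individuals of known source and local ancestry to orient
#' one PCA axis (source mean below local mean), then labels every sample:
#' beyond the local cutoff is `local`, beyond the source cutoff is `source`,
#' between the cutoffs is `admixed`. Default cutoffs bracket the central
#' `admixed_band` fraction of the gap between the reference-group means,
#' where F1 offspring of one local and one source parent are expected.
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param source_ids,local_ids sample ids of reference individuals.
#' @param axis component index used for classification (default 2).
#' @param admixed_band central fraction of the reference gap labelled
#'   admixed (default 0.5).
#' @param source_cutoff,local_cutoff explicit cutoffs overriding the
#'   defaults, on the oriented axis.
#' @return character vector of labels (`"local"`, `"source"`, `"admixed"`)
#'   named by sample id, with the cutoffs in attributes.
#' @export
classify_ancestry <- function(pca, source_ids, local_ids, axis = 2L,
                              admixed_band = 0.5,
                              source_cutoff = NULL, local_cutoff = NULL) {
  sc <- pca$scores
  if (axis > ncol(sc)) stop("axis exceeds available components")
  v <- sc[, axis]
  if (!all(source_ids %in% rownames(sc)) || !all(local_ids %in% rownames(sc)))
    stop("reference ids missing from PCA scores")
  s <- v[source_ids]; l <- v[local_ids]
  if (mean(s) > mean(l)) { v <- -v; s <- -s; l <- -l }
  if (max(s) >= min(l))
    stop("reference groups overlap on axis ", axis,
         "; choose a different axis or explicit thresholds")
  gap <- mean(l) - mean(s)
  if (is.null(source_cutoff))
    source_cutoff <- mean(s) + (1 - admixed_band) / 2 * gap
  if (is.null(local_cutoff))
    local_cutoff <- mean(l) - (1 - admixed_band) / 2 * gap
  if (source_cutoff >= local_cutoff) stop("source_cutoff must be below local_cutoff")
  lab <- ifelse(v >= local_cutoff, "local",
                ifelse(v <= source_cutoff, "source", "admixed"))
  names(lab) <- rownames(sc)
  attr(lab, "source_cutoff") <- source_cutoff
  attr(lab, "local_cutoff") <- local_cutoff
  lab
}

#' Pairwise Weir-Cockerham FST between sites
#'
#' Per-locus Weir-Cockerham (1984) variance components for each pair of
#' sites, combined across loci as a ratio of sums. Negative pairwise
#' estimates are floored at 0 in the reported matrix; raw values are kept in
#' the `raw` attribute.
#'
#' @param ds a [genotype_dataset()].
#' @param sites site label per sample (default from `sample_meta$site`).
#' @return symmetric FST matrix over sites (diagonal 0) with attribute `raw`.
#' @export
pairwise_fst <- function(ds, sites = ds$sample_meta$site) {
  sites <- as.character(sites)
  tab <- table(sites[!is.na(sites)])
  usable <- names(tab)[tab >= 2]
  dropped <- setdiff(names(tab), usable)
  if (length(dropped))
    message("sites excluded from FST (fewer than 2 individuals): ",
            paste(dropped, collapse = ", "))
  if (length(usable) < 2) stop("need >= 2 sites with >= 2 individuals")
  k <- length(usable)
  fst <- matrix(0, k, k, dimnames = list(usable, usable))
  raw <- fst
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- .wc_fst_two(ds$dosages[sites %in% usable[i] & !is.na(sites), , drop = FALSE],
                     ds$dosages[sites %in% usable[j] & !is.na(sites), , drop = FALSE])
    raw[i, j] <- raw[j, i] <- v
    fst[i, j] <- fst[j, i] <- max(0, v)
  }
  attr(fst, "raw") <- raw
  fst
}

# Weir & Cockerham (1984) theta for two populations, ratio-of-sums over loci
.wc_fst_two <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  ok <- n1 >= 2 & n2 >= 2
  n1 <- n1[ok]; n2 <- n2[ok]
  d1 <- d1[, ok, drop = FALSE]; d2 <- d2[, ok, drop = FALSE]
  p1 <- colSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(d2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  denom <- sum((a + b + cc)[poly])
  if (denom == 0) return(0)
  sum(a[poly]) / denom
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper triangles; significance by joint
#' row/column permutation of the second matrix, two-sided:
#' p = (#{|r*| >= |r|} + 1) / (n_perm + 1).
#'
#' @param m1,m2 symmetric distance matrices of equal dimension.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = 1L) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have equal dimensions")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant distance matrix; Mantel r undefined")
  r <- stats::cor(x, y)
  n <- nrow(m1)
  hits <- withr_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      o <- sample(n)
      abs(stats::cor(x, m2[o, o][ut])) >= abs(r)
    }, logical(1)))
  })
  list(r = r, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}
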