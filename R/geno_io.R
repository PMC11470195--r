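#' Construct a genotype dataset
#'
#' The central data container of the package: a biallelic SNP dosage matrix
#' (individuals x loci, values 0/1/2 counting copies of the minor allele,
#' `NA` for missing calls) together with per-locus and per-sample metadata
#' and a provenance log of the operations applied so far.
#'
#' @param dosages integer matrix, individuals x loci, values in {0,1,2,NA}.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the rownames of `dosages`.
#' @param locus_meta data.frame with one row per locus. Recognised columns:
#'   `locus_id`, `tag_id`, `chrom`, `pos` (1-based bp), `mean_depth`,
#'   `reproducibility`, `call_rate`. Missing columns are filled with `NA`.
#' @param sample_meta data.frame with one row per sample. Recognised columns:
#'   `sample_id`, `site`, `river_km`, `capture_year`, `capture_date`,
#'   `total_length_mm`, `ancestry`, `cohort`, `age_class`.
#' @param provenance character vector of log lines.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, sample_ids = rownames(dosages),
                             locus_meta = NULL, sample_meta = NULL,
                             provenance = character()) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(sample_ids))
    sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length must equal number of rows of dosages")
  locus_meta <- .complete_locus_meta(locus_meta, colnames(dosages), ncol(dosages))
  if (anyDuplicated(locus_meta$locus_id)) stop("locus ids must be unique")
  sample_meta <- .complete_sample_meta(sample_meta, sample_ids)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- locus_meta$locus_id
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 locus_meta = locus_meta, sample_meta = sample_meta,
                 provenance = provenance),
            class = "genotype_dataset")
}

.locus_meta_cols <- c("locus_id", "tag_id", "chrom", "pos", "mean_depth",
                      "reproducibility", "call_rate")
.sample_meta_cols <- c("sample_id", "site", "river_km", "capture_year",
                       "capture_date", "total_length_mm", "ancestry",
                       "cohort", "age_class")

.complete_locus_meta <- function(locus_meta, ids, n_loci) {
  if (is.null(locus_meta)) {
    locus_meta <- data.frame(
      locus_id = if (!is.null(ids)) ids else sprintf("L%04d", seq_len(n_loci)))
  }
  locus_meta <- as.data.frame(locus_meta, stringsAsFactors = FALSE)
  if (nrow(locus_meta) != n_loci)
    stop("locus_meta must have one row per locus")
  for (cc in .locus_meta_cols)
    if (is.null(locus_meta[[cc]])) locus_meta[[cc]] <- NA
  locus_meta$locus_id <- as.character(locus_meta$locus_id)
  ok <- !is.na(locus_meta$reproducibility)
  if (any(locus_meta$reproducibility[ok] < 0 | locus_meta$reproducibility[ok] > 1))
    stop("reproducibility must lie in [0, 1]")
  ok <- !is.na(locus_meta$pos)
  if (any(locus_meta$pos[ok] <= 0)) stop("pos must be positive when present")
  rownames(locus_meta) <- NULL
  locus_meta[, .locus_meta_cols]
}

.complete_sample_meta <- function(sample_meta, sample_ids) {
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = sample_ids)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (nrow(sample_meta) != length(sample_ids))
    stop("sample_meta must have one row per sample")
  sample_meta$sample_id <- sample_ids
  for (cc in .sample_meta_cols)
    if (is.null(sample_meta[[cc]])) sample_meta[[cc]] <- NA
  if (all(is.na(sample_meta$ancestry))) sample_meta$ancestry <- "unknown"
  rownames(sample_meta) <- NULL
  sample_meta[, .sample_meta_cols]
}

#' @exportS3Method base::print
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  sites <- unique(stats::na.omit(x$sample_meta$site))
  if (length(sites)) cat("  sites:", paste(sites, collapse = ", "), "\n")
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in utils::tail(x$provenance, 5)) cat("   -", p, "\n")
  }
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_dataset <- function(x) dim(x$dosages)

.log_op <- function(ds, msg) {
  ds$provenance <- c(ds$provenance, msg)
  ds
}

#' Read genotypes from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{`vcf`}{Standard VCF; only biallelic SNP records are kept (others are
#'     skipped, with the count logged in the provenance). Dosages count the
#'     ALT allele and are re-oriented to the minor allele after loading.}
#'   \item{`dart_csv`}{One row per locus with columns `locus_id`, `tag_id`,
#'     `chrom`, `pos`, `depth`, `reproducibility`, followed by one dosage
#'     column per sample. A pragmatic single-row stand-in for DArT two-row
#'     reports; a true two-row parser is a documented extension point.}
#'   \item{`dosage_csv`}{One row per sample: `sample_id` then one column per
#'     locus holding dosages.}
#' }
#'
#' @param path file path.
#' @param format one of `"vcf"`, `"dart_csv"`, `"dosage_csv"`.
#' @param orient_minor logical; re-code dosages to count the minor allele
#'   (computed on the full dataset at load time). Default `TRUE`.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("dosage_csv", "dart_csv", "vcf"),
                           orient_minor = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ds <- switch(format,
               vcf = .read_vcf(path),
               dart_csv = .read_dart_csv(path),
               dosage_csv = .read_dosage_csv(path))
  if (orient_minor) ds <- .orient_minor(ds)
  .log_op(ds, sprintf("read_genotypes(%s, format=%s)", basename(path), format))
}

.orient_minor <- function(ds) {
  p <- colMeans(ds$dosages, na.rm = TRUE) / 2
  flip <- which(!is.na(p) & p > 0.5)
  if (length(flip))
    ds$dosages[, flip] <- 2L - ds$dosages[, flip]
  ds$provenance <- c(ds$provenance,
                     sprintf("oriented to minor allele (%d loci flipped)", length(flip)))
  ds
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  clean <- gsub("\\|", "/", gt)
  dos_t <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos_t[clean == "0/0"] <- 0L
  dos_t[clean %in% c("0/1", "1/0")] <- 1L
  dos_t[clean == "1/1"] <- 2L
  dos <- t(dos_t)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  lm <- data.frame(locus_id = ids, tag_id = ids,
                   chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  rownames(dos) <- colnames(gt)
  ds <- genotype_dataset(dos, colnames(gt), locus_meta = lm)
  .log_op(ds, sprintf("vcf: %d biallelic SNPs kept, %d non-biallelic records skipped",
                      sum(biallelic), n_skipped))
}

.read_dart_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("locus_id", "tag_id", "chrom", "pos", "depth", "reproducibility")
  if (!all(need %in% names(tab)))
    stop("malformed dart_csv (line 1): header must start with ",
         paste(need, collapse = ", "))
  samp <- setdiff(names(tab), need)
  if (!length(samp)) stop("malformed dart_csv: no sample columns")
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  storage.mode(dos) <- "integer"
  lm <- data.frame(locus_id = as.character(tab$locus_id),
                   tag_id = as.character(tab$tag_id),
                   chrom = as.character(tab$chrom),
                   pos = suppressWarnings(as.integer(tab$pos)),
                   mean_depth = as.numeric(tab$depth),
                   reproducibility = as.numeric(tab$reproducibility))
  genotype_dataset(dos, samp, locus_meta = lm)
}

.read_dosage_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("malformed dosage_csv (line 1): first column must be sample_id")
  dos <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- tab$sample_id
  genotype_dataset(dos, tab$sample_id,
                   locus_meta = data.frame(locus_id = colnames(dos)))
}

#' Write genotypes to CSV
#'
#' @param ds a [genotype_dataset()].
#' @param path output file path.
#' @param format `"dosage_csv"` or `"dart_csv"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, format = c("dosage_csv", "dart_csv")) {
  format <- match.arg(format)
  if (format == "dosage_csv") {
    tab <- data.frame(sample_id = ds$sample_ids, check.names = FALSE)
    tab <- cbind(tab, as.data.frame(ds$dosages, check.names = FALSE))
  } else {
    lm <- ds$locus_meta
    tab <- data.frame(locus_id = lm$locus_id, tag_id = lm$tag_id,
                      chrom = lm$chrom, pos = lm$pos, depth = lm$mean_depth,
                      reproducibility = lm$reproducibility, check.names = FALSE)
    tab <- cbind(tab, as.data.frame(t(ds$dosages), check.names = FALSE))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Attach sample metadata
#'
#' Joins a metadata table onto the dataset by `sample_id`. Every sample in the
#' dataset must appear exactly once in the table; table rows for unknown
#' samples are dropped (logged).
#'
#' @param ds a [genotype_dataset()].
#' @param table data.frame with a `sample_id` column plus any of the
#'   recognised sample-metadata columns (`site`, `river_km`, `capture_year`,
#'   `capture_date`, `total_length_mm`, `ancestry`, `cohort`, `age_class`).
#' @return The dataset with `sample_meta` populated.
#' @export
attach_metadata <- function(ds, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$sample_id)) stop("metadata table needs a sample_id column")
  dup <- unique(table$sample_id[duplicated(table$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in metadata table: ", paste(dup, collapse = ", "))
  missing <- setdiff(ds$sample_ids, table$sample_id)
  if (length(missing))
    stop("sample ids absent from metadata table: ", paste(missing, collapse = ", "))
  extra <- setdiff(table$sample_id, ds$sample_ids)
  idx <- match(ds$sample_ids, table$sample_id)
  sm <- ds$sample_meta
  for (cc in intersect(names(table), setdiff(.sample_meta_cols, "sample_id")))
    sm[[cc]] <- table[[cc]][idx]
  ds$sample_meta <- sm
  .log_op(ds, sprintf("attach_metadata: %d matched, %d unmatched table rows dropped",
                      length(ds$sample_ids), length(extra)))
}

#' Subset a genotype dataset
#'
#' @param ds a [genotype_dataset()].
#' @param samples sample selector: logical/integer vector over rows, character
#'   vector of sample ids, or a function of `sample_meta` returning a logical
#'   vector. `NULL` keeps all samples.
#' @param loci locus selector: logical/integer vector over columns, character
#'   vector of locus ids, or a function of `locus_meta`. `NULL` keeps all.
#' @return The subsetted dataset (provenance appended).
#' @export
subset_genotypes <- function(ds, samples = NULL, loci = NULL) {
  ri <- .resolve_selector(samples, ds$sample_ids, ds$sample_meta, "sample")
  ci <- .resolve_selector(loci, ds$locus_meta$locus_id, ds$locus_meta, "locus")
  ds$dosages <- ds$dosages[ri, ci, drop = FALSE]
  ds$sample_ids <- ds$sample_ids[ri]
  ds$sample_meta <- ds$sample_meta[ri, , drop = FALSE]
  rownames(ds$sample_meta) <- NULL
  ds$locus_meta <- ds$locus_meta[ci, , drop = FALSE]
  rownames(ds$locus_meta) <- NULL
  .log_op(ds, sprintf("subset: %d samples x %d loci", length(ri), length(ci)))
}

.resolve_selector <- function(sel, ids, meta, what) {
  n <- length(ids)
  if (is.null(sel)) return(seq_len(n))
  if (is.function(sel)) sel <- sel(meta)
  if (is.logical(sel)) {
    if (length(sel) != n) stop(what, " logical selector has wrong length")
    idx <- which(sel)
  } else if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop("unknown ", what, " ids: ",
                         paste(sel[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(sel)
    if (any(idx < 1 | idx > n)) stop(what, " index out of range")
  }
  if (!length(idx)) stop("empty ", what, " selection")
  idx
}

#' Write sample metadata CSV
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(ds, path) {
  utils::write.csv(ds$sample_meta, path, row.names = FALSE, na = "")
  invisible(path)
}
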