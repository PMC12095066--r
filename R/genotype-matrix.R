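#' Construct a genotype matrix
#'
#' Bundles biallelic SNP dosages (counts of the alternate allele, coded
#' 0/1/2) with line and marker identifiers and per-marker minor allele
#' frequencies. Dosages are stored uncentered; marker-effect models centre
#' them internally.
#'
#' @param dosages integer matrix, lines in rows, markers in columns, values
#'   in \{0, 1, 2\}; no missing values.
#' @param line_ids,marker_ids character vectors naming rows and columns.
#'   Default to the dimnames of `dosages`.
#' @return An object of class `genotype_matrix` with fields `line_ids`,
#'   `marker_ids`, `dosages` and `maf`.
#' @export
genotype_matrix <- function(dosages,
                            line_ids = rownames(dosages),
                            marker_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(dosages)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (nrow(dosages) < 2) abort("need at least 2 lines")
  if (anyDuplicated(marker_ids)) abort("marker ids must be unique")
  if (anyDuplicated(line_ids)) abort("line ids must be unique")
  if (anyNA(dosages)) {
    idx <- which(is.na(dosages), arr.ind = TRUE)[1, ]
    abort(sprintf("missing genotype call for line '%s' at marker '%s'",
                  line_ids[idx[1]], marker_ids[idx[2]]))
  }
  bad <- which(!(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(dosages))
    abort(sprintf(
      "dosage for line '%s' at marker '%s' is %s; expected 0, 1 or 2",
      line_ids[idx[1]], marker_ids[idx[2]], format(dosages[bad[1]])))
  }
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(line_ids, marker_ids)
  structure(
    list(line_ids = line_ids, marker_ids = marker_ids,
         dosages = dosages, maf = compute_maf(dosages)),
    class = "genotype_matrix")
}

compute_maf <- function(dosages) {
  p <- colMeans(dosages) / 2
  maf <- pmin(p, 1 - p)
  names(maf) <- colnames(dosages)
  maf
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d lines x %d markers; maf range [%.3f, %.3f]\n",
              length(x$line_ids), length(x$marker_ids),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-marker summary of a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param ... unused.
#' @return A tibble with one row per marker: `marker`, `maf`, `mean_dosage`.
#' @method tidy genotype_matrix
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(marker = x$marker_ids,
         maf = unname(x$maf),
         mean_dosage = unname(colMeans(x$dosages)))
}

#' Read a genotype matrix from disk
#'
#' Supports a delimited dosage table (first column line ids, remaining
#' columns one marker each, values 0/1/2) or a VCF of biallelic SNPs.
#' Multi-allelic VCF records are skipped with a message reporting the count;
#' any missing genotype call is an error (imputation is expected upstream).
#'
#' @param path path to the file.
#' @param format `"dosage_table"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("dosage_table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("cannot read genotype file '%s'", path))
  if (format == "dosage_table") read_dosage_table(path) else read_vcf_dosages(path)
}

read_dosage_table <- function(path) {
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("dosage table needs a line-id column plus markers")
  line_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  marker_ids <- colnames(tab)[-1]
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("missing genotype call for line '%s' at marker '%s'",
                  line_ids[idx[1]], marker_ids[idx[2]]))
  }
  num <- suppressWarnings(as.numeric(vals))
  nonint <- which(is.na(num) | num != round(num))
  if (length(nonint)) {
    idx <- arrayInd(nonint[1], dim(vals))
    abort(sprintf(
      "non-integer dosage '%s' for line '%s' at marker '%s'",
      vals[nonint[1]], line_ids[idx[1]], marker_ids[idx[2]]))
  }
  m <- matrix(num, nrow(vals), ncol(vals),
              dimnames = list(line_ids, marker_ids))
  genotype_matrix(m)
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    inform(sprintf("skipped %d multi-allelic VCF record(s)", n_skip))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  marker_ids <- rownames(gt)
  if (is.null(marker_ids) || anyNA(marker_ids)) {
    fix <- vcfR::getFIX(v)
    marker_ids <- paste(fix[, "CHROM"], fix[, "POS"], sep = "_")
  }
  line_ids <- colnames(gt)
  if (anyNA(gt)) {
    idx <- which(is.na(gt), arr.ind = TRUE)[1, ]
    abort(sprintf("missing genotype call for line '%s' at marker '%s'",
                  line_ids[idx[2]], marker_ids[idx[1]]))
  }
  # count alternate alleles in the GT string, ignoring phasing
  dos <- vapply(seq_len(ncol(gt)), function(j) {
    alleles <- strsplit(gt[, j], "[/|]")
    vapply(alleles, function(a) sum(a == "1"), numeric(1))
  }, numeric(nrow(gt)))
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  m <- t(dos)
  dimnames(m) <- list(line_ids, marker_ids)
  genotype_matrix(m)
}

#' Remove markers below a minor-allele-frequency threshold
#'
#' @param G a [genotype_matrix()].
#' @param min_maf markers with minor allele frequency strictly below this
#'   value are dropped; must lie in `[0, 0.5)`. The conventional screen for
#'   genomic prediction panels is 0.05.
#' @return A [genotype_matrix()] with the surviving markers in their
#'   original order.
#' @export
filter_by_maf <- function(G, min_maf = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (min_maf < 0 || min_maf >= 0.5) abort("min_maf must lie in [0, 0.5)")
  keep <- G$maf >= min_maf
  if (!any(keep)) {
    abort(sprintf(
      "all %d markers have maf < %g; lower the threshold",
      length(G$maf), min_maf))
  }
  genotype_matrix(G$dosages[, keep, drop = FALSE])
}
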