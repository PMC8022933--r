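#' Quality-control thresholds for SNP genotype filtering
#'
#' Per-call and per-SNP filtering thresholds applied when deriving genotypes
#' from a VCF and when filtering a genotype matrix. Defaults follow common
#' practice for reduced-representation sequencing of an outbred F1 family:
#' each allele of a heterozygous call needs at least 3 supporting reads, a
#' homozygous call at least 5, calls need genotype quality (Phred) of at
#' least 30, SNPs with more than 5\% missing calls are removed, and SNPs
#' whose offspring counts deviate from the Mendelian segregation ratio at
#' the 0.01 level are removed.
#'
#' @param min_het_allele_depth Minimum reads supporting each allele of a
#'   heterozygous call.
#' @param min_hom_depth Minimum reads supporting a homozygous call.
#' @param min_genotype_quality Minimum Phred-scaled genotype quality.
#' @param max_missing_rate Maximum tolerated fraction of missing calls per
#'   SNP (strictly greater is removed); denominator is the clone count.
#' @param seg_test_alpha Significance level of the segregation chi-square
#'   test; SNPs are kept only when p is strictly greater.
#' @return A list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(min_het_allele_depth = 3L,
                          min_hom_depth = 5L,
                          min_genotype_quality = 30,
                          max_missing_rate = 0.05,
                          seg_test_alpha = 0.01) {
  stopifnot(min_het_allele_depth >= 0, min_hom_depth >= 0,
            min_genotype_quality >= 0,
            max_missing_rate >= 0, max_missing_rate <= 1,
            seg_test_alpha > 0, seg_test_alpha < 1)
  structure(list(min_het_allele_depth = as.integer(min_het_allele_depth),
                 min_hom_depth = as.integer(min_hom_depth),
                 min_genotype_quality = min_genotype_quality,
                 max_missing_rate = max_missing_rate,
                 seg_test_alpha = seg_test_alpha),
            class = "qc_thresholds")
}

#' Pearson chi-square test of a Mendelian segregation ratio
#'
#' Tests observed offspring genotype-class counts against the expected
#' Mendelian ratio of a cross type (1:1, 1:2:1 or 1:1:1:1). The plain
#' Pearson statistic is used without continuity correction; classes with
#' expected count below 1 are flagged (attribute \code{low_expected}) but
#' the statistic is still reported.
#'
#' @param counts Named vector of genotype-class counts, restricted to the
#'   cross's expected classes (absent classes count 0).
#' @param cross A \code{cross_type} (from \code{\link{infer_cross_type}})
#'   or a cross type code string.
#' @return A list with \code{chi2}, \code{df} and \code{p} (upper tail of
#'   the chi-square distribution).
#' @examples
#' segregation_chi2(c(aa = 86, ab = 86), "aaxab")  # perfect 1:1 fit
#' segregation_chi2(c(aa = 70, ab = 30), "aaxab")  # chi2 = 16
#' @export
segregation_chi2 <- function(counts, cross) {
  if (is.character(cross)) {
    cls <- cross_classes(cross)
    rat <- cross_ratio(cross)
  } else {
    stopifnot(inherits(cross, "cross_type"), isTRUE(cross$segregating))
    cls <- cross$classes
    rat <- cross$ratio
  }
  if (is.null(names(counts)))
    stop("counts must be named by genotype class")
  extra <- setdiff(names(counts)[counts > 0], cls)
  if (length(extra))
    stop("nonzero count for class outside the expected set: ",
         paste(extra, collapse = ", "))
  obs <- stats::setNames(numeric(length(cls)), cls)
  obs[names(counts)[names(counts) %in% cls]] <-
    counts[names(counts) %in% cls]
  total <- sum(obs)
  if (total < 1) stop("total count must be at least 1")
  expd <- total * rat / sum(rat)
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(cls) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  out <- list(chi2 = chi2, df = df, p = p)
  if (any(expd < 1)) attr(out, "low_expected") <- TRUE
  out
}

#' Filter SNPs on missingness and Mendelian segregation
#'
#' Applies the per-SNP stage of genotype quality control: a SNP is removed
#' when its missing-call fraction (over all clones) strictly exceeds
#' \code{max_missing_rate}, and otherwise removed when the segregation
#' chi-square p-value is not strictly greater than \code{seg_test_alpha}.
#' Locus order is preserved and the filter is idempotent.
#'
#' @param geno A \code{geno_matrix} (see \code{\link{read_genotype_table}}).
#' @param qc A \code{\link{qc_thresholds}} object.
#' @return A list with \code{geno} (the filtered matrix) and \code{report},
#'   a \code{qc_report} with counts \code{n_input}, \code{n_kept},
#'   \code{removed_by_missingness}, \code{removed_by_segregation} and the
#'   per-cross-type tally \code{kept_by_cross_type}.
#' @export
filter_snps <- function(geno, qc = qc_thresholds()) {
  stopifnot(inherits(geno, "geno_matrix"))
  n_clones <- length(geno$clones)
  n_snps <- nrow(geno$loci)
  keep <- logical(n_snps)
  miss_removed <- 0L
  seg_removed <- 0L
  for (s in seq_len(n_snps)) {
    calls <- geno$calls[, s]
    miss_rate <- sum(is.na(calls)) / n_clones
    if (miss_rate > qc$max_missing_rate) {
      miss_removed <- miss_removed + 1L
      next
    }
    tab <- table(calls[!is.na(calls)])
    res <- segregation_chi2(stats::setNames(as.numeric(tab), names(tab)),
                            geno$loci$seg_type[s])
    if (res$p > qc$seg_test_alpha) keep[s] <- TRUE
    else seg_removed <- seg_removed + 1L
  }
  kept_types <- table(factor(geno$loci$seg_type[keep],
                             levels = cross_types()$code))
  report <- structure(
    list(n_input = n_snps,
         n_kept = sum(keep),
         removed_by_missingness = miss_removed,
         removed_by_segregation = seg_removed,
         kept_by_cross_type = stats::setNames(as.integer(kept_types),
                                              names(kept_types))),
    class = "qc_report")
  list(geno = subset_geno(geno, which(keep)), report = report)
}

#' Tabulate a QC report in segregation-type layout
#'
#' @param report A \code{qc_report} from \code{\link{filter_snps}}.
#' @return A data frame with one row per cross type (segregation type,
#'   ratio, genotype classes, number kept) followed by removal counts as
#'   attributes.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  ct <- cross_types()
  out <- data.frame(
    seg_type = ct$code,
    ratio = vapply(ct$ratio, paste, "", collapse = ":"),
    classes = vapply(ct$classes, paste, "", collapse = ","),
    n = as.integer(report$kept_by_cross_type[ct$code]),
    stringsAsFactors = FALSE)
  attr(out, "removed_by_missingness") <- report$removed_by_missingness
  attr(out, "removed_by_segregation") <- report$removed_by_segregation
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality-control report\n")
  cat("  input SNPs:            ", x$n_input, "\n")
  cat("  kept:                  ", x$n_kept, "\n")
  cat("  removed (missingness): ", x$removed_by_missingness, "\n")
  cat("  removed (segregation): ", x$removed_by_segregation, "\n")
  kept <- x$kept_by_cross_type[x$kept_by_cross_type > 0]
  if (length(kept))
    cat("  kept by cross type:    ",
        paste(names(kept), kept, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
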