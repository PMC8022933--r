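# Descriptive summaries of the longitudinal phenotype and follow-up
# statistics on scan results.

#' Descriptive summary of a longitudinal phenotype table
#'
#' Per-time-point mean, standard deviation and coefficient of variation
#' (CV = 100 * SD / mean) over all trees; per-interval growth increments
#' (computed per tree between consecutive time points, trees with both
#' measurements) summarized the same way; the phenotypic correlation
#' matrix over trees (pairwise-complete); and, when a relationship matrix
#' is supplied, per-time-point heritabilities from tree-level univariate
#' REML fits.
#'
#' @param pheno A \code{\link{pheno_table}} with at least two time points.
#' @param A Optional relationship matrix; enables the heritability column.
#' @param opts \code{\link{reml_opts}} for the heritability fits.
#' @return A list of class \code{pheno_summary} with elements
#'   \code{timepoint_stats}, \code{increment_stats}, \code{correlations}
#'   and \code{heritability}.
#' @export
phenotype_summary <- function(pheno, A = NULL, opts = reml_opts()) {
  stopifnot(inherits(pheno, "pheno_table"))
  tp <- attr(pheno, "timepoints")
  m <- length(tp)
  df <- as.data.frame(pheno)
  keystr <- paste(df$clone, df$block, df$tree, sep = "\r")
  trees <- unique(keystr)
  if (length(trees) < 2) stop("need at least 2 trees")
  H <- matrix(NA_real_, nrow = length(trees), ncol = m,
              dimnames = list(NULL, tp))
  H[cbind(match(keystr, trees),
          match(as.character(df$timepoint), tp))] <- df$height

  col_stats <- function(M, labels) {
    mean_ <- colMeans(M, na.rm = TRUE)
    sd_ <- apply(M, 2, stats::sd, na.rm = TRUE)
    cv <- ifelse(mean_ > 0, 100 * sd_ / mean_, NA_real_)
    data.frame(label = labels, n = colSums(!is.na(M)), mean = mean_,
               sd = sd_, cv_percent = cv, stringsAsFactors = FALSE,
               row.names = NULL)
  }
  tp_stats <- col_stats(H, tp)

  inc_stats <- NULL
  if (m >= 2) {
    inc <- H[, -1, drop = FALSE] - H[, -m, drop = FALSE]
    inc_stats <- col_stats(inc, paste(tp[-m], tp[-1], sep = "-"))
  }
  correlations <- suppressWarnings(
    stats::cor(H, use = "pairwise.complete.obs"))

  h2 <- NULL
  if (!is.null(A))
    h2 <- timepoint_heritability(pheno, A, tp, opts)

  structure(list(timepoint_stats = tp_stats,
                 increment_stats = inc_stats,
                 correlations = correlations,
                 heritability = h2),
            class = "pheno_summary")
}

#' @export
print.pheno_summary <- function(x, ...) {
  cat("Per-time-point height summary:\n")
  print(x$timepoint_stats, digits = 4)
  if (!is.null(x$increment_stats)) {
    cat("\nGrowth increments between consecutive time points:\n")
    print(x$increment_stats, digits = 4)
  }
  if (!is.null(x$heritability)) {
    cat("\nHeritability per time point:\n")
    print(round(x$heritability, 3))
  }
  invisible(x)
}

#' Kruskal-Wallis rank-sum comparison of two groups of values
#'
#' Tie-corrected Kruskal-Wallis H statistic with a chi-square (df = 1)
#' p-value, as used to compare -log10(p) values between groups of
#' significant SNPs. When every value in both groups is identical the
#' test is degenerate: H = 0 and p = 1 are returned with a
#' \code{zero_variance} flag.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @return A list with \code{H}, \code{p} and \code{zero_variance}.
#' @export
group_rank_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  if (length(unique(c(values_a, values_b))) == 1L)
    return(list(H = 0, p = 1, zero_variance = TRUE))
  k <- stats::kruskal.test(list(values_a, values_b))
  list(H = unname(k$statistic), p = k$p.value, zero_variance = FALSE)
}

#' Distances between adjacent significant SNPs within chromosomes
#'
#' Computes the physical distance between consecutive significant SNPs on
#' each chromosome (sorted internally by position); chromosomes and
#' scaffolds carrying a single significant SNP contribute no pairs.
#'
#' @param results A data frame with \code{snp_id}, \code{chrom},
#'   \code{pos} and optionally \code{significant} (when present, only
#'   significant rows are used).
#' @return A list with \code{distances} (data frame \code{chrom},
#'   \code{snp_a}, \code{snp_b}, \code{distance}), \code{min} (NA when no
#'   pair exists) and \code{min_pair} (the IDs attaining the minimum).
#' @export
adjacent_snp_distances <- function(results) {
  df <- as.data.frame(results)
  if ("significant" %in% names(df))
    df <- df[df$significant %in% TRUE, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    out[[ch]] <- data.frame(
      chrom = ch,
      snp_a = sub$snp_id[-nrow(sub)],
      snp_b = sub$snp_id[-1],
      distance = diff(sub$pos),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(list(distances = data.frame(chrom = character(0),
                                       snp_a = character(0),
                                       snp_b = character(0),
                                       distance = numeric(0)),
                min = NA_real_, min_pair = character(0)))
  distances <- do.call(rbind, out)
  rownames(distances) <- NULL
  i <- which.min(distances$distance)
  list(distances = distances, min = distances$distance[i],
       min_pair = c(distances$snp_a[i], distances$snp_b[i]))
}

#' Flag significant SNPs consistent in position with known QTL intervals
#'
#' A SNP is consistent when it lies inside a QTL interval on its
#' chromosome or within \code{max_dist} bp of the interval's nearest
#' edge.
#'
#' @param results A data frame with \code{snp_id}, \code{chrom},
#'   \code{pos} (and optionally \code{significant}; when present only
#'   significant rows are annotated).
#' @param qtls Data frame of intervals with \code{chrom}, \code{start},
#'   \code{end}, \code{label} (1-based inclusive; see
#'   \code{\link{read_qtl_intervals}}).
#' @param max_dist Maximum distance in bp from an interval edge.
#' @return A data frame \code{snp_id}, \code{consistent},
#'   \code{nearest_dist} (0 inside an interval, NA when the chromosome
#'   has no interval) and \code{nearest_label}.
#' @export
qtl_consistency <- function(results, qtls, max_dist = 5e6) {
  df <- as.data.frame(results)
  if ("significant" %in% names(df))
    df <- df[df$significant %in% TRUE, , drop = FALSE]
  out <- data.frame(snp_id = df$snp_id, consistent = FALSE,
                    nearest_dist = NA_real_,
                    nearest_label = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    q <- qtls[qtls$chrom == df$chrom[i], , drop = FALSE]
    if (!nrow(q)) next
    dist <- ifelse(df$pos[i] < q$start, q$start - df$pos[i],
                   ifelse(df$pos[i] > q$end, df$pos[i] - q$end, 0))
    j <- which.min(dist)
    out$nearest_dist[i] <- dist[j]
    out$nearest_label[i] <- q$label[j]
    out$consistent[i] <- dist[j] <= max_dist
  }
  out
}

#' Range and total of per-SNP variance explained
#'
#' @param results A data frame with an \code{r2_percent} column (usually
#'   the significant SNPs of a scan).
#' @return A list with \code{min}, \code{max} and \code{sum} of the
#'   \code{r2_percent} values.
#' @export
r2_totals <- function(results) {
  r2 <- as.data.frame(results)$r2_percent
  r2 <- r2[!is.na(r2)]
  if (!length(r2)) stop("results must contain r2_percent values")
  list(min = min(r2), max = max(r2), sum = sum(r2))
}
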