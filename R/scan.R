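# Genome-wide scan orchestration: per-SNP multivariate Wald tests with
# Bonferroni thresholding, sub-kilobase region collapsing, Manhattan-ready
# coordinates and the two-stage univariate comparison scan.

#' Scan configuration
#'
#' @param mode \code{"p3d"} (estimate variance components once under the
#'   null and reuse them for every SNP) or \code{"exact"} (re-run REML per
#'   SNP). P3D keeps large scans tractable and is the default.
#' @param alpha Genome-wide significance level for the Bonferroni
#'   correction.
#' @param collapse_window Width in bp below which neighbouring significant
#'   SNPs are collapsed to their most significant representative.
#' @param seed Integer seed fixing any randomized computation in the scan.
#' @param reml \code{\link{reml_opts}} passed to the REML fits.
#' @return A list of class \code{scan_config}.
#' @export
scan_config <- function(mode = c("p3d", "exact"), alpha = 0.01,
                        collapse_window = 1000, seed = 1L,
                        reml = reml_opts()) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, collapse_window >= 0)
  structure(list(mode = mode, alpha = alpha,
                 collapse_window = collapse_window,
                 seed = as.integer(seed), reml = reml),
            class = "scan_config")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Genome-wide significance level.
#' @param n_tests Number of tests (SNPs).
#' @return A list with the exact \code{p_thresh} = alpha / n_tests and
#'   \code{neg_log10_thresh}, plus reporting-ready values rounded to 3
#'   significant digits and 2 decimals respectively.
#' @examples
#' bonferroni_threshold(0.01, 22670)
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  p <- alpha / n_tests
  list(p_thresh = p, neg_log10_thresh = -log10(p),
       p_thresh_reported = signif(p, 3),
       neg_log10_reported = round(-log10(p), 2))
}

#' Genome-wide multivariate association scan
#'
#' Tests every SNP for association with the multivariate (longitudinal)
#' phenotype using the vectorized Wald F test. The null model (intercept
#' and blocks, no SNP) is fit once by REML; in \code{p3d} mode its
#' covariance estimates are reused for every per-SNP generalized
#' least-squares test, while \code{exact} mode re-runs REML per SNP. For
#' each SNP, clones with a missing call are dropped from that SNP's fit
#' (recorded in \code{n_used}); monomorphic SNPs are reported as
#' untestable with p = 1 rather than removed, so the output has one row
#' per input SNP. \eqn{R^2} is computed from the V-weighted residual sums
#' of squares of the nested null/full designs under the null covariance.
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param geno A QC-filtered \code{geno_matrix}.
#' @param A Relationship matrix covering the clones (e.g.
#'   \code{\link{build_fullsib_A}}).
#' @param cfg A \code{\link{scan_config}}.
#' @return A data frame of class \code{snp_scan}, one row per SNP, with
#'   columns \code{snp_id}, \code{chrom}, \code{pos}, \code{seg_type},
#'   \code{F}, \code{df1}, \code{df2}, \code{p}, \code{neg_log10_p},
#'   \code{r2_percent}, one \code{effect_} column per time point,
#'   \code{n_used} and \code{significant}; the Bonferroni threshold, mode
#'   and drop log are stored as attributes.
#' @export
scan_multivariate <- function(pheno, geno, A, cfg = scan_config()) {
  stopifnot(inherits(pheno, "pheno_table"), inherits(geno, "geno_matrix"))
  set.seed(cfg$seed)
  tp <- attr(pheno, "timepoints")
  m <- length(tp)
  common <- intersect(unique(as.data.frame(pheno)$clone), geno$clones)
  if (!length(common))
    stop("no clones shared between phenotype and genotype tables")
  df <- as.data.frame(pheno)
  pheno_sub <- new_pheno_table(df[df$clone %in% common, , drop = FALSE], tp)

  null_design <- build_design(pheno_sub)
  null_fit <- reml_fit(null_design, A, cfg$reml)
  VGn <- null_fit$VG; VEn <- null_fit$VE

  n_tests <- nrow(geno$loci)
  thr <- bonferroni_threshold(cfg$alpha, n_tests)

  # cache rotation and null-design quantities per clone subset
  cache <- new.env(parent = emptyenv())
  subset_ctx <- function(clones_incl) {
    key <- paste(clones_incl, collapse = "|")
    ctx <- cache[[key]]
    if (is.null(ctx)) {
      dfk <- df[df$clone %in% clones_incl, , drop = FALSE]
      ph <- new_pheno_table(dfk, tp)
      nd <- build_design(ph)
      A_sub <- subset_A(A, nd$clones)
      rot <- rotate_clone_space(nd$clone_index, A_sub)
      st0 <- mv_stats(nd, A, rot = rot)
      rss0 <- mv_eval(st0, VGn, VEn)$rss
      ctx <- list(rot = rot, rss0 = rss0, ph = ph)
      cache[[key]] <- ctx
    }
    ctx
  }

  eff_cols <- paste0("effect_", tp)
  n_snps <- nrow(geno$loci)
  rows <- vector("list", n_snps)
  n_untestable <- 0L
  for (s in seq_len(n_snps)) {
    calls <- geno$calls[, s]
    names(calls) <- geno$clones
    calls <- calls[names(calls) %in% common]
    base <- as.list(geno$loci[s, c("snp_id", "chrom", "pos", "seg_type")])
    res <- tryCatch({
      clones_incl <- sort(names(calls)[!is.na(calls)])
      ctx <- subset_ctx(clones_incl)
      design <- build_design(ctx$ph, calls)
      same_rot <- identical(design$clones, clones_incl)
      rot <- if (same_rot) ctx$rot else NULL
      if (cfg$mode == "p3d") {
        fit_s <- mvlmm_gls(design, A, VGn, VEn, rot = rot)
        rss1 <- fit_s$rss
      } else {
        fit_s <- reml_fit(design, A, cfg$reml)
        rss1 <- mv_eval(mv_stats(design, A, rot = rot), VGn, VEn)$rss
      }
      wf <- wald_F(fit_s, snp_wald_hypothesis(design))
      r2 <- 100 * snp_r2(ctx$rss0, rss1)
      eff <- rep(NA_real_, m)
      if (length(design$classes) == 2) eff <- unname(snp_effects(fit_s))
      c(base,
        list(F = wf$F, df1 = wf$df1, df2 = wf$df2, p = wf$p,
             neg_log10_p = -log10(wf$p), r2_percent = r2),
        stats::setNames(as.list(eff), eff_cols),
        list(n_used = design$n, significant = wf$p <= thr$p_thresh))
    }, clonescan_monomorphic = function(e) {
      n_untestable <<- n_untestable + 1L
      c(base,
        list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_, p = 1,
             neg_log10_p = 0, r2_percent = NA_real_),
        stats::setNames(as.list(rep(NA_real_, m)), eff_cols),
        list(n_used = 0L, significant = FALSE))
    })
    rows[[s]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "p_threshold") <- thr$p_thresh
  attr(out, "neg_log10_threshold") <- thr$neg_log10_thresh
  attr(out, "alpha") <- cfg$alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "mode") <- cfg$mode
  attr(out, "timepoints") <- tp
  attr(out, "log") <- list(n_clones = length(common),
                           n_trees = null_design$n,
                           n_snps = n_snps,
                           n_untestable = n_untestable)
  attr(out, "null_fit") <- null_fit
  class(out) <- c("snp_scan", "data.frame")
  out
}

#' Collapse clusters of nearby significant SNPs to one representative
#'
#' Consecutive significant SNPs on a chromosome closer than \code{window}
#' bp are chained into one cluster (single linkage); each cluster is
#' represented by its most significant member (ties broken by smaller
#' position). Non-significant results pass through untouched, so the
#' output never gains significant records.
#'
#' @param results A \code{snp_scan} data frame sorted by (chrom, pos).
#' @param window Collapse window in bp; SNPs exactly \code{window} apart
#'   are not merged (strict \code{<}).
#' @return The filtered results, with attributes preserved.
#' @export
collapse_regions <- function(results, window = 1000) {
  ord <- order(results$chrom, results$pos)
  res <- results[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  sig_idx <- which(res$significant %in% TRUE)
  if (length(sig_idx) > 1) {
    sig <- res[sig_idx, ]
    cluster <- cumsum(c(1, !(diff(sig$pos) < window &
                               sig$chrom[-1] == sig$chrom[-nrow(sig)])))
    for (cl in unique(cluster)) {
      members <- sig_idx[cluster == cl]
      if (length(members) > 1) {
        best <- members[order(res$p[members], res$pos[members])][1]
        keep[setdiff(members, best)] <- FALSE
      }
    }
  }
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("p_threshold", "neg_log10_threshold", "alpha", "n_tests",
              "mode", "timepoints"))
    attr(out, a) <- attr(results, a)
  class(out) <- class(results)
  out
}

#' Manhattan-plot-ready coordinate table
#'
#' Lays chromosomes end to end in name order with scaffolds after, and
#' assigns each SNP a cumulative genome coordinate alongside its
#' -log10(p). The significance threshold line is echoed as an attribute.
#'
#' @param results A \code{snp_scan} data frame.
#' @param threshold p-value threshold for the horizontal line; defaults
#'   to the scan's recorded threshold.
#' @return A data frame with \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{cum_pos}, \code{neg_log10_p}, \code{significant}; attribute
#'   \code{threshold_line} gives -log10 of the threshold.
#' @export
manhattan_table <- function(results, threshold = NULL) {
  if (!nrow(results)) stop("results must be non-empty")
  if (is.null(threshold)) threshold <- attr(results, "p_threshold")
  chroms <- unique(results$chrom)
  is_sca <- grepl("^scaffold", chroms, ignore.case = TRUE)
  chrom_order <- c(sort(chroms[!is_sca]), sort(chroms[is_sca]))
  sizes <- vapply(chrom_order, function(ch)
    max(results$pos[results$chrom == ch]), numeric(1))
  offsets <- stats::setNames(cumsum(c(0, sizes[-length(sizes)])),
                             chrom_order)
  ord <- order(match(results$chrom, chrom_order), results$pos)
  res <- results[ord, , drop = FALSE]
  out <- data.frame(snp_id = res$snp_id, chrom = res$chrom, pos = res$pos,
                    cum_pos = res$pos + offsets[res$chrom],
                    neg_log10_p = res$neg_log10_p,
                    significant = res$significant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(threshold))
    attr(out, "threshold_line") <- -log10(threshold)
  out
}

#' Two-stage univariate comparison scan at one time point
#'
#' Stage 1 fits ordinary least squares of height on sum-to-zero block and
#' clone effects at the chosen time point and extracts the clone BLUEs
#' (intercept plus clone effect). Stage 2 scans the c clone BLUEs with
#' the univariate mixed model (covariance
#' \eqn{\sigma_g^2 A + \sigma_e^2 I}), estimating the variance components
#' once under the null (P3D, no compression: one record per clone) — this
#' is the m = 1 special case of \code{\link{scan_multivariate}} applied
#' to the BLUE table.
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param geno A \code{geno_matrix}.
#' @param A Relationship matrix covering the clones.
#' @param timepoint Time-point label to analyze.
#' @param cfg A \code{\link{scan_config}}.
#' @return A \code{snp_scan} data frame; the stage-1 BLUEs are attached
#'   as attribute \code{blues}.
#' @export
two_stage_univariate <- function(pheno, geno, A, timepoint,
                                 cfg = scan_config()) {
  tp_all <- attr(pheno, "timepoints")
  if (!timepoint %in% tp_all)
    stop("timepoint ", timepoint, " not present in the phenotype table")
  blues <- clone_blues(pheno, timepoint)
  blue_df <- data.frame(clone = names(blues), block = "B1", tree = "t1",
                        timepoint = timepoint, height = unname(blues),
                        stringsAsFactors = FALSE)
  blue_pheno <- new_pheno_table(blue_df, timepoints = timepoint)
  out <- scan_multivariate(blue_pheno, geno, A, cfg)
  attr(out, "blues") <- blues
  out
}

#' Clone BLUEs at one time point (stage 1 of the univariate scan)
#'
#' Ordinary least squares of height on sum-to-zero block contrasts and
#' fixed sum-to-zero clone effects; the BLUE of clone j is the intercept
#' plus its clone effect. Clones with no surviving tree at the time point
#' are dropped with a warning.
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param timepoint Time-point label.
#' @return Named numeric vector of clone BLUEs.
#' @export
clone_blues <- function(pheno, timepoint) {
  df <- as.data.frame(pheno)
  sub <- df[as.character(df$timepoint) == timepoint, , drop = FALSE]
  if (!nrow(sub)) stop("no records at timepoint ", timepoint)
  all_clones <- sort(unique(df$clone))
  clones <- sort(unique(sub$clone))
  missing_cl <- setdiff(all_clones, clones)
  if (length(missing_cl))
    warning(length(missing_cl),
            " clone(s) with no tree at ", timepoint, " dropped: ",
            paste(utils::head(missing_cl, 5), collapse = ", "))
  blocks <- sort(unique(sub$block))
  b <- length(blocks)
  cc <- length(clones)
  n <- nrow(sub)
  p <- 1L + (b - 1L) + (cc - 1L)
  X <- matrix(0, n, p)
  X[, 1] <- 1
  bi <- match(sub$block, blocks)
  if (b >= 2)
    for (r in seq_len(b - 1L)) {
      X[bi == r, 1L + r] <- 1
      X[bi == b, 1L + r] <- -1
    }
  gi <- match(sub$clone, clones)
  off <- 1L + (b - 1L)
  for (s in seq_len(cc - 1L)) {
    X[gi == s, off + s] <- 1
    X[gi == cc, off + s] <- -1
  }
  coef <- qr.coef(qr(X), sub$height)
  mu <- coef[1]
  gamma <- coef[off + seq_len(cc - 1L)]
  gamma <- c(gamma, -sum(gamma))
  stats::setNames(mu + gamma, clones)
}
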