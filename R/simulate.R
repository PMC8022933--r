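# Synthetic full-sib genotypes and RCBD longitudinal phenotypes with
# exactly the statistical structure the analysis assumes: clone genetic
# values Vec(G) ~ N(0, A (x) VG) for the full-sib A (a common component
# shared by all clones plus an independent clone component, each with
# covariance 0.5*VG), independent per-tree residuals ~ N(0, VE), fixed
# block effects summing to zero per time point, and optional planted QTL
# class effects.

#' Configuration for the synthetic full-sib RCBD generator
#'
#' Defaults emulate the target study design: 172 clones in 3 blocks with
#' up to 6 cuttings per clone per block and independent survival dropout
#' tuned to an expected 1664 measured trees; 8 time points with grand
#' means rising through the growing season, coefficients of variation
#' declining from about 32\% to 22\%, heritabilities about 0.55 early
#' declining to 0.47 late, and autoregressive-decay genetic (0.98 per
#' step) and residual (0.95 per step) correlations so that adjacent
#' time-point phenotypic correlations exceed 0.94; and a cross-type
#' mixture proportional to the observed segregation-type spectrum
#' (1:1 types dominate). When \code{m} is smaller than 8 and the
#' per-time-point vectors are not supplied, the defaults are subsampled
#' at evenly spaced time points so the season's span is kept.
#'
#' @param c Number of clones.
#' @param b Number of blocks.
#' @param k Cuttings per clone per block.
#' @param survival Probability a cutting yields a measured tree.
#' @param m Number of time points.
#' @param mu Per-time-point grand means (cm), length m.
#' @param cv_percent Per-time-point coefficients of variation (\%),
#'   length m; with \code{h2} these determine the default VG/VE diagonals.
#' @param h2 Per-time-point heritabilities used for the default VG/VE
#'   split.
#' @param block_frac Block effects as fractions of \code{mu}: length-b
#'   vector summing to zero (each block's effect is
#'   \code{block_frac[i] * mu}).
#' @param VG,VE Optional explicit m x m covariance matrices; override the
#'   \code{cv_percent}/\code{h2} construction.
#' @param n_snps Number of simulated SNPs.
#' @param cross_mix Named probabilities over the six cross types; default
#'   proportional to the observed spectrum (13512 abxaa : 8968 aaxab :
#'   105 abxab : 48 abxcc : 23 aaxbc : 14 abxac).
#' @param missing_rate Per-call missingness probability.
#' @param qtl_spec List of planted QTLs, each a list with \code{snp}
#'   (locus index into the sorted genotype matrix) and \code{effects}
#'   (m x g class-effect matrix, columns named by genotype class); see
#'   \code{\link{make_qtl_spec}}.
#' @param seed Integer seed; the genotype stream uses \code{seed}, the
#'   phenotype stream \code{seed + 1}.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(c = 172L, b = 3L, k = 6L,
                       survival = 1664 / 3096,
                       m = 8L,
                       mu = NULL, cv_percent = NULL, h2 = NULL,
                       block_frac = NULL,
                       VG = NULL, VE = NULL,
                       n_snps = 2000L,
                       cross_mix = NULL,
                       missing_rate = 0.02,
                       qtl_spec = list(),
                       seed = 20170608L) {
  stopifnot(c >= 1, b >= 1, k >= 1, survival > 0, survival <= 1, m >= 1,
            n_snps >= 1, missing_rate >= 0, missing_rate < 1)
  mu_full <- c(52, 77, 103, 125, 147, 172, 196, 205)
  cv_full <- c(32, 30, 28.5, 27, 26, 24.5, 23, 22)
  h2_full <- c(0.55, 0.55, 0.54, 0.54, 0.54, 0.50, 0.47, 0.47)
  if (is.null(mu) || is.null(cv_percent) || is.null(h2)) {
    if (m > 8 && (is.null(mu) || is.null(cv_percent) || is.null(h2)))
      stop("for m > 8 supply mu, cv_percent and h2 explicitly")
    idx <- unique(round(seq(1, 8, length.out = m)))
    if (length(idx) < m) idx <- seq_len(m)
    if (is.null(mu)) mu <- mu_full[idx]
    if (is.null(cv_percent)) cv_percent <- cv_full[idx]
    if (is.null(h2)) h2 <- h2_full[idx]
  }
  stopifnot(length(mu) == m, length(cv_percent) == m, length(h2) == m,
            all(mu > 0), all(cv_percent > 0), all(h2 >= 0), all(h2 < 1))
  sigmaP <- cv_percent / 100 * mu
  ar_corr <- function(rho) rho^abs(outer(seq_len(m), seq_len(m), `-`))
  if (is.null(VG)) {
    sg <- sqrt(h2) * sigmaP
    VG <- ar_corr(0.98) * outer(sg, sg)
  }
  if (is.null(VE)) {
    se <- sqrt(1 - h2) * sigmaP
    VE <- ar_corr(0.95) * outer(se, se)
  }
  stopifnot(nrow(VG) == m, nrow(VE) == m)
  if (min(eigen(VG, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("VG must be positive semidefinite")
  if (min(eigen(VE, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("VE must be positive definite")
  if (is.null(block_frac)) {
    block_frac <- if (b == 1) 0 else {
      f <- seq(0.03, -0.03, length.out = b)
      f - mean(f)
    }
  }
  stopifnot(length(block_frac) == b, abs(sum(block_frac)) < 1e-8)
  block_effects <- outer(block_frac, mu)          # b x m, columns sum to 0
  if (is.null(cross_mix)) {
    counts <- c(aaxab = 8968, aaxbc = 23, abxaa = 13512,
                abxcc = 48, abxab = 105, abxac = 14)
    cross_mix <- counts / sum(counts)
  }
  stopifnot(setequal(names(cross_mix), cross_types()$code),
            abs(sum(cross_mix) - 1) < 1e-8)
  for (q in qtl_spec) {
    stopifnot(is.list(q), !is.null(q$snp), !is.null(q$effects),
              q$snp >= 1, q$snp <= n_snps)
  }
  structure(list(c = as.integer(c), b = as.integer(b), k = as.integer(k),
                 survival = survival, m = as.integer(m),
                 timepoints = paste0("T", seq_len(m)),
                 mu = mu, sigmaP = sigmaP, h2 = h2,
                 block_effects = block_effects,
                 VG = VG, VE = VE,
                 n_snps = as.integer(n_snps),
                 cross_mix = cross_mix[cross_types()$code],
                 missing_rate = missing_rate,
                 qtl_spec = qtl_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Study-like preset configuration
#'
#' Returns the documented default \code{\link{sim_config}} whose emergent
#' statistics approximate the target study: about 1664 trees from 172
#' clones in 3 blocks of up to 6 cuttings, declining CV, adjacent
#' phenotypic correlations above 0.94, heritabilities in 0.47-0.55, and
#' the observed segregation-type mixture. The seed is fixed so
#' regeneration is byte-identical.
#'
#' @return A \code{sim_config}.
#' @export
study_like_preset <- function() sim_config()

# multivariate normal draws via Cholesky; Sigma may be PSD
rmvn <- function(n, Sigma) {
  m <- nrow(Sigma)
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  matrix(stats::rnorm(n * m), n, m) %*% rt
}

#' Simulate F1 full-sib genotypes
#'
#' Draws each SNP's cross type from the configured mixture, then each
#' clone's genotype class independently from the Mendelian segregation
#' ratio (loci unlinked), applies per-call missingness, and assigns
#' positions uniformly along 19 synthetic chromosomes of 20 Mb.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A \code{geno_matrix} sorted by (chrom, pos).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ct <- cross_types()
  clones <- sprintf("C%03d", seq_len(cfg$c))
  codes <- sample(ct$code, cfg$n_snps, replace = TRUE,
                  prob = cfg$cross_mix[ct$code])
  calls <- matrix(NA_character_, nrow = cfg$c, ncol = cfg$n_snps)
  for (s in seq_len(cfg$n_snps)) {
    i <- match(codes[s], ct$code)
    cls <- ct$classes[[i]]
    rat <- ct$ratio[[i]]
    v <- sample(cls, cfg$c, replace = TRUE, prob = rat / sum(rat))
    if (cfg$missing_rate > 0)
      v[stats::runif(cfg$c) < cfg$missing_rate] <- NA_character_
    calls[, s] <- v
  }
  chrom_len <- 2e7
  chrom <- sprintf("Chr%02d", sample.int(19, cfg$n_snps, replace = TRUE))
  pos <- sample.int(chrom_len, cfg$n_snps, replace = TRUE)
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos[dup] <- sample.int(chrom_len, sum(dup), replace = TRUE)
    key <- paste(chrom, pos)
  }
  loci <- data.frame(snp_id = sprintf("SNP%05d", seq_len(cfg$n_snps)),
                     chrom = chrom, pos = pos, seg_type = codes,
                     stringsAsFactors = FALSE)
  new_geno_matrix(clones, loci, calls)
}

#' Planted-QTL specification with growth-proportional effects
#'
#' Builds a QTL entry for \code{\link{sim_config}}'s \code{qtl_spec}: the
#' genotype-class difference at time point t is proportional to the grand
#' mean \eqn{\mu_t} (QTL effects on height scale with tree size), with
#' overall magnitude set as a fraction of the final time point's
#' phenotypic standard deviation. Class effects are symmetric around zero
#' (for a 1:1 SNP the two classes get +/- half the difference).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param geno The simulated \code{geno_matrix} the index refers to.
#' @param snp Locus index (row of \code{geno$loci}).
#' @param size Class difference at the last time point, in units of that
#'   time point's phenotypic SD.
#' @return A list with \code{snp} and \code{effects} (m x g matrix with
#'   columns named by genotype class, rows summing to zero).
#' @export
make_qtl_spec <- function(cfg, geno, snp, size = 0.5) {
  stopifnot(snp >= 1, snp <= nrow(geno$loci))
  cls <- cross_classes(geno$loci$seg_type[snp])
  g <- length(cls)
  m <- cfg$m
  delta <- size * cfg$sigmaP[m] * cfg$mu / cfg$mu[m]
  grades <- (seq_len(g) - (g + 1) / 2) / ((g - 1) / 2)
  effects <- outer(delta / 2, grades)
  dimnames(effects) <- list(cfg$timepoints, cls)
  list(snp = as.integer(snp), effects = effects)
}

#' Simulate RCBD longitudinal phenotypes on simulated genotypes
#'
#' Composes heights as grand mean + fixed block effect + planted QTL
#' class effects + clone polygenic value + tree residual. Polygenic
#' values follow Vec(G) ~ N(0, A (x) VG) for the full-sib A via a shared
#' component u0 ~ N(0, 0.5 VG) plus independent clone components
#' u_j ~ N(0, 0.5 VG); residuals are independent N(0, VE) per tree.
#' Trees are realized per (clone, block, cutting) with the survival
#' probability. The rare tree whose sampled height vector is not all
#' positive has its residual redrawn (heights are physical lengths);
#' the stored truth decomposition reproduces every height exactly.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param geno A \code{geno_matrix} from \code{\link{simulate_genotypes}}
#'   (or compatible).
#' @return A list of class \code{sim_dataset} with \code{pheno},
#'   \code{geno} and \code{truth} (mu, block_effects, VG, VE, polygenic
#'   matrix G, per-clone QTL contributions, per-tree residuals, tree
#'   metadata).
#' @export
simulate_phenotypes <- function(cfg, geno) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "geno_matrix"))
  set.seed(cfg$seed + 1L)
  clones <- geno$clones
  c_ <- length(clones)
  m <- cfg$m

  qtl_contrib <- matrix(0, c_, m)
  for (q in cfg$qtl_spec) {
    calls <- geno$calls[, q$snp]
    obs <- unique(calls[!is.na(calls)])
    if (length(obs) < 2)
      stop("QTL at locus index ", q$snp,
           " is monomorphic in the simulated genotypes")
    eff <- q$effects
    stopifnot(nrow(eff) == m)
    for (j in seq_len(c_)) {
      if (is.na(calls[j])) next
      if (!calls[j] %in% colnames(eff))
        stop("QTL effects lack a column for class ", calls[j])
      qtl_contrib[j, ] <- qtl_contrib[j, ] + eff[, calls[j]]
    }
  }

  u0 <- drop(rmvn(1, 0.5 * cfg$VG))
  Uj <- rmvn(c_, 0.5 * cfg$VG)
  G <- sweep(Uj, 2, u0, `+`)
  rownames(G) <- clones

  grid <- expand.grid(cutting = seq_len(cfg$k), block = seq_len(cfg$b),
                      clone = seq_len(c_))
  alive <- stats::runif(nrow(grid)) < cfg$survival
  grid <- grid[alive, , drop = FALSE]
  n_tree <- nrow(grid)
  if (!n_tree) stop("no surviving trees; increase survival or k")
  E <- rmvn(n_tree, cfg$VE)
  base <- matrix(cfg$mu, n_tree, m, byrow = TRUE) +
    cfg$block_effects[grid$block, , drop = FALSE] +
    qtl_contrib[grid$clone, , drop = FALSE] + G[grid$clone, , drop = FALSE]
  H <- base + E
  bad <- which(apply(H, 1, function(r) any(r <= 0)))
  for (i in bad) {
    for (try in 1:100) {
      E[i, ] <- drop(rmvn(1, cfg$VE))
      H[i, ] <- base[i, ] + E[i, ]
      if (all(H[i, ] > 0)) break
    }
    if (any(H[i, ] <= 0)) {         # pathological configuration
      E[i, ] <- pmax(H[i, ], 0.1) - base[i, ]
      H[i, ] <- base[i, ] + E[i, ]
    }
  }

  trees <- data.frame(clone = clones[grid$clone],
                      block = sprintf("B%d", grid$block),
                      tree = sprintf("K%d", grid$cutting),
                      stringsAsFactors = FALSE)
  long <- data.frame(
    clone = rep(trees$clone, times = m),
    block = rep(trees$block, times = m),
    tree = rep(trees$tree, times = m),
    timepoint = rep(cfg$timepoints, each = n_tree),
    height = as.vector(H),
    stringsAsFactors = FALSE)
  pheno <- pheno_table(long, timepoints = cfg$timepoints)

  truth <- list(mu = cfg$mu,
                block_effects = cfg$block_effects,
                VG = cfg$VG, VE = cfg$VE,
                G = G, qtl_contrib = qtl_contrib,
                qtl_spec = cfg$qtl_spec,
                residuals = E, trees = trees)
  structure(list(pheno = pheno, geno = geno, truth = truth),
            class = "sim_dataset")
}

#' Simulate a complete dataset (genotypes then phenotypes)
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A \code{sim_dataset}; see \code{\link{simulate_phenotypes}}.
#' @export
simulate_dataset <- function(cfg = study_like_preset()) {
  geno <- simulate_genotypes(cfg)
  simulate_phenotypes(cfg, geno)
}

#' Render simulated genotypes as a VCF for testing the VCF path
#'
#' Writes a minimal VCF 4.2 file with the two parents (genotypes implied
#' by each SNP's cross type; the female is sample \code{parent_ids[1]})
#' followed by the clones. Canonical allele letters a/b/c map to REF A
#' and ALTs C,G. Per-genotype fields GT:AD:DP:GQ are filled with depths
#' and qualities that pass the default \code{\link{qc_thresholds}}, so
#' reading the file back recovers the simulated classes exactly.
#'
#' @param geno A \code{geno_matrix}.
#' @param path Output path.
#' @param parent_ids Sample IDs for the two parents.
#' @export
write_simulated_vcf <- function(geno, path, parent_ids = c("P1", "P2")) {
  stopifnot(inherits(geno, "geno_matrix"))
  ct <- cross_types()
  allele_nt <- c(a = "A", b = "C", c = "G")
  allele_ix <- c(a = 0L, b = 1L, c = 2L)
  gt_of <- function(cls) {
    ix <- sort(allele_ix[strsplit(cls, "")[[1]]])
    paste(ix, collapse = "/")
  }
  samp_field <- function(cls, n_alt) {
    if (is.na(cls)) return("./.")
    ix <- allele_ix[strsplit(cls, "")[[1]]] + 1L
    ad <- rep(0L, n_alt + 1L)
    if (ix[1] == ix[2]) ad[ix[1]] <- 12L else ad[ix] <- c(8L, 7L)
    paste0(gt_of(cls), ":", paste(ad, collapse = ","), ":",
           sum(ad), ":99")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", parent_ids, geno$clones),
          collapse = "\t")), con)
  for (s in seq_len(nrow(geno$loci))) {
    code <- geno$loci$seg_type[s]
    i <- match(code, ct$code)
    letters_used <- sort(unique(strsplit(
      paste0(ct$female[i], ct$male[i]), "")[[1]]))
    n_alt <- max(allele_ix[letters_used])
    alt <- if (n_alt == 0) "." else
      paste(allele_nt[match(seq_len(n_alt), allele_ix)], collapse = ",")
    fields <- c(geno$loci$chrom[s], geno$loci$pos[s], geno$loci$snp_id[s],
                "A", alt, ".", "PASS", ".", "GT:AD:DP:GQ",
                samp_field(ct$female[i], n_alt),
                samp_field(ct$male[i], n_alt),
                vapply(geno$calls[, s], samp_field, "", n_alt = n_alt))
    writeLines(paste(fields, collapse = "\t"), con)
  }
}

#' Write the ground truth of a simulated dataset to tab-separated text
#'
#' @param sim A \code{sim_dataset}.
#' @param dir Output directory (created if needed); writes
#'   \code{phenotypes.tsv}, \code{genotypes.tsv}, \code{truth_G.tsv} and
#'   \code{genotypes.vcf}.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phenotype_table(sim$pheno, file.path(dir, "phenotypes.tsv"))
  write_genotype_table(sim$geno, file.path(dir, "genotypes.tsv"))
  G <- as.data.frame(sim$truth$G)
  names(G) <- paste0("G_", seq_len(ncol(G)))
  G <- cbind(clone = rownames(sim$truth$G), G)
  con <- file(file.path(dir, "truth_G.tsv"), "w")
  writeLines(paste0("#fields=", paste(names(G), collapse = "\t")), con)
  utils::write.table(G, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_simulated_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}
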