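test_that("Bonferroni threshold reporting matches the stated precision", {
  thr <- bonferroni_threshold(0.01, 22670)
  expect_equal(thr$p_thresh_reported, 4.41e-7)
  expect_equal(thr$neg_log10_reported, 6.36)
  expect_equal(bonferroni_threshold(0.05, 1)$p_thresh, 0.05)
  expect_equal(bonferroni_threshold(0.05, 1)$neg_log10_reported, 1.30)
  thr3 <- bonferroni_threshold(0.01, 100)
  expect_equal(thr3$p_thresh, 1e-4)
  expect_equal(thr3$neg_log10_reported, 4.00)
})

test_that("scan output is complete, deterministic and order-invariant", {
  cfg <- sim_config(c = 30, b = 2, k = 2, survival = 1, m = 2,
                    n_snps = 15, missing_rate = 0.05, seed = 42)
  sim <- simulate_dataset(cfg)
  A <- build_fullsib_A(sim$geno$clones)
  res1 <- scan_multivariate(sim$pheno, sim$geno, A, scan_config(seed = 3))
  expect_s3_class(res1, "snp_scan")
  expect_equal(nrow(res1), 15)
  expect_equal(res1$neg_log10_p, -log10(res1$p), tolerance = 1e-9)
  expect_true(all(res1$r2_percent >= 0 & res1$r2_percent <= 100,
                  na.rm = TRUE))
  # byte-identical re-run
  res2 <- scan_multivariate(sim$pheno, sim$geno, A, scan_config(seed = 3))
  f1 <- tempfile(); f2 <- tempfile()
  write_scan_results(res1, f1)
  write_scan_results(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # SNP input order does not change per-SNP results
  perm <- sample(15)
  geno_perm <- clonescan:::subset_geno(sim$geno, perm)
  res3 <- scan_multivariate(sim$pheno, geno_perm, A,
                            scan_config(seed = 3))
  res3 <- res3[match(res1$snp_id, res3$snp_id), ]
  expect_equal(res3$p, res1$p, tolerance = 1e-12)
})

test_that("monomorphic SNPs are reported untestable with p = 1", {
  cfg <- sim_config(c = 20, b = 2, k = 2, survival = 1, m = 2,
                    n_snps = 5, missing_rate = 0, seed = 10)
  sim <- simulate_dataset(cfg)
  sim$geno$calls[, 3] <- "aa"     # force monomorphism
  A <- build_fullsib_A(sim$geno$clones)
  res <- scan_multivariate(sim$pheno, sim$geno, A, scan_config(seed = 1))
  expect_equal(nrow(res), 5)
  expect_equal(res$p[3], 1)
  expect_true(is.na(res$F[3]))
  expect_false(res$significant[3])
  expect_equal(attr(res, "log")$n_untestable, 1)
})

test_that("region collapsing chains gaps under the window and keeps min p", {
  mk <- function(pos, p, chrom = "Chr01") {
    data.frame(snp_id = paste0("S", seq_along(pos)), chrom = chrom,
               pos = pos, seg_type = "aaxab", F = 1, df1 = 1, df2 = 10,
               p = p, neg_log10_p = -log10(p), r2_percent = 1,
               n_used = 10, significant = p < 1e-6,
               stringsAsFactors = FALSE)
  }
  # chaining: 100 and 900 merge (gap 800), 2100 is separate (gap 1200)
  res <- mk(c(100, 900, 2100), c(1e-8, 1e-9, 1e-10))
  out <- collapse_regions(res, window = 1000)
  expect_equal(out$pos, c(900, 2100))
  # single significant SNP passes through unchanged
  one <- mk(500, 1e-8)
  expect_equal(collapse_regions(one, 1000)$pos, 500)
  # exactly window apart: not merged (strict <)
  res2 <- mk(c(1000, 2000), c(1e-8, 1e-9))
  expect_equal(nrow(collapse_regions(res2, 1000)), 2)
  # non-significant rows are never altered and never removed
  res3 <- mk(c(100, 900, 950), c(1e-8, 0.5, 1e-9))
  out3 <- collapse_regions(res3, 1000)
  expect_true("S2" %in% out3$snp_id)
  expect_equal(sum(out3$significant), 1)
  # ties broken by smaller position
  res4 <- mk(c(100, 600), c(1e-9, 1e-9))
  expect_equal(collapse_regions(res4, 1000)$pos, 100)
})

test_that("Manhattan coordinates lay chromosomes end to end, scaffolds last", {
  res <- data.frame(
    snp_id = paste0("S", 1:5),
    chrom = c("Chr02", "Chr01", "Chr01", "scaffold_45", "Chr02"),
    pos = c(50, 100, 400, 10, 300),
    neg_log10_p = 1:5, significant = FALSE,
    stringsAsFactors = FALSE)
  tab <- manhattan_table(res, threshold = 4.41e-7)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$chrom, c("Chr01", "Chr01", "Chr02", "Chr02",
                            "scaffold_45"))
  # Chr02 offset by Chr01's max position; scaffold after both
  expect_equal(tab$cum_pos, c(100, 400, 450, 700, 710))
  expect_equal(attr(tab, "threshold_line"), -log10(4.41e-7),
               tolerance = 1e-12)
})

test_that("p3d and exact scans agree on a small panel", {
  cfg <- sim_config(c = 50, b = 2, k = 2, survival = 1, m = 2,
                    n_snps = 20, missing_rate = 0.05, seed = 33)
  sim <- simulate_dataset(cfg)
  A <- build_fullsib_A(sim$geno$clones)
  r1 <- scan_multivariate(sim$pheno, sim$geno, A,
                          scan_config(mode = "p3d", seed = 1))
  r2 <- scan_multivariate(sim$pheno, sim$geno, A,
                          scan_config(mode = "exact", seed = 1))
  expect_gt(stats::cor(r1$p, r2$p, method = "spearman"), 0.99)
})

test_that("stage-1 clone BLUEs equal clone means in a balanced no-block toy", {
  ph <- make_toy_pheno(cc = 5, b = 1, k = 3, m = 1, seed = 2)
  blues <- clone_blues(ph, "T1")
  df <- as.data.frame(ph)
  means <- tapply(df$height, df$clone, mean)
  expect_equal(unname(blues[names(means)]), as.numeric(means),
               tolerance = 1e-10)
})

test_that("two-stage univariate scan equals the m = 1 scan on the BLUE table", {
  cfg <- sim_config(c = 30, b = 3, k = 2, survival = 0.9, m = 2,
                    n_snps = 8, missing_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  A <- build_fullsib_A(sim$geno$clones)
  uni <- two_stage_univariate(sim$pheno, sim$geno, A, "T1",
                              scan_config(seed = 1))
  blues <- attr(uni, "blues")
  blue_ph <- pheno_table(
    data.frame(clone = names(blues), block = "B1", tree = "t1",
               timepoint = "T1", height = unname(blues),
               stringsAsFactors = FALSE), "T1")
  direct <- scan_multivariate(blue_ph, sim$geno, A, scan_config(seed = 1))
  expect_equal(uni$p, direct$p, tolerance = 1e-12)
  expect_equal(uni$df2, direct$df2)
  # a clone absent at the time point is dropped with a warning
  df <- as.data.frame(sim$pheno)
  drop_cl <- sim$geno$clones[1]
  df <- df[!(df$clone == drop_cl & df$timepoint == "T1"), ]
  ph2 <- pheno_table(df, attr(sim$pheno, "timepoints"))
  expect_warning(clone_blues(ph2, "T1"), "dropped")
})

test_that("a strong planted QTL is the top hit among null SNPs", {
  hits <- vapply(1:5, function(rep) {
    cfg0 <- sim_config(c = 100, b = 3, k = 2, survival = 1, m = 3,
                       n_snps = 60, missing_rate = 0, seed = 500 + rep)
    geno <- simulate_genotypes(cfg0)
    qtl <- make_qtl_spec(cfg0, geno, snp = 30, size = 0.6)
    cfg <- sim_config(c = 100, b = 3, k = 2, survival = 1, m = 3,
                      n_snps = 60, missing_rate = 0, seed = 500 + rep,
                      qtl_spec = list(qtl))
    sim <- simulate_phenotypes(cfg, geno)
    A <- build_fullsib_A(geno$clones)
    res <- scan_multivariate(sim$pheno, sim$geno, A,
                             scan_config(seed = 1))
    which.min(res$p) == 30
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
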