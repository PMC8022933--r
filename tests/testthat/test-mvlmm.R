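test_that("full-sib relationship matrix has the closed-form structure", {
  A3 <- build_fullsib_A(3)
  expect_equal(unname(A3),
               matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  expect_equal(unname(build_fullsib_A(1)), matrix(1, 1, 1))
  A <- build_fullsib_A(172)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), 0.5 + 0.5 * 172)
  expect_equal(sort(unique(round(ev, 9))), c(0.5, 86.5))
  expect_equal(sum(abs(ev - 0.5) < 1e-9), 171)
  expect_error(build_fullsib_A(0), "at least 1")
  ids <- build_fullsib_A(c("a", "b"))
  expect_equal(rownames(ids), c("a", "b"))
})

test_that("design matrices have the expected coefficient counts", {
  ph <- make_toy_pheno(cc = 6, b = 3, k = 1, m = 2)
  d0 <- build_design(ph)
  expect_equal(d0$p, 3)     # intercept + 2 block contrasts
  expect_equal(d0$coef_index$block, 2:3)
  expect_null(d0$coef_index$genotype)
  # sum-to-zero block contrasts: each contrast row sums to zero over a
  # balanced layout
  expect_equal(unname(rowSums(d0$X[-1, , drop = FALSE])), c(0, 0))

  calls2 <- make_toy_calls(paste0("C", 1:6), c("aa", "ab"))
  d2 <- build_design(ph, calls2)
  expect_equal(d2$p, 4)     # + 1 genotype contrast (g = 2)

  calls4 <- make_toy_calls(paste0("C", 1:6),
                           c("aa", "ab", "ac", "bc"))
  d4 <- build_design(ph, calls4)
  expect_equal(d4$p, 6)     # + 3 genotype contrasts (g = 4)
  expect_equal(length(d4$coef_index$genotype), 3)

  # monomorphic SNP is a typed error
  mono <- make_toy_calls(paste0("C", 1:6), "aa")
  expect_error(build_design(ph, mono), class = "clonescan_monomorphic")

  # single block: no block contrasts
  ph1 <- make_toy_pheno(cc = 4, b = 1, k = 2, m = 1)
  expect_equal(build_design(ph1)$p, 1)
})

test_that("complete-case rule drops trees missing any time point", {
  ph <- make_toy_pheno(cc = 3, b = 2, k = 1, m = 3)
  df <- as.data.frame(ph)
  df <- df[!(df$clone == "C1" & df$block == "B1" &
               df$timepoint == "T2"), ]
  ph2 <- pheno_table(df, attr(ph, "timepoints"))
  d <- build_design(ph2)
  expect_equal(d$n, 5)           # 6 trees, one incomplete
  expect_false(any(d$obs$clone == "C1" & d$obs$block == "B1"))
})

test_that("univariate REML on a balanced one-way layout matches ANOVA", {
  set.seed(3)
  cc <- 4; k <- 3
  df <- expand.grid(clone = paste0("C", 1:cc), tree = paste0("t", 1:k),
                    stringsAsFactors = FALSE)
  df$block <- "B1"; df$timepoint <- "T1"
  g <- stats::rnorm(cc, 0, 2)
  df$height <- 50 + g[match(df$clone, paste0("C", 1:cc))] +
    stats::rnorm(nrow(df), 0, 1.5)
  ph <- pheno_table(df, "T1")
  A <- diag(cc); dimnames(A) <- list(paste0("C", 1:cc), paste0("C", 1:cc))
  fit <- reml_fit(build_design(ph), A)
  av <- stats::anova(stats::lm(height ~ clone, df))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  expect_equal(fit$VE[1, 1], msw, tolerance = 1e-5)
  expect_equal(fit$VG[1, 1], (msb - msw) / k, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("pure-noise data drives the genetic covariance to zero", {
  set.seed(8)
  df <- expand.grid(clone = paste0("C", 1:40), block = c("B1", "B2"),
                    tree = paste0("t", 1:3), stringsAsFactors = FALSE)
  df$timepoint <- "T1"
  df$height <- 50 + stats::rnorm(nrow(df))
  ph <- pheno_table(df, "T1")
  fit <- reml_fit(build_design(ph), build_fullsib_A(paste0("C", 1:40)))
  expect_lt(fit$VG[1, 1], 0.05 * fit$VE[1, 1])
  expect_equal(fit$VE[1, 1], 1, tolerance = 0.2)
})

test_that("rotated implementation equals the dense-V oracle on random toys", {
  for (seed in 1:8) {
    m <- 1 + seed %% 3
    g <- if (seed %% 2 == 0) 2 else 3
    toy <- random_toy_design(seed, n_max = 15, m = m, b = 2, g = g)
    A <- build_fullsib_A(toy$clones)
    design <- build_design(toy$pheno, toy$calls)
    set.seed(1000 + seed)
    VG <- random_pd(m, 3); VE <- random_pd(m, 5)
    M <- snp_wald_hypothesis(design)
    fit <- mvlmm_gls(design, A, VG, VE)
    oracle <- dense_mvlmm(design, A, VG, VE, M = M)
    wf <- wald_F(fit, M)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(fit$B_hat, oracle$B_hat, tolerance = 1e-8)
    expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(wf$F, oracle$F, tolerance = 1e-8)
    expect_equal(wf$p, oracle$p, tolerance = 1e-8)
    expect_equal(wf$df2, oracle$df2)
  }
})

test_that("REML optimum beats random covariance probes (m = 2 toy)", {
  toy <- random_toy_design(21, n_max = 12, m = 2, b = 2, g = 2)
  A <- build_fullsib_A(toy$clones)
  design <- build_design(toy$pheno, toy$calls)
  fit <- reml_fit(design, A)
  st <- clonescan:::mv_stats(design, A)
  set.seed(99)
  probes <- replicate(100, {
    VG <- random_pd(2, stats::runif(1, 0.1, 20))
    VE <- random_pd(2, stats::runif(1, 0.1, 20))
    tryCatch(clonescan:::mv_eval(st, VG, VE)$loglik,
             error = function(e) -Inf)
  })
  expect_true(all(fit$loglik >= probes - 1e-6))
})

test_that("estimates and tests are invariant to observation order", {
  toy <- random_toy_design(31, n_max = 14, m = 2, b = 2, g = 2)
  A <- build_fullsib_A(toy$clones)
  df <- as.data.frame(toy$pheno)
  set.seed(5)
  ph_perm <- pheno_table(df[sample(nrow(df)), ],
                         attr(toy$pheno, "timepoints"))
  d1 <- build_design(toy$pheno, toy$calls)
  d2 <- build_design(ph_perm, toy$calls)
  f1 <- reml_fit(d1, A)
  f2 <- reml_fit(d2, A)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(f1$VG, f2$VG, tolerance = 1e-6)
  w1 <- wald_F(f1, snp_wald_hypothesis(d1))
  w2 <- wald_F(f2, snp_wald_hypothesis(d2))
  expect_equal(w1$F, w2$F, tolerance = 1e-8)
})

test_that("with VG = 0 and A = I the Wald F equals the classical ANOVA F", {
  set.seed(17)
  cc <- 6
  df <- expand.grid(clone = paste0("C", 1:cc), block = c("B1", "B2"),
                    tree = "t1", stringsAsFactors = FALSE)
  df$timepoint <- "T1"
  df$height <- 50 + stats::rnorm(nrow(df), 0, 2)
  ph <- pheno_table(df, "T1")
  calls <- make_toy_calls(paste0("C", 1:cc))
  A <- diag(cc); dimnames(A) <- list(paste0("C", 1:cc), paste0("C", 1:cc))
  design <- build_design(ph, calls)
  # OLS oracle: F test of the genotype factor given blocks
  df$geno <- calls[df$clone]
  full <- stats::lm(height ~ block + geno, df)
  av <- stats::anova(full)
  # with VG = 0 the REML estimate of VE is the full-model residual mean
  # square; the Wald F at that covariance is the classical ANOVA F
  sig2 <- av["Residuals", "Mean Sq"]
  fit <- mvlmm_gls(design, A, VG = matrix(0, 1, 1),
                   VE = matrix(sig2, 1, 1))
  wf <- wald_F(fit, snp_wald_hypothesis(design))
  F_ols <- av["geno", "F value"]
  expect_equal(wf$F, F_ols, tolerance = 1e-8)
  expect_equal(wf$df1, 1)
  # denominator df convention is m(n - p), matching the OLS residual df
  expect_equal(wf$df2, av["Residuals", "Df"])
  expect_equal(wf$p, av["geno", "Pr(>F)"], tolerance = 1e-8)
})

test_that("a symmetric two-clone layout gives F = 0 and p = 1 exactly", {
  # identical phenotype vectors for the aa and ab clone make the genotype
  # contrast BLUE exactly zero
  df <- expand.grid(clone = c("C1", "C2"), block = c("B1", "B2"),
                    tree = c("t1", "t2"), stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("T1", "T2"), function(tp)
    cbind(df, timepoint = tp,
          height = rep(c(30, 40), length.out = nrow(df)) +
            10 * (tp == "T2"))))
  long$height <- ave(long$height, long$block, long$tree, long$timepoint)
  ph <- pheno_table(long, c("T1", "T2"))
  calls <- c(C1 = "aa", C2 = "ab")
  A <- build_fullsib_A(c("C1", "C2"))
  design <- build_design(ph, calls)
  fit <- mvlmm_gls(design, A, VG = diag(2), VE = diag(2))
  expect_equal(max(abs(fit$B_hat[, design$coef_index$genotype])), 0)
  wf <- wald_F(fit, snp_wald_hypothesis(design))
  expect_equal(wf$F, 0)
  expect_equal(wf$p, 1)
})

test_that("hypothesis matrix has q = m(g-1) indicator rows", {
  fake_design <- function(m, p, geno_rows) {
    list(m = m, p = p, coef_index = list(genotype = geno_rows))
  }
  expect_equal(attr(snp_wald_hypothesis(fake_design(8, 4, 4L)), "q"), 8)
  expect_equal(attr(snp_wald_hypothesis(fake_design(8, 6, 4:6)), "q"), 24)
  expect_equal(attr(snp_wald_hypothesis(fake_design(1, 4, 4L)), "q"), 1)
  M <- snp_wald_hypothesis(fake_design(2, 3, 3L))
  expect_equal(dim(M), c(2, 6))
  # selects positions (j-1)m + t for the genotype coefficient
  expect_equal(which(M[1, ] == 1), 5)
  expect_equal(which(M[2, ] == 1), 6)
  expect_error(snp_wald_hypothesis(list(m = 2, p = 2,
                                        coef_index = list())),
               "genotype")
})

test_that("R-squared, SNP effects and heritability arithmetic", {
  expect_equal(snp_r2(200, 150), 0.25)
  expect_equal(snp_r2(100, 100), 0)
  expect_equal(snp_r2(100, 0), 1)
  expect_error(snp_r2(0, 0), "positive")
  expect_error(snp_r2(100, 120), "exceeds")

  fake_fit <- function(B, classes, m) {
    structure(list(B_hat = B, classes = classes,
                   coef_index = list(intercept = 1,
                                     genotype = 2:(2 + length(classes) - 2)),
                   timepoints = paste0("T", seq_len(m))),
              class = "mvlmm_fit")
  }
  # g = 2: effect is twice the contrast coefficient
  f2 <- fake_fit(cbind(c(10, 20), c(1.5, -0.5)), c("aa", "ab"), 2)
  expect_equal(unname(snp_effects(f2)), c(3, -1))
  # zero coefficients give zero effects
  f0 <- fake_fit(cbind(c(10, 20), c(0, 0)), c("aa", "ab"), 2)
  expect_equal(unname(snp_effects(f0)), c(0, 0))
  # g = 3: class-effect matrix with rows summing to zero
  f3 <- fake_fit(cbind(c(10, 20), c(1, 2), c(0.5, -1)),
                 c("aa", "ab", "bb"), 2)
  eff <- snp_effects(f3)
  expect_equal(dim(eff), c(2, 3))
  expect_equal(unname(rowSums(eff)), c(0, 0))

  expect_equal(heritability(1, 1), 0.5)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(0.55, 0.45), 0.55)
  expect_error(heritability(0, 0), "zero")

  expect_equal(genetic_correlations(diag(c(2, 3))), diag(2))
  expect_equal(genetic_correlations(matrix(c(4, 2, 2, 1), 2))[1, 2], 1)
  expect_equal(genetic_correlations(matrix(c(1, .5, .5, 1), 2))[1, 2],
               0.5)
  expect_error(genetic_correlations(matrix(c(0, 0, 0, 1), 2)),
               "time point")
})
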