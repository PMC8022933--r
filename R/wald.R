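# Hypothesis testing and per-marker summaries on a fitted model. Vec(B)
# stacks the m x p coefficient matrix column by column, so time points run
# fastest within each coefficient: coefficient j, time point t sits at
# position (j-1)*m + t. This ordering is the single source of truth for
# constructing hypothesis matrices.

#' Hypothesis matrix selecting all genotype-contrast coefficients
#'
#' Builds the full-row-rank indicator matrix M testing the null that every
#' per-time-point genotype-contrast coefficient is zero, i.e. the SNP has
#' no effect at any time point: q = m * (g - 1) rows.
#'
#' @param design An \code{mvlmm_design} containing a genotype block (or a
#'   fitted \code{mvlmm_fit} carrying the same coefficient index).
#' @return An object of class \code{hypothesis_matrix}: the q x (m*p)
#'   matrix with attribute \code{q}.
#' @export
snp_wald_hypothesis <- function(design) {
  ci <- design$coef_index
  if (is.null(ci$genotype))
    stop("design has no genotype-contrast coefficients")
  m <- design$m
  p <- if (!is.null(design$p)) design$p else nrow(design$X)
  sel <- as.vector(outer(seq_len(m), (ci$genotype - 1L) * m, `+`))
  M <- matrix(0, length(sel), m * p)
  M[cbind(seq_along(sel), sel)] <- 1
  structure(M, q = length(sel), class = c("hypothesis_matrix", "matrix"))
}

#' Vectorized Wald F test of a linear hypothesis on Vec(B)
#'
#' Evaluates the F statistic
#' \deqn{F = \frac{1}{q} (M\,\mathrm{Vec}(B))' [M W^{-1} M']^{-1}
#'   (M\,\mathrm{Vec}(B))}
#' where W is the information matrix of Vec(B) under the fitted
#' covariance, with q numerator and m(n-p) denominator degrees of
#' freedom. The rotated representation is used throughout; the mn x mn
#' covariance matrix is never formed.
#'
#' @param fit An \code{mvlmm_fit} or \code{mvlmm_gls} object.
#' @param M A full-row-rank q x (m*p) hypothesis matrix (e.g. from
#'   \code{\link{snp_wald_hypothesis}}).
#' @return A list with \code{F}, \code{df1}, \code{df2} and \code{p}.
#' @export
wald_F <- function(fit, M) {
  stopifnot(inherits(fit, "mvlmm_fit"))
  M <- as.matrix(M)
  q <- nrow(M)
  if (ncol(M) != fit$m * fit$p)
    stop("hypothesis matrix has ", ncol(M), " columns; expected ",
         fit$m * fit$p)
  if (qr(M)$rank < q) stop("hypothesis matrix is rank deficient")
  beta <- as.vector(fit$B_hat)
  Mb <- M %*% beta
  MWiM <- M %*% solve(fit$W, t(M))
  MWiM <- (MWiM + t(MWiM)) / 2
  rc <- rcond(MWiM)
  if (rc < 1e-12)
    stop("inner matrix numerically singular (rcond = ",
         format(rc, digits = 3), ")")
  Fstat <- drop(crossprod(Mb, solve(MWiM, Mb))) / q
  df2 <- fit$m * (fit$n - fit$p)
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Fraction of phenotypic variance explained by a SNP
#'
#' \eqn{R^2 = 1 - RSS_1 / RSS_0}, where both residual sums of squares are
#' V-weighted generalized-least-squares quadratic forms computed under the
#' null model's covariance estimate (so the full-model RSS can never
#' exceed the null RSS for nested designs on the same observations).
#'
#' @param rss_null Null-model residual sum of squares (positive).
#' @param rss_full Full-model residual sum of squares, at most
#'   \code{rss_null} up to numerical noise.
#' @return R-squared as a fraction in [0, 1].
#' @export
snp_r2 <- function(rss_null, rss_full) {
  if (rss_null <= 0) stop("rss_null must be positive")
  if (rss_full > rss_null * (1 + 1e-8))
    stop("rss_full exceeds rss_null; both must use the null covariance")
  max(0, min(1, 1 - rss_full / rss_null))
}

#' Per-time-point SNP effects from a fitted model
#'
#' For a two-class (1:1) SNP the effect at time point t is the difference
#' between the two genotype-class effects; under the sum-to-zero contrast
#' with a single coefficient \eqn{\beta_t} this equals \eqn{2\beta_t}. For
#' SNPs with more than two observed classes the full m x g class-effect
#' matrix is returned (rows sum to zero).
#'
#' @param fit An \code{mvlmm_fit} from a model with a genotype block.
#' @return A named numeric vector (g = 2) or an m x g matrix (g > 2).
#' @export
snp_effects <- function(fit) {
  ci <- fit$coef_index
  if (is.null(ci$genotype))
    stop("fit has no genotype-contrast coefficients")
  g <- length(fit$classes)
  Bg <- fit$B_hat[, ci$genotype, drop = FALSE]   # m x (g-1)
  if (g == 2) {
    eff <- 2 * Bg[, 1]
    names(eff) <- fit$timepoints
    return(eff)
  }
  effects <- cbind(Bg, -rowSums(Bg))
  dimnames(effects) <- list(fit$timepoints, fit$classes)
  effects
}

#' Narrow-sense heritability from univariate variance components
#'
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}, with components
#' from a univariate REML fit in which clone effects are random with the
#' full-sib relationship structure.
#'
#' @param sigma_g2 Additive genetic variance (non-negative).
#' @param sigma_e2 Residual variance (positive, unless
#'   \code{sigma_g2 > 0}).
#' @return Heritability in [0, 1].
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  if (sigma_g2 < 0 || sigma_e2 < 0)
    stop("variance components must be non-negative")
  tot <- sigma_g2 + sigma_e2
  if (tot == 0) stop("both variance components are zero")
  sigma_g2 / tot
}

#' Genetic correlation matrix from a genetic covariance matrix
#'
#' @param VG Genetic covariance matrix (or an \code{mvlmm_fit}, whose VG
#'   is used) with strictly positive diagonal.
#' @return The m x m genetic correlation matrix with unit diagonal.
#' @export
genetic_correlations <- function(VG) {
  if (inherits(VG, "mvlmm_fit")) VG <- VG$VG
  dg <- diag(VG)
  if (any(dg <= 0))
    stop("zero genetic variance at time point ", which(dg <= 0)[1])
  cr <- stats::cov2cor(VG)
  cr[cr > 1] <- 1
  cr[cr < -1] <- -1
  cr
}

#' Per-time-point heritability from tree-level univariate REML fits
#'
#' Fits the univariate model (height on blocks with random clone effects
#' under the full-sib relationship matrix) separately at each time point
#' and returns \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)}.
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param A Relationship matrix covering the phenotyped clones.
#' @param timepoints Labels to fit (default: all).
#' @param opts \code{\link{reml_opts}}.
#' @return Named numeric vector of heritabilities.
#' @export
timepoint_heritability <- function(pheno, A,
                                   timepoints = attr(pheno, "timepoints"),
                                   opts = reml_opts()) {
  df <- as.data.frame(pheno)
  vapply(timepoints, function(tp) {
    sub <- df[as.character(df$timepoint) == tp, , drop = FALSE]
    ph1 <- new_pheno_table(sub, timepoints = tp)
    fit <- reml_fit(build_design(ph1), A, opts)
    heritability(fit$VG[1, 1], fit$VE[1, 1])
  }, numeric(1))
}
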