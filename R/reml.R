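# Multivariate REML under the Kronecker covariance
#   cov(Vec(Y)) = Z'AZ (x) VG + I_n (x) VE
# The key computational device is a two-level decorrelation. First, the
# genetic covariance K = Z'AZ has rank c (one dimension per clone): its
# nonzero eigenpairs come from the c x c matrix N^{1/2} A N^{1/2} (N the
# diagonal of per-clone tree counts), and the orthogonal complement (the
# within-clone contrast space) carries pure residual covariance VE. All
# likelihood and GLS quantities therefore reduce to c rotated "clone
# space" columns plus closed-form complement totals, at O(c^3) instead of
# O(n^3). Second, for a given (VG, VE) the generalized eigendecomposition
# L^-1 VG L^-T = Q L Q' (VE = L L') whitens the traits so every rotated
# observation has diagonal covariance 1 + d_i * lambda, turning the
# multivariate GLS into m independent weighted least-squares problems.

# eigen-rotation of the clone space; A_sub already subset to the clones
rotate_clone_space <- function(clone_index, A_sub) {
  c_ <- nrow(A_sub)
  n_j <- tabulate(clone_index, nbins = c_)
  if (any(n_j == 0)) stop("every clone must have at least one observation")
  nsq <- sqrt(n_j)
  M <- A_sub * outer(nsq, nsq)
  eg <- eigen(M, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("relationship matrix is not positive definite on the clone set")
  Qs <- eg$vectors / nsq          # rows are clones
  list(d = eg$values, U1 = Qs[clone_index, , drop = FALSE], n_j = n_j)
}

# sufficient statistics for likelihood/GLS evaluation
mv_stats <- function(design, A, rot = NULL) {
  Y <- design$Y; X <- design$X
  if (qr(t(X))$rank < design$p)
    stop("design matrix is rank deficient")
  if (design$n <= design$p)
    stop("need more observations than fixed-effect coefficients")
  A_sub <- subset_A(A, design$clones)
  if (is.null(rot)) rot <- rotate_clone_space(design$clone_index, A_sub)
  X1 <- X %*% rot$U1
  Y1 <- Y %*% rot$U1
  XXt <- tcrossprod(X)
  XYt <- tcrossprod(X, Y)        # p x m
  YYt <- tcrossprod(Y)
  list(d = rot$d, X1 = X1, Y1 = Y1,
       XX0 = XXt - tcrossprod(X1), XY0 = XYt - tcrossprod(X1, Y1),
       YY0 = YYt - tcrossprod(Y1),
       XXt = XXt, XYt = XYt, YYt = YYt,
       n = design$n, p = design$p, m = design$m, c = length(rot$d),
       rot = rot)
}

# restricted log-likelihood and (optionally) GLS estimates at fixed
# (VG, VE); the workhorse behind both the optimizer and the P3D scan
mv_eval <- function(st, VG, VE, gls = FALSE) {
  m <- st$m; p <- st$p; n <- st$n; c_ <- st$c
  R <- tryCatch(chol(VE), error = function(e)
    stop("VE is not positive definite"))
  ldVE <- 2 * sum(log(diag(R)))
  L <- t(R)
  S <- forwardsolve(L, t(forwardsolve(L, VG)))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  Cmat <- t(es$vectors) %*% forwardsolve(L, diag(m))
  Yt1 <- Cmat %*% st$Y1                       # m x c
  YY0t <- Cmat %*% st$YY0 %*% t(Cmat)
  XY0t <- st$XY0 %*% t(Cmat)                  # p x m
  v <- 1 + outer(lam, st$d)                   # m x c
  logdetV <- n * ldVE + sum(log(v))
  logdetW <- -p * ldVE
  RSS <- 0
  Btil <- matrix(0, m, p)
  infos <- if (gls) vector("list", m) else NULL
  for (t_ in seq_len(m)) {
    w <- 1 / v[t_, ]
    X1w <- sweep(st$X1, 2, w, "*")
    info_t <- tcrossprod(X1w, st$X1) + st$XX0
    rhs_t <- st$X1 %*% (w * Yt1[t_, ]) + XY0t[, t_]
    ch <- tryCatch(chol(info_t), error = function(e)
      stop("rotated information matrix is numerically singular"))
    b_t <- backsolve(ch, forwardsolve(t(ch), rhs_t))
    logdetW <- logdetW + 2 * sum(log(diag(ch)))
    RSS <- RSS + sum(w * Yt1[t_, ]^2) + YY0t[t_, t_] - sum(b_t * rhs_t)
    Btil[t_, ] <- b_t
    if (gls) infos[[t_]] <- info_t
  }
  loglik <- -0.5 * (logdetV + logdetW + RSS) -
    0.5 * (n - p) * m * log(2 * pi)
  out <- list(loglik = loglik, rss = RSS)
  if (gls) {
    B_hat <- solve(Cmat, Btil)
    mp <- m * p
    Wfull <- matrix(0, mp, mp)
    for (t_ in seq_len(m)) {
      idx <- t_ + m * (seq_len(p) - 1L)
      Wfull[idx, idx] <- infos[[t_]]
    }
    IpC <- kronecker(diag(p), Cmat)
    out$W <- crossprod(IpC, Wfull %*% IpC)
    out$B_hat <- B_hat
    out$Btil <- Btil
    out$Cmat <- Cmat
    out$v <- v
  }
  out
}

# log-Cholesky packing of a symmetric PD matrix
theta_to_spd <- function(theta, m) {
  R <- matrix(0, m, m)
  R[upper.tri(R, diag = TRUE)] <- theta
  diag(R) <- exp(diag(R))
  crossprod(R)
}
spd_to_theta <- function(M) {
  R <- chol(M)
  diag(R) <- log(diag(R))
  R[upper.tri(R, diag = TRUE)]
}

#' Optimizer settings for \code{\link{reml_fit}}
#'
#' @param tol Relative restricted-log-likelihood change below which the
#'   EM stage stops.
#' @param max_iter EM iteration cap.
#' @param polish Run a BFGS polish on the log-Cholesky parametrization
#'   after EM.
#' @param ve_floor_frac Eigenvalue floor for VE, as a fraction of its mean
#'   diagonal.
#' @return A list of class \code{reml_opts}.
#' @export
reml_opts <- function(tol = 1e-8, max_iter = 500L, polish = TRUE,
                      ve_floor_frac = 1e-8) {
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 polish = polish, ve_floor_frac = ve_floor_frac),
            class = "reml_opts")
}

floor_pd <- function(M, floor_val) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, floor_val)
  eg$vectors %*% (vals * t(eg$vectors))
}

#' Fit the multivariate mixed model by REML
#'
#' Estimates the genetic and residual covariance matrices (VG, VE) of the
#' multivariate mixed model by restricted maximum likelihood, using the
#' eigen-rotated representation (the full covariance matrix of Vec(Y) is
#' never materialized), and returns the generalized-least-squares BLUE of
#' the fixed-effect coefficient matrix B at the optimum. The maximizer
#' runs EM-style covariance updates, accepting only steps that do not
#' decrease the exact restricted likelihood, followed by a BFGS polish on
#' the log-Cholesky parametrization. VG is kept positive semidefinite and
#' VE eigenvalues are floored at a small fraction of its mean diagonal.
#'
#' @param design An \code{mvlmm_design} from \code{\link{build_design}}.
#' @param A Additive relationship matrix covering the design's clones
#'   (e.g. \code{\link{build_fullsib_A}}).
#' @param opts A \code{\link{reml_opts}} list.
#' @return An object of class \code{mvlmm_fit}: \code{VG}, \code{VE},
#'   \code{B_hat} (m x p), \code{W} (the mp x mp information matrix of
#'   Vec(B)), \code{loglik}, \code{rss}, \code{converged}, \code{n_iter},
#'   plus the design dimensions and coefficient index needed by the test
#'   layer.
#' @export
reml_fit <- function(design, A, opts = reml_opts()) {
  st <- mv_stats(design, A)
  m <- st$m; n <- st$n; p <- st$p; c_ <- st$c

  # start from the OLS residual covariance split evenly
  B0 <- t(solve(st$XXt, st$XYt))
  S <- (st$YYt - B0 %*% st$XYt - t(B0 %*% st$XYt) +
          B0 %*% st$XXt %*% t(B0)) / max(n - p, 1)
  S <- (S + t(S)) / 2
  ridge <- 1e-6 * mean(diag(S)) + 1e-12
  VG <- S / 2 + ridge * diag(m)
  VE <- S / 2 + ridge * diag(m)

  ll <- mv_eval(st, VG, VE)$loglik
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(opts$max_iter)) {
    upd <- em_update(st, VG, VE)
    ve_floor <- opts$ve_floor_frac * mean(diag(upd$VE))
    VE_new <- floor_pd(upd$VE, ve_floor)
    VG_new <- floor_pd(upd$VG, 0)
    ll_new <- tryCatch(mv_eval(st, VG_new, VE_new)$loglik,
                       error = function(e) -Inf)
    n_iter <- it
    if (!is.finite(ll_new) || ll_new < ll - 1e-10) break
    rel <- abs(ll_new - ll) / (abs(ll) + 1)
    VG <- VG_new; VE <- VE_new; ll <- ll_new
    if (rel < opts$tol) { converged <- TRUE; break }
  }

  if (opts$polish) {
    ve_floor <- opts$ve_floor_frac * mean(diag(VE)) + 1e-12
    theta0 <- c(spd_to_theta(VG + 1e-10 * mean(diag(VE)) * diag(m)),
                spd_to_theta(VE))
    nt <- length(theta0) / 2
    negll <- function(theta) {
      out <- tryCatch({
        VGp <- theta_to_spd(theta[seq_len(nt)], m)
        VEp <- theta_to_spd(theta[nt + seq_len(nt)], m)
        -mv_eval(st, VGp, VEp)$loglik
      }, error = function(e) NA_real_)
      if (!is.finite(out)) 1e12 else out
    }
    op <- tryCatch(
      stats::optim(theta0, negll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && -op$value > ll) {
      VGp <- floor_pd(theta_to_spd(op$par[seq_len(nt)], m), 0)
      VEp <- floor_pd(theta_to_spd(op$par[nt + seq_len(nt)], m), ve_floor)
      llp <- tryCatch(mv_eval(st, VGp, VEp)$loglik,
                      error = function(e) -Inf)
      if (llp >= ll) {
        VG <- VGp; VE <- VEp; ll <- llp
        converged <- TRUE
      }
    }
  }

  fin <- mv_eval(st, VG, VE, gls = TRUE)
  structure(list(VG = VG, VE = VE, B_hat = fin$B_hat, W = fin$W,
                 loglik = fin$loglik, rss = fin$rss,
                 converged = converged, n_iter = n_iter,
                 n = n, p = p, m = m, c = c_,
                 coef_index = design$coef_index,
                 classes = design$classes, clones = design$clones,
                 timepoints = design$timepoints,
                 d = st$d),
            class = "mvlmm_fit")
}

# EM-style update of (VG, VE) conditional on the current GLS B-hat
em_update <- function(st, VG, VE) {
  m <- st$m; n <- st$n; c_ <- st$c
  ev <- mv_eval(st, VG, VE, gls = TRUE)
  B <- ev$B_hat
  r1 <- st$Y1 - B %*% st$X1                 # m x c, clone-space residuals
  Cmat <- ev$Cmat
  Rw <- (Cmat %*% r1) / ev$v
  SR <- crossprod(Cmat, Rw)                  # columns Sigma_j^{-1} r_j
  VG_acc <- matrix(0, m, m)
  VE_acc <- matrix(0, m, m)
  d <- st$d
  for (j in seq_len(c_)) {
    # Sigma_j^{-1} from the whitening transform
    Sji <- crossprod(Cmat * sqrt(1 / ev$v[, j]))
    u <- d[j] * VG %*% SR[, j, drop = FALSE]
    e <- VE %*% SR[, j, drop = FALSE]
    VG_acc <- VG_acc + tcrossprod(u) / d[j] + VG - d[j] * VG %*% Sji %*% VG
    VE_acc <- VE_acc + tcrossprod(e) + VE - VE %*% Sji %*% VE
  }
  BXY0 <- B %*% st$XY0
  E0 <- st$YY0 - BXY0 - t(BXY0) + B %*% st$XX0 %*% t(B)
  list(VG = (VG_acc + t(VG_acc)) / (2 * c_),
       VE = (VE_acc + t(VE_acc) + E0 + t(E0)) / (2 * n))
}

#' Generalized least squares at fixed covariance components
#'
#' Computes the BLUE of the fixed effects, the information matrix of
#' Vec(B), the restricted log-likelihood and the V-weighted residual sum
#' of squares for given (VG, VE) — the per-marker workhorse of the P3D
#' scan mode, where the null model's covariance estimates are reused for
#' every SNP.
#'
#' @inheritParams reml_fit
#' @param VG,VE Genetic and residual covariance matrices (m x m).
#' @param rot Optional precomputed clone-space rotation (internal reuse).
#' @return An object of classes \code{mvlmm_gls} and \code{mvlmm_fit}
#'   with the same fields as \code{\link{reml_fit}} (\code{converged} is
#'   \code{NA}).
#' @export
mvlmm_gls <- function(design, A, VG, VE, rot = NULL) {
  st <- mv_stats(design, A, rot = rot)
  fin <- mv_eval(st, VG, VE, gls = TRUE)
  structure(list(VG = VG, VE = VE, B_hat = fin$B_hat, W = fin$W,
                 loglik = fin$loglik, rss = fin$rss,
                 converged = NA, n_iter = 0L,
                 n = st$n, p = st$p, m = st$m, c = st$c,
                 coef_index = design$coef_index,
                 classes = design$classes, clones = design$clones,
                 timepoints = design$timepoints,
                 d = st$d),
            class = c("mvlmm_gls", "mvlmm_fit"))
}

#' @export
print.mvlmm_fit <- function(x, ...) {
  cat("Multivariate mixed-model fit: m =", x$m, ", n =", x$n,
      ", p =", x$p, ", clones =", x$c, "\n")
  cat("restricted log-likelihood:", format(x$loglik), "\n")
  if (!is.na(x$converged))
    cat("converged:", x$converged, "after", x$n_iter, "EM iterations\n")
  invisible(x)
}
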