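# Independent dense oracle: evaluates the restricted likelihood, GLS
# estimates and Wald F by literally materializing the mn x mn covariance
# V = K (x) VG + I (x) VE and inverting it, for toy problem sizes only.
# Shares no code with the package's rotated implementation.

dense_mvlmm <- function(design, A, VG, VE, M = NULL) {
  Y <- design$Y; X <- design$X
  n <- design$n; m <- design$m; p <- design$p
  Z <- matrix(0, length(design$clones), n)
  Z[cbind(design$clone_index, seq_len(n))] <- 1
  A_sub <- A[design$clones, design$clones]
  K <- t(Z) %*% A_sub %*% Z
  V <- kronecker(K, VG) + kronecker(diag(n), VE)
  Vi <- solve(V)
  Xf <- kronecker(t(X), diag(m))
  W <- t(Xf) %*% Vi %*% Xf
  beta <- solve(W, t(Xf) %*% Vi %*% as.vector(Y))
  r <- as.vector(Y) - Xf %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  loglik <- -0.5 * (as.numeric(determinant(V)$modulus) +
                      as.numeric(determinant(W)$modulus) + rss) -
    0.5 * (n - p) * m * log(2 * pi)
  out <- list(loglik = loglik, B_hat = matrix(beta, m, p), W = W,
              rss = rss)
  if (!is.null(M)) {
    q <- nrow(M)
    Mb <- M %*% beta
    Fstat <- drop(t(Mb) %*% solve(M %*% solve(W) %*% t(M)) %*% Mb) / q
    out$F <- Fstat
    out$df1 <- q
    out$df2 <- m * (n - p)
    out$p <- stats::pf(Fstat, q, out$df2, lower.tail = FALSE)
  }
  out
}

# random symmetric PD matrix with unit-scale diagonal
random_pd <- function(m, scale = 1) {
  R <- matrix(stats::rnorm(m * m), m)
  scale * (crossprod(R) / m + diag(m) * 0.5)
}

# random toy dataset with clones of unequal replication
random_toy_design <- function(seed, n_max = 15, m = 2, b = 2, g = 2) {
  set.seed(seed)
  cc <- sample(3:5, 1)
  clones <- paste0("C", seq_len(cc))
  rows <- list()
  for (cl in clones) for (bl in paste0("B", seq_len(b))) {
    for (t_ in seq_len(sample(1:2, 1)))
      rows[[length(rows) + 1]] <- data.frame(
        clone = cl, block = bl, tree = paste0("t", t_),
        stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  if (nrow(grid) > n_max) grid <- grid[seq_len(n_max), , drop = FALSE]
  tp <- paste0("T", seq_len(m))
  long <- do.call(rbind, lapply(tp, function(t_)
    data.frame(grid, timepoint = t_,
               height = 40 + stats::rnorm(nrow(grid), 0, 4),
               stringsAsFactors = FALSE)))
  ph <- pheno_table(long, tp)
  classes <- c("aa", "ab", "bb")[seq_len(g)]
  calls <- stats::setNames(rep(classes, length.out = cc), clones)
  list(pheno = ph, calls = calls, clones = clones)
}
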