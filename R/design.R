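# Fixed-effect design matrices with sum-to-zero contrasts, following the
# row-design convention: X is p x n, the response Y is m x n, and clones
# enter through a 0/1 incidence (represented by a per-observation clone
# index). Only trees with a complete vector of heights over all time
# points enter the fit.

#' Build design matrices for the multivariate mixed model
#'
#' Constructs the \eqn{p \times n} fixed-effect design X (intercept row,
#' \eqn{b-1} sum-to-zero block-contrast rows and, when a SNP is supplied,
#' \eqn{g-1} sum-to-zero genotype-contrast rows over the observed genotype
#' classes in alphabetical order) together with the \eqn{m \times n}
#' response matrix and the clone incidence. Block contrasts encode block
#' \eqn{r < b} as +1, the last block as -1; genotype contrasts are
#' analogous. Trees missing any time point are excluded (complete-case
#' rule); when a SNP is supplied, trees of clones with a missing call are
#' excluded as well.
#'
#' @param pheno A \code{\link{pheno_table}}.
#' @param snp_calls Optional named character vector mapping clone IDs to
#'   genotype classes (\code{NA} = missing); omit for the null model.
#' @return An object of class \code{mvlmm_design}: list with \code{Y}
#'   (m x n), \code{X} (p x n), \code{n}, \code{p}, \code{m},
#'   \code{clone_index} (1..c per observation), \code{clones},
#'   \code{blocks}, \code{classes} (observed genotype classes or
#'   \code{NULL}), \code{coef_index} (row ranges of X per coefficient
#'   role) and \code{obs} (per-tree metadata).
#' @export
build_design <- function(pheno, snp_calls = NULL) {
  stopifnot(inherits(pheno, "pheno_table"))
  tp <- attr(pheno, "timepoints")
  m <- length(tp)
  df <- as.data.frame(pheno)
  keystr <- paste(df$clone, df$block, df$tree, sep = "\r")
  trees <- df[!duplicated(keystr), c("clone", "block", "tree")]
  tkey <- paste(trees$clone, trees$block, trees$tree, sep = "\r")
  H <- matrix(NA_real_, nrow = nrow(trees), ncol = m)
  H[cbind(match(keystr, tkey),
          match(as.character(df$timepoint), tp))] <- df$height
  complete <- rowSums(!is.na(H)) == m
  trees <- trees[complete, , drop = FALSE]
  H <- H[complete, , drop = FALSE]

  classes <- NULL
  if (!is.null(snp_calls)) {
    if (is.null(names(snp_calls)))
      stop("snp_calls must be named by clone ID")
    calls <- snp_calls[trees$clone]
    keep <- !is.na(calls) & trees$clone %in% names(snp_calls)
    trees <- trees[keep, , drop = FALSE]
    H <- H[keep, , drop = FALSE]
    calls <- calls[keep]
    classes <- sort(unique(as.character(calls)))
    if (length(classes) < 2)
      stop(structure(class = c("clonescan_monomorphic", "error",
                               "condition"),
                     list(message = paste0(
                       "SNP is monomorphic among included clones (",
                       length(classes), " observed class)"),
                       call = sys.call(-1))))
  }
  if (!nrow(trees)) stop("no complete trees available for the fit")

  clones <- sort(unique(trees$clone))
  clone_index <- match(trees$clone, clones)
  blocks <- sort(unique(trees$block))
  b <- length(blocks)
  n <- nrow(trees)

  rows <- list(matrix(1, 1, n))
  coef_index <- list(intercept = 1L)
  p <- 1L
  if (b >= 2) {
    Xb <- matrix(0, b - 1L, n)
    bi <- match(trees$block, blocks)
    for (r in seq_len(b - 1L)) {
      Xb[r, bi == r] <- 1
      Xb[r, bi == b] <- -1
    }
    rows <- c(rows, list(Xb))
    coef_index$block <- p + seq_len(b - 1L)
    p <- p + b - 1L
  }
  if (!is.null(classes)) {
    g <- length(classes)
    Xg <- matrix(0, g - 1L, n)
    gi <- match(as.character(calls), classes)
    for (s in seq_len(g - 1L)) {
      Xg[s, gi == s] <- 1
      Xg[s, gi == g] <- -1
    }
    rows <- c(rows, list(Xg))
    coef_index$genotype <- p + seq_len(g - 1L)
    p <- p + g - 1L
  }
  X <- do.call(rbind, rows)
  structure(list(Y = t(H), X = X, n = n, p = p, m = m,
                 clone_index = clone_index, clones = clones,
                 blocks = blocks, classes = classes,
                 coef_index = coef_index, timepoints = tp,
                 obs = trees),
            class = "mvlmm_design")
}
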