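#' Additive relationship matrix for full-sib clones
#'
#' For clones drawn from a single full-sib family of unrelated, non-inbred
#' parents the expected coefficient of coancestry between any two distinct
#' clones is 0.25, so the additive genetic relationship matrix (twice the
#' kinship) has ones on the diagonal and 0.5 elsewhere:
#' \eqn{A = 0.5 I + 0.5 J}. Its eigenvalues are 0.5 with multiplicity
#' \eqn{c - 1} and \eqn{0.5 + 0.5c} with multiplicity 1, so it is always
#' positive definite.
#'
#' @param clones Either a clone count (\eqn{c \ge 1}) or a character vector
#'   of clone IDs.
#' @return A \eqn{c \times c} numeric matrix with \code{dimnames} set to
#'   the clone IDs.
#' @examples
#' build_fullsib_A(3)
#' @export
build_fullsib_A <- function(clones) {
  if (is.numeric(clones) && length(clones) == 1L) {
    if (clones < 1) stop("clone count must be at least 1")
    ids <- as.character(seq_len(clones))
  } else {
    ids <- as.character(clones)
    if (!length(ids)) stop("clone count must be at least 1")
    if (anyDuplicated(ids)) stop("clone IDs must be unique")
  }
  c_ <- length(ids)
  A <- matrix(0.5, c_, c_, dimnames = list(ids, ids))
  diag(A) <- 1
  A
}

# subset a relationship matrix to a clone set, by name when available
subset_A <- function(A, clones) {
  if (!is.null(rownames(A))) {
    idx <- match(clones, rownames(A))
    if (anyNA(idx))
      stop("clone(s) absent from relationship matrix: ",
           paste(clones[is.na(idx)], collapse = ", "))
  } else {
    if (nrow(A) != length(clones))
      stop("unnamed relationship matrix must match the clone set size")
    idx <- seq_along(clones)
  }
  A[idx, idx, drop = FALSE]
}
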