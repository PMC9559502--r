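#' Selected inverse of a sparse SPD matrix
#'
#' Computes the entries of `C^{-1}` on the sparsity pattern of the Cholesky
#' factor of `C` (which contains the pattern of `C` itself) by the
#' Takahashi/Erisman-Tinney recurrences.  This is the exact machinery behind
#' prediction error variances and the EM-REML trace terms: only the entries
#' of the inverse coefficient matrix that the formulas touch are computed,
#' never the dense inverse.
#'
#' @param C sparse symmetric positive definite matrix, or a pre-computed
#'   `CHMfactor` from [Matrix::Cholesky()] (simplicial, `LDL = FALSE`).
#' @return sparse symmetric matrix holding `C^{-1}` on the factor pattern,
#'   in the original (unpermuted) ordering.
#' @export
selected_inverse <- function(C) {
  Ch <- if (is(C, "CHMfactor")) C
        else Matrix::Cholesky(forceSymmetric(C), LDL = FALSE,
                              super = FALSE, perm = TRUE)
  e <- Matrix::expand(Ch)
  L <- e$L                                   # P C P' = L L'
  perm <- Ch@perm + 1L
  n <- nrow(L)
  dL <- L@x[L@p[-length(L@p)] + 1L]          # diagonal first in each column
  nnz_col <- diff(L@p)
  Lx <- L@x / rep.int(dL, nnz_col)           # unit-L / D form
  Pfull <- as(L + Matrix::t(L), "generalMatrix")   # full symmetric pattern
  Zx <- takahashi_selinv(L@p, L@i, Lx, dL^2, Pfull@p, Pfull@i)
  Z <- Pfull
  Z@x <- Zx
  # back to original ordering
  ip <- order(perm)
  Z <- Z[ip, ip]
  Z <- Matrix::forceSymmetric(Z, uplo = "L")
  dimnames(Z) <- dimnames(C)
  Z
}
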