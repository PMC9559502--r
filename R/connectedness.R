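#' Prediction-error covariance of the herd effects
#'
#' The variances and covariances of the estimated herd effects are read off
#' the herd rows/columns of the inverse MME coefficient matrix, scaled by
#' the residual variance: `sigma2_e (C^{-1})_{herd block}`.  Requires the
#' herd factor in the model with all levels retained (the design module's
#' convention when `include_herd` is on).
#'
#' @param sys a [assemble_mme()] system (or a solved result).
#' @return dense symmetric matrix, herd labels as dimnames.
#' @export
herd_effect_precision <- function(sys) {
  if (is(sys, "evaluation_result")) { Ch <- sys$chol; sys <- sys$sys }
  else Ch <- mme_cholesky(sys)
  idx <- sys$index_map$herd
  if (is.null(idx))
    stop("herd is not a fixed factor in this system; ",
         "rebuild the model frame with include_herd = TRUE")
  n <- nrow(sys$lhs)
  E <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(n, length(idx)))
  S <- as.matrix(Matrix::solve(Ch, E))
  cov <- sys$vc$sigma2_e * S[idx, , drop = FALSE]
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(sys$labels[idx], sys$labels[idx])
  cov
}

#' Connectedness rating matrix
#'
#' The connectedness rating between two herds is the correlation between
#' their estimated herd effects,
#' `CR(i,j) = Cov(h_i, h_j) / sqrt(Var(h_i) Var(h_j))`, computed from the
#' prediction-error covariance of the herd effects.  Ratings are reported
#' as proportions in `[-1, 1]`.
#'
#' @param cov herd-effect covariance block from [herd_effect_precision()].
#' @param dataset_tag label for the data subset that produced the matrix.
#' @return a `connectedness_matrix`: symmetric, unit diagonal.
#' @export
connectedness_rating_matrix <- function(cov, dataset_tag = "") {
  d <- diag(cov)
  if (any(d <= 0))
    stop("herd(s) with no information (zero effect variance): ",
         paste(colnames(cov)[d <= 0], collapse = ", "))
  cr <- cov / sqrt(outer(d, d))
  cr <- (cr + t(cr)) / 2
  diag(cr) <- 1
  structure(cr, class = c("connectedness_matrix", "matrix"),
            dataset_tag = dataset_tag)
}

#' @export
print.connectedness_matrix <- function(x, digits = 6, ...) {
  tag <- attr(x, "dataset_tag")
  cat("Connectedness rating", if (nzchar(tag)) paste0(" [", tag, "]"), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Connectedness report over dataset variants
#'
#' Long-format CR table over one or more datasets with below-threshold
#' flags.  The conventional minimum for across-herd genetic evaluation of
#' NBA is a rating of 0.015 (1.5%).
#'
#' @param crs a `connectedness_matrix` or list of them.
#' @param threshold flag herd pairs whose rating falls below this
#'   proportion.
#' @return data.frame `dataset_tag, herd_i, herd_j, cr, below_threshold`
#'   (both orientations of each pair).
#' @export
cr_report <- function(crs, threshold = 0.015) {
  if (is(crs, "connectedness_matrix")) crs <- list(crs)
  rows <- lapply(crs, function(cr) {
    h <- colnames(cr)
    g <- expand.grid(herd_i = h, herd_j = h, stringsAsFactors = FALSE)
    g <- g[g$herd_i != g$herd_j, ]
    g$cr <- cr[cbind(g$herd_i, g$herd_j)]
    g$dataset_tag <- attr(cr, "dataset_tag")
    g$below_threshold <- g$cr < threshold
    g[, c("dataset_tag", "herd_i", "herd_j", "cr", "below_threshold")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
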