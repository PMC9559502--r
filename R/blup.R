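#' Assemble the mixed-model equations
#'
#' Henderson's MME for the repeatability model: the coefficient matrix is
#' `W'W` augmented by `I sigma2_e/sigma2_l` on the common-litter block,
#' `I sigma2_e/sigma2_p` on the permanent-environment block and
#' `A^{-1} sigma2_e/sigma2_a` on the animal block; the right-hand side is
#' `W'y`.  A random term with zero variance is dropped from the system with
#' a warning.
#'
#' @param dm a [build_design_matrices()] result.
#' @param y response; defaults to the one in `dm`.
#' @param A_inv sparse inverse relationship matrix aligned with `dm$Za`.
#' @param vc a [variance_components()].
#' @return a `mixed_model_system`: sparse symmetric `lhs`, `rhs`,
#'   `index_map` (effect name to equation indices, including every fixed
#'   block and each random term) and the variance ratios used.
#' @export
assemble_mme <- function(dm, y = dm$y, A_inv = NULL, vc) {
  for (k in c("l", "p", "a")) {
    slot <- switch(k, l = "Zl", p = "Zp", a = "Za")
    if (!is.null(dm[[slot]]) && sigma_of(vc, k) <= 0) {
      warning("random term '", k, "' has zero variance: dropped from system")
      dm[[slot]] <- NULL
    }
  }
  if (!is.null(dm$Za) && is.null(A_inv))
    stop("A_inv required when the animal term is in the model")
  parts <- mme_parts(dm, y, A_inv)
  lhs <- parts$WtW
  ratio <- c()
  for (k in parts$terms) {
    lam <- vc$sigma2_e / sigma_of(vc, k)
    lhs <- lhs + lam * parts$pen[[k]]
    ratio[k] <- lam
  }
  index_map <- lapply(dm$column_map, identity)
  for (k in parts$terms) index_map[[switch(k, l = "litter", p = "pe",
                                           a = "animal")]] <- parts$idx[[k]]
  labels <- c(colnames(dm$X),
              if (!is.null(dm$Zl)) paste0("litter.", dm$litter_ids),
              if (!is.null(dm$Zp)) paste0("pe.", dm$sow_ids),
              if (!is.null(dm$Za)) paste0("animal.", dm$animal_ids))
  structure(list(lhs = lhs, rhs = parts$Wty, index_map = index_map,
                 variance_ratios = ratio, vc = vc, n_records = parts$n,
                 n_fixed = parts$p, labels = labels,
                 animal_ids = dm$animal_ids, sow_ids = dm$sow_ids,
                 yty = parts$yty),
            class = "mixed_model_system")
}

mme_cholesky <- function(sys) {
  tryCatch(
    Matrix::Cholesky(sys$lhs, LDL = FALSE, super = FALSE, perm = TRUE),
    error = function(e) {
      msg <- "mixed-model equations are singular (confounded fixed effects?)"
      if (nrow(sys$lhs) <= 500) {
        q <- qr(as.matrix(sys$lhs))
        if (q$rank < nrow(sys$lhs)) {
          dep <- sys$labels[sort(q$pivot[(q$rank + 1L):nrow(sys$lhs)])]
          msg <- paste0(msg, "; dependent columns: ",
                        paste(dep, collapse = ", "))
        }
      }
      stop(msg, call. = FALSE)
    })
}

#' Solve the mixed-model equations
#'
#' Direct sparse symmetric factorization (no iteration), so solutions are
#' exact and reproducible bit-wise for fixed input.  The fixed part is full
#' rank by the design module's coding; residual rank deficiency (confounded
#' factors) is an error.
#'
#' @param sys a [assemble_mme()] system.
#' @return an `evaluation_result` with `fixed_solutions` (named), `ebv`
#'   (named by animal id, piglets), litter and permanent-environment
#'   solutions, and the Cholesky factor retained for downstream
#'   prediction-error work.
#' @export
solve_mme <- function(sys) {
  Ch <- mme_cholesky(sys)
  sol <- as.numeric(Matrix::solve(Ch, sys$rhs))
  im <- sys$index_map
  fixed_idx <- sort(unlist(im[setdiff(names(im), c("litter", "pe", "animal"))]))
  res <- list(fixed_solutions = setNames(sol[fixed_idx], sys$labels[fixed_idx]),
              solutions = sol, chol = Ch, sys = sys)
  if (!is.null(im$animal))
    res$ebv <- setNames(sol[im$animal], sys$animal_ids)
  if (!is.null(im$pe))
    res$pe <- setNames(sol[im$pe], sys$sow_ids)
  if (!is.null(im$litter))
    res$litter <- sol[im$litter]
  class(res) <- "evaluation_result"
  res
}

#' Prediction error variance and reliability of EBVs
#'
#' `PEV_i = sigma2_e C^ii` over the animal block of the inverse MME
#' coefficient matrix (computed exactly by sparse selected inversion) and
#' `r2 = 1 - PEV/Var(a)`.  An animal with no records and no phenotyped
#' relatives has `PEV = sigma2_a`, hence reliability 0.
#'
#' @param res a [solve_mme()] result (or a `mixed_model_system`, solved
#'   internally).
#' @param vc variance components; defaults to the ones in the system.
#' @return `res` with `pev` and `reliability` (named by animal id) filled.
#' @export
compute_pev_reliability <- function(res, vc = NULL) {
  if (is(res, "mixed_model_system")) res <- solve_mme(res)
  sys <- res$sys
  if (is.null(vc)) vc <- sys$vc
  if (is.null(sys$index_map$animal))
    stop("no animal term in the system")
  Zinv <- selected_inverse(res$chol)
  caa <- Matrix::diag(Zinv)[sys$index_map$animal]
  pev <- vc$sigma2_e * caa
  rel <- 1 - pev / vc$sigma2_a
  if (any(rel < -1e-10 | rel > 1 + 1e-10))
    warning("reliability clipped beyond numerical tolerance")
  res$pev <- setNames(pev, sys$animal_ids)
  res$reliability <- setNames(pmin(pmax(rel, 0), 1), sys$animal_ids)
  res
}

#' Per-herd reliability summary
#'
#' N, mean, SD, min and max of EBV reliability per contemporary group
#' (herd) and overall, mirroring the layout of average-reliability tables
#' in across-herd evaluations.
#'
#' @param res an [compute_pev_reliability()] result.
#' @param groups named vector: herd label per animal id (names = ids).
#' @param animals which animals enter the averages: `"informative"` (all
#'   pedigree animals with nonzero information, the default),
#'   `"phenotyped"` (sows with records only), or `"all"`.
#' @return data.frame with one row per herd plus `ALL`.
#' @export
summarize_reliability <- function(res, groups,
                                  animals = c("informative", "phenotyped",
                                              "all")) {
  animals <- match.arg(animals)
  rel <- res$reliability
  if (is.null(rel)) stop("run compute_pev_reliability() first")
  keep <- switch(animals,
                 informative = rel > 1e-8,
                 phenotyped = names(rel) %in% as.character(res$sys$sow_ids),
                 all = rep(TRUE, length(rel)))
  rel <- rel[keep]
  grp <- as.character(groups[names(rel)])
  ok <- !is.na(grp)
  rel <- rel[ok]; grp <- grp[ok]
  one <- function(r, label) data.frame(
    herd = label, n = length(r), mean = mean(r),
    sd = if (length(r) > 1) stats::sd(r) else 0,
    min = min(r), max = max(r))
  herds <- sort(unique(grp))
  empty <- setdiff(names(table(groups)), herds)
  if (length(empty))
    warning("group(s) with no summarized animals omitted: ",
            paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(herds, function(h) one(rel[grp == h], h)))
  rbind(out, one(rel, "ALL"))
}

#' EBV report table
#'
#' @param res an evaluation result with reliabilities.
#' @param groups named herd vector per animal id.
#' @return data.frame `animal, herd, ebv, pev, reliability`.
#' @export
ebv_table <- function(res, groups) {
  ids <- names(res$ebv)
  data.frame(animal = as.integer(ids),
             herd = as.character(groups[ids]),
             ebv = unname(res$ebv),
             pev = if (is.null(res$pev)) NA_real_ else unname(res$pev),
             reliability = if (is.null(res$reliability)) NA_real_
                           else unname(res$reliability))
}
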