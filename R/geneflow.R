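#' Gene-flow decomposition of the relationship matrix
#'
#' Builds the lower-triangular gene-flow matrix `T` (t(i,j) = expected
#' fraction of animal i's genome descending through ancestor j), the
#' diagonal Mendelian-sampling variance matrix `W`, and the base-animal x
#' herd incidence `Q`.  `T W T' = A`, the numerator relationship matrix
#' (verified against the tabular A in the test suite).
#'
#' @param ped a [pedigree()] object.
#' @param F inbreeding coefficients; computed if missing.
#' @param cap dense-memory guard on pedigree size.
#' @return list with `T` (dense lower triangular, unit diagonal), `W`
#'   (numeric vector of Mendelian sampling variances) and `Q` (n x herds
#'   0/1 matrix, nonzero rows only for base animals), class
#'   `gene_flow_decomposition`.
#' @export
build_T_W <- function(ped, F = compute_inbreeding(ped), cap = 2000L) {
  n <- n_animals(ped)
  if (n > cap)
    stop("pedigree has ", n, " animals; dense T is capped at ", cap,
         " (gene_flow_contributions() works at any scale)")
  pp <- parent_positions(ped)
  T <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (pp$sire[i] > 0L) T[i, ] <- T[i, ] + 0.5 * T[pp$sire[i], ]
    if (pp$dam[i] > 0L) T[i, ] <- T[i, ] + 0.5 * T[pp$dam[i], ]
    T[i, i] <- 1
  }
  Fs <- ifelse(pp$sire > 0L, F[pmax(pp$sire, 1L)], 0)
  Fd <- ifelse(pp$dam > 0L, F[pmax(pp$dam, 1L)], 0)
  nk <- (pp$sire > 0L) + (pp$dam > 0L)
  W <- ifelse(nk == 2L, 0.5 - 0.25 * (Fs + Fd),
              ifelse(nk == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  ids <- as.character(ped$records$animal)
  dimnames(T) <- list(ids, ids)
  base <- is_base(ped)
  herds <- sort(unique(stats::na.omit(ped$records$herd[base])))
  Q <- matrix(0, n, length(herds), dimnames = list(ids, herds))
  hb <- ped$records$herd[base]
  if (any(is.na(hb))) stop("base animal(s) with no herd of origin")
  Q[cbind(which(base), match(hb, herds))] <- 1
  structure(list(T = T, W = W, Q = Q), class = "gene_flow_decomposition")
}

# per-animal origin-herd gene fractions M = T Q, computed by the pedigree
# recursion (no dense T needed).  A missing single parent is treated as a
# phantom founder of the animal's own herd so every row sums to 1.
origin_fractions <- function(ped) {
  pp <- parent_positions(ped)
  rec <- ped$records
  base <- is_base(ped)
  herds <- sort(unique(stats::na.omit(rec$herd[base])))
  if (any(base & is.na(rec$herd)))
    stop("base animal(s) with no herd of origin")
  n <- n_animals(ped)
  M <- matrix(0, n, length(herds), dimnames = list(rec$animal, herds))
  own <- match(rec$herd, herds)
  for (i in seq_len(n)) {
    if (base[i]) { M[i, own[i]] <- 1; next }
    row <- numeric(length(herds))
    for (p in c(pp$sire[i], pp$dam[i])) {
      if (p > 0L) row <- row + 0.5 * M[p, ]
      else row[own[i]] <- row[own[i]] + 0.5   # phantom parent, local founder
    }
    M[i, ] <- row
  }
  M
}

#' Gene-flow contributions between herds
#'
#' The genetic contribution of origin herd k to a group h is the average
#' fraction of group-h animals' genes that descend from herd-k base
#' animals: the group mean of the rows of `T Q`.  With phenotyped animals
#' grouped by their herd (optionally herd-year) this expresses the
#' proportion of genes in a herd that originate from other herds.
#'
#' @param x a [pedigree()] (recursion, any scale) or a
#'   [build_T_W()] decomposition (explicit `T Q` product).
#' @param groups data.frame with columns `animal` and `group` (e.g. the
#'   herd, or herd-year, of each phenotyped sow).
#' @return a `gene_flow_result`: `contribution` matrix (groups x origin
#'   herds, rows sum to 1) and the group sizes.
#' @export
gene_flow_contributions <- function(x, groups) {
  stopifnot(all(c("animal", "group") %in% names(groups)),
            nrow(groups) > 0)
  if (is(x, "gene_flow_decomposition")) {
    M <- x$T %*% x$Q
  } else {
    M <- origin_fractions(x)
  }
  rows <- match(as.character(groups$animal), rownames(M))
  if (anyNA(rows))
    stop("grouped animal(s) absent from pedigree: ",
         paste(utils::head(groups$animal[is.na(rows)], 5L), collapse = ", "))
  glab <- sort(unique(as.character(groups$group)))
  contribution <- t(vapply(glab, function(g) {
    colMeans(M[rows[groups$group == g], , drop = FALSE])
  }, numeric(ncol(M))))
  dimnames(contribution) <- list(glab, colnames(M))
  structure(list(contribution = contribution,
                 group_sizes = table(as.character(groups$group))),
            class = "gene_flow_result")
}

#' Long-format gene-flow report
#'
#' Directional herd-to-herd gene proportions for a dataset variant over a
#' year window, suitable for tabulation or plotting.
#'
#' @param res a [gene_flow_contributions()] result.
#' @param dataset_tag dataset label.
#' @param year_window label for the period covered.
#' @return data.frame `group_herd, origin_herd, proportion, dataset_tag,
#'   year_window`.
#' @export
gene_flow_report <- function(res, dataset_tag = "", year_window = "all") {
  cm <- res$contribution
  g <- expand.grid(group_herd = rownames(cm), origin_herd = colnames(cm),
                   stringsAsFactors = FALSE)
  g$proportion <- cm[cbind(g$group_herd, g$origin_herd)]
  g$dataset_tag <- dataset_tag
  g$year_window <- year_window
  g[order(g$group_herd, g$origin_herd), ]
}
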