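#' @useDynLib herdlink, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import Matrix
#' @importFrom methods as new is
#' @importFrom stats rnorm runif rpois sd var setNames aggregate
#' @importFrom utils modifyList
NULL

PEDIGREE_COLS <- c("animal", "sire", "dam", "herd", "birth_year", "sex", "breed")

#' Construct a validated, topologically ordered pedigree
#'
#' A pedigree is a generation-ordered table of animals with parent links,
#' herd, birth year, sex and breed.  Unknown parents are coded 0.  Base
#' animals are animals with both parents unknown; they are the founder set
#' for relationship and gene-flow accounting.
#'
#' @param records data.frame with columns `animal`, `sire`, `dam`, `herd`,
#'   `birth_year`, `sex` (`"M"`/`"F"`), `breed`.  Extra columns (e.g.
#'   `birth_litter`) are carried along.
#' @param on_missing_parent `"insert"` (default) adds a referenced but
#'   unlisted parent as a base animal with a warning; `"error"` aborts.
#' @return An object of class `pedigree`: the reordered records plus an
#'   `order_index` map from animal id to row position.
#' @export
pedigree <- function(records, on_missing_parent = c("insert", "error")) {
  on_missing_parent <- match.arg(on_missing_parent)
  records <- as.data.frame(records)
  missing_cols <- setdiff(PEDIGREE_COLS, names(records))
  if (length(missing_cols))
    stop("pedigree records lack columns: ", paste(missing_cols, collapse = ", "))
  records$animal <- as.integer(records$animal)
  records$sire <- as.integer(records$sire)
  records$dam <- as.integer(records$dam)
  if (anyNA(records$animal) || any(records$animal <= 0L))
    stop("animal ids must be positive integers")
  records$sire[is.na(records$sire)] <- 0L
  records$dam[is.na(records$dam)] <- 0L

  dup <- records$animal[duplicated(records$animal)]
  if (length(dup))
    stop("duplicate animal_id in pedigree: ", paste(unique(dup), collapse = ", "))
  self <- records$animal[records$animal == records$sire | records$animal == records$dam]
  if (length(self))
    stop("self-parentage for animal ", paste(self, collapse = ", "))

  referenced <- setdiff(unique(c(records$sire, records$dam)), c(0L, records$animal))
  if (length(referenced)) {
    if (on_missing_parent == "error")
      stop("parent ids absent from pedigree: ", paste(referenced, collapse = ", "))
    warning(length(referenced), " referenced parent(s) not listed; ",
            "inserted as base animals")
    as_sire <- referenced %in% records$sire
    filler <- records[rep(1L, length(referenced)), , drop = FALSE]
    filler[] <- lapply(filler, function(x) rep(if (is.numeric(x)) NA_integer_ else NA, length(referenced)))
    filler$animal <- referenced
    filler$sire <- 0L
    filler$dam <- 0L
    filler$herd <- NA
    filler$birth_year <- suppressWarnings(min(records$birth_year, na.rm = TRUE)) - 1L
    filler$sex <- ifelse(as_sire, "M", "F")
    filler$breed <- NA
    records <- rbind(records, filler)
  }

  # sex consistency: sires male, dams female
  sex_of <- setNames(as.character(records$sex), records$animal)
  bad_sire <- records$sire[records$sire != 0L & sex_of[as.character(records$sire)] != "M"]
  if (length(bad_sire))
    stop("sire(s) not recorded as male: ", paste(unique(bad_sire), collapse = ", "))
  bad_dam <- records$dam[records$dam != 0L & sex_of[as.character(records$dam)] != "F"]
  if (length(bad_dam))
    stop("dam(s) not recorded as female: ", paste(unique(bad_dam), collapse = ", "))

  records <- topo_sort_pedigree(records)
  rownames(records) <- NULL
  structure(
    list(records = records,
         order_index = setNames(seq_len(nrow(records)), records$animal)),
    class = "pedigree")
}

# Kahn's algorithm; deterministic (by input order), errors on cycles.
topo_sort_pedigree <- function(records) {
  n <- nrow(records)
  id2pos <- setNames(seq_len(n), records$animal)
  sp <- ifelse(records$sire == 0L, 0L, id2pos[as.character(records$sire)])
  dp <- ifelse(records$dam == 0L, 0L, id2pos[as.character(records$dam)])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sp[i], dp[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L
    order[k] <- v
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n) {
    rem <- which(indeg > 0L)
    # walk parent links among the remainder to exhibit one cycle
    cur <- rem[1L]; seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(sp[cur], dp[cur])
      nxt <- nxt[nxt %in% rem]
      cur <- nxt[1L]
    }
    cyc <- seen[which(seen == cur):length(seen)]
    stop("pedigree cycle involving animals: ",
         paste(records$animal[cyc], collapse = " -> "))
  }
  records[order, , drop = FALSE]
}

#' Read a pedigree CSV
#'
#' Expected dialect: header row, UTF-8, columns
#' `animal,sire,dam,herd,birth_year,sex,breed`, unknown parents coded 0.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping required field
#'   names to the file's column names, e.g. `c(animal = "id")`.
#' @param on_missing_parent see [pedigree()].
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path, column_map = NULL,
                          on_missing_parent = c("insert", "error")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!is.null(column_map)) {
    for (field in names(column_map)) {
      if (!column_map[[field]] %in% names(df))
        stop("column '", column_map[[field]], "' not in file")
      names(df)[names(df) == column_map[[field]]] <- field
    }
  }
  pedigree(df, on_missing_parent = on_missing_parent)
}

#' Write a pedigree CSV in the package dialect
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  data.table::fwrite(ped$records[, intersect(c(PEDIGREE_COLS, "birth_litter"),
                                             names(ped$records))], path)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", n_animals(x), " animals, ",
      sum(is_base(x)), " base (",
      sprintf("%.1f%%", 100 * mean(is_base(x))), "), herds: ",
      paste(sort(unique(stats::na.omit(x$records$herd))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of animals in a pedigree
#' @param ped a pedigree.
#' @export
n_animals <- function(ped) nrow(ped$records)

#' Logical vector: is each animal a base animal (both parents unknown)?
#' @param ped a pedigree.
#' @export
is_base <- function(ped) ped$records$sire == 0L & ped$records$dam == 0L

# positional parent indices (0 = unknown)
parent_positions <- function(ped) {
  idx <- ped$order_index
  list(
    sire = ifelse(ped$records$sire == 0L, 0L,
                  unname(idx[as.character(ped$records$sire)])),
    dam = ifelse(ped$records$dam == 0L, 0L,
                 unname(idx[as.character(ped$records$dam)])))
}

#' Inbreeding coefficients
#'
#' Meuwissen-Luo style recursion on the ordered pedigree; exact, with
#' Mendelian sampling variances accounting for parental inbreeding.
#'
#' @param ped a [pedigree()] object.
#' @return numeric vector F, one per animal in pedigree order (0 for any
#'   animal with an unknown parent).
#' @export
compute_inbreeding <- function(ped) {
  pp <- parent_positions(ped)
  F <- inbreeding_ml(pp$sire, pp$dam)
  names(F) <- ped$records$animal
  F
}

#' Dense numerator relationship matrix (tabular method)
#'
#' Brute-force oracle: builds A by the tabular recursion
#' `A(i,j) = (A(j,s_i) + A(j,d_i)) / 2`, `A(i,i) = 1 + F(i)` in pedigree
#' order.  Intended for small pedigrees and as the reference for the sparse
#' inverse and the gene-flow decomposition.
#'
#' @param ped a [pedigree()] object.
#' @param cap refuse pedigrees larger than this (dense memory guard).
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
build_A_tabular <- function(ped, cap = 2000L) {
  n <- n_animals(ped)
  if (n > cap)
    stop("pedigree has ", n, " animals; tabular A is capped at ", cap,
         " (use build_A_inverse for the sparse path)")
  pp <- parent_positions(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pp$sire[i]; d <- pp$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(ped$records$animal, ped$records$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `1/d_i` at (i,i), `-1/(2 d_i)` at (i, parent) and `1/(4 d_i)` at
#' (parent, parent) positions, where `d_i` is the Mendelian sampling
#' variance given parental inbreeding.
#'
#' @param ped a [pedigree()] object.
#' @param F inbreeding coefficients from [compute_inbreeding()]; computed
#'   if missing.
#' @return sparse symmetric matrix (`dsCMatrix`) in pedigree order.
#' @export
build_A_inverse <- function(ped, F = compute_inbreeding(ped)) {
  n <- n_animals(ped)
  pp <- parent_positions(ped)
  s <- pp$sire; d <- pp$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  nk <- (s > 0L) + (d > 0L)
  msv <- ifelse(nk == 2L, 0.5 - 0.25 * (Fs + Fd),
                ifelse(nk == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / msv

  i <- seq_len(n)
  ii <- i; jj <- i; xx <- alpha                               # (i,i)
  ks <- which(s > 0L)
  ii <- c(ii, ks); jj <- c(jj, s[ks]); xx <- c(xx, -alpha[ks] / 2)
  ii <- c(ii, s[ks]); jj <- c(jj, s[ks]); xx <- c(xx, alpha[ks] / 4)
  kd <- which(d > 0L)
  ii <- c(ii, kd); jj <- c(jj, d[kd]); xx <- c(xx, -alpha[kd] / 2)
  ii <- c(ii, d[kd]); jj <- c(jj, d[kd]); xx <- c(xx, alpha[kd] / 4)
  kb <- which(s > 0L & d > 0L)
  ii <- c(ii, pmax(s[kb], d[kb])); jj <- c(jj, pmin(s[kb], d[kb]))
  xx <- c(xx, alpha[kb] / 4)

  keep_lower <- ii >= jj
  Ainv <- Matrix::sparseMatrix(i = ii[keep_lower], j = jj[keep_lower],
                               x = xx[keep_lower], dims = c(n, n),
                               symmetric = TRUE)
  dimnames(Ainv) <- list(ped$records$animal, ped$records$animal)
  Ainv
}

#' Pedigree and data summary per herd
#'
#' Mirrors the usual data-structure table of a multi-herd evaluation: per
#' herd and overall, the number of pedigree animals, percentage of base
#' animals, number of animals with production records, litter counts per
#' breed and the NBA mean and SD.
#'
#' @param ped a [pedigree()] object.
#' @param phen optional phenotype table (see [simulate_phenotypes()] for the
#'   column contract); when `NULL` only pedigree counts are reported.
#' @return data.frame, one row per herd plus an `ALL` row.
#' @export
pedigree_summary <- function(ped, phen = NULL) {
  rec <- ped$records
  base <- is_base(ped)
  herds <- sort(unique(stats::na.omit(rec$herd)))
  row_for <- function(sel, label, phen_sel) {
    out <- data.frame(
      herd = label,
      n_pedigree = sum(sel),
      pct_base = round(100 * sum(base & sel) / max(1L, sum(sel)), 2),
      stringsAsFactors = FALSE)
    if (!is.null(phen)) {
      ph <- phen[phen_sel, , drop = FALSE]
      out$n_with_records <- length(unique(ph$sow))
      out$n_litters <- nrow(ph)
      out$nba_mean <- round(mean(ph$nba), 2)
      out$nba_sd <- round(stats::sd(ph$nba), 2)
      for (b in c("L", "LW", "LxLW", "LWxL"))
        out[[paste0("litters_", b)]] <- sum(ph$genotype == b)
    }
    out
  }
  rows <- lapply(herds, function(h)
    row_for(!is.na(rec$herd) & rec$herd == h, h,
            if (is.null(phen)) NULL else phen$herd == h))
  rows <- c(rows, list(row_for(rep(TRUE, nrow(rec)), "ALL",
                               if (is.null(phen)) NULL else rep(TRUE, nrow(phen)))))
  do.call(rbind, rows)
}

#' Restrict a pedigree to a set of animals and all their ancestors
#'
#' @param ped a [pedigree()] object.
#' @param ids animal ids to keep (their ancestor closure is added).
#' @return a new, smaller [pedigree()].
#' @export
prune_pedigree <- function(ped, ids) {
  rec <- ped$records
  keep <- rec$animal %in% ids
  repeat {
    parents <- unique(c(rec$sire[keep], rec$dam[keep]))
    grow <- rec$animal %in% setdiff(parents, c(0L, rec$animal[keep]))
    if (!any(grow)) break
    keep <- keep | grow
  }
  pedigree(rec[keep, , drop = FALSE])
}
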