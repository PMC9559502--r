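PHENOTYPE_COLS <- c("sow", "parity", "year", "month", "genotype", "litter_sire",
                    "herd", "age_days", "wci_days", "prev_lact_days",
                    "birth_litter", "nba")

#' Specify the fixed and random structure of the litter-size model
#'
#' The full repeatability model for number born alive (NBA) has fixed
#' parity, mating season (year x month), sow genotype, litter sire, herd,
#' weaning-to-conception class, a quadratic age-at-farrowing covariate
#' nested within parity and a linear previous-lactation covariate, plus
#' random common-litter, permanent-environment and additive animal effects.
#'
#' Identifiability convention: the herd factor keeps all levels and the
#' intercept is omitted whenever herd is in the model, so herd-effect
#' contrasts are directly usable for connectedness ratings; every other
#' factor is reference coded (first level dropped), factors nested within
#' herd drop one level per herd, and the litter-sire factor drops one sire
#' per home herd (which also keeps the fixed part full rank when herds
#' share no sires).
#'
#' @param fixed character vector of fixed factors, a subset of
#'   `c("parity", "season", "genotype", "litter_sire", "wci_class")`.
#' @param nested_in_herd factors coded as herd x level (one reference level
#'   dropped per herd); ignored when `include_herd` is `FALSE`.
#' @param age_covariate include the centered linear + quadratic age at
#'   farrowing, nested within parity.
#' @param prev_lact_covariate include the centered linear previous-lactation
#'   covariate (zero for first parities).
#' @param random random terms, subset of `c("litter", "pe", "animal")`.
#' @param include_herd include herd as a fixed factor (multi-herd runs).
#' @export
model_spec <- function(fixed = c("parity", "season", "genotype",
                                 "litter_sire", "wci_class"),
                       nested_in_herd = "season",
                       age_covariate = TRUE,
                       prev_lact_covariate = TRUE,
                       random = c("litter", "pe", "animal"),
                       include_herd = TRUE) {
  if (length(fixed))
    fixed <- match.arg(fixed, c("parity", "season", "genotype", "litter_sire",
                                "wci_class"), several.ok = TRUE)
  random <- match.arg(random, c("litter", "pe", "animal"), several.ok = TRUE)
  structure(list(fixed = fixed,
                 nested_in_herd = intersect(nested_in_herd, fixed),
                 age_covariate = age_covariate,
                 prev_lact_covariate = prev_lact_covariate,
                 random = random,
                 include_herd = include_herd),
            class = "model_spec")
}

#' Contemporary-group model for connectedness scenarios
#'
#' Herd, herd-specific season and parity effects, the litter-sire fixed
#' effect and all three random terms.  Management factors are nested within
#' herd, so two herds are connected only through animals: shared (AI)
#' litter sires and pedigree ties.  In a genetically disconnected
#' population the coefficient matrix is then exactly block-diagonal by
#' herd and the connectedness rating is zero, rather than the statistical
#' carry-over that globally shared season or parity levels would induce.
#' @export
model_spec_scenario <- function() {
  model_spec(fixed = c("parity", "season", "litter_sire"),
             nested_in_herd = c("parity", "season"),
             age_covariate = FALSE, prev_lact_covariate = FALSE,
             include_herd = TRUE)
}

#' Encode phenotype records into a model frame
#'
#' Deterministic (lexicographic) factor-level indexing, weaning-to-conception
#' binning, and covariate centering on the grand mean of the analysed subset.
#' First-parity records have no previous lactation or weaning interval and
#' get a dedicated not-applicable class and a zero (i.e. mean) covariate
#' value.
#'
#' @param phen phenotype data.frame (columns `sow, parity, year, month,
#'   genotype, litter_sire, herd, age_days, wci_days, prev_lact_days,
#'   birth_litter, nba`).
#' @param spec a [model_spec()].
#' @param wci_bins upper edges (days) of the weaning-to-conception classes;
#'   default classes 0-5, 6-20, 21-40, >40.
#' @return a `model_frame` list: encoded data, the spec, and centering
#'   constants.
#' @export
build_model_frame <- function(phen, spec = model_spec(),
                              wci_bins = c(5, 20, 40)) {
  phen <- as.data.frame(phen)
  missing_cols <- setdiff(PHENOTYPE_COLS, names(phen))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(all(phen$parity >= 1), all(phen$age_days > 0))
  if (anyDuplicated(phen[, c("sow", "parity")]))
    stop("a sow's parities must be distinct")

  df <- data.frame(sow = as.integer(phen$sow),
                   y = as.numeric(phen$nba),
                   herd = as.character(phen$herd),
                   stringsAsFactors = FALSE)
  df$parity <- factor(phen$parity, levels = sort(unique(phen$parity)))
  df$season <- factor(sprintf("%d-%02d", phen$year, phen$month))
  df$genotype <- factor(as.character(phen$genotype))
  df$litter_sire <- factor(as.character(phen$litter_sire))
  wci <- cut(phen$wci_days, c(-Inf, wci_bins, Inf),
             labels = c(sprintf("wci%02d", c(0, wci_bins[-length(wci_bins)] + 1)),
                        sprintf("wci%02d+", wci_bins[length(wci_bins)])))
  wci <- as.character(wci)
  wci[phen$parity == 1] <- "wciNA"
  df$wci_class <- factor(wci, levels = c("wciNA", sort(setdiff(unique(wci), "wciNA"))))

  include_herd <- spec$include_herd
  herd_levels <- sort(unique(df$herd))
  if (include_herd && length(herd_levels) < 2L) {
    message("single herd in data: herd factor dropped")
    include_herd <- FALSE
  }
  df$herd_f <- factor(df$herd, levels = herd_levels)

  centers <- list(age = mean(phen$age_days))
  df$age_c <- phen$age_days - centers$age
  later <- phen$parity > 1
  centers$prev_lact <- if (any(later)) mean(phen$prev_lact_days[later]) else 0
  df$prev_lact_c <- ifelse(later, phen$prev_lact_days - centers$prev_lact, 0)
  df$birth_litter <- ifelse(is.na(phen$birth_litter) | phen$birth_litter == 0,
                            paste0("self", phen$sow),
                            paste0("lit", phen$birth_litter))

  # drop factor levels that became empty after subsetting
  for (v in c("parity", "season", "genotype", "litter_sire", "wci_class")) {
    if (nlevels(df[[v]]) > length(unique(as.character(df[[v]])))) {
      warning("dropping empty levels of ", v)
      df[[v]] <- droplevels(df[[v]])
    }
  }

  spec$include_herd <- include_herd
  structure(list(data = df, spec = spec, centers = centers,
                 herd_levels = herd_levels, wci_bins = wci_bins),
            class = "model_frame")
}

# sparse 0/1 incidence of a factor, one column per level
sp_incidence <- function(f) {
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f),
                       x = rep(1, length(f)),
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

#' Build the sparse design matrices of the matrix-form model
#'
#' `y = X b + Z_l l + Z_p p + Z_a a + e`: `X` carries all fixed effects and
#' covariates, `Z_l` the common birth-litter incidence, `Z_p` the
#' permanent-environment (sow) incidence and `Z_a` the animal incidence with
#' one column for every pedigree animal, including animals without records.
#'
#' @param frame a [build_model_frame()] result.
#' @param ped the [pedigree()]; every sow with records must be present.
#' @return a `design_matrices` list: `X`, `Zl`, `Zp`, `Za`, response `y`,
#'   `column_map` (effect name to X column indices), and index vectors.
#' @export
build_design_matrices <- function(frame, ped) {
  df <- frame$data
  spec <- frame$spec
  n <- nrow(df)
  missing_sows <- setdiff(unique(df$sow), ped$records$animal)
  if (length(missing_sows))
    stop("sows with records absent from pedigree: ",
         paste(utils::head(missing_sows, 5L), collapse = ", "))

  blocks <- list()
  column_map <- list()
  add_block <- function(name, M) {
    start <- sum(vapply(blocks, ncol, 0L)) + 1L
    blocks[[name]] <<- M
    column_map[[name]] <<- seq.int(start, length.out = ncol(M))
  }

  if (spec$include_herd) {
    add_block("herd", sp_incidence(df$herd_f))
  } else {
    add_block("intercept",
              Matrix::Matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"),
                             sparse = TRUE))
  }

  for (fac in spec$fixed) {
    f <- df[[fac]]
    if (nlevels(f) < 2L && fac != "wci_class") next  # degenerate factor
    if (spec$include_herd && fac %in% spec$nested_in_herd) {
      inter <- droplevels(interaction(df$herd_f, f, sep = ":", lex.order = TRUE))
      M <- sp_incidence(inter)
      drop_first_per_herd <- !duplicated(sub(":.*$", "", levels(inter)))
      M <- M[, !drop_first_per_herd, drop = FALSE]
    } else if (fac == "litter_sire" && spec$include_herd) {
      # drop one reference sire per home herd (full rank even with
      # herd-nested sire usage)
      M <- sp_incidence(f)
      home <- vapply(levels(f), function(s) df$herd[match(s, as.character(f))], "")
      drop <- !duplicated(home)
      M <- M[, !drop, drop = FALSE]
    } else if (fac == "wci_class") {
      # the not-applicable class is parity 1 by construction; dropping it
      # alone leaves the remaining classes summing to the parity>1
      # indicator, so one real class is dropped as well
      M <- sp_incidence(f)
      drop <- colnames(M) %in% c("wciNA", setdiff(colnames(M), "wciNA")[1L])
      M <- M[, !drop, drop = FALSE]
      if (ncol(M) == 0L) next
    } else {
      M <- sp_incidence(f)[, -1L, drop = FALSE]
    }
    colnames(M) <- paste0(fac, ".", colnames(M))
    add_block(fac, M)
  }

  if (spec$age_covariate) {
    P <- sp_incidence(df$parity)
    lin <- P * df$age_c
    quad <- P * df$age_c^2
    colnames(lin) <- paste0("age.lin.p", levels(df$parity))
    colnames(quad) <- paste0("age.quad.p", levels(df$parity))
    add_block("age", cbind(lin, quad))
  }
  if (spec$prev_lact_covariate && any(df$prev_lact_c != 0)) {
    add_block("prev_lact",
              Matrix::Matrix(df$prev_lact_c, n, 1,
                             dimnames = list(NULL, "prev_lact"), sparse = TRUE))
  }

  X <- do.call(cbind, blocks)

  # guarantee a full-rank fixed part: the reference coding above handles the
  # structural confounds, but a stochastic dataset can still disconnect a
  # within-herd two-way classification (e.g. a season reached by a single
  # parity).  R's LINPACK QR pivots only negligible columns to the end, so
  # earlier blocks (herd first) are always preserved.
  qX <- qr(as.matrix(X))
  if (qX$rank < ncol(X)) {
    drop_cols <- sort(qX$pivot[(qX$rank + 1L):ncol(X)])
    warning("dropping ", length(drop_cols),
            " linearly dependent fixed-effect column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    keep <- setdiff(seq_len(ncol(X)), drop_cols)
    X <- X[, keep, drop = FALSE]
    column_map <- lapply(column_map, function(ix) {
      kept <- setdiff(ix, drop_cols)
      match(kept, keep)
    })
    column_map <- column_map[vapply(column_map, length, 0L) > 0L]
  }

  out <- list(X = X, y = df$y, column_map = column_map, spec = spec,
              n_records = n)
  if ("litter" %in% spec$random) {
    lf <- factor(df$birth_litter)
    out$Zl <- sp_incidence(lf)
    out$litter_ids <- levels(lf)
  }
  if ("pe" %in% spec$random) {
    pf <- factor(df$sow, levels = sort(unique(df$sow)))
    out$Zp <- sp_incidence(pf)
    out$sow_ids <- as.integer(levels(pf))
  }
  if ("animal" %in% spec$random) {
    pos <- unname(ped$order_index[as.character(df$sow)])
    out$Za <- Matrix::sparseMatrix(i = seq_len(n), j = pos, x = rep(1, n),
                                   dims = c(n, n_animals(ped)),
                                   dimnames = list(NULL, ped$records$animal))
    out$animal_ids <- ped$records$animal
  }
  out$herd_of_record <- df$herd
  class(out) <- "design_matrices"
  out
}
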