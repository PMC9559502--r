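#' Scenario presets for the multi-herd simulator
#'
#' Three stated worlds, all built around herds A, B and C of unequal size
#' with herd B acting as the AI centre:
#' \describe{
#'   \item{`disconnected`}{no AI-boar sharing, no gilt trade, purebred only
#'     — the end-to-end null (zero connectedness, identity gene flow).}
#'   \item{`ai_connected`}{herd B's AI centre sires half of the matings in
#'     A and C, with a small B-to-A/C gilt trade; purebred (L, LW) only.}
#'   \item{`ai_connected_with_crossbreds`}{as `ai_connected`, plus
#'     reciprocal F1 crossbreeding (LxLW, LWxL) in herds A and C.}
#' }
#'
#' Defaults are roughly 1/20 of the reference population's volume
#' (~2,900 farrowings over 10 years against ~58,000 over 14) so the whole
#' pipeline runs in seconds; `scale` multiplies herd sizes.  The true
#' variance components default to the purebred three-herd estimates
#' (0.825, 1.171, 0.189, 10.324) — the crossbred preset uses the
#' purebred-plus-crossbred ones (0.970, 0.727, 0.181, 8.754) — and the
#' baseline NBA is 16.05 with herd deviations matching the observed herd
#' means (A 16.18, B 14.00, C 16.88).
#'
#' @param name one of `disconnected`, `ai_connected`,
#'   `ai_connected_with_crossbreds`.
#' @param scale multiplier on founder herd sizes.
#' @param years simulated span (>= 3 generations at the default 10).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param ... named overrides of any config field.
#' @return a `sim_config` list.
#' @export
scenario_presets <- function(name = c("disconnected", "ai_connected",
                                      "ai_connected_with_crossbreds"),
                             scale = 1, years = 10L, seed = 1L, ...) {
  if (!name[1L] %in% c("disconnected", "ai_connected",
                       "ai_connected_with_crossbreds"))
    stop("unknown preset '", name[1L], "'; available: disconnected, ",
         "ai_connected, ai_connected_with_crossbreds")
  name <- name[1L]
  connected <- name != "disconnected"
  crossbred <- name == "ai_connected_with_crossbreds"
  cfg <- list(
    preset = name,
    herds = data.frame(label = c("A", "B", "C"),
                       n_sows = ceiling(c(80, 28, 40) * scale),
                       n_boars = ceiling(c(10, 14, 8) * pmax(1, sqrt(scale))),
                       stringsAsFactors = FALSE),
    years = as.integer(years),
    year0 = 2008L,
    litters_per_sow_year = 2L,
    # fraction of matings in each destination herd sired by origin-herd
    # (AI) boars: destination -> named origin fractions
    ai_sharing = if (connected) list(A = c(B = 0.3), C = c(B = 0.3)) else list(),
    # fraction of sow replacements in each destination drawn from
    # origin-born gilts
    gilt_trade = if (connected) list(A = c(B = 0.06), C = c(B = 0.06)) else list(),
    # fraction of purebred matings producing reciprocal F1 litters
    crossbreeding = c(A = if (crossbred) 0.7 else 0, B = 0,
                      C = if (crossbred) 0.7 else 0),
    vc_true = if (crossbred) variance_components(0.970, 0.727, 0.181, 8.754)
              else variance_components(0.825, 1.171, 0.189, 10.324),
    mean_nba = 16.05,
    fixed_effects = list(
      parity = c(-0.5, 0.1, 0.35, 0.4, 0.3, 0.1, -0.15, -0.4),
      season_sd = 0.3,
      genotype = c(L = 0, LW = 0.2, LxLW = 0.5, LWxL = 0.5),
      herd = c(A = 0.13, B = -2.05, C = 0.83),
      age_lin = 0.0015, age_quad = -2e-6,
      wci = c(0, -0.1, -0.3, -0.5),
      prev_lact_slope = 0.01),
    cull_rate = 0.28, boar_cull_rate = 0.25, max_parity = 8L,
    registration = list(p_litter = 0.22, p_second = 0.35, p_boar = 0.05),
    round_nba = FALSE,
    seed = as.integer(seed))
  cfg <- modifyList(cfg, list(...))
  stopifnot(cfg$crossbreeding >= 0, cfg$crossbreeding <= 1,
            all(unlist(cfg$ai_sharing) >= 0),
            all(vapply(cfg$ai_sharing, sum, 0) <= 1),
            !is.null(cfg$seed))
  class(cfg) <- "sim_config"
  cfg
}

opposite_breed <- function(b) ifelse(b == "L", "LW", "L")

#' Simulate a multi-herd pig pedigree
#'
#' Founders are base animals per herd; each year every active sow farrows
#' `litters_per_sow_year` times, sires are drawn per the AI-sharing
#' fractions (falling back to local boars), replacement gilts and young
#' boars are registered from a fraction of litters, sows are culled at
#' random or at the parity cap, and vacancies are refilled from the gilt
#' pool with the configured herd-to-herd trade (migrated gilts carry the
#' destination herd label; their herd of origin remains traceable through
#' their base ancestors).  Deterministic under `cfg$seed`.
#'
#' @param cfg a [scenario_presets()] configuration.
#' @return a [pedigree()] with a `birth_litter` column; the per-farrowing
#'   litter table is attached as `attr(ped, "litters")` and the config as
#'   `attr(ped, "config")`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped_sire <- integer(0); ped_dam <- integer(0); ped_herd <- character(0)
  ped_year <- integer(0); ped_sex <- character(0); ped_breed <- character(0)
  ped_litter <- integer(0)
  add_animal <- function(sire, dam, herd, birth_year, sex, breed,
                         birth_litter = 0L) {
    ped_sire <<- c(ped_sire, sire); ped_dam <<- c(ped_dam, dam)
    ped_herd <<- c(ped_herd, herd); ped_year <<- c(ped_year, birth_year)
    ped_sex <<- c(ped_sex, sex); ped_breed <<- c(ped_breed, breed)
    ped_litter <<- c(ped_litter, birth_litter)
    length(ped_sire)
  }

  lcap <- 100000L
  lit <- new.env(parent = emptyenv())
  for (f in c("sow", "parity", "year", "month", "litter_sire", "age_days",
              "wci_days", "prev_lact_days"))
    assign(f, integer(lcap), envir = lit)
  lit$genotype <- character(lcap); lit$herd <- character(lcap)
  lit$litter_geno <- character(lcap)
  lit$n <- 0L

  herds <- cfg$herds$label
  y0 <- cfg$year0

  # active-population state kept in plain vectors (hot loop)
  boar_id <- integer(0); boar_herd <- character(0); boar_breed <- character(0)
  sow_id <- integer(0); sow_herd <- character(0); sow_breed <- character(0)
  sow_bt <- numeric(0); sow_pn <- integer(0)
  # founders: breeds split half/half inside every herd so any required
  # mating is feasible
  for (h in seq_along(herds)) {
    nb <- cfg$herds$n_boars[h]; ns <- cfg$herds$n_sows[h]
    bb <- rep(c("L", "LW"), length.out = nb)
    for (k in seq_len(nb)) {
      id <- add_animal(0L, 0L, herds[h], y0 - sample(1:3, 1L), "M", bb[k])
      boar_id <- c(boar_id, id); boar_herd <- c(boar_herd, herds[h])
      boar_breed <- c(boar_breed, bb[k])
    }
    sb <- rep(c("L", "LW"), length.out = ns)
    for (k in seq_len(ns)) {
      by <- y0 - sample(1:2, 1L)
      id <- add_animal(0L, 0L, herds[h], by, "F", sb[k])
      sow_id <- c(sow_id, id); sow_herd <- c(sow_herd, herds[h])
      sow_breed <- c(sow_breed, sb[k]); sow_bt <- c(sow_bt, by + 0.5)
      sow_pn <- c(sow_pn, 1L)
    }
  }
  # unrecruited registered gilts (birth herd; destination decided at
  # recruitment) and young boar pool
  gilt_id <- integer(0); gilt_herd <- character(0); gilt_breed <- character(0)
  gilt_bt <- numeric(0)
  yb_id <- integer(0); yb_herd <- character(0); yb_breed <- character(0)
  yb_year <- integer(0)

  pick_sire <- function(dest, req_breed, ai_only = FALSE) {
    ai <- cfg$ai_sharing[[dest]]
    origin <- dest
    if (!is.null(ai) && length(ai)) {
      if (ai_only) {
        # cross matings are AI matings: semen of the other breed comes from
        # the AI centre, not from local boars
        origin <- names(ai)[which.max(ai)]
      } else {
        u <- runif(1)
        k <- which(u < cumsum(ai))
        if (length(k)) origin <- names(ai)[k[1L]]
      }
    }
    for (try_herd in unique(c(origin, dest, herds))) {
      cand <- boar_id[boar_herd == try_herd & boar_breed == req_breed]
      if (length(cand))
        return(cand[sample.int(length(cand), 1L)])
    }
    stop("infeasible config: no ", req_breed, " boar available for herd ", dest)
  }

  for (year in seq.int(y0, length.out = cfg$years)) {
    for (h in herds) {
      for (si in which(sow_herd == h)) {
        m1 <- sample(1:6, 1L)
        months <- (m1 + cumsum(c(0L, rep(6L, cfg$litters_per_sow_year - 1L))) - 1L) %% 12L + 1L
        for (month in months) {
          if (sow_pn[si] > cfg$max_parity) next
          parity <- sow_pn[si]
          sow_pn[si] <- parity + 1L
          sbreed <- sow_breed[si]
          pure <- sbreed %in% c("L", "LW")
          cross <- pure && runif(1) < cfg$crossbreeding[[h]]
          req <- if (!pure) sample(c("L", "LW"), 1L)
                 else if (cross) opposite_breed(sbreed)
                 else sbreed
          # cross matings and commercial (F1-sow) matings are AI matings:
          # the semen comes from the AI centre, purebred nucleus matings
          # mostly use local boars
          sire <- pick_sire(h, req, ai_only = cross || !pure)
          sire_breed <- boar_breed[match(sire, boar_id)]
          litter_geno <- if (!pure) sbreed
                         else if (cross) paste0(sire_breed, "x", sbreed)
                         else sbreed
          li <- lit$n + 1L
          if (li > lcap) stop("litter capacity exceeded")
          lit$n <- li
          lit$sow[li] <- sow_id[si]; lit$parity[li] <- parity
          lit$year[li] <- year; lit$month[li] <- month
          lit$genotype[li] <- sbreed; lit$litter_sire[li] <- sire
          lit$herd[li] <- h
          lit$age_days[li] <- as.integer(round((year + month / 12 - sow_bt[si]) * 365.25))
          lit$wci_days[li] <- if (parity == 1L) NA_integer_
            else rpois(1L, 6L) + if (runif(1) < 0.15) rpois(1L, 25L) else 0L
          lit$prev_lact_days[li] <- if (parity == 1L) NA_integer_
            else 21L + rpois(1L, 7L)
          lit$litter_geno[li] <- litter_geno
          # register replacement offspring (purebred or F1 litters from
          # pure dams only; F1 dams' litters are terminal)
          if (pure && runif(1) < cfg$registration$p_litter) {
            ng <- 1L + (runif(1) < cfg$registration$p_second)
            for (g in seq_len(ng)) {
              id <- add_animal(sire, sow_id[si], h, year, "F", litter_geno, li)
              gilt_id <- c(gilt_id, id); gilt_herd <- c(gilt_herd, h)
              gilt_breed <- c(gilt_breed, litter_geno)
              gilt_bt <- c(gilt_bt, year + month / 12)
            }
          }
          if (pure && !cross && runif(1) < cfg$registration$p_boar) {
            id <- add_animal(sire, sow_id[si], h, year, "M", litter_geno, li)
            yb_id <- c(yb_id, id); yb_herd <- c(yb_herd, h)
            yb_breed <- c(yb_breed, litter_geno); yb_year <- c(yb_year, year)
          }
        }
      }
    }

    # year end: cull and replace
    keep_sow <- runif(length(sow_id)) >= cfg$cull_rate & sow_pn <= cfg$max_parity
    sow_id <- sow_id[keep_sow]; sow_herd <- sow_herd[keep_sow]
    sow_breed <- sow_breed[keep_sow]; sow_bt <- sow_bt[keep_sow]
    sow_pn <- sow_pn[keep_sow]
    for (h in seq_along(herds)) {
      lbl <- herds[h]
      vacancies <- cfg$herds$n_sows[h] - sum(sow_herd == lbl)
      if (vacancies <= 0L) next
      trade <- cfg$gilt_trade[[lbl]]
      for (v in seq_len(vacancies)) {
        origin <- lbl
        if (!is.null(trade) && length(trade)) {
          u <- runif(1)
          k <- which(u < cumsum(trade))
          if (length(k)) origin <- names(trade)[k[1L]]
        }
        age_ok <- gilt_bt <= year - 0.5 & gilt_bt > year - 3
        cand <- which(gilt_herd == origin & age_ok)
        if (!length(cand)) cand <- which(gilt_herd == lbl & age_ok)
        if (!length(cand)) next  # herd shrinks this year
        pick <- cand[sample.int(length(cand), 1L)]
        id <- gilt_id[pick]
        ped_herd[id] <- lbl  # migrated gilts carry the destination label
        sow_id <- c(sow_id, id); sow_herd <- c(sow_herd, lbl)
        sow_breed <- c(sow_breed, gilt_breed[pick])
        sow_bt <- c(sow_bt, gilt_bt[pick]); sow_pn <- c(sow_pn, 1L)
        gilt_id <- gilt_id[-pick]; gilt_herd <- gilt_herd[-pick]
        gilt_breed <- gilt_breed[-pick]; gilt_bt <- gilt_bt[-pick]
      }
    }
    # boar turnover
    keep <- runif(length(boar_id)) >= cfg$boar_cull_rate
    for (h in seq_along(herds)) {
      lbl <- herds[h]
      in_h <- boar_herd == lbl
      if (sum(keep & in_h) < 2L) keep[in_h] <- TRUE
      short <- cfg$herds$n_boars[h] - sum(keep & in_h)
      if (short > 0L) {
        take <- utils::head(which(yb_herd == lbl & yb_year < year), short)
        if (length(take)) {
          boar_id <- c(boar_id, yb_id[take])
          boar_herd <- c(boar_herd, yb_herd[take])
          boar_breed <- c(boar_breed, yb_breed[take])
          keep <- c(keep, rep(TRUE, length(take)))
          yb_id <- yb_id[-take]; yb_herd <- yb_herd[-take]
          yb_breed <- yb_breed[-take]; yb_year <- yb_year[-take]
        }
      }
    }
    boar_id <- boar_id[keep]; boar_herd <- boar_herd[keep]
    boar_breed <- boar_breed[keep]
  }

  nl <- lit$n
  litters <- data.frame(
    litter_id = seq_len(nl), sow = lit$sow[1:nl], parity = lit$parity[1:nl],
    year = lit$year[1:nl], month = lit$month[1:nl],
    genotype = lit$genotype[1:nl], litter_sire = lit$litter_sire[1:nl],
    herd = lit$herd[1:nl], age_days = lit$age_days[1:nl],
    wci_days = lit$wci_days[1:nl], prev_lact_days = lit$prev_lact_days[1:nl],
    litter_geno = lit$litter_geno[1:nl], stringsAsFactors = FALSE)

  rec <- data.frame(animal = seq_along(ped_sire), sire = ped_sire,
                    dam = ped_dam, herd = ped_herd, birth_year = ped_year,
                    sex = ped_sex, breed = ped_breed,
                    birth_litter = ped_litter, stringsAsFactors = FALSE)
  out <- pedigree(rec)
  attr(out, "litters") <- litters
  attr(out, "config") <- cfg
  out
}

#' Simulate NBA phenotypes on a simulated pedigree
#'
#' Generative reading of the analysis model: each farrowing record is the
#' fixed part (baseline NBA, parity curve, herd deviation, herd-specific
#' season effects, genotype, age and weaning-interval terms) plus the sow's
#' additive genetic value, her permanent-environment deviation, the common
#' effect of the litter she was born in, and a residual.  Breeding values
#' are sampled down the pedigree: founders `N(0, sigma2_a)`, offspring
#' midparent plus a Mendelian deviation with variance
#' `sigma2_a (1 - (F_s + F_d)/2) / 2`.  NBA is continuous by default
#' (`cfg$round_nba` rounds and floors at 0 as a robustness mode).
#'
#' @param ped a [simulate_pedigree()] result.
#' @param cfg the same config used for the pedigree.
#' @return phenotype data.frame (`sow, parity, year, month, genotype,
#'   litter_sire, herd, age_days, wci_days, prev_lact_days, birth_litter,
#'   nba`), with the simulated truth (`a`, `p`, `l`, `F`) attached as
#'   `attr(phen, "truth")`.
#' @export
simulate_phenotypes <- function(ped, cfg = attr(ped, "config")) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed + 499999L)
  litters <- attr(ped, "litters")
  if (is.null(litters)) stop("pedigree lacks a litter table; use simulate_pedigree()")
  vc <- cfg$vc_true
  rec <- ped$records
  n <- n_animals(ped)
  pp <- parent_positions(ped)
  F <- compute_inbreeding(ped)

  # additive values down the ordered pedigree
  Fs <- ifelse(pp$sire > 0L, F[pmax(pp$sire, 1L)], 0)
  Fd <- ifelse(pp$dam > 0L, F[pmax(pp$dam, 1L)], 0)
  nk <- (pp$sire > 0L) + (pp$dam > 0L)
  msv <- ifelse(nk == 2L, 0.5 * (1 - (Fs + Fd) / 2),
                ifelse(nk == 1L, 0.75 - 0.25 * (Fs + Fd), 1))
  z <- rnorm(n, sd = sqrt(vc$sigma2_a * msv))
  a <- numeric(n)
  for (i in seq_len(n)) {
    mid <- 0
    if (pp$sire[i] > 0L) mid <- mid + 0.5 * a[pp$sire[i]]
    if (pp$dam[i] > 0L) mid <- mid + 0.5 * a[pp$dam[i]]
    a[i] <- mid + z[i]
  }
  names(a) <- rec$animal

  sow_pos <- unname(ped$order_index[as.character(litters$sow)])
  sow_ids <- sort(unique(litters$sow))
  p_dev <- setNames(rnorm(length(sow_ids), sd = sqrt(vc$sigma2_p)), sow_ids)
  # common-litter deviations: one per distinct birth litter (founder sows
  # get their own singleton litter)
  bl <- rec$birth_litter[sow_pos]
  bl_lab <- ifelse(bl == 0L, paste0("self", litters$sow), paste0("lit", bl))
  lit_ids <- sort(unique(bl_lab))
  l_dev <- setNames(rnorm(length(lit_ids), sd = sqrt(vc$sigma2_l)), lit_ids)

  fe <- cfg$fixed_effects
  skey <- paste(litters$herd, litters$year, litters$month, sep = "_")
  su <- sort(unique(skey))
  season_eff <- setNames(rnorm(length(su), sd = fe$season_sd), su)
  age_c <- litters$age_days - mean(litters$age_days)
  later <- litters$parity > 1
  plc <- ifelse(later, litters$prev_lact_days - mean(litters$prev_lact_days[later]), 0)
  wci_class <- cut(litters$wci_days, c(-Inf, 5, 20, 40, Inf), labels = FALSE)
  wci_eff <- ifelse(later, fe$wci[wci_class], 0)
  wci_eff[is.na(wci_eff)] <- 0

  mu <- cfg$mean_nba +
    fe$parity[pmin(litters$parity, length(fe$parity))] +
    fe$herd[litters$herd] +
    season_eff[skey] +
    fe$genotype[litters$genotype] +
    fe$age_lin * age_c + fe$age_quad * age_c^2 +
    wci_eff + fe$prev_lact_slope * plc

  nba <- mu + a[sow_pos] + p_dev[as.character(litters$sow)] +
    l_dev[bl_lab] + rnorm(nrow(litters), sd = sqrt(vc$sigma2_e))
  if (isTRUE(cfg$round_nba)) nba <- pmax(0, round(nba))

  phen <- data.frame(
    sow = litters$sow, parity = litters$parity, year = litters$year,
    month = litters$month, genotype = litters$genotype,
    litter_sire = litters$litter_sire, herd = litters$herd,
    age_days = litters$age_days,
    wci_days = ifelse(later, litters$wci_days, 0L),
    prev_lact_days = ifelse(later, litters$prev_lact_days, 0L),
    birth_litter = bl, nba = as.numeric(nba),
    stringsAsFactors = FALSE)
  attr(phen, "truth") <- list(a = a, p = p_dev, l = l_dev, F = F,
                              vc = vc, fixed_part = as.numeric(mu))
  phen
}

#' Write / read the phenotype CSV dialect
#' @param phen phenotype data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phen, path) {
  data.table::fwrite(phen[, PHENOTYPE_COLS], path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  missing_cols <- setdiff(PHENOTYPE_COLS, names(df))
  if (length(missing_cols))
    stop("phenotype file lacks columns: ", paste(missing_cols, collapse = ", "))
  df
}
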