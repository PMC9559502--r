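#' Variance components of the repeatability NBA model
#'
#' Container for the additive (`sigma2_a`), permanent-environment
#' (`sigma2_p`), common-litter (`sigma2_l`) and residual (`sigma2_e`)
#' variances, in squared piglets, with the phenotypic variance and the
#' ratios h2, p2, l2, e2 derived on construction.
#'
#' @param sigma2_a,sigma2_p,sigma2_l,sigma2_e variances (>= 0); a term not
#'   in the model can be set to 0.
#' @export
variance_components <- function(sigma2_a, sigma2_p = 0, sigma2_l = 0,
                                sigma2_e = 1) {
  v <- c(a = sigma2_a, p = sigma2_p, l = sigma2_l, e = sigma2_e)
  if (any(v < 0)) stop("variances must be non-negative")
  structure(list(sigma2_a = unname(v["a"]), sigma2_p = unname(v["p"]),
                 sigma2_l = unname(v["l"]), sigma2_e = unname(v["e"]),
                 phenotypic = sum(v)),
            class = "variance_components")
}

#' Variance ratios on the phenotypic scale
#'
#' `h2` is the direct heritability, `p2` the proportion of permanent
#' environmental variance, `l2` the proportion of common litter
#' environmental variance and `e2` the residual proportion; they sum to 1.
#'
#' @param vc a [variance_components()] object.
#' @return named numeric vector `c(h2, p2, l2, e2)`.
#' @export
ratios <- function(vc) {
  if (vc$phenotypic <= 0) stop("zero phenotypic variance")
  c(h2 = vc$sigma2_a, p2 = vc$sigma2_p, l2 = vc$sigma2_l,
    e2 = vc$sigma2_e) / vc$phenotypic
}

#' @export
print.variance_components <- function(x, ...) {
  r <- ratios(x)
  cat(sprintf("Var(a)=%.4g Var(p)=%.4g Var(l)=%.4g Var(e)=%.4g Var(ph)=%.4g\n",
              x$sigma2_a, x$sigma2_p, x$sigma2_l, x$sigma2_e, x$phenotypic))
  cat(sprintf("h2=%.4f p2=%.4f l2=%.4f e2=%.4f\n", r[1], r[2], r[3], r[4]))
  invisible(x)
}

#' Variance-component report table
#'
#' One-row data.frame mirroring the usual Var(a)/Var(p)/Var(l)/Var(e)/Var(ph)
#' plus ratio layout of variance-component tables.  Standard errors are not
#' estimated by EM-REML and are reported as `NA`.
#' @param vc a [variance_components()].
#' @param label dataset label for the row.
#' @export
varcomp_table <- function(vc, label = "ABC") {
  r <- ratios(vc)
  data.frame(dataset = label, var_a = vc$sigma2_a, var_p = vc$sigma2_p,
             var_l = vc$sigma2_l, var_e = vc$sigma2_e,
             var_ph = vc$phenotypic,
             h2 = unname(r["h2"]), p2 = unname(r["p2"]),
             l2 = unname(r["l2"]), e2 = unname(r["e2"]),
             se = NA_real_)
}

# MME building blocks shared by em_reml() and assemble_mme(): the data part
# W'W / W'y and the embedded penalty matrices for each random term.
mme_parts <- function(dm, y, A_inv) {
  terms <- character(0)
  Zs <- list()
  if (!is.null(dm$Zl)) { terms <- c(terms, "l"); Zs$l <- dm$Zl }
  if (!is.null(dm$Zp)) { terms <- c(terms, "p"); Zs$p <- dm$Zp }
  if (!is.null(dm$Za)) { terms <- c(terms, "a"); Zs$a <- dm$Za }
  W <- do.call(cbind, c(list(dm$X), unname(Zs)))
  p <- ncol(dm$X)
  sizes <- vapply(Zs, ncol, 0L)
  offsets <- p + cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- terms
  idx <- lapply(terms, function(k)
    seq.int(offsets[[k]] + 1L, length.out = sizes[[k]]))
  names(idx) <- terms
  ntot <- ncol(W)
  pen <- list()
  for (k in terms) {
    if (k == "a") {
      stopifnot(nrow(A_inv) == sizes[["a"]])
      T <- as(A_inv, "TsparseMatrix")
      pen$a <- Matrix::sparseMatrix(i = idx$a[T@i + 1L], j = idx$a[T@j + 1L],
                                    x = T@x, dims = c(ntot, ntot),
                                    symmetric = FALSE)
      pen$a <- Matrix::forceSymmetric(pen$a, uplo = "L")
    } else {
      pen[[k]] <- Matrix::sparseMatrix(i = idx[[k]], j = idx[[k]],
                                       x = rep(1, sizes[[k]]),
                                       dims = c(ntot, ntot), symmetric = TRUE)
    }
  }
  list(WtW = Matrix::forceSymmetric(Matrix::crossprod(W)),
       Wty = as.numeric(Matrix::crossprod(W, y)), yty = sum(y^2),
       n = length(y), p = p, terms = terms, idx = idx, pen = pen,
       sizes = sizes)
}

sigma_of <- function(vc, k)
  switch(k, l = vc$sigma2_l, p = vc$sigma2_p, a = vc$sigma2_a)

#' EM-REML variance components for the repeatability animal model
#'
#' Expectation-maximisation REML on the mixed-model equations: at each
#' iteration the MME are solved with the current variance ratios, the
#' random-effect components are updated from `(u'Ku + sigma2_e tr(K C^kk))/q`
#' using exact traces of the inverse coefficient matrix (sparse Takahashi
#' selected inversion on the Cholesky pattern), and the residual from
#' `y'(y - W s)/(n - rank(X))`.  The restricted log-likelihood is evaluated
#' each iteration and is monotone non-decreasing across the recorded trace.
#'
#' Because plain EM converges slowly for small variance ratios, the default
#' adds guarded SQUAREM-style extrapolation on the log-variance scale: every
#' cycle of two EM steps proposes an accelerated point, which is accepted
#' only if its (cheaply evaluated) restricted likelihood beats the plain EM
#' alternative — so monotonicity is preserved by construction and every
#' accepted point is an exact-EM-map evaluation.
#'
#' @param dm a [build_design_matrices()] result.
#' @param y response vector; defaults to the one stored in `dm`.
#' @param A_inv sparse inverse numerator relationship matrix aligned with
#'   `dm$Za` columns.
#' @param init optional [variance_components()] starting values (strictly
#'   positive for included terms).  Default: 10/10/5/75 percent of the raw
#'   phenotypic variance for a/p/l/e.
#' @param tol convergence tolerance on the maximum relative parameter
#'   change over one EM step.
#' @param max_iter cap on EM-map evaluations; if reached the result is
#'   returned with `converged = FALSE`.
#' @param floor lower bound for components (boundary flag raised when hit).
#' @param accelerate use the guarded SQUAREM extrapolation (default TRUE).
#' @param verbose print per-iteration estimates.
#' @return list with `vc` (a [variance_components()]), `trace`
#'   (per-EM-step data.frame with components and restricted log-likelihood),
#'   `converged`, `iterations`, `boundary`.
#' @export
em_reml <- function(dm, y = dm$y, A_inv, init = NULL, tol = 1e-6,
                    max_iter = 500L, floor = 1e-8, accelerate = TRUE,
                    verbose = FALSE) {
  parts <- mme_parts(dm, y, A_inv)
  terms <- parts$terms
  vy <- stats::var(y)
  if (is.null(init)) {
    init <- variance_components(
      sigma2_a = if ("a" %in% terms) 0.10 * vy else 0,
      sigma2_p = if ("p" %in% terms) 0.10 * vy else 0,
      sigma2_l = if ("l" %in% terms) 0.05 * vy else 0,
      sigma2_e = vy * (0.75 + 0.10 * !("a" %in% terms) +
                         0.10 * !("p" %in% terms) + 0.05 * !("l" %in% terms)))
  }
  for (k in terms)
    if (sigma_of(init, k) <= 0) stop("init must be strictly positive for term ", k)

  # constant: log|A| = -log|A_inv|
  logdetA <- if ("a" %in% terms)
    -2 * as.numeric(Matrix::determinant(
      Matrix::Cholesky(A_inv, LDL = FALSE, super = FALSE), sqrt = TRUE)$modulus)
  else 0
  qtot <- sum(parts$sizes)

  build_C <- function(theta) {
    C <- parts$WtW
    for (k in terms) C <- C + (theta["e"] / theta[k]) * parts$pen[[k]]
    C
  }

  # symbolic factorization and pattern machinery, built once
  Ch0 <- tryCatch(
    Matrix::Cholesky(build_C(c(a = init$sigma2_a, p = init$sigma2_p,
                               l = init$sigma2_l, e = init$sigma2_e)),
                     LDL = FALSE, super = FALSE, perm = TRUE),
    error = function(e) stop(
      "singular MME coefficient matrix (confounded effects?): ",
      conditionMessage(e)))
  e0 <- Matrix::expand(Ch0)
  Lp <- e0$L@p; Li <- e0$L@i
  ncol_nnz <- diff(Lp)
  Pf <- as(e0$L + Matrix::t(e0$L), "generalMatrix")
  Pp <- Pf@p; Pi <- Pf@i
  perm <- Ch0@perm + 1L
  ip <- order(perm)                       # original index -> permuted position
  diag_slot <- which(Pi + 1L == rep.int(seq_along(ncol_nnz), diff(Pp)))
  slot_of <- Pf
  slot_of@x <- as.numeric(seq_along(Pi))
  # selected-inverse slots for the A-inverse trace (full pattern of A_inv)
  tr_slots <- tr_w <- NULL
  if ("a" %in% terms) {
    At <- as(as(A_inv, "generalMatrix"), "TsparseMatrix")
    pi2 <- ip[parts$idx$a[At@i + 1L]]
    pj2 <- ip[parts$idx$a[At@j + 1L]]
    tr_slots <- as.integer(slot_of[cbind(pi2, pj2)])
    tr_w <- At@x
  }
  dsl <- lapply(parts$idx, function(ix) diag_slot[ip[ix]])

  rll_of <- function(theta, Ch) {
    sol <- as.numeric(Matrix::solve(Ch, parts$Wty))
    ySSR <- parts$yty - sum(sol * parts$Wty)
    rll <- -0.5 * ((parts$n - parts$p - qtot) * log(theta["e"]) +
                     sum(vapply(terms, function(k)
                       parts$sizes[[k]] * log(theta[k]), 0)) +
                     2 * as.numeric(Matrix::determinant(Ch, sqrt = TRUE)$modulus) +
                     ySSR / theta["e"] + logdetA)
    list(rll = unname(rll), sol = sol, ySSR = ySSR)
  }
  cheap_rll <- function(theta) {
    tryCatch({
      Ch <- Matrix::update(Ch0, build_C(theta))
      rll_of(theta, Ch)$rll
    }, error = function(e) -Inf, warning = function(w) -Inf)
  }
  # one EM-map evaluation: returns the new parameter and rll at theta
  em_step <- function(theta) {
    Ch <- Matrix::update(Ch0, build_C(theta))
    r <- rll_of(theta, Ch)
    eL <- Matrix::expand(Ch)
    dL <- eL$L@x[Lp[-length(Lp)] + 1L]
    Lx <- eL$L@x / rep.int(dL, ncol_nnz)
    Zx <- takahashi_selinv(Lp, Li, Lx, dL^2, Pp, Pi)
    new <- theta
    for (k in terms) {
      u <- r$sol[parts$idx[[k]]]
      if (k == "a") {
        quad <- as.numeric(Matrix::crossprod(u, A_inv %*% u))
        tr <- sum(tr_w * Zx[tr_slots])
      } else {
        quad <- sum(u^2)
        tr <- sum(Zx[dsl[[k]]])
      }
      new[k] <- (quad + theta["e"] * tr) / parts$sizes[[k]]
    }
    new["e"] <- r$ySSR / (parts$n - parts$p)
    if (any(new[terms] < floor)) new[terms] <- pmax(new[terms], floor)
    list(theta = new, rll = r$rll)
  }

  cur <- c(a = init$sigma2_a, p = init$sigma2_p, l = init$sigma2_l,
           e = init$sigma2_e)
  active <- c(terms, "e")
  trace <- list()
  converged <- FALSE
  it <- 0L
  record <- function(theta, rll) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iter = it, sigma2_a = unname(theta["a"]), sigma2_p = unname(theta["p"]),
      sigma2_l = unname(theta["l"]), sigma2_e = unname(theta["e"]), rll = rll)
    if (verbose)
      message(sprintf("it %3d  a=%.5f p=%.5f l=%.5f e=%.5f rll=%.4f",
                      it, theta["a"], theta["p"], theta["l"], theta["e"], rll))
  }
  rel_change <- function(a, b) max(abs(a[active] - b[active]) /
                                     pmax(abs(b[active]), floor))

  while (it < max_iter && !converged) {
    it <- it + 1L
    s1 <- em_step(cur)
    record(cur, s1$rll)
    if (rel_change(s1$theta, cur) < tol) { cur <- s1$theta; converged <- TRUE; break }
    if (!accelerate || it + 1L > max_iter) { cur <- s1$theta; next }
    it <- it + 1L
    s2 <- em_step(s1$theta)
    record(s1$theta, s2$rll)
    if (rel_change(s2$theta, s1$theta) < tol) { cur <- s2$theta; converged <- TRUE; break }
    # SQUAREM extrapolation on the log scale, guarded by the restricted
    # likelihood so the accepted sequence stays monotone
    l0 <- log(cur[active]); l1 <- log(s1$theta[active]); l2 <- log(s2$theta[active])
    r <- l1 - l0
    v <- (l2 - l1) - r
    alpha <- -sqrt(sum(r^2)) / max(sqrt(sum(v^2)), 1e-12)
    alpha <- min(alpha, -1)
    rll2 <- cheap_rll(s2$theta)
    cur <- s2$theta
    for (bt in 1:8) {        # backtrack the extrapolation toward alpha = -1
      prop <- s2$theta
      prop[active] <- exp(l0 - 2 * alpha * r + alpha^2 * v)
      if (all(is.finite(prop[active])) && cheap_rll(prop) >= rll2) {
        cur <- prop
        break
      }
      if (alpha >= -1) break
      alpha <- (alpha - 1) / 2
    }
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter, " iterations")
  boundary <- any(cur[terms] <= floor * (1 + 1e-12))
  vc <- variance_components(
    sigma2_a = if ("a" %in% terms) unname(cur["a"]) else 0,
    sigma2_p = if ("p" %in% terms) unname(cur["p"]) else 0,
    sigma2_l = if ("l" %in% terms) unname(cur["l"]) else 0,
    sigma2_e = unname(cur["e"]))
  list(vc = vc, trace = do.call(rbind, trace),
       converged = converged, iterations = it, boundary = boundary)
}
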