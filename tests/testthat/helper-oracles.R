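# Shared fixtures and independent oracles for the test suite.
# Everything here is deliberately brute-force / dense: tests compare the
# package's sparse machinery against these implementations.

# random valid pedigree: founders plus descendants with parents drawn from
# earlier animals of the right sex
random_pedigree <- function(n = 60, n_founders = max(6L, round(n / 4)),
                            herds = c("A", "B"), seed = 1) {
  set.seed(seed)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  sire <- dam <- integer(n)
  for (i in seq_len(n)[-seq_len(n_founders)]) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    sire[i] <- if (length(males)) males[sample.int(length(males), 1L)] else 0L
    dam[i] <- if (length(females)) females[sample.int(length(females), 1L)] else 0L
  }
  pedigree(data.frame(
    animal = 1:n, sire = sire, dam = dam,
    herd = sample(herds, n, replace = TRUE),
    birth_year = 2000L + (seq_len(n) %/% 10L),
    sex = sex, breed = "L", stringsAsFactors = FALSE))
}

# tiny phenotype table on a given pedigree: one record per parity for a
# subset of females
tiny_phenotypes <- function(ped, n_parities = 2, seed = 1, herd_col = TRUE) {
  set.seed(seed)
  rec <- ped$records
  sows <- rec$animal[rec$sex == "F"]
  df <- expand.grid(sow = sows, parity = seq_len(n_parities))
  df$year <- 2009L + df$parity
  df$month <- 3L + 6L * (df$parity %% 2L)
  df$genotype <- "L"
  df$litter_sire <- rec$animal[rec$sex == "M"][1L]
  df$herd <- if (herd_col) rec$herd[match(df$sow, rec$animal)] else "A"
  df$age_days <- 380L + 180L * df$parity + sample(0:30, nrow(df), replace = TRUE)
  df$wci_days <- ifelse(df$parity == 1L, 0L, sample(3:30, nrow(df), replace = TRUE))
  df$prev_lact_days <- ifelse(df$parity == 1L, 0L, 25L + sample(0:10, nrow(df), replace = TRUE))
  df$birth_litter <- 0L
  df$nba <- rnorm(nrow(df), 15, 3)
  df
}

# dense generalized-least-squares oracle for the mixed model
# y = Xb + sum_k Z_k u_k + e,  u_k ~ N(0, G_k), e ~ N(0, I sigma2_e).
# Returns fixed solutions, BLUPs and the PEV of each random effect from
# first principles (V-inverse algebra), no MME involved.
gls_oracle <- function(X, Zs, Gs, sigma2_e, y) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (k in seq_along(Zs)) V <- V + Zs[[k]] %*% Gs[[k]] %*% t(Zs[[k]])
  Vi <- solve(V)
  XVX <- solve(t(X) %*% Vi %*% X)
  b <- XVX %*% t(X) %*% Vi %*% y
  resid <- y - X %*% b
  P <- Vi - Vi %*% X %*% XVX %*% t(X) %*% Vi
  u <- lapply(seq_along(Zs), function(k) Gs[[k]] %*% t(Zs[[k]]) %*% Vi %*% resid)
  # PEV via var(u - u_hat) = G - G Z' P Z G
  pev <- lapply(seq_along(Zs), function(k) {
    G <- Gs[[k]]
    unname(diag(G - G %*% t(Zs[[k]]) %*% P %*% Zs[[k]] %*% G))
  })
  list(b = as.numeric(b), u = lapply(u, as.numeric), pev = pev)
}

# assemble + dense-invert the MME directly (independent of solve_mme /
# selected_inverse): for PEV cross-checks
dense_mme_oracle <- function(X, Zs, Ks, lambdas, y) {
  W <- cbind(X, do.call(cbind, Zs))
  C <- crossprod(W)
  off <- ncol(X)
  for (k in seq_along(Zs)) {
    ix <- off + seq_len(ncol(Zs[[k]]))
    C[ix, ix] <- C[ix, ix] + lambdas[[k]] * Ks[[k]]
    off <- off + ncol(Zs[[k]])
  }
  Ci <- solve(C)
  sol <- Ci %*% crossprod(W, y)
  list(C = C, Cinv = Ci, sol = as.numeric(sol))
}

expect_equal_mat <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
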