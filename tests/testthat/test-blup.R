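# BLUP fixture: a small multi-herd instance with all three random terms,
# solved both by the package and by dense first-principles oracles.
blup_fixture <- function(seed = 3, n = 40, vc = variance_components(2, 1, 0.5, 8)) {
  ped <- random_pedigree(n = n, seed = seed)
  phen <- tiny_phenotypes(ped, n_parities = 2, seed = seed)
  spec <- model_spec(fixed = c("parity", "season"), nested_in_herd = character(0),
                     age_covariate = FALSE, prev_lact_covariate = FALSE)
  frame <- build_model_frame(phen, spec)
  dm <- build_design_matrices(frame, ped)
  A_inv <- build_A_inverse(ped)
  sys <- assemble_mme(dm, A_inv = A_inv, vc = vc)
  list(ped = ped, phen = phen, dm = dm, A_inv = A_inv, vc = vc, sys = sys)
}

test_that("assemble_mme reproduces the displayed MME structure", {
  fx <- blup_fixture()
  sys <- fx$sys
  expect_equal(nrow(sys$lhs),
               ncol(fx$dm$X) + ncol(fx$dm$Zl) + ncol(fx$dm$Zp) + ncol(fx$dm$Za))
  expect_true(Matrix::isSymmetric(sys$lhs))
  # animal block = Za'Za + A_inv * lambda_a entrywise
  ia <- sys$index_map$animal
  lam <- fx$vc$sigma2_e / fx$vc$sigma2_a
  expect_equal_mat(sys$lhs[ia, ia],
                   Matrix::crossprod(fx$dm$Za) + lam * fx$A_inv, 1e-10)
  # doubling sigma2_a halves the augmentation exactly
  vc2 <- variance_components(2 * fx$vc$sigma2_a, fx$vc$sigma2_p,
                             fx$vc$sigma2_l, fx$vc$sigma2_e)
  sys2 <- assemble_mme(fx$dm, A_inv = fx$A_inv, vc = vc2)
  diffm <- sys2$lhs[ia, ia] - sys$lhs[ia, ia]
  expect_equal_mat(diffm, -lam / 2 * fx$A_inv, 1e-10)
  # trio hand assembly, one record on the offspring
  trio <- pedigree(data.frame(animal = 1:3, sire = c(0L, 0L, 1L),
                              dam = c(0L, 0L, 2L), herd = "A",
                              birth_year = c(2000L, 2000L, 2001L),
                              sex = c("M", "F", "F"), breed = "L"))
  ph <- tiny_phenotypes(trio, n_parities = 1)
  ph <- ph[ph$sow == 3L, ]
  spec <- model_spec(fixed = character(0), age_covariate = FALSE,
                     prev_lact_covariate = FALSE, random = "animal",
                     include_herd = FALSE)
  dm3 <- build_design_matrices(build_model_frame(ph, spec), trio)
  vc3 <- variance_components(sigma2_a = 2, sigma2_e = 4)
  sys3 <- assemble_mme(dm3, A_inv = build_A_inverse(trio), vc = vc3)
  hand <- rbind(c(1, 0, 0, 1),
                c(0, 3, 1, -2),
                c(0, 1, 3, -2),
                c(1, -2, -2, 1 + 4)) # [mu | a1 a2 a3], lambda = 2
  expect_equal_mat(sys3$lhs, hand, 1e-12)
})

test_that("zero-variance random terms are dropped with a warning", {
  fx <- blup_fixture()
  vc0 <- variance_components(sigma2_a = 2, sigma2_p = 1, sigma2_l = 0,
                             sigma2_e = 8)
  expect_warning(sys <- assemble_mme(fx$dm, A_inv = fx$A_inv, vc = vc0),
                 "zero variance")
  expect_null(sys$index_map$litter)
  expect_equal(nrow(sys$lhs),
               ncol(fx$dm$X) + ncol(fx$dm$Zp) + ncol(fx$dm$Za))
})

test_that("solve_mme: mean-only model and prior-mean EBVs", {
  # mean-only fixed model, no random terms: lhs [n], rhs [sum y]
  ped <- random_pedigree(n = 12, n_founders = 12, seed = 4, herds = "A")
  phen <- tiny_phenotypes(ped, n_parities = 1, seed = 4)
  spec <- model_spec(fixed = character(0), age_covariate = FALSE,
                     prev_lact_covariate = FALSE, random = "animal",
                     include_herd = FALSE)
  dm <- build_design_matrices(build_model_frame(phen, spec), ped)
  vc <- variance_components(sigma2_a = 1e-6, sigma2_e = 10)
  sys <- assemble_mme(dm, A_inv = build_A_inverse(ped), vc = vc)
  res <- solve_mme(sys)
  expect_equal(unname(res$fixed_solutions["(Intercept)"]), mean(phen$nba),
               tolerance = 1e-6)
  # an unrelated, unphenotyped animal has EBV exactly 0
  fx <- blup_fixture(seed = 6)
  rec <- fx$ped$records
  loner <- rbind(rec, data.frame(animal = 999L, sire = 0L, dam = 0L,
                                 herd = "A", birth_year = 2003L, sex = "F",
                                 breed = "L"))
  ped2 <- pedigree(loner)
  dm2 <- build_design_matrices(build_model_frame(fx$phen, fx$dm$spec), ped2)
  sys2 <- assemble_mme(dm2, A_inv = build_A_inverse(ped2), vc = fx$vc)
  res2 <- compute_pev_reliability(solve_mme(sys2))
  expect_equal(unname(res2$ebv["999"]), 0)
  expect_equal(unname(res2$reliability["999"]), 0)
  expect_equal(unname(res2$pev["999"]), fx$vc$sigma2_a, tolerance = 1e-10)
})

test_that("MME solutions and PEV match dense GLS / dense-inverse oracles", {
  for (seed in c(3, 11, 21)) {
    fx <- blup_fixture(seed = seed)
    res <- compute_pev_reliability(solve_mme(fx$sys))
    A <- build_A_tabular(fx$ped)
    X <- as.matrix(fx$dm$X)
    Zs <- list(as.matrix(fx$dm$Zl), as.matrix(fx$dm$Zp), as.matrix(fx$dm$Za))
    Gs <- list(diag(fx$vc$sigma2_l, ncol(Zs[[1]])),
               diag(fx$vc$sigma2_p, ncol(Zs[[2]])),
               fx$vc$sigma2_a * A)
    or <- gls_oracle(X, Zs, Gs, fx$vc$sigma2_e, fx$dm$y)
    expect_equal(unname(res$fixed_solutions), or$b, tolerance = 1e-6)
    expect_equal(unname(res$ebv), or$u[[3]], tolerance = 1e-6)
    expect_equal(unname(res$pev), or$pev[[3]], tolerance = 1e-8)
    # PEV also equals sigma2_e x dense inverse diagonal of the MME
    lam <- fx$vc$sigma2_e / c(fx$vc$sigma2_l, fx$vc$sigma2_p, fx$vc$sigma2_a)
    dor <- dense_mme_oracle(X, Zs, list(diag(ncol(Zs[[1]])), diag(ncol(Zs[[2]])),
                                        as.matrix(solve(A))),
                            as.list(lam), fx$dm$y)
    ia <- fx$sys$index_map$animal
    expect_equal(unname(res$pev),
                 unname(fx$vc$sigma2_e * diag(dor$Cinv)[ia]),
                 tolerance = 1e-8)
  }
})

test_that("reliability arithmetic, clipping and monotone information", {
  vc <- variance_components(sigma2_a = 0.825, sigma2_e = 10)
  # r2 = 1 - pev / sigma2_a
  expect_equal(1 - 0.2 / 0.825, 0.75757575757, tolerance = 1e-8)
  fx <- blup_fixture(seed = 5)
  res <- compute_pev_reliability(solve_mme(fx$sys))
  expect_true(all(res$reliability >= 0 & res$reliability <= 1))
  expect_equal(unname(res$reliability),
               unname(1 - res$pev / fx$vc$sigma2_a), tolerance = 1e-10)
  # adding a phenotyped daughter never decreases the sire reliability
  ped <- fx$ped
  sire_id <- ped$records$animal[match("M", ped$records$sex)]
  rec2 <- rbind(ped$records,
                data.frame(animal = 500L, sire = sire_id, dam = 0L, herd = "A",
                           birth_year = 2005L, sex = "F", breed = "L"))
  ped2 <- pedigree(rec2)
  extra <- fx$phen[1, ]
  extra$sow <- 500L
  phen2 <- rbind(fx$phen, extra)
  dmx <- build_design_matrices(build_model_frame(phen2, fx$dm$spec), ped2)
  sys2 <- assemble_mme(dmx, A_inv = build_A_inverse(ped2), vc = fx$vc)
  res2 <- compute_pev_reliability(solve_mme(sys2))
  id <- as.character(sire_id)
  expect_gte(res2$reliability[id] + 1e-12, res$reliability[id])
})

test_that("summarize_reliability groups, conventions and ebv_table", {
  fx <- blup_fixture(seed = 12)
  res <- compute_pev_reliability(solve_mme(fx$sys))
  herd_of <- setNames(fx$ped$records$herd, fx$ped$records$animal)
  s_ph <- summarize_reliability(res, herd_of, animals = "phenotyped")
  all_row <- s_ph[s_ph$herd == "ALL", ]
  expect_equal(sum(s_ph$n[s_ph$herd != "ALL"]), all_row$n)
  expect_equal(all_row$n, length(unique(fx$phen$sow)))
  s_inf <- summarize_reliability(res, herd_of, animals = "informative")
  expect_gte(s_inf[s_inf$herd == "ALL", "n"], all_row$n)
  # constant reliabilities give SD 0
  res0 <- res
  res0$reliability[] <- 0.5
  s0 <- summarize_reliability(res0, herd_of, animals = "all")
  expect_equal(s0$sd, rep(0, nrow(s0)))
  tab <- ebv_table(res, herd_of)
  expect_equal(nrow(tab), n_animals(fx$ped))
  expect_true(all(c("animal", "herd", "ebv", "pev", "reliability") %in% names(tab)))
})
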