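test_that("pedigree construction validates, orders and round-trips", {
  rec <- data.frame(animal = c(3L, 1L, 2L), sire = c(1L, 0L, 0L),
                    dam = c(2L, 0L, 0L), herd = "A", birth_year = c(2001L, 2000L, 2000L),
                    sex = c("F", "M", "F"), breed = "L")
  ped <- pedigree(rec)
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$records$animal, c(1L, 2L, 3L))
  # order-invariance: reversed input gives the same ordered pedigree
  ped2 <- pedigree(rec[c(2, 3, 1), ])
  expect_equal(ped$records, ped2$records)
  # topological invariant on a random pedigree
  rp <- random_pedigree(n = 80, seed = 42)
  pp <- herdlink:::parent_positions(rp)
  nonbase <- which(!is_base(rp))
  expect_true(all(pp$sire[nonbase] < nonbase | pp$sire[nonbase] == 0L))
  expect_true(all(pp$dam[nonbase] < nonbase | pp$dam[nonbase] == 0L))
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_pedigree(rp, f)
  rp2 <- read_pedigree(f)
  cols <- c("animal", "sire", "dam", "herd", "birth_year", "sex", "breed")
  expect_equal(rp$records[cols], rp2$records[cols])
})

test_that("pedigree errors: duplicates, self-parentage, cycles, sex, missing parents", {
  base <- data.frame(animal = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                     herd = "A", birth_year = 2000L,
                     sex = c("M", "F", "F"), breed = "L")
  dup <- base; dup$animal[2] <- 1L
  expect_error(pedigree(dup), "duplicate")
  self <- base; self$sire[3] <- 3L
  expect_error(pedigree(self), "self-parentage")
  cyc <- base; cyc$sex[3] <- "M"; cyc$sire[1] <- 3L; cyc$sire[3] <- 1L; cyc$dam[3] <- 0L
  expect_error(pedigree(cyc), "cycle")
  badsex <- base; badsex$sire[3] <- 2L; badsex$dam[3] <- 1L
  expect_error(pedigree(badsex), "male")
  miss <- base; miss$sire[3] <- 9L
  expect_warning(p <- pedigree(miss), "inserted as base")
  expect_true(9L %in% p$records$animal)
  expect_error(pedigree(miss, on_missing_parent = "error"), "absent")
})

test_that("inbreeding matches the tabular-A oracle", {
  # full sibs mated: F(offspring) = 0.25
  fs <- pedigree(data.frame(
    animal = 1:5, sire = c(0L, 0L, 1L, 1L, 3L), dam = c(0L, 0L, 2L, 2L, 4L),
    herd = "A", birth_year = c(1, 1, 2, 2, 3) + 2000L,
    sex = c("M", "F", "M", "F", "F"), breed = "L"))
  expect_equal(unname(compute_inbreeding(fs)), c(0, 0, 0, 0, 0.25))
  # sire x daughter: F = 0.25
  sd <- pedigree(data.frame(
    animal = 1:4, sire = c(0L, 0L, 1L, 1L), dam = c(0L, 0L, 2L, 3L),
    herd = "A", birth_year = 2000L + c(1, 1, 2, 3),
    sex = c("M", "F", "F", "F"), breed = "L"))
  expect_equal(unname(compute_inbreeding(sd))[4], 0.25)
  # founders only
  fo <- random_pedigree(n = 10, n_founders = 10, seed = 1)
  expect_equal(unname(compute_inbreeding(fo)), rep(0, 10))
  # property: diag(A) - 1 equals F exactly, random pedigrees
  for (s in 1:5) {
    ped <- random_pedigree(n = 70, seed = s)
    A <- build_A_tabular(ped)
    expect_equal(unname(diag(A)) - 1, unname(compute_inbreeding(ped)),
                 tolerance = 1e-12)
  }
})

test_that("tabular A recursions give textbook relationships", {
  two <- random_pedigree(n = 2, n_founders = 2, seed = 1)
  expect_equal_mat(build_A_tabular(two), diag(2), 1e-14)
  trio <- pedigree(data.frame(animal = 1:3, sire = c(0L, 0L, 1L),
                              dam = c(0L, 0L, 2L), herd = "A",
                              birth_year = c(2000L, 2000L, 2001L),
                              sex = c("M", "F", "F"), breed = "L"))
  A <- build_A_tabular(trio)
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[2, 3], 0.5)
  fs <- pedigree(data.frame(animal = 1:4, sire = c(0L, 0L, 1L, 1L),
                            dam = c(0L, 0L, 2L, 2L), herd = "A",
                            birth_year = 2000L + c(0, 0, 1, 1),
                            sex = c("M", "F", "M", "F"), breed = "L"))
  expect_equal(build_A_tabular(fs)[3, 4], 0.5)
  expect_error(build_A_tabular(random_pedigree(30), cap = 10), "capped")
})

test_that("sparse A-inverse matches dense inversion of tabular A", {
  # founders only -> identity
  fo <- random_pedigree(n = 8, n_founders = 8, seed = 2)
  expect_equal_mat(build_A_inverse(fo), diag(8), 1e-12)
  # trio closed form
  trio <- pedigree(data.frame(animal = 1:3, sire = c(0L, 0L, 1L),
                              dam = c(0L, 0L, 2L), herd = "A",
                              birth_year = c(2000L, 2000L, 2001L),
                              sex = c("M", "F", "F"), breed = "L"))
  Ai <- as.matrix(build_A_inverse(trio))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2.0))
  expect_equal(Ai[1, 2], 0.5)
  expect_equal(Ai[1, 3], -1.0)
  expect_equal(Ai[2, 3], -1.0)
  # oracle equivalence incl. inbred pedigrees with single unknown parents
  for (s in 1:6) {
    ped <- random_pedigree(n = 50 + 10 * s, seed = 100 + s)
    A <- build_A_tabular(ped)
    Ai <- build_A_inverse(ped)
    expect_lt(max(abs(as.matrix(Ai %*% A) - diag(n_animals(ped)))), 1e-8)
  }
})

test_that("A becomes block diagonal without cross-herd parent links", {
  set.seed(9)
  mk <- function(off, herd) data.frame(
    animal = off + 1:20,
    sire = c(rep(0L, 8), off + sample(1:2, 12, replace = TRUE)),
    dam = c(rep(0L, 8), off + sample(3:8, 12, replace = TRUE)),
    herd = herd, birth_year = c(rep(2000L, 8), rep(2001L, 12)),
    sex = c("M", "M", rep("F", 18)), breed = "L")
  ped <- pedigree(rbind(mk(0L, "A"), mk(100L, "B")))
  A <- build_A_tabular(ped)
  herd_of <- ped$records$herd
  expect_equal(max(abs(A[herd_of == "A", herd_of == "B"])), 0)
})

test_that("pedigree_summary counts bases, records and litters", {
  ped <- random_pedigree(n = 10, n_founders = 3, seed = 3, herds = "A")
  s <- pedigree_summary(ped)
  expect_equal(s$pct_base[s$herd == "ALL"], 30)
  # with phenotypes: additivity of per-herd counts
  ped2 <- random_pedigree(n = 40, seed = 5)
  phen <- tiny_phenotypes(ped2, n_parities = 2, seed = 5)
  s2 <- pedigree_summary(ped2, phen)
  all_row <- s2[s2$herd == "ALL", ]
  herd_rows <- s2[s2$herd != "ALL", ]
  for (col in c("n_pedigree", "n_with_records", "n_litters",
                "litters_L", "litters_LW"))
    expect_equal(sum(herd_rows[[col]]), all_row[[col]])
})

test_that("prune_pedigree keeps ancestor closure only", {
  ped <- random_pedigree(n = 60, seed = 11)
  rec <- ped$records
  target <- rec$animal[55]
  sub <- prune_pedigree(ped, target)
  expect_true(target %in% sub$records$animal)
  # closure: all parents of kept animals are kept or unknown
  expect_true(all(sub$records$sire %in% c(0L, sub$records$animal)))
  expect_true(all(sub$records$dam %in% c(0L, sub$records$animal)))
  # relationships unchanged on the kept subset
  A_full <- build_A_tabular(ped)
  A_sub <- build_A_tabular(sub)
  ids <- as.character(sub$records$animal)
  expect_equal_mat(A_sub, A_full[ids, ids], 1e-12)
})
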