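test_that("tabular A matches hand-computed pedigrees", {
  expect_equal(unclass(build_A(data.frame(id = c("a", "b"), sire = NA,
                                          dam = NA)))[1:2, 1:2],
               diag(2), ignore_attr = TRUE)
  A <- build_A(trio_ped())
  expect_equal(A["o", "s"], 0.5)
  expect_equal(A["o", "d"], 0.5)
  expect_equal(A["o", "o"], 1)
  # offspring of full sibs is inbred with F = 0.25
  expect_equal(build_A(fullsib_mating_ped())["z", "z"], 1.25)
})

test_that("A equals the gene-dropping IBD oracle on a random pedigree", {
  ped <- small_herd_ped(n_off = 40, seed = 3)
  A <- build_A(ped)
  Ahat <- gene_drop_relationship(ped, n_loci = 3e4, seed = 11)
  expect_lt(max(abs(A - Ahat[rownames(A), colnames(A)])), 0.03)
})

test_that("A is positive semidefinite on random pedigrees", {
  for (s in 1:5) {
    ped <- small_herd_ped(n_off = 25, seed = s)
    ev <- eigen(build_A(ped), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("pedigree validation flags cycles and duplicates", {
  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(validate_pedigree(cyc), "cycle")
  dup <- data.frame(id = c("a", "a"), sire = NA, dam = NA)
  expect_error(validate_pedigree(dup), "duplicate")
  # parent without own record becomes a founder, with a warning
  expect_warning(out <- validate_pedigree(
    data.frame(id = "k", sire = "u", dam = NA)), "founder")
  expect_true("u" %in% out$id)
})

test_that("A22 extraction is principal-submatrix indexing", {
  ped <- six_ped()
  A <- build_A(ped)
  expect_equal(extract_A22(A, c("2", "5")),
               A[c("2", "5"), c("2", "5")], ignore_attr = TRUE)
  expect_equal(unclass(extract_A22(A, rownames(A))), unclass(A),
               ignore_attr = TRUE)
  expect_equal(dim(extract_A22(A, "6")), c(1L, 1L))
  expect_error(extract_A22(A, "zz"), "not in A")
})

test_that("VanRaden G matches hand computation and centring identities", {
  g <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(unclass(build_G(g)),
               matrix(c(2, -2, -2, 2), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)
  # all heterozygous at p = 0.5: centring annihilates Z
  h <- matrix(1, 3, 4, dimnames = list(letters[1:3], paste0("m", 1:4)))
  expect_equal(max(abs(build_G(h))), 0)
  mono <- matrix(2, 3, 2, dimnames = list(letters[1:3], c("m1", "m2")))
  expect_error(build_G(mono), "monomorphic")
})

test_that("G diagonal averages about 1 for unrelated founders", {
  ped <- data.frame(id = paste0("f", 1:80), sire = NA, dam = NA)
  geno <- simulate_genotypes(ped, 5000, seed = 21)
  G <- build_G(geno)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("G is invariant to marker and animal permutations", {
  ped <- small_herd_ped(n_off = 15, seed = 6)
  geno <- simulate_genotypes(ped, 400, seed = 7)
  G <- suppressWarnings(build_G(geno))
  pm <- sample(ncol(geno))
  pa <- sample(nrow(geno))
  G2 <- suppressWarnings(build_G(geno[, pm]))
  G3 <- suppressWarnings(build_G(geno[pa, ]))
  expect_equal(unclass(G2), unclass(G), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(G3[rownames(G), colnames(G)]), unclass(G),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("H-inverse collapses to A-inverse when G = A22 or no genotypes", {
  A <- build_A(six_ped())
  Ai <- solve_sym(A)
  gids <- c("3", "5", "6")
  A22i <- solve_sym(extract_A22(A, gids))
  expect_equal(unclass(build_H_inverse(Ai, A22i, A22i, gids)), unclass(Ai),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unclass(build_H_inverse(Ai, NULL, NULL, character(0))),
               unclass(Ai), tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("inverting assembled H-inverse reproduces the closed-form H", {
  A <- build_A(six_ped())
  gids <- c("3", "5", "6")
  A22 <- extract_A22(A, gids)
  set.seed(1)
  G <- A22 + 0.1 * crossprod(matrix(rnorm(9), 3))
  G <- (G + t(G)) / 2
  Hinv <- build_H_inverse(solve_sym(A), solve_sym(A22), solve_sym(G), gids)
  H <- solve_sym(Hinv)
  ug <- setdiff(rownames(A), gids)
  A12 <- A[ug, gids]
  A22i <- solve_sym(A22)
  Hdir <- unclass(A)
  Hdir[gids, gids] <- G
  Hdir[ug, gids] <- A12 %*% A22i %*% G
  Hdir[gids, ug] <- t(Hdir[ug, gids])
  Hdir[ug, ug] <- A[ug, ug] +
    A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  expect_equal(unclass(H), Hdir, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("build_H advises blending when G is singular", {
  ped <- small_herd_ped(n_off = 12, seed = 8)
  # 2 markers for 12+12 animals: G rank-deficient
  geno <- simulate_genotypes(ped, 2, seed = 9)
  expect_error(suppressWarnings(build_H(ped, geno, blend_weight = 0)),
               "blend_weight")
})
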