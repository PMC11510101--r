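test_that("pedigree simulation honours the design and is deterministic", {
  # founders only
  p0 <- simulate_pedigree(herd_design(n_dams = 2, n_sires = 1,
                                      n_offspring = 0, n_genotyped = 0,
                                      n_with_microbiota = 0), seed = 1)
  expect_equal(nrow(p0), 3)
  expect_true(all(is.na(p0$sire)))
  # the study-shaped herd: 101 + 72 founders + 739 offspring
  des <- herd_design()
  ped <- simulate_pedigree(des, seed = 2)
  expect_equal(nrow(ped), 101 + 72 + 739)
  off <- ped[!ped$founder, ]
  expect_equal(nrow(off), 739)
  expect_true(all(off$sire %in% ped$id) && all(off$dam %in% ped$id))
  expect_identical(ped, simulate_pedigree(des, seed = 2))
  expect_false(identical(ped, simulate_pedigree(des, seed = 3)))
})

test_that("gene dropping is Mendelian in every trio", {
  ped <- small_herd_ped(n_off = 30, seed = 4)
  dos <- simulate_genotypes(ped, 200, seed = 5)
  idx <- match(ped$id, rownames(dos))
  for (i in which(!ped$founder)) {
    o <- dos[ped$id[i], ]
    s <- dos[ped$sire[i], ]
    d <- dos[ped$dam[i], ]
    # offspring dosage bounded by what the parents can transmit
    lo <- (s == 2) + (d == 2)
    hi <- 2 - (s == 0) - (d == 0)
    expect_true(all(o >= lo & o <= hi))
  }
  expect_error(simulate_genotypes(ped, 0), "n_snps")
})

test_that("parent-offspring realized IBD sharing is about one half", {
  ped <- trio_ped()
  Ahat <- gene_drop_relationship(ped, n_loci = 2e4, seed = 6)
  expect_lt(abs(Ahat["o", "s"] - 0.5), 0.02)
  expect_lt(abs(Ahat["o", "d"] - 0.5), 0.02)
  expect_equal(Ahat["s", "d"], 0)
})

test_that("microbiome counts are multinomial at fixed depth", {
  counts <- simulate_microbiome(paste0("a", 1:40), n_asvs = 50, depth = 777,
                                seed = 7)
  expect_true(all(rowSums(counts) == 777))
  # zero dispersion: all animals share one expected profile, so the
  # inter-animal spread of a common ASV shrinks with depth
  c_lo <- simulate_microbiome(paste0("a", 1:50), n_asvs = 10, depth = 100,
                              log_sd = 0, seed = 8)
  c_hi <- simulate_microbiome(paste0("a", 1:50), n_asvs = 10, depth = 10000,
                              log_sd = 0, seed = 8)
  expect_gt(mean(apply(c_lo / 100, 2, sd)),
            mean(apply(c_hi / 10000, 2, sd)))
})

test_that("presence probability controls realized prevalence", {
  counts <- simulate_microbiome(paste0("a", 1:100), n_asvs = 200,
                                depth = 2000, presence_prob = 0.1, seed = 9)
  prev <- colMeans(counts > 0)
  # ~ binomial(100, 0.1) per ASV, averaged over 200 ASVs
  expect_lt(abs(mean(prev) - 0.1), 0.01)
})

test_that("phenotypes reduce to the fixed-effect surface at zero variance", {
  ped <- small_herd_ped(n_off = 40, seed = 10)
  tr <- true_params(var_a = 0, var_m = 0, var_p = 0, var_e = 0, mu = 5,
                    fixed_effects = c(gender = 1, batch = 2, diet = 0.5))
  ph <- simulate_phenotypes(ped, tr, seed = 11)
  eta <- 5 + (ph$gender == "M") + 2 * (ph$batch != "B1") +
    0.5 * (ph$diet != "T1")
  expect_equal(ph$y, eta, tolerance = 1e-12)
})

test_that("simulated genetic variance matches its target at large n", {
  des <- herd_design(n_dams = 2, n_sires = 2, n_offspring = 20000,
                     n_genotyped = 0, n_with_microbiota = 0)
  ped <- simulate_pedigree(des, seed = 12)
  tr <- true_params(var_a = 1, var_m = 0, var_p = 0, var_e = 0,
                    fixed_effects = numeric(0))
  ph <- simulate_phenotypes(ped, tr, seed = 12)
  expect_lt(abs(stats::var(attr(ph, "effects")$a[ph$id, 1]) - 1), 0.02)
})

test_that("a perfectly correlated bivariate draw has correlation one", {
  ped <- small_herd_ped(n_off = 60, seed = 13)
  Sa <- matrix(c(0.5, sqrt(0.5 * 0.3), sqrt(0.5 * 0.3), 0.3), 2)
  tr <- true_params(Sigma_a = Sa, Sigma_p = diag(0, 2), Sigma_e = diag(0, 2),
                    fixed_effects = numeric(0))
  ph <- simulate_phenotypes(ped, tr, K_genetic = build_A(ped), seed = 14)
  a <- attr(ph, "effects")$a
  expect_gt(stats::cor(a[, 1], a[, 2]), 0.99999)
  expect_gt(stats::cor(ph$y1, ph$y2, method = "spearman"), 0.99999)
})

test_that("non-PSD generative covariance is refused by name", {
  ped <- small_herd_ped(n_off = 10, seed = 15)
  K <- diag(10 + 12)
  K[1, 2] <- K[2, 1] <- 2   # indefinite
  rownames(K) <- colnames(K) <- ped$id
  expect_error(simulate_phenotypes(ped, true_params(), K_genetic = K),
               "K_genetic")
})

test_that("genotyped subset picks one male and one female per litter", {
  ped <- simulate_pedigree(herd_design(n_dams = 10, n_sires = 5,
                                       n_offspring = 80, n_genotyped = 20,
                                       n_with_microbiota = 0), seed = 16)
  ids <- select_genotyped(ped, 20, seed = 17)
  expect_equal(length(ids), 20)
  sel <- ped[match(ids, ped$id), ]
  expect_true(all(!sel$founder))
  # every litter here has both sexes, so each (dam, sex) cell is picked once
  expect_true(all(table(sel$dam, sel$sex) <= 1))
})

test_that("simulate_herd composes a coherent data set", {
  des <- herd_design(n_dams = 12, n_sires = 6, n_offspring = 80,
                     n_genotyped = 24, n_with_microbiota = 70)
  herd <- suppressWarnings(simulate_herd(des, n_snps = 500, n_asvs = 80,
                                         depth = 800, seed = 18))
  expect_equal(nrow(herd$geno), 24)
  expect_equal(nrow(herd$counts), 70)
  expect_equal(sum(herd$pheno$genotyped), 24)
  expect_equal(sum(herd$pheno$microbiota), 70)
  expect_true(all(rownames(herd$O) %in% herd$pheno$id))
})

test_that("herd design invariants are enforced", {
  expect_error(herd_design(n_dams = 0), "n_dams")
  expect_error(herd_design(n_offspring = 10, n_genotyped = 20), "exceed")
})
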