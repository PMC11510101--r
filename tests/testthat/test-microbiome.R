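test_that("rarefaction fixes row totals and drops shallow samples", {
  counts <- simulate_microbiome(paste0("a", 1:12), n_asvs = 30, depth = 300,
                                seed = 2)
  counts[1, ] <- c(50, rep(0, 29))               # below depth
  expect_message(out <- rarefy(counts, 100, seed = 3), "dropping 1")
  expect_equal(nrow(out), 11)
  expect_true(all(rowSums(out) == 100))
  # a single-ASV sample keeps all reads in that ASV
  one <- matrix(c(200L, 0L), 1, 2, dimnames = list("s1", c("x", "y")))
  expect_equal(unname(rarefy(one, 50)[1, ]), c(50L, 0L))
  expect_error(rarefy(one, 500), "fewer than")
})

test_that("prevalence filter keeps the 20% boundary inclusive", {
  counts <- matrix(0L, 100, 3,
                   dimnames = list(paste0("s", 1:100), c("a19", "a20", "all")))
  counts[1:19, "a19"] <- 5L
  counts[1:20, "a20"] <- 5L
  counts[, "all"] <- 1L
  out <- prevalence_filter(counts, 0.20)
  expect_equal(colnames(out), c("a20", "all"))
  # 2 of 10 samples is exactly 0.20: retained
  c10 <- matrix(0L, 10, 2, dimnames = list(paste0("t", 1:10), c("u", "v")))
  c10[1:2, "u"] <- 1L
  c10[, "v"] <- 1L
  expect_true("u" %in% colnames(prevalence_filter(c10, 0.20)))
  expect_error(prevalence_filter(c10[3:10, "u", drop = FALSE]), "no ASV")
})

test_that("standardization yields exact column mean 0 and population sd 1", {
  counts <- simulate_microbiome(paste0("a", 1:25), n_asvs = 40, depth = 500,
                                seed = 5)
  M <- standardize_abundance(counts)
  expect_lt(max(abs(colMeans(M))), 1e-10)
  expect_lt(max(abs(colMeans(M^2) - 1)), 1e-10)
})

test_that("two-sample standardization is forced to +/- 1", {
  # with pseudocount 1: P(asvA) = 10/100 and 100/200 for the two samples
  counts <- matrix(c(9L, 89L,
                     99L, 99L), 2, 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("asvA", "asvB")))
  M <- standardize_abundance(counts)
  expect_equal(unname(M[, "asvA"]), c(-1, 1))
  expect_equal(abs(unname(M[, "asvB"])), c(1, 1))
})

test_that("zero-variance ASV columns are dropped with a warning", {
  # equal sample totals make the 'flat' ASV's relative abundance constant
  counts <- matrix(c(10L, 30L, 60L,
                     10L, 60L, 30L,
                     10L, 45L, 45L), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("s", 1:3), c("flat", "v1", "v2")))
  expect_warning(M <- standardize_abundance(counts), "zero-variance")
  expect_equal(colnames(M), c("v1", "v2"))
  expect_error(standardize_abundance(counts[1, , drop = FALSE]),
               "two samples")
})

test_that("O = MM'/m matches a hand product and the trace identity", {
  M <- matrix(c(1, -1,
                0, 0,
                -1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  O <- build_O(M)
  expect_equal(unclass(O), tcrossprod(M) / 2, ignore_attr = TRUE)
  counts <- simulate_microbiome(paste0("a", 1:30), n_asvs = 60, depth = 400,
                                presence_prob = 0.7, seed = 8)
  pp <- microbiome_pipeline(counts, depth = 400, seed = 9)
  expect_equal(sum(diag(pp$O)) / nrow(pp$O), 1, tolerance = 1e-12)
  expect_gt(min(eigen(pp$O, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("O is invariant to ASV relabeling and equivariant to animals", {
  counts <- simulate_microbiome(paste0("a", 1:15), n_asvs = 30, depth = 300,
                                seed = 10)
  pp <- microbiome_pipeline(counts, depth = 300, seed = 1)
  M <- pp$M
  expect_equal(unclass(build_O(M[, sample(ncol(M))])), unclass(build_O(M)),
               tolerance = 1e-12, ignore_attr = TRUE)
  perm <- sample(nrow(M))
  O2 <- build_O(M[perm, ])
  expect_equal(unclass(O2[rownames(M), rownames(M)]),
               unclass(build_O(M)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical microbiota profiles give identical O rows", {
  M <- standardize_abundance(matrix(c(5L, 20L,
                                      5L, 20L,
                                      20L, 5L), 3, 2, byrow = TRUE,
                                    dimnames = list(c("s1", "s2", "s3"),
                                                    c("u", "v"))))
  O <- build_O(M)
  expect_equal(O["s1", ], O["s2", ])
  expect_lt(abs(det(O)), 1e-10)
})
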