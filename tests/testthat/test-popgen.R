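genepop_fixture <- function(path) {
  writeLines(c(
    "toy gorgonian panel",
    "locA", "locB",
    "POP",
    "i1 ,  0101 0102",
    "i2 ,  0102 0202",
    "i3 ,  0101 0000",
    "POP",
    "i4 ,  0202 0102",
    "i5 ,  0102 0101"
  ), path)
  path
}

test_that("GENEPOP parsing matches a hand-constructed fixture", {
  f <- genepop_fixture(tempfile(fileext = ".gen"))
  gm <- read_genepop(f)
  expect_equal(gm$loci, c("locA", "locB"))
  expect_equal(gm$ids, paste0("i", 1:5))
  expect_equal(gm$populations, c("pop1", "pop1", "pop1", "pop2", "pop2"))
  expect_equal(gm$calls[1, , ], matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_true(all(is.na(gm$calls[3, 2, ])))
  # allele counts at locA: pop1 has 5 copies of 1, 1 copy of 2
  a <- c(gm$calls[1:3, 1, ])
  expect_equal(sum(a == 1), 5)
  expect_equal(sum(a == 2), 1)
})

test_that("GENEPOP round-trip preserves calls, loci and population structure", {
  gm <- simulate_genotypes(sim_config(seed = 8))
  # punch in some missing calls
  gm$calls[3, 5, ] <- NA_integer_
  gm$calls[10, 1, ] <- NA_integer_
  f <- tempfile(fileext = ".gen")
  write_genepop(gm, f)
  back <- read_genepop(f)
  expect_identical(back$calls, gm$calls)
  expect_equal(back$loci, gm$loci)
  expect_equal(back$ids, gm$ids)
  expect_equal(as.integer(factor(back$populations)),
               as.integer(factor(gm$populations)))
})

test_that("malformed GENEPOP files raise errors naming the line", {
  f <- genepop_fixture(tempfile(fileext = ".gen"))
  l <- readLines(f)
  bad1 <- tempfile(); writeLines(c(l[1:4], "i1 , 0101", l[6:10]), bad1)
  expect_error(read_genepop(bad1), "line 5.*1 genotype fields for 2 loci")
  bad2 <- tempfile(); writeLines(c(l[1:5], "i2 , 001001 000222", l[7:10]), bad2)
  expect_error(read_genepop(bad2), "line 6.*mixed")
  bad3 <- tempfile(); writeLines(l[4:10], bad3)
  expect_error(read_genepop(bad3), "POP|malformed")
})

test_that("diversity summary matches the unbiased-He and rarefaction oracles", {
  # one locus, 10 heterozygous individuals -> p = 0.5, n = 10
  calls <- lapply(1:10, function(i) matrix(c(1L, 2L), 1, 2))
  gm1 <- toy_genotypes(calls, populations = rep("p1", 10))
  d <- diversity_summary(gm1)
  expect_equal(d$Ho, 1)                       # all heterozygotes
  expect_equal(d$He, (20 / 19) * (1 - 0.5))   # Nei unbiased, p = 0.5, n = 10
  # rarefaction vs exhaustive subset enumeration: 4 diploids, rarefy to 4 genes
  pool <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L)
  calls2 <- lapply(seq(1, 8, by = 2), function(i) matrix(pool[i:(i + 1)], 1, 2))
  gm2 <- toy_genotypes(calls2, populations = rep("p1", 4))
  d2 <- diversity_summary(gm2, rarefy_to = 4)
  subsets <- combn(8, 4)
  oracle <- mean(apply(subsets, 2, function(ix) length(unique(pool[ix]))))
  expect_equal(d2$richness, oracle)
  # monomorphic locus: He = 0, not an error
  gm3 <- toy_genotypes(lapply(1:4, function(i) matrix(c(1L, 1L), 1, 2)),
                       populations = rep("p1", 4))
  expect_equal(diversity_summary(gm3)$He, 0)
})

test_that("Weir-Cockerham theta matches the frozen variance-component oracle", {
  # 1 locus / 2 alleles / 2 pops; theta computed independently from the
  # a, b, c component formulas: a = 0.11, b = 0.05, c = 0.4
  p1 <- list(c(1L, 1L), c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L))
  p2 <- list(c(1L, 2L), c(2L, 2L), c(2L, 2L), c(1L, 2L), c(2L, 2L))
  calls <- lapply(c(p1, p2), function(g) matrix(g, 1, 2))
  gm <- toy_genotypes(calls, populations = rep(c("p1", "p2"), each = 5))
  fst <- wc_fst(gm, n_permutations = 0)
  expect_equal(fst$global_theta, 11 / 56, tolerance = 1e-12)
})

test_that("theta is invariant to allele relabelling and locus order", {
  gm <- simulate_genotypes(sim_config(seed = 12, theta_target = 0.05))
  base <- wc_fst(gm, n_permutations = 0)$global_theta
  gm2 <- gm
  gm2$calls <- gm$calls[, rev(seq_along(gm$loci)), , drop = FALSE]
  gm2$loci <- rev(gm$loci)
  expect_equal(wc_fst(gm2, n_permutations = 0)$global_theta, base)
  gm3 <- gm
  gm3$calls <- (max(gm$calls, na.rm = TRUE) + 1L) - gm$calls  # relabel codes
  expect_equal(wc_fst(gm3, n_permutations = 0)$global_theta, base)
})

test_that("duplicated populations give non-positive theta and structure gives significance", {
  gm <- simulate_genotypes(sim_config(seed = 3, n_populations = 1,
                                      theta_target = 0))
  dup <- genotype_matrix(gm$calls[rep(1:30, 2), , , drop = FALSE],
                         ids = sprintf("d%02d", 1:60),
                         populations = rep(c("p1", "p2"), each = 30),
                         loci = gm$loci)
  expect_lte(wc_fst(dup, n_permutations = 0)$global_theta, 0)

  gs <- simulate_genotypes(sim_config(seed = 5, theta_target = 0.1))
  fst <- wc_fst(gs, n_permutations = 99, seed = 1)
  expect_lte(fst$global_p, 0.05)
  expect_true(all(fst$pairwise_p[upper.tri(fst$pairwise_p)] > 0))  # never 0
  expect_true(isSymmetric(fst$pairwise))
})

test_that("theta is undefined for populations with too few typed individuals", {
  calls <- lapply(1:4, function(i) matrix(c(1L, 2L), 1, 2))
  calls[[4]] <- matrix(NA_integer_, 1, 2)
  gm <- toy_genotypes(calls, populations = c("a", "a", "a", "b"))
  expect_error(wc_fst(gm), "fewer than 2 typed")
})

test_that("sMLH matches hand computation and equals 1 on average for complete data", {
  # 3 inds, 2 loci; ind3 missing locus 1
  calls <- list(matrix(c(1L, 2L, 1L, 1L), 2, 2, byrow = TRUE),
                matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE),
                matrix(c(NA_integer_, NA_integer_, 1L, 2L), 2, 2, byrow = TRUE))
  gm <- toy_genotypes(calls, populations = rep("p", 3))
  s <- compute_smlh(gm)
  # locus means: loc1 = 1 (ind1, ind2), loc2 = 2/3; denominators 5/6, 5/6, 2/3
  expect_equal(s$smlh, c(0.5 / (5 / 6), 1 / (5 / 6), 1 / (2 / 3)))
  gm2 <- simulate_genotypes(sim_config(seed = 21))
  expect_equal(mean(compute_smlh(gm2)$smlh), 1, tolerance = 1e-12)
})

test_that("DAPC memberships are valid probabilities and BIC picks the argmin", {
  gm <- simulate_genotypes(sim_config(seed = 2, theta_target = 0.2))
  d <- dapc_clusters(gm, seed = 2)
  expect_equal(rowSums(d$memberships), rep(1, length(gm$ids)),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(d$chosen_k, d$bic_curve$k[which.min(d$bic_curve$bic)])
  expect_error(dapc_clusters(gm, max_k = 1000), "max_k")
})

test_that("perfect heterozygosity-fitness coupling yields the minimal p-value", {
  x <- seq(0.5, 1.5, length.out = 12)
  ni <- setNames(x, sprintf("c%02d", 1:12))
  sm <- data.frame(colony_id = names(ni), smlh = x)
  h <- heterosis_test(ni, sm, n_perm = 199, seed = 1)
  expect_equal(h$p_value, 1 / 200)
  expect_equal(h$observed_slope, 1)
  expect_error(heterosis_test(ni, transform(sm, smlh = 1), n_perm = 10),
               "zero variance")
})
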