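test_that("unbiased haploid diversity matches hand-computed values", {
  # n = 2, two distinct alleles: h = 0.5, uh = 1
  d <- make_data(cbind(L1 = c(100L, 102L)), c("A", "A"))
  uh <- unbiased_haploid_diversity(allele_frequencies(d))
  expect_equal(unname(uh$per_locus["L1", "A"]), 1)

  # monomorphic locus: uh = 0 at any n
  d <- make_data(cbind(L1 = rep(100L, 7)), rep("A", 7))
  uh <- unbiased_haploid_diversity(allele_frequencies(d))
  expect_equal(unname(uh$per_locus["L1", "A"]), 0)

  # n = 4, counts {2,1,1}: h = 0.625, uh = 5/6
  d <- make_data(cbind(L1 = c(100L, 100L, 102L, 104L)), rep("A", 4))
  uh <- unbiased_haploid_diversity(allele_frequencies(d))
  expect_equal(unname(uh$per_locus["L1", "A"]), 4 / 3 * 0.625)
})

test_that("uh is undefined for n < 2 and invariant to allele relabeling", {
  calls <- cbind(L1 = c(100L, 102L, 104L), L2 = c(200L, NA, NA))
  rownames(calls) <- paste0("s", 1:3)
  d <- make_data(calls, c("A", "A", "A"))
  expect_warning(uh <- unbiased_haploid_diversity(allele_frequencies(d)),
                 "n < 2")
  expect_true(is.na(uh$per_locus["L2", "A"]))
  expect_equal(uh$summary$n_loci, 1L)

  set.seed(3)
  calls <- random_calls(30, 4, n_alleles = 6)
  d1 <- make_data(calls, rep(c("A", "B"), 15))
  relab <- calls * 3L + 7L     # order-preserving relabeling
  d2 <- make_data(relab, rep(c("A", "B"), 15))
  expect_equal(unbiased_haploid_diversity(allele_frequencies(d1))$per_locus,
               unbiased_haploid_diversity(allele_frequencies(d2))$per_locus)
})

test_that("closed-form rarefaction equals exhaustive enumeration", {
  # worked example: N = 4, counts {2,1,1}, g = 2 -> alpha = 11/6
  d <- make_data(cbind(L1 = c(100L, 100L, 102L, 104L)), rep("A", 4))
  r <- rarefied_richness(allele_frequencies(d), g = 2)
  expect_equal(unname(r$alpha["L1", "A"]), 11 / 6, tolerance = 1e-12)
  expect_equal(unname(r$alpha["L1", "A"]), enum_alpha(c(2, 1, 1), 2),
               tolerance = 1e-12)

  # random cases with N_j <= 12, all g
  set.seed(42)
  for (rep in 1:15) {
    k <- sample(2:5, 1)
    counts <- as.vector(stats::rmultinom(1, sample(4:12, 1),
                                         rep(1 / k, k)))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    N <- sum(counts)
    calls <- cbind(L1 = as.integer(100 + 2 * rep(seq_along(counts), counts)))
    d <- make_data(calls, rep("A", N))
    for (g in unique(c(1, 2, sample(seq_len(N), 2)))) {
      r <- rarefied_richness(allele_frequencies(d), g = g)
      expect_equal(unname(r$alpha["L1", "A"]), enum_alpha(counts, g),
                   tolerance = 1e-10)
    }
  }
})

test_that("closed-form rarefaction agrees with Monte-Carlo at larger N", {
  set.seed(99)
  counts <- c(18, 9, 6, 4, 2, 1)
  N <- sum(counts)
  calls <- cbind(L1 = as.integer(100 + 2 * rep(seq_along(counts), counts)))
  d <- make_data(calls, rep("A", N))
  g <- 10
  r <- rarefied_richness(allele_frequencies(d), g = g)
  B <- 10000
  mc <- replicate(B, length(unique(sample(rep(seq_along(counts), counts),
                                          g))))
  se <- stats::sd(mc) / sqrt(B)
  expect_lt(abs(unname(r$alpha["L1", "A"]) - mean(mc)), 3 * se)
})

test_that("rarefaction boundary identities hold", {
  # g = N_j recovers the observed number of distinct alleles
  d <- make_data(cbind(L1 = c(100L, 100L, 102L, 104L, 104L)), rep("A", 5))
  r <- rarefied_richness(allele_frequencies(d), g = 5)
  expect_equal(unname(r$alpha["L1", "A"]), 3)

  # alpha_g is non-decreasing in g
  set.seed(8)
  calls <- random_calls(20, 2, n_alleles = 8)
  d <- make_data(calls, rep("A", 20))
  fr <- allele_frequencies(d)
  a <- vapply(1:20, function(g) rarefied_richness(fr, g = g)$alpha[1, 1], 0)
  expect_true(all(diff(a) >= -1e-12))
  # and bounded by min(g, inventory)
  expect_true(all(a <= pmin(1:20, nrow(fr$L1$counts)) + 1e-12))
})

test_that("private allelic richness behaves at its extremes", {
  # two monomorphic populations with disjoint alleles: pi_1 = 1 each
  d <- make_data(cbind(L1 = c(100L, 100L, 102L, 102L)),
                 c("A", "A", "B", "B"))
  r <- rarefied_richness(allele_frequencies(d), g = 1)
  expect_equal(unname(r$pi["L1", ]), c(A = 1, B = 1), ignore_attr = TRUE)

  # every allele in both strata at full-size g: pi = 0
  d <- make_data(cbind(L1 = c(100L, 102L, 100L, 102L)),
                 c("A", "A", "B", "B"))
  r <- rarefied_richness(allele_frequencies(d), g = 2)
  expect_equal(unname(r$pi["L1", ]), c(0, 0), ignore_attr = TRUE)

  # two-strata closed form against an independent evaluation
  set.seed(12)
  c1 <- c(`100` = 4, `102` = 2, `104` = 1)
  c2 <- c(`102` = 3, `106` = 2)
  calls <- cbind(L1 = as.integer(c(rep(names(c1), c1), rep(names(c2), c2))))
  d <- make_data(calls, rep(c("A", "B"), c(sum(c1), sum(c2))))
  g <- 3
  r <- rarefied_richness(allele_frequencies(d), g = g)
  expect_equal(unname(r$pi["L1", "A"]), enum_pi_two_strata(c1, c2, g),
               tolerance = 1e-10)
  expect_equal(unname(r$pi["L1", "B"]), enum_pi_two_strata(c2, c1, g),
               tolerance = 1e-10)
  # pi <= alpha
  expect_true(all(r$pi <= r$alpha + 1e-12))
})

test_that("strata below g are excluded per locus and g is validated", {
  calls <- cbind(L1 = c(100L, 102L, 104L, 100L))
  d <- make_data(calls, c("A", "A", "A", "B"))
  r <- rarefied_richness(allele_frequencies(d), g = 2)
  expect_true(is.na(r$alpha["L1", "B"]))
  expect_false(is.na(r$alpha["L1", "A"]))
  expect_error(rarefied_richness(allele_frequencies(d), g = 0), "positive")
  expect_warning(rarefied_richness(allele_frequencies(d), g = 10),
                 "dropped")
})

test_that("regional pooling feeds rarefaction with summed counts", {
  calls <- cbind(L1 = c(100L, 100L, 100L, 102L))
  d <- make_data(calls, c("P1", "P1", "P2", "P2"),
                 region = c(P1 = "r1", P2 = "r1"))
  fr <- allele_frequencies(d, by = "region")
  expect_equal(fr$L1$counts[, "r1"], c(`100` = 3L, `102` = 1L))
  r <- rarefied_richness(fr, g = 4)
  expect_equal(unname(r$alpha["L1", "r1"]), 2)
})
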