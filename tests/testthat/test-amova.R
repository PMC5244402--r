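test_that("complete fixation gives Phi_ST = 1 with zero within variance", {
  calls <- cbind(L1 = c(100L, 100L, 102L, 102L))
  rownames(calls) <- paste0("s", 1:4)
  d <- make_data(calls, c("A", "A", "B", "B"))
  a <- amova(d, n_perm = 0)
  expect_equal(unname(a$phi["phi_st"]), 1)
  expect_equal(a$table$sigma2[a$table$stratum == "within_populations"], 0)
})

test_that("hand-computed toy AMOVA is reproduced exactly", {
  # pop1 = {A,A}, pop2 = {A,B}: SS_total 0.75, within 0.5, among 0.25,
  # sigma2_within 0.25, sigma2_among 0, Phi_ST 0
  calls <- cbind(L1 = c(100L, 100L, 100L, 102L))
  rownames(calls) <- paste0("s", 1:4)
  d <- make_data(calls, c("A", "A", "B", "B"))
  a <- amova(d, n_perm = 0)
  tab <- a$table
  expect_equal(tab$SS[tab$stratum == "total"], 0.75, tolerance = 1e-12)
  expect_equal(tab$SS[tab$stratum == "within_populations"], 0.5,
               tolerance = 1e-12)
  expect_equal(tab$SS[tab$stratum == "among_populations"], 0.25,
               tolerance = 1e-12)
  expect_equal(tab$sigma2[tab$stratum == "within_populations"], 0.25,
               tolerance = 1e-12)
  expect_equal(tab$sigma2[tab$stratum == "among_populations"], 0,
               tolerance = 1e-12)
  expect_equal(unname(a$phi["phi_st"]), 0, tolerance = 1e-12)
})

test_that("degrees of freedom follow the sampling design", {
  sim <- simulate_ssr(island_mainland_config(seed = 1))
  a <- amova(sim$data, n_perm = 0)
  expect_equal(a$table$df, c(1, 9, 209, 219))
})

test_that("sums of squares are additive across strata", {
  set.seed(11)
  calls <- random_calls(36, 4, n_alleles = 5, missing = 0.1)
  pops <- rep(c("A", "B", "C", "D"), each = 9)
  region <- c(A = "r1", B = "r1", C = "r2", D = "r2")
  d <- make_data(calls, pops, region)
  a <- amova(d, n_perm = 0)
  tab <- a$table
  expect_equal(sum(tab$SS[tab$stratum != "total"]),
               tab$SS[tab$stratum == "total"], tolerance = 1e-9)
  expect_true(all(tab$SS >= -1e-12))
})

test_that("single-region AMOVA equals an independent two-level oracle", {
  set.seed(13)
  for (rep in 1:4) {
    calls <- random_calls(30, 3, n_alleles = 4,
                          missing = ifelse(rep > 2, 0.15, 0))
    pops <- rep(c("A", "B", "C"), each = 10)
    d <- make_data(calls, pops)
    a <- amova(d, n_perm = 0)
    want <- brute_two_level_amova(calls, pops)
    expect_equal(unname(a$phi["phi_st"]), unname(want["phi_st"]),
                 tolerance = 1e-10)
  }
})

test_that("three-level AMOVA with all pops in one region matches two-level", {
  set.seed(19)
  calls <- random_calls(32, 3, n_alleles = 5)
  pops <- rep(c("A", "B", "C", "D"), each = 8)
  d1 <- make_data(calls, pops)   # single region
  a1 <- amova(d1, n_perm = 0)
  expect_equal(unname(a1$phi["phi_st"]),
               unname(brute_two_level_amova(calls, pops)["phi_st"]),
               tolerance = 1e-10)
  expect_true(is.na(a1$phi["phi_ct"]))
})

test_that("AMOVA is invariant to allele relabeling", {
  set.seed(29)
  calls <- random_calls(24, 3, n_alleles = 4)
  pops <- rep(c("A", "B", "C"), each = 8)
  region <- c(A = "r1", B = "r1", C = "r2")
  d1 <- make_data(calls, pops, region)
  d2 <- make_data(calls * 5L + 3L, pops, region)
  a1 <- amova(d1, n_perm = 0); a2 <- amova(d2, n_perm = 0)
  expect_equal(a1$table$SS, a2$table$SS)
  expect_equal(a1$phi, a2$phi)
})

test_that("structured data yield significant permutation tests", {
  # two regions of fixed, disjoint populations: everything significant
  calls <- cbind(L1 = rep(c(100L, 102L, 104L, 106L), each = 6),
                 L2 = rep(c(200L, 202L, 204L, 206L), each = 6))
  rownames(calls) <- paste0("s", 1:24)
  pops <- rep(c("A", "B", "C", "D"), each = 6)
  region <- c(A = "r1", B = "r1", C = "r2", D = "r2")
  d <- make_data(calls, pops, region)
  a <- amova(d, n_perm = 199, seed = 5)
  expect_lt(a$p["phi_st"], 0.01)
  expect_lt(a$p["phi_sc"], 0.05)
})

test_that("pairwise FST matrix is symmetric, zero-diagonal, and exact at the
           extremes", {
  calls <- cbind(L1 = c(100L, 100L, 102L, 102L, 100L, 102L),
                 L2 = c(200L, 200L, 202L, 202L, 200L, 202L))
  rownames(calls) <- paste0("s", 1:6)
  d <- make_data(calls, c("A", "A", "B", "B", "C", "C"))
  f <- pairwise_fst(d, n_perm = 0)
  expect_equal(f$fst, t(f$fst))
  expect_equal(unname(diag(f$fst)), rep(0, 3))
  expect_equal(f$fst["A", "B"], 1)    # fixed disjoint pair

  set.seed(41)
  calls <- random_calls(60, 4, n_alleles = 6)
  d <- make_data(calls, rep(c("A", "B", "C"), each = 20))
  f <- pairwise_fst(d, n_perm = 0)
  expect_true(all(abs(f$fst[lower.tri(f$fst)]) < 0.06))
})

test_that("a population of size 1 is skipped with NA", {
  calls <- cbind(L1 = c(100L, 102L, 104L, 100L, 102L))
  rownames(calls) <- paste0("s", 1:5)
  d <- make_data(calls, c("A", "A", "A", "A", "B"))
  f <- pairwise_fst(d, n_perm = 0)
  expect_true(is.na(f$fst["A", "B"]))
})
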