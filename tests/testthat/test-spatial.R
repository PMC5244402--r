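test_that("Edwards chord distance matches hand-computed values", {
  # identical frequencies -> 0
  calls <- cbind(L1 = c(100L, 102L, 100L, 102L))
  d <- make_data(calls, c("A", "A", "B", "B"))
  D <- edwards_distance(allele_frequencies(d))
  expect_equal(D["A", "B"], 0)

  # disjoint monomorphic -> 1
  calls <- cbind(L1 = c(100L, 100L, 102L, 102L))
  d <- make_data(calls, c("A", "A", "B", "B"))
  D <- edwards_distance(allele_frequencies(d))
  expect_equal(D["A", "B"], 1)

  # freqs (1, 0) vs (0.5, 0.5): sqrt(1 - sqrt(0.5))
  calls <- cbind(L1 = c(100L, 100L, 100L, 102L))
  d <- make_data(calls, c("A", "A", "B", "B"))
  D <- edwards_distance(allele_frequencies(d))
  expect_equal(D["A", "B"], sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
})

test_that("great-circle distances behave like a metric", {
  set.seed(3)
  lat <- runif(12, -60, 60); lon <- runif(12, -170, 170)
  D <- geo_distance_matrix(lat, lon)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 12))
  for (r in 1:30) {
    ijk <- sample(12, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
  # co-located points at distance 0
  D2 <- geo_distance_matrix(c(40, 40), c(-3, -3))
  expect_equal(D2[1, 2], 0)
})

test_that("Mantel test is exact on a perfect linear relation", {
  sites <- toy_sites(6)
  geo <- geo_distance_matrix(sites$latitude, sites$longitude)
  gen <- 0.001 * geo + 0.01
  diag(gen) <- 0
  m <- mantel_ibd(gen, geo, n_perm = 199, seed = 1)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_lte(m$p, 0.01)
  # constant matrix -> NA
  m2 <- mantel_ibd(matrix(1, 6, 6) - diag(6) * 0, geo, n_perm = 99)
  expect_true(is.na(m2$r))
})

test_that("distance-pair KDE integrates to one and centers on the data", {
  set.seed(4)
  n <- 8
  geo <- as.matrix(dist(cbind(runif(n, 0, 1000), runif(n, 0, 1000))))
  gen <- as.matrix(dist(runif(n)))
  k <- distance_pair_kde(gen, geo, grid = 80)
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  expect_equal(sum(k$z) * dx * dy, 1, tolerance = 0.01)
  expect_true(all(k$z >= 0))
  # all-identical pairs: a single mode at that point, bandwidth floored
  geo1 <- matrix(500, 4, 4); diag(geo1) <- 0
  gen1 <- matrix(0.3, 4, 4); diag(gen1) <- 0
  k1 <- distance_pair_kde(gen1, geo1, grid = 40)
  peak <- which(k1$z == max(k1$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(k1$x[peak[1]] - 500), 50)
  expect_lt(abs(k1$y[peak[2]] - 0.3), 0.1)
})

spatial_fixture <- function(per_site = 6, n_loci = 2, alleles = 4,
                            seed = 1, k_sites = 4) {
  set.seed(seed)
  sites <- toy_sites(k_sites)
  n <- per_site * k_sites
  calls <- random_calls(n, n_loci, n_alleles = alleles)
  make_spatial_data(calls, rep(sites$population, each = per_site), sites)
}

test_that("a universal allele makes observed and expected coincide exactly", {
  sites <- toy_sites(3)
  calls <- cbind(L1 = rep(100L, 9))
  rownames(calls) <- paste0("s", 1:9)
  d <- make_spatial_data(calls, rep(sites$population, each = 3), sites)
  s <- sasha(d, n_perm = 0)
  expect_identical(s$observed_mean_km, s$expected_mean_km)
  expect_equal(sort(s$observed), sort(s$expected))
})

test_that("site-private alleles give observed mean zero below expectation", {
  sites <- toy_sites(3)
  # every allele confined to one site
  calls <- cbind(L1 = rep(c(100L, 102L, 104L), each = 4))
  rownames(calls) <- paste0("s", 1:12)
  d <- make_spatial_data(calls, rep(sites$population, each = 4), sites)
  s <- sasha(d, n_perm = 199, seed = 2)
  expect_equal(s$observed_mean_km, 0)
  expect_gt(s$expected_mean_km, 0)
  expect_lt(s$p, 0.05)
})

test_that("SAShA permutation null is calibrated under random placement", {
  rej <- 0L; n_rep <- 60L
  for (b in seq_len(n_rep)) {
    d <- spatial_fixture(per_site = 5, seed = 600 + b)
    s <- sasha(d, n_perm = 99, seed = b)
    if (s$p < 0.05) rej <- rej + 1L
  }
  expect_lt(rej / n_rep, 0.15)
  expect_gt(rej / n_rep, 0)  # not degenerate either side
})

test_that("the panmictic expectation is invariant to allele permutation", {
  d <- spatial_fixture(seed = 9)
  s1 <- sasha(d, n_perm = 0)
  perm_calls <- d$calls
  set.seed(1)
  for (l in 1:ncol(perm_calls))
    perm_calls[, l] <- perm_calls[sample(nrow(perm_calls)), l]
  d2 <- make_spatial_data(perm_calls, as.character(d$population), d$sites)
  s2 <- sasha(d2, n_perm = 0)
  expect_identical(s1$expected_mean_km, s2$expected_mean_km)
  expect_identical(sort(s1$expected), sort(s2$expected))
})

test_that("permutation-null means converge to the panmictic expectation", {
  d <- spatial_fixture(per_site = 6, seed = 33)
  s <- sasha(d, n_perm = 400, seed = 5)
  se <- stats::sd(s$perm_means) / sqrt(length(s$perm_means))
  expect_lt(abs(mean(s$perm_means) - s$expected_mean_km),
            max(3 * se, 0.02 * s$expected_mean_km))
})

test_that("an allele carried by all individuals is never restricted", {
  sites <- toy_sites(3)
  calls <- cbind(L1 = rep(100L, 9),
                 L2 = rep(c(200L, 202L, 204L), 3))
  rownames(calls) <- paste0("s", 1:9)
  d <- make_spatial_data(calls, rep(sites$population, each = 3), sites)
  g <- detect_gra(d, n_boot = 300, seed = 1)
  expect_false(g$restricted[g$locus == "L1"])
})

test_that("an allele confined to a distant peripheral site is restricted", {
  sites <- data.frame(population = c("P1", "P2", "P3", "Far"),
                      region = "all",
                      latitude = c(40, 40.3, 40.6, 55),
                      longitude = c(-3, -3.3, -3.6, 20))
  set.seed(2)
  calls <- cbind(L1 = c(sample(c(100L, 102L), 30, replace = TRUE),
                        rep(900L, 10)))
  rownames(calls) <- paste0("s", 1:40)
  d <- make_spatial_data(calls, rep(sites$population, each = 10), sites)
  g <- detect_gra(d, n_boot = 1000, seed = 3)
  expect_true(g$restricted[g$allele == 900])
})

test_that("GRA false-positive rate under random placement is near nominal", {
  # per-axis 95% CIs flagged on either axis: nominal rate between 5% and
  # ~9.75% depending on axis correlation
  flagged <- 0L; total <- 0L
  for (b in 1:3) {
    d <- spatial_fixture(per_site = 12, n_loci = 4, alleles = 8,
                         seed = 70 + b, k_sites = 5)
    g <- detect_gra(d, n_boot = 400, seed = b)
    flagged <- flagged + sum(g$restricted)
    total <- total + nrow(g)
  }
  rate <- flagged / total
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.16)
})

test_that("GRA flags are invariant to rigid translation of coordinates", {
  d <- spatial_fixture(seed = 12)
  g1 <- detect_gra(d, n_boot = 500, seed = 4)
  sites2 <- d$sites
  sites2$latitude <- sites2$latitude + 2
  sites2$longitude <- sites2$longitude + 5
  d2 <- make_spatial_data(d$calls, as.character(d$population), sites2)
  g2 <- detect_gra(d2, n_boot = 500, seed = 4)
  expect_equal(g1$restricted, g2$restricted)
})

test_that("restricted-subset SAShA uses only the subset's loci", {
  d <- spatial_fixture(per_site = 8, seed = 44)
  sub <- data.frame(locus = "L1",
                    allele = sort(unique(d$calls[, 1]))[1])
  s_sub <- sasha(d, n_perm = 0, subset = sub)
  # the expectation comes from locus L1 alone
  d_l1 <- make_spatial_data(d$calls[, "L1", drop = FALSE],
                            as.character(d$population), d$sites)
  s_l1 <- sasha(d_l1, n_perm = 0)
  expect_identical(s_sub$expected_mean_km, s_l1$expected_mean_km)
  expect_lte(length(s_sub$observed), length(s_l1$observed))
})
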