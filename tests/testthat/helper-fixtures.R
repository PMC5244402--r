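# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as explicit loops / enumerations so they
# share no code path with the package implementations they check.

make_data <- function(calls, pops, region = NULL, sites = NULL) {
  if (is.null(region)) {
    upops <- unique(pops)
    region <- stats::setNames(rep("all", length(upops)), upops)
  }
  genotype_dataset(calls, pops, region, sites = sites)
}

# dataset on a handful of sites with explicit coordinates
make_spatial_data <- function(calls, pops, sites_df) {
  region <- stats::setNames(sites_df$region, sites_df$population)
  genotype_dataset(calls, pops, region, sites = sites_df)
}

random_calls <- function(n, L, n_alleles = 5, missing = 0,
                         alleles = NULL) {
  if (is.null(alleles)) alleles <- 100 + 2 * seq_len(n_alleles)
  m <- matrix(sample(alleles, n * L, replace = TRUE), n, L)
  if (missing > 0) m[runif(n * L) < missing] <- NA
  rownames(m) <- paste0("s", seq_len(n))
  colnames(m) <- paste0("L", seq_len(L))
  m
}

# --- rarefaction oracles -------------------------------------------------

# exhaustive enumeration: mean number of distinct alleles over ALL
# g-subsets of the gene copies (N <= 12 or so)
enum_alpha <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(i) length(unique(copies[i]))))
}

# Monte-Carlo rarefaction without replacement
mc_alpha <- function(counts, g, B = 10000) {
  copies <- rep(seq_along(counts), counts)
  mean(replicate(B, length(unique(sample(copies, g)))))
}

# closed-form private richness for two strata by direct probability
# computation (independent of the package's log-gamma path)
enum_pi_two_strata <- function(counts1, counts2, g) {
  # expected count of alleles in a g-subset of stratum 1 absent from a
  # g-subset of stratum 2; allele universe = union of names
  alleles <- union(names(counts1), names(counts2))
  c1 <- stats::setNames(rep(0, length(alleles)), alleles)
  c1[names(counts1)] <- counts1
  c2 <- stats::setNames(rep(0, length(alleles)), alleles)
  c2[names(counts2)] <- counts2
  n1 <- sum(c1); n2 <- sum(c2)
  q <- function(n, m, g) {              # P(allele with m copies in subset)
    if (g > n - m) 1 else 1 - choose(n - m, g) / choose(n, g)
  }
  sum(vapply(alleles, function(a)
    q(n1, c1[a], g) * (1 - q(n2, c2[a], g)), 0))
}

# --- rBarD brute-force oracle -------------------------------------------

brute_rbar_d <- function(calls) {
  n <- nrow(calls); L <- ncol(calls)
  pairs <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) pairs[[length(pairs) + 1]] <- c(i, j)
  d <- matrix(NA_real_, length(pairs), L)
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    for (l in 1:L) {
      a <- calls[i, l]; b <- calls[j, l]
      if (!is.na(a) && !is.na(b)) d[k, l] <- if (a != b) 1 else 0
    }
  }
  D <- numeric(length(pairs))
  for (k in seq_along(pairs)) D[k] <- sum(d[k, ], na.rm = TRUE)
  VO <- var(D)
  vl <- numeric(L)
  for (l in 1:L) vl[l] <- var(d[, l], na.rm = TRUE)
  vl[is.na(vl)] <- 0
  VE <- sum(vl)
  denom <- 0
  for (l in 1:(L - 1)) for (m in (l + 1):L)
    denom <- denom + 2 * sqrt(vl[l] * vl[m])
  c(Ia = VO / VE - 1, rBarD = (VO - VE) / denom)
}

# --- two-level AMOVA oracle ---------------------------------------------

# direct quadratic-form implementation of the one-region (two-level) AMOVA
# on haploid mismatch distance, per-locus sums of squares and components
# summed over loci; explicit loops throughout
brute_two_level_amova <- function(calls, pops) {
  pops <- as.character(pops)
  upop <- unique(pops)
  sb_tot <- 0; sc_tot <- 0
  for (l in seq_len(ncol(calls))) {
    x <- unname(calls[, l])
    idx <- which(!is.na(x))
    if (length(idx) < 2) next
    nl <- length(idx)
    ss_tot <- 0
    for (i in idx) for (j in idx) if (i < j)
      ss_tot <- ss_tot + (x[i] != x[j])
    ss_tot <- ss_tot / nl
    ss_w <- 0
    sizes <- numeric(length(upop))
    for (p in seq_along(upop)) {
      members <- idx[pops[idx] == upop[p]]
      sizes[p] <- length(members)
      if (length(members) < 2) next
      s <- 0
      for (i in members) for (j in members) if (i < j) s <- s + (x[i] != x[j])
      ss_w <- ss_w + s / length(members)
    }
    P <- sum(sizes > 0)
    df_b <- P - 1; df_c <- nl - P
    if (df_b < 1) next
    n0 <- (nl - sum(sizes^2) / nl) / df_b
    ms_c <- if (df_c > 0) ss_w / df_c else 0
    ms_b <- (ss_tot - ss_w) / df_b
    sc_tot <- sc_tot + ms_c
    sb_tot <- sb_tot + (ms_b - ms_c) / n0
  }
  c(phi_st = sb_tot / (sb_tot + sc_tot), sigma_b = sb_tot, sigma_c = sc_tot)
}

make_separated_sim <- function(n_per = 20, k = 3, L = 6, a = 3, seed = 1) {
  # k groups with disjoint allele sets at every locus, plus within-group
  # polymorphism over a alleles: separation is total by construction
  # (a = 1 gives fixed, zero-variance clusters)
  set.seed(seed)
  calls <- NULL
  for (l in seq_len(L)) {
    col <- integer(0)
    for (g in seq_len(k)) {
      pool <- 1000L * g + 2L * seq_len(a)
      col <- c(col, pool[sample.int(a, n_per, replace = TRUE)])
    }
    calls <- cbind(calls, col)
  }
  colnames(calls) <- paste0("L", seq_len(L))
  rownames(calls) <- paste0("s", seq_len(k * n_per))
  list(calls = calls, truth = rep(seq_len(k), each = n_per))
}

# --- misc ----------------------------------------------------------------

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# small sites table spanning a few hundred km
toy_sites <- function(k = 4) {
  data.frame(population = paste0("P", seq_len(k)),
             region = rep("all", k),
             latitude = 40 + seq_len(k) * 0.9,
             longitude = -5 + seq_len(k) * 1.1,
             stringsAsFactors = FALSE)
}
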