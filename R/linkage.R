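#' Multilocus genotype (MLG) assignment
#'
#' Groups individuals by exact equality of their allele vectors. Missing is
#' not a wildcard: two rows differing only in missingness are distinct MLGs.
#'
#' @param data a \code{genpop_data} object
#' @return list with \code{mlg} (integer vector, MLG id per individual),
#'   \code{n_mlg} (number of distinct MLGs), \code{sizes} (table of MLG
#'   sizes) and \code{per_population} (data.frame population, n, n_mlg)
#' @export
find_mlgs <- function(data) {
  key <- apply(data$calls, 1, function(r)
    paste(ifelse(is.na(r), ".", r), collapse = "/"))
  mlg <- match(key, unique(key))
  per_pop <- do.call(rbind, lapply(levels(data$population), function(p) {
    i <- data$population == p
    data.frame(population = p, n = sum(i),
               n_mlg = length(unique(mlg[i])), stringsAsFactors = FALSE)
  }))
  list(mlg = mlg, n_mlg = length(unique(mlg)), sizes = table(mlg),
       per_population = per_pop)
}

# pairwise mismatch matrix for one population: rows = unordered pairs,
# cols = loci; NA where either member is missing at the locus
pair_mismatch <- function(calls) {
  n <- nrow(calls)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- matrix(NA_real_, nrow(pr), ncol(calls))
  for (l in seq_len(ncol(calls))) {
    x <- calls[, l]
    d[, l] <- as.numeric(x[pr[, 1]] != x[pr[, 2]])
  }
  d
}

rbar_d_stat <- function(d) {
  # d: pairs x loci mismatch matrix (NA = pair unscored at that locus)
  vl <- apply(d, 2, stats::var, na.rm = TRUE)
  vl[is.na(vl)] <- 0
  D <- rowSums(d, na.rm = TRUE)
  VO <- stats::var(D)
  VE <- sum(vl)
  s <- sqrt(vl)
  denom <- sum(outer(s, s))- sum(vl)   # 2 * sum_{l<m} sqrt(vl vm)
  Ia <- if (VE > 0) VO / VE - 1 else NA_real_
  rbar <- if (denom > 0) (VO - VE) / denom else NA_real_
  c(Ia = Ia, rBarD = rbar, VO = VO, VE = VE)
}

#' Unbiased index of association (rBarD) with permutation test
#'
#' For each unordered pair of individuals in a population, the number of
#' mismatching loci D is the sum of per-locus 0/1 mismatch indicators
#' (pairs missing at a locus are dropped from that locus). With
#' \eqn{V_O = var(D)} over pairs and \eqn{V_E = \sum_l var(d_l)},
#' \deqn{I_A = V_O / V_E - 1, \qquad
#'   \bar r_d = (V_O - V_E) / (2 \sum_{l<m} \sqrt{var_l \, var_m})}
#' Sample variances (denominator n_pairs - 1) are used throughout. The null
#' of no association is simulated by independently permuting each locus
#' column within the population; \eqn{p = (\#\{perm \ge obs\} + 1)/(B + 1)}.
#'
#' @param data a \code{genpop_data} object
#' @param population population name, or NULL to pool all individuals
#' @param n_perm number of permutations (0 = skip the test)
#' @param seed integer seed for the permutation stream
#' @return list: population, n, n_mlg, Ia, rBarD, VO, VE, p, n_perm
#' @export
rbar_d <- function(data, population = NULL, n_perm = 999L, seed = 1L) {
  calls <- data$calls
  if (!is.null(population)) {
    if (!population %in% levels(data$population))
      stop("unknown population: ", population)
    calls <- calls[data$population == population, , drop = FALSE]
  }
  n <- nrow(calls)
  if (n < 3L) stop("need at least 3 individuals")
  if (ncol(calls) < 2L) stop("need at least 2 loci")
  d <- pair_mismatch(calls)
  obs <- rbar_d_stat(d)
  key <- apply(calls, 1, paste, collapse = "/")
  p <- NA_real_
  if (n_perm > 0L && is.finite(obs["rBarD"])) {
    set.seed(seed)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      dp <- matrix(NA_real_, nrow(pr), ncol(calls))
      for (l in seq_len(ncol(calls))) {
        x <- calls[sample.int(n), l]
        dp[, l] <- as.numeric(x[pr[, 1]] != x[pr[, 2]])
      }
      if (rbar_d_stat(dp)["rBarD"] >= obs["rBarD"]) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  list(population = if (is.null(population)) "ALL" else population,
       n = n, n_mlg = length(unique(key)),
       Ia = unname(obs["Ia"]), rBarD = unname(obs["rBarD"]),
       VO = unname(obs["VO"]), VE = unname(obs["VE"]),
       p = p, n_perm = n_perm)
}

#' Per-population linkage summary table
#'
#' Runs \code{\link{rbar_d}} in every population with at least 3
#' individuals.
#'
#' @param data a \code{genpop_data} object
#' @param n_perm permutations per population
#' @param seed base seed; population index is added so each population has
#'   its own reproducible stream
#' @return data.frame: population, n, n_mlg, Ia, rBarD, p, n_perm
#' @export
linkage_table <- function(data, n_perm = 999L, seed = 1L) {
  pops <- levels(data$population)
  rows <- lapply(seq_along(pops), function(i) {
    if (sum(data$population == pops[i]) < 3L)
      return(data.frame(population = pops[i],
                        n = sum(data$population == pops[i]),
                        n_mlg = NA, Ia = NA, rBarD = NA, p = NA,
                        n_perm = n_perm, stringsAsFactors = FALSE))
    r <- rbar_d(data, pops[i], n_perm = n_perm, seed = seed + i)
    data.frame(population = pops[i], n = r$n, n_mlg = r$n_mlg, Ia = r$Ia,
               rBarD = r$rBarD, p = r$p, n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
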