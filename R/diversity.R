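#' Nei's unbiased haploid diversity
#'
#' Per (stratum, locus): \eqn{h = 1 - \sum_a p_a^2} on non-missing calls and
#' its small-sample correction \eqn{uh = n/(n-1) \, h}. Stratum summaries are
#' the mean over loci with \eqn{n \ge 2} and the standard error over loci
#' (sd across loci / sqrt(number of defined loci)).
#'
#' @param freqs an \code{\link{allele_frequencies}} table
#' @return list of class \code{"diversity_result"} with \code{per_locus}
#'   (uh matrix, loci x strata, NA where undefined) and \code{summary}
#'   (data.frame: stratum, n loci defined, uh_mean, uh_se)
#' @export
unbiased_haploid_diversity <- function(freqs) {
  strata <- attr(freqs, "strata")
  uh <- vapply(freqs, function(l) {
    h <- 1 - colSums(l$freq^2)
    n <- l$n
    out <- ifelse(n >= 2L, n / (n - 1) * h, NA_real_)
    unname(out)
  }, numeric(length(strata)))
  uh <- matrix(t(uh), nrow = length(freqs), ncol = length(strata),
               dimnames = list(names(freqs), strata))
  if (any(is.na(uh)))
    warning("some (stratum, locus) cells have n < 2; excluded from means")
  summ <- data.frame(
    stratum = strata,
    n_loci = colSums(!is.na(uh)),
    uh_mean = colMeans(uh, na.rm = TRUE),
    uh_se = apply(uh, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    }),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_locus = uh, summary = summ),
            class = "diversity_result")
}

# log of C(n, k) choose ratio helper: C(n - m, g) / C(n, g), computed in log
# space; returns 0 when g > n - m (subsample must contain the allele).
choose_ratio <- function(n, m, g) {
  if (g > n - m) return(0)
  exp(lchoose(n - m, g) - lchoose(n, g))
}

#' Rarefaction-standardized allelic and private allelic richness
#'
#' Expected number of distinct alleles (\eqn{\alpha_g}) and of private
#' alleles (\eqn{\pi_g}) in random subsamples of g gene copies drawn without
#' replacement, per stratum and locus:
#' \deqn{\alpha_g = \sum_a Q_{ja}(g), \quad
#'   Q_{ja}(g) = 1 - \binom{N_j - N_{ja}}{g} / \binom{N_j}{g}}
#' \deqn{\pi_g = \sum_a Q_{ja}(g) \prod_{k \ne j} (1 - Q_{ka}(g))}
#' Binomial ratios are evaluated through log-gamma. Strata with fewer than g
#' scored calls at a locus are excluded from that locus (both as focal and
#' as comparison strata for privacy).
#'
#' @param freqs an \code{\link{allele_frequencies}} table (population- or
#'   region-stratified; build the latter with
#'   \code{allele_frequencies(data, by = "region")})
#' @param g standardized sample size (number of gene copies); default is
#'   the largest g available everywhere: \code{min} over strata and loci of
#'   the non-missing sample size.
#' @return list of class \code{"rarefaction_result"}: \code{g};
#'   \code{alpha} and \code{pi} (loci x strata matrices, NA where the
#'   stratum was excluded); \code{summary} data.frame (stratum, AR_mean,
#'   AR_se, PAR_mean, PAR_se over loci).
#' @export
rarefied_richness <- function(freqs, g = NULL) {
  strata <- attr(freqs, "strata")
  nmat <- vapply(freqs, `[[`, numeric(length(strata)), "n")
  nmat <- matrix(nmat, ncol = length(freqs),
                 dimnames = list(strata, names(freqs)))
  if (is.null(g)) g <- max(1L, min(nmat))
  g <- as.integer(g)
  if (g <= 0L) stop("g must be a positive integer")
  L <- length(freqs)
  alpha <- pi_ <- matrix(NA_real_, L, length(strata),
                         dimnames = list(names(freqs), strata))
  dropped <- character(0)
  for (l in seq_len(L)) {
    cnt <- freqs[[l]]$counts
    n <- freqs[[l]]$n
    inc <- which(n >= g)
    if (length(inc) == 0L) { dropped <- c(dropped, names(freqs)[l]); next }
    # Q[a, j]: probability allele a appears in a g-subsample of stratum j
    Q <- vapply(inc, function(j) {
      vapply(seq_len(nrow(cnt)), function(a)
        1 - choose_ratio(n[j], cnt[a, j], g), 0)
    }, numeric(nrow(cnt)))
    Q <- matrix(Q, nrow = nrow(cnt))
    alpha[l, inc] <- colSums(Q)
    for (jj in seq_along(inc)) {
      others <- Q[, -jj, drop = FALSE]
      pi_[l, inc[jj]] <- sum(Q[, jj] * apply(1 - others, 1, prod))
    }
  }
  if (length(dropped))
    warning("loci dropped (every stratum below g): ",
            paste(dropped, collapse = ", "))
  se <- function(m) apply(m, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  summ <- data.frame(stratum = strata, g = g,
                     n_loci = colSums(!is.na(alpha)),
                     AR_mean = colMeans(alpha, na.rm = TRUE),
                     AR_se = se(alpha),
                     PAR_mean = colMeans(pi_, na.rm = TRUE),
                     PAR_se = se(pi_),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(g = g, alpha = alpha, pi = pi_, summary = summ),
            class = "rarefaction_result")
}

#' Combined diversity summary table
#'
#' One row per population (and per region when requested) with uh, AR and
#' PAR summaries at the requested standardized sizes.
#'
#' @param data a \code{genpop_data} object
#' @param g_pop standardized size for the population level (default: rule of
#'   \code{\link{rarefied_richness}})
#' @param g_region standardized size for the region level
#' @return data.frame
#' @export
diversity_table <- function(data, g_pop = NULL, g_region = NULL) {
  fp <- allele_frequencies(data, by = "population")
  fr <- allele_frequencies(data, by = "region")
  uh <- unbiased_haploid_diversity(fp)$summary
  rp <- rarefied_richness(fp, g = g_pop)$summary
  rr <- rarefied_richness(fr, g = g_region)$summary
  pop_tab <- merge(uh, rp, by = "stratum", sort = FALSE)
  pop_tab$level <- "population"
  rr$level <- "region"
  uh_r <- unbiased_haploid_diversity(fr)$summary
  reg_tab <- merge(uh_r, rr, by = "stratum", sort = FALSE)
  cols <- c("level", "stratum", "g", "uh_mean", "uh_se",
            "AR_mean", "AR_se", "PAR_mean", "PAR_se")
  rbind(pop_tab[, cols], reg_tab[, cols])
}
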