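#' Mating-type idiomorph ratio tests
#'
#' Goodness-of-fit of idiomorph counts against a 1:1 expectation, per
#' population and pooled over all samples. The chi-square statistic is
#' \eqn{(n_1 - n_2)^2 / (n_1 + n_2)} with 1 df; a two-sided exact binomial p
#' is reported alongside (preferable for small samples). Samples with NONE
#' (failed amplification) or BOTH are counted but excluded from the tests.
#'
#' @param mat data.frame with \code{sample_id}, \code{idiomorph} (see
#'   \code{\link{read_mat}})
#' @param data a \code{genpop_data} object supplying the population of each
#'   sample
#' @param bonferroni apply Bonferroni correction across populations to both
#'   p-value columns (default FALSE; the pooled row is never corrected)
#' @return data.frame: population ("ALL" = pooled), n1, n2, n_none, n_both,
#'   chi2, p_chi2, p_exact
#' @export
mat_ratio_tests <- function(mat, data, bonferroni = FALSE) {
  idx <- match(mat$sample_id, rownames(data$calls))
  if (anyNA(idx))
    stop("mat table contains sample ids absent from the dataset: ",
         paste(mat$sample_id[is.na(idx)][1], "..."))
  pop <- as.character(data$population)[idx]
  one_test <- function(idio) {
    n1 <- sum(idio == "MAT1-1"); n2 <- sum(idio == "MAT1-2")
    n <- n1 + n2
    if (n == 0L)
      return(c(n1 = 0, n2 = 0, n_none = sum(idio == "NONE"),
               n_both = sum(idio == "BOTH"), chi2 = NA, p_chi2 = NA,
               p_exact = NA))
    chi2 <- (n1 - n2)^2 / n
    c(n1 = n1, n2 = n2, n_none = sum(idio == "NONE"),
      n_both = sum(idio == "BOTH"), chi2 = chi2,
      p_chi2 = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      p_exact = stats::binom.test(n1, n, 0.5)$p.value)
  }
  pops <- levels(data$population)
  rows <- lapply(pops, function(p) one_test(mat$idiomorph[pop == p]))
  out <- as.data.frame(do.call(rbind, c(rows, list(one_test(mat$idiomorph)))))
  out <- cbind(population = c(pops, "ALL"), out)
  rownames(out) <- NULL
  if (bonferroni) {
    k <- length(pops)
    out$p_chi2[seq_len(k)] <- pmin(1, out$p_chi2[seq_len(k)] * k)
    out$p_exact[seq_len(k)] <- pmin(1, out$p_exact[seq_len(k)] * k)
  }
  out
}

#' Heterothallism consistency check
#'
#' A heterothallic haploid must carry exactly one idiomorph. Lists samples
#' recorded as BOTH (violations) and NONE (amplification failures) and the
#' overall amplification success fraction.
#'
#' @param mat data.frame with \code{sample_id}, \code{idiomorph}
#' @return list with \code{violations} (sample ids with BOTH),
#'   \code{failures} (sample ids with NONE), \code{n},
#'   \code{success_fraction} (share of samples with a single idiomorph)
#' @export
heterothallism_check <- function(mat) {
  viol <- mat$sample_id[mat$idiomorph == "BOTH"]
  fail <- mat$sample_id[mat$idiomorph == "NONE"]
  list(violations = viol, failures = fail, n = nrow(mat),
       success_fraction = 1 - (length(viol) + length(fail)) / nrow(mat))
}
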