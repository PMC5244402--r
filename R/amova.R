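# Hierarchical distance-based AMOVA on haploid mismatch distances,
# "weighted average over loci": per-locus sums of squares and variance
# components are computed on the individuals scored at that locus and summed
# across loci; Phi statistics come from the summed components.

# Per-locus precomputation: index of scored individuals and their pairwise
# 0/1 mismatch matrix (doubles, zero diagonal).
locus_blocks <- function(calls) {
  lapply(seq_len(ncol(calls)), function(l) {
    x <- calls[, l]
    idx <- which(!is.na(x))
    v <- x[idx]
    D <- outer(v, v, "!=") * 1
    list(idx = idx, D = D)
  })
}

# Sums of squares for one locus under a grouping. pop: integer group id per
# individual (full length N); returns per-group pair-sum matrix and sizes.
group_pair_sums <- function(block, pop, n_groups) {
  g <- pop[block$idx]
  sizes <- tabulate(g, n_groups)
  keep <- sort(unique(g))
  M <- rowsum(block$D, g)            # rows ordered by sort(unique(g))
  B <- rowsum(t(M), g)               # symmetric D, so orientation is safe
  full <- matrix(0, n_groups, n_groups)
  full[keep, keep] <- B
  list(B = full, sizes = sizes)
}

# Three-level variance components for one locus.
# pop: integer population id per individual (length N, NA never allowed
# here); reg_of_pop: integer region id per population.
locus_components <- function(block, pop, reg_of_pop) {
  P <- length(reg_of_pop)
  gs <- group_pair_sums(block, pop, P)
  sizes <- gs$sizes                       # per-population n at this locus
  B <- gs$B                               # population pair-sum matrix
  nl <- sum(sizes)
  present <- which(sizes > 0)
  G_ids <- sort(unique(reg_of_pop[present]))
  G <- length(G_ids)
  Pn <- length(present)
  ss_total <- sum(B) / (2 * nl)
  ss_wp <- sum(diag(B)[present] / (2 * sizes[present]))
  regsz <- vapply(G_ids, function(r) sum(sizes[reg_of_pop == r]), 0)
  ss_wr <- sum(vapply(seq_along(G_ids), function(k) {
    p <- which(reg_of_pop == G_ids[k] & sizes > 0)
    sum(B[p, p, drop = FALSE]) / (2 * regsz[k])
  }, 0))
  ss_ap <- ss_wr - ss_wp
  ss_ar <- ss_total - ss_wr
  df_c <- nl - Pn
  if (G >= 2) {
    df_a <- G - 1
    df_b <- Pn - G
    sum_np2_over_Ng <- sum(vapply(seq_along(G_ids), function(k) {
      p <- which(reg_of_pop == G_ids[k] & sizes > 0)
      sum(sizes[p]^2) / regsz[k]
    }, 0))
    n1 <- if (df_b > 0) (nl - sum_np2_over_Ng) / df_b else NA_real_
    n2 <- (sum_np2_over_Ng - sum(sizes^2) / nl) / df_a
    n3 <- (nl - sum(regsz^2) / nl) / df_a
    ms_c <- if (df_c > 0) ss_wp / df_c else 0
    ms_b <- if (df_b > 0) ss_ap / df_b else NA_real_
    ms_a <- ss_ar / df_a
    sc <- ms_c
    sb <- if (df_b > 0) (ms_b - sc) / n1 else 0
    sa <- (ms_a - sc - n2 * sb) / n3
    c(sa = sa, sb = sb, sc = sc,
      ss_ar = ss_ar, ss_ap = ss_ap, ss_wp = ss_wp, ss_total = ss_total)
  } else {
    # single region: two-level design (among populations / within)
    df_b <- Pn - 1
    n0 <- if (df_b > 0) (nl - sum(sizes^2) / nl) / df_b else NA_real_
    ms_c <- if (df_c > 0) ss_wp / df_c else 0
    ms_b <- if (df_b > 0) (ss_total - ss_wp) / df_b else NA_real_
    sc <- ms_c
    sb <- if (df_b > 0) (ms_b - sc) / n0 else 0
    c(sa = NA_real_, sb = sb, sc = sc,
      ss_ar = 0, ss_ap = ss_total - ss_wp, ss_wp = ss_wp,
      ss_total = ss_total)
  }
}

# Summed-over-loci components for a given grouping.
amova_components <- function(blocks, pop, reg_of_pop) {
  acc <- vapply(blocks, locus_components, numeric(7),
                pop = pop, reg_of_pop = reg_of_pop)
  # a locus whose scored individuals span a single region carries no
  # among-region information; treat its missing component as 0
  rowSums(acc, na.rm = TRUE)
}

phi_from_components <- function(cmp, two_level) {
  sa <- cmp["sa"]; sb <- cmp["sb"]; sc <- cmp["sc"]
  if (two_level) {
    tot <- sb + sc
    c(phi_ct = NA_real_, phi_sc = NA_real_,
      phi_st = unname(sb / tot))
  } else {
    tot <- sa + sb + sc
    c(phi_ct = unname(sa / tot), phi_sc = unname(sb / (sb + sc)),
      phi_st = unname((sa + sb) / tot))
  }
}

#' Hierarchical AMOVA with Phi-statistics
#'
#' Three-level analysis of molecular variance (among regions / among
#' populations within regions / within populations) on haploid allele
#' mismatch distances, computed as a weighted average over loci: each
#' locus contributes sums of squares and variance components from the
#' individuals scored at it (pairwise per-locus deletion of missing data),
#' and components are summed across loci. Degrees of freedom are reported
#' for the full design. With a single region the analysis reduces to the
#' two-level design and only Phi_ST is defined.
#'
#' Permutation tests use the standard schemes: Phi_ST, individuals permuted
#' across all populations; Phi_SC, individuals permuted among populations
#' within regions; Phi_CT, whole populations permuted among regions.
#' p = (count >= observed + 1) / (n_perm + 1).
#'
#' @param data a \code{genpop_data} object
#' @param n_perm permutations per statistic (default 20000; 0 skips tests)
#' @param seed integer seed
#' @return object of class \code{"amova_result"}: \code{table} (data.frame
#'   with stratum, df, SS, sigma2, pct), \code{phi} (named vector),
#'   \code{p} (named vector), \code{n_perm}
#' @export
amova <- function(data, n_perm = 20000L, seed = 1L) {
  calls <- data$calls
  pops <- levels(data$population)
  regs <- unique(unname(data$region_of))
  pop <- as.integer(data$population)
  reg_of_pop <- match(data$region_of[pops], regs)
  two_level <- length(regs) < 2L
  N <- nrow(calls); P <- length(pops); G <- length(regs)
  blocks <- locus_blocks(calls)
  cmp <- amova_components(blocks, pop, reg_of_pop)
  phi <- phi_from_components(cmp, two_level)
  if (two_level) {
    tab <- data.frame(
      stratum = c("among_populations", "within_populations", "total"),
      df = c(P - 1, N - P, N - 1),
      SS = unname(c(cmp["ss_ap"], cmp["ss_wp"], cmp["ss_total"])),
      sigma2 = unname(c(cmp["sb"], cmp["sc"], cmp["sb"] + cmp["sc"])),
      stringsAsFactors = FALSE)
    tot <- cmp["sb"] + cmp["sc"]
  } else {
    tab <- data.frame(
      stratum = c("among_regions", "among_populations_within_regions",
                  "within_populations", "total"),
      df = c(G - 1, P - G, N - P, N - 1),
      SS = unname(c(cmp["ss_ar"], cmp["ss_ap"], cmp["ss_wp"],
                    cmp["ss_total"])),
      sigma2 = unname(c(cmp["sa"], cmp["sb"], cmp["sc"],
                        cmp["sa"] + cmp["sb"] + cmp["sc"])),
      stringsAsFactors = FALSE)
    tot <- cmp["sa"] + cmp["sb"] + cmp["sc"]
  }
  tab$pct <- 100 * tab$sigma2 / unname(tot)
  tab$pct[nrow(tab)] <- NA
  if (any(tab$sigma2[-nrow(tab)] < 0, na.rm = TRUE))
    attr(tab, "note") <- "negative variance component(s) reported raw"
  p <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (n_perm > 0L) {
    set.seed(seed)
    cnt <- c(0L, 0L, 0L)
    # Phi_ST: permute individuals across all populations
    for (b in seq_len(n_perm)) {
      pp <- pop[sample.int(N)]
      st <- phi_from_components(amova_components(blocks, pp, reg_of_pop),
                                two_level)["phi_st"]
      if (!is.na(st) && st >= phi["phi_st"] - 1e-12) cnt[3] <- cnt[3] + 1L
    }
    p["phi_st"] <- (cnt[3] + 1) / (n_perm + 1)
    if (!two_level) {
      # Phi_SC: permute individuals among populations within regions
      reg_ind <- reg_of_pop[pop]
      for (b in seq_len(n_perm)) {
        pp <- pop
        for (r in seq_len(G)) {
          i <- which(reg_ind == r)
          pp[i] <- pop[i][sample.int(length(i))]
        }
        sc <- phi_from_components(amova_components(blocks, pp, reg_of_pop),
                                  two_level)["phi_sc"]
        if (!is.na(sc) && sc >= phi["phi_sc"] - 1e-12) cnt[2] <- cnt[2] + 1L
      }
      p["phi_sc"] <- (cnt[2] + 1) / (n_perm + 1)
      # Phi_CT: permute whole populations among regions
      for (b in seq_len(n_perm)) {
        rr <- reg_of_pop[sample.int(P)]
        ct <- phi_from_components(amova_components(blocks, pop, rr),
                                  length(unique(rr)) < 2L)["phi_ct"]
        if (!is.na(ct) && ct >= phi["phi_ct"] - 1e-12) cnt[1] <- cnt[1] + 1L
      }
      p["phi_ct"] <- (cnt[1] + 1) / (n_perm + 1)
    }
  }
  structure(list(table = tab, phi = phi, p = p, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (haploid mismatch distance, summed over loci)\n")
  print(x$table, row.names = FALSE, digits = 4)
  phis <- sprintf("%s = %.4f (p = %s)", names(x$phi), x$phi,
                  ifelse(is.na(x$p), "NA", format(x$p, digits = 3)))
  cat(paste(phis, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise population F_ST (Phi_ST) matrix
#'
#' Each population pair is analyzed as a two-group one-level AMOVA on the
#' haploid mismatch distance; significance by permuting individuals between
#' the two populations.
#'
#' @param data a \code{genpop_data} object
#' @param n_perm permutations per pair (0 skips tests)
#' @param seed integer seed
#' @param adjust_bh apply Benjamini-Hochberg adjustment across pairs
#' @return list with \code{fst} and \code{p} (symmetric matrices with zero
#'   / NA diagonals) and \code{n_perm}
#' @export
pairwise_fst <- function(data, n_perm = 999L, seed = 1L, adjust_bh = FALSE) {
  pops <- levels(data$population)
  P <- length(pops)
  fst <- matrix(0, P, P, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    sel <- data$population %in% pops[c(i, j)]
    if (sum(data$population == pops[i]) < 2L ||
        sum(data$population == pops[j]) < 2L) {
      fst[i, j] <- fst[j, i] <- NA_real_
      next
    }
    calls <- data$calls[sel, , drop = FALSE]
    grp <- as.integer(droplevels(data$population[sel]))
    blocks <- locus_blocks(calls)
    reg1 <- c(1L, 1L)
    obs <- phi_from_components(amova_components(blocks, grp, reg1),
                               TRUE)["phi_st"]
    fst[i, j] <- fst[j, i] <- unname(obs)
    if (n_perm > 0L && !is.na(obs)) {
      n <- length(grp); cnt <- 0L
      for (b in seq_len(n_perm)) {
        st <- phi_from_components(
          amova_components(blocks, grp[sample.int(n)], reg1),
          TRUE)["phi_st"]
        if (!is.na(st) && st >= obs - 1e-12) cnt <- cnt + 1L
      }
      pv[i, j] <- pv[j, i] <- (cnt + 1) / (n_perm + 1)
    }
  }
  if (adjust_bh) {
    up <- upper.tri(pv)
    pv[up] <- stats::p.adjust(pv[up], "BH")
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  list(fst = fst, p = pv, n_perm = n_perm)
}
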