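#' Run the full analysis pipeline
#'
#' Executes every stage on a dataset — mating-type tests, diversity and
#' rarefied richness, multilocus linkage, hierarchical AMOVA and pairwise
#' FST, DAPC, isolation by distance, SAShA and geographically restricted
#' alleles — writes one CSV per stage plus a consolidated
#' \code{report.json}, and returns the results. Stages run independently: a
#' failure is recorded in the report and the remaining stages continue.
#' Every stochastic stage derives its own seed substream from the global
#' seed and the stage name, so per-stage results do not depend on execution
#' order. Identical inputs and seed give an identical report.
#'
#' @param data a \code{genpop_data} object (with sites for the spatial
#'   stages)
#' @param mat optional mating-type data.frame; NULL disables that stage
#' @param out_dir output directory for CSVs and report.json, or NULL to
#'   skip writing
#' @param seed global seed
#' @param g_pop,g_region rarefaction sizes (NULL = data-driven default)
#' @param n_perm_linkage,n_perm_amova,n_perm_fst,n_perm_mantel,n_perm_sasha
#'   permutation counts per stage
#' @param n_boot_gra bootstrap draws for the allele-centroid test
#' @param k_max maximum K explored by the clustering stage
#' @return list of stage results plus \code{report} (the report list)
#' @export
run_all <- function(data, mat = NULL, out_dir = NULL, seed = 1L,
                    g_pop = NULL, g_region = NULL,
                    n_perm_linkage = 999L, n_perm_amova = 20000L,
                    n_perm_fst = 999L, n_perm_mantel = 999L,
                    n_perm_sasha = 1000L, n_boot_gra = 1000L,
                    k_max = 10L) {
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  report <- list(schema = "haplopop-report/1", seed = seed,
                 n_individuals = n_individuals(data),
                 n_loci = n_loci(data),
                 n_populations = nlevels(data$population),
                 n_regions = length(unique(data$region_of)))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  wcsv <- function(df, file) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }

  if (!is.null(mat)) {
    res$mat <- stage("mat", mat_ratio_tests(mat, data))
    res$heterothallism <- stage("mat", heterothallism_check(mat))
    if (!is.null(res$mat)) {
      wcsv(res$mat, "mat_tests.csv")
      all_row <- res$mat[res$mat$population == "ALL", ]
      report$mat <- list(
        n1 = all_row$n1, n2 = all_row$n2, chi2 = all_row$chi2,
        p_chi2 = all_row$p_chi2,
        success_fraction = res$heterothallism$success_fraction,
        n_violations = length(res$heterothallism$violations))
    }
  }

  res$diversity <- stage("diversity",
                         diversity_table(data, g_pop = g_pop,
                                         g_region = g_region))
  if (!is.null(res$diversity)) {
    wcsv(res$diversity, "diversity.csv")
    popd <- res$diversity[res$diversity$level == "population", ]
    regd <- res$diversity[res$diversity$level == "region", ]
    report$diversity <- list(
      uh_mean = mean(popd$uh_mean), AR_mean = mean(popd$AR_mean),
      PAR_mean = mean(popd$PAR_mean), g_pop = popd$g[1],
      g_region = regd$g[1],
      regional = stats::setNames(
        lapply(seq_len(nrow(regd)), function(i)
          list(AR = regd$AR_mean[i], PAR = regd$PAR_mean[i])),
        regd$stratum))
  }

  res$linkage <- stage("linkage",
                       linkage_table(data, n_perm = n_perm_linkage,
                                     seed = derive_seed(seed, "linkage")))
  if (!is.null(res$linkage)) {
    wcsv(res$linkage, "linkage.csv")
    report$linkage <- list(rBarD_mean = mean(res$linkage$rBarD, na.rm = TRUE),
                           n_significant = sum(res$linkage$p < 0.05,
                                               na.rm = TRUE),
                           n_mlg_total = find_mlgs(data)$n_mlg,
                           n_perm = n_perm_linkage)
  }

  res$amova <- stage("amova",
                     amova(data, n_perm = n_perm_amova,
                           seed = derive_seed(seed, "amova")))
  if (!is.null(res$amova)) {
    tab <- res$amova$table
    tab$phi <- c(res$amova$phi[seq_len(nrow(tab) - 1)], NA)
    tab$p <- c(res$amova$p[seq_len(nrow(tab) - 1)], NA)
    wcsv(tab, "amova.csv")
    report$amova <- list(df = tab$df, pct = tab$pct,
                         phi = as.list(res$amova$phi),
                         p = as.list(res$amova$p), n_perm = n_perm_amova)
  }

  res$fst <- stage("fst",
                   pairwise_fst(data, n_perm = n_perm_fst,
                                seed = derive_seed(seed, "fst")))
  if (!is.null(res$fst)) {
    if (!is.null(out_dir)) {
      utils::write.csv(res$fst$fst, file.path(out_dir, "fst_matrix.csv"))
      utils::write.csv(res$fst$p, file.path(out_dir, "fst_pvalues.csv"))
    }
    off <- res$fst$fst[lower.tri(res$fst$fst)]
    report$fst <- list(min = min(off, na.rm = TRUE),
                       max = max(off, na.rm = TRUE),
                       mean = mean(off, na.rm = TRUE),
                       n_significant = sum(res$fst$p[lower.tri(res$fst$p)] <
                                             0.05, na.rm = TRUE),
                       n_perm = n_perm_fst)
  }

  res$dapc <- stage("dapc",
                    dapc(data, k_max = k_max,
                         seed = derive_seed(seed, "dapc")))
  if (!is.null(res$dapc)) {
    wcsv(res$dapc$bic, "dapc_bic.csv")
    wcsv(data.frame(sample_id = rownames(data$calls),
                    cluster = res$dapc$cluster,
                    res$dapc$membership, check.names = FALSE),
         "dapc_memberships.csv")
    if (!is.null(res$dapc$coords))
      wcsv(data.frame(sample_id = rownames(data$calls), res$dapc$coords),
           "dapc_coords.csv")
    wcsv(as.data.frame.matrix(res$dapc$cluster_by_population),
         "cluster_by_population.csv")
    report$dapc <- list(k_opt = res$dapc$k_opt, n_pca = res$dapc$n_pca,
                        min_max_membership =
                          min(apply(res$dapc$membership, 1, max)))
  }

  if (!is.null(data$sites)) {
    res$ibd <- stage("ibd", {
      fp <- allele_frequencies(data)
      gen <- edwards_distance(fp)
      geo <- geo_distance_matrix(
        data$sites$latitude[match(rownames(gen), data$sites$population)],
        data$sites$longitude[match(rownames(gen), data$sites$population)])
      dimnames(geo) <- dimnames(gen)
      man <- mantel_ibd(gen, geo, n_perm = n_perm_mantel,
                        seed = derive_seed(seed, "mantel"))
      kde <- distance_pair_kde(gen, geo)
      list(gen = gen, geo = geo, mantel = man, kde = kde)
    })
    if (!is.null(res$ibd)) {
      pairs <- which(lower.tri(res$ibd$gen), arr.ind = TRUE)
      wcsv(data.frame(pop1 = rownames(res$ibd$gen)[pairs[, 1]],
                      pop2 = colnames(res$ibd$gen)[pairs[, 2]],
                      gen_dist = res$ibd$gen[pairs],
                      geo_km = res$ibd$geo[pairs]), "ibd.csv")
      report$ibd <- list(mantel_r = res$ibd$mantel$r,
                         mantel_p = res$ibd$mantel$p,
                         n_perm = n_perm_mantel)
    }

    res$sasha <- stage("sasha",
                       sasha(data, n_perm = n_perm_sasha,
                             seed = derive_seed(seed, "sasha")))
    if (!is.null(res$sasha)) {
      wcsv(data.frame(subset = "all",
                      observed_mean = res$sasha$observed_mean_km,
                      expected_mean = res$sasha$expected_mean_km,
                      p = res$sasha$p), "sasha_summary.csv")
      report$sasha <- list(observed_mean_km = res$sasha$observed_mean_km,
                           expected_mean_km = res$sasha$expected_mean_km,
                           p = res$sasha$p, n_perm = n_perm_sasha)
    }

    res$gra <- stage("gra",
                     detect_gra(data, n_boot = n_boot_gra,
                                seed = derive_seed(seed, "gra")))
    if (!is.null(res$gra)) {
      wcsv(res$gra, "gra.csv")
      restricted <- res$gra[res$gra$restricted, c("locus", "allele")]
      report$gra <- list(n_alleles = nrow(res$gra),
                         n_restricted = nrow(restricted),
                         pct_restricted = 100 * nrow(restricted) /
                           nrow(res$gra),
                         n_boot = n_boot_gra)
      if (nrow(restricted) > 0 && !is.null(res$sasha)) {
        res$sasha_gra <- stage("sasha", sasha(
          data, n_perm = n_perm_sasha,
          seed = derive_seed(seed, "sasha_gra"), subset = restricted))
        if (!is.null(res$sasha_gra))
          report$gra$observed_mean_km <- res$sasha_gra$observed_mean_km
        if (!is.null(res$sasha_gra))
          report$gra$expected_mean_km <- res$sasha_gra$expected_mean_km
        if (!is.null(res$sasha_gra))
          report$gra$p <- res$sasha_gra$p
      }
    }
  }

  if (length(errors)) report$errors <- errors
  res$report <- report
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  res
}
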