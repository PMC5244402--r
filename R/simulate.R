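#' Configuration for the hierarchical haploid SSR simulator
#'
#' The generator draws allele frequencies down a three-level hierarchy
#' (ancestral pool -> regional pools -> population pools) using
#' Balding-Nichols compound Dirichlet steps, then optionally applies founder
#' truncation, directed migration admixture and distance-decay mixing before
#' sampling individuals.
#'
#' @param regions list of regions; each region is a list with \code{name}
#'   and \code{populations}, itself a list of populations, each with
#'   \code{name}, \code{n}, \code{latitude}, \code{longitude} and optional
#'   \code{founder_k} (cap on distinct founding alleles per locus).
#' @param n_loci number of unlinked loci.
#' @param alleles_range integer range (min, max) of the ancestral allele
#'   inventory per locus; the realized inventory per locus is drawn
#'   uniformly in this range.
#' @param F_region,F_pop Balding-Nichols differentiation parameters (in
#'   [0, 1)) of the regional pools around the ancestral pool and of the
#'   population pools around their regional pool; roughly the expected
#'   FST contributed at each level.
#' @param migration square matrix (regions x regions, dimnames = region
#'   names) of directed admixture rates: population frequencies in region r
#'   become \code{(1 - sum_in) p + sum_s migration[s, r] * pool_s}. Row
#'   sums into any region must be <= 1. \code{NULL} = no migration.
#' @param ibd_decay mixing strength in [0, 1] pulling each population's
#'   frequencies toward a distance-weighted average of the others
#'   (weights \code{exp(-d/ibd_scale)}), creating isolation by distance.
#' @param ibd_scale e-folding distance (km) of the mixing weights.
#' @param clonality_rate probability that an individual is an exact
#'   multilocus copy of a previously drawn individual of its population.
#' @param linkage_rho probability that a locus call copies the
#'   frequency-rank of the call at the previous locus, inducing multilocus
#'   association detectable by rBarD.
#' @param missing_rate per-call missing probability.
#' @param mat_ratio probability of the MAT1-1 idiomorph.
#' @param mat_fail_rate probability that MAT amplification fails
#'   (idiomorph recorded as NONE).
#' @param seed integer seed governing all draws.
#' @return a list of class \code{"sim_config"}
#' @export
sim_config <- function(regions, n_loci = 8L, alleles_range = c(16L, 46L),
                       F_region = 0.01, F_pop = 0.01, migration = NULL,
                       ibd_decay = 0, ibd_scale = 700, clonality_rate = 0,
                       linkage_rho = 0, missing_rate = 0.03,
                       mat_ratio = 0.5, mat_fail_rate = 0, seed = 1L) {
  stopifnot(length(regions) >= 1L, n_loci >= 1L,
            alleles_range[1] >= 1L, alleles_range[2] >= alleles_range[1])
  probs <- c(F_region, F_pop, ibd_decay, clonality_rate, linkage_rho,
             missing_rate, mat_ratio, mat_fail_rate)
  if (any(probs < 0 | probs > 1)) stop("all rates must lie in [0, 1]")
  rnames <- vapply(regions, `[[`, "", "name")
  if (!is.null(migration)) {
    migration <- as.matrix(migration)
    if (!identical(dim(migration), c(length(rnames), length(rnames))))
      stop("migration must be a regions x regions matrix")
    if (is.null(dimnames(migration)))
      dimnames(migration) <- list(rnames, rnames)
    if (any(migration < 0 | migration > 1) || any(colSums(migration) > 1))
      stop("migration rates must be in [0,1] with column sums <= 1")
  }
  for (r in regions)
    for (p in r$populations)
      stopifnot(p$n >= 1L, abs(p$latitude) <= 90, abs(p$longitude) <= 180)
  structure(list(regions = regions, n_loci = as.integer(n_loci),
                 alleles_range = as.integer(alleles_range),
                 F_region = F_region, F_pop = F_pop, migration = migration,
                 ibd_decay = ibd_decay, ibd_scale = ibd_scale,
                 clonality_rate = clonality_rate, linkage_rho = linkage_rho,
                 missing_rate = missing_rate, mat_ratio = mat_ratio,
                 mat_fail_rate = mat_fail_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation design: 2 regions, 11 populations, 220 haploids
#'
#' Mirrors the sampling design of a Mediterranean mainland / Macaronesian
#' island survey of a strictly sexual epiphytic lichen fungus: 3 island and
#' 8 mainland populations (8-29 samples each, 220 in total, mean 20), 8
#' hypervariable unlinked loci with ancestral inventories of 16-46 alleles,
#' 3\% missing calls, balanced mating types with 7\% amplification failure,
#' island founder effects (10 founding alleles per locus) with weak
#' asymmetric mainland-to-island migration, and distance-decay mixing over a
#' ~3,000 km extent producing isolation by distance. Coordinates are
#' synthetic approximations of the named localities.
#'
#' @param seed integer seed
#' @param ... overrides passed on to \code{\link{sim_config}}
#' @return a \code{\link{sim_config}}
#' @export
island_mainland_config <- function(seed = 1L, ...) {
  pop <- function(name, n, lat, lon, founder_k = NULL)
    list(name = name, n = as.integer(n), latitude = lat, longitude = lon,
         founder_k = founder_k)
  regions <- list(
    list(name = "island", populations = list(
      pop("Tenerife",      25, 28.32, -16.54, founder_k = 10L),
      pop("GranCanaria1",  20, 28.06, -15.58, founder_k = 10L),
      pop("GranCanaria2",  20, 27.95, -15.57, founder_k = 10L))),
    list(name = "mainland", populations = list(
      pop("Morocco",   20, 33.43, -5.10),
      pop("Cadiz",      8, 36.50, -5.60),
      pop("Marvao",    21, 39.40, -7.38),
      pop("Covilha",   17, 40.28, -7.50),
      pop("Famalicao", 29, 40.35, -7.55),
      pop("Gredos",    25, 40.25, -5.14),
      pop("Herbes",    14, 40.72,  0.03),
      pop("Sicily",    21, 37.90, 14.00))))
  migration <- matrix(0, 2, 2, dimnames = list(c("island", "mainland"),
                                               c("island", "mainland")))
  migration["mainland", "island"] <- 0.05
  defaults <- list(regions = regions, n_loci = 8L,
                   alleles_range = c(16L, 46L), F_region = 0.01,
                   F_pop = 0.01, migration = migration, ibd_decay = 0.6,
                   ibd_scale = 500, clonality_rate = 0, linkage_rho = 0,
                   missing_rate = 0.03, mat_ratio = 0.5,
                   mat_fail_rate = 0.07, seed = seed)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

# flatten the region/population tree into a data.frame
config_sites <- function(config) {
  do.call(rbind, lapply(config$regions, function(r)
    do.call(rbind, lapply(r$populations, function(p)
      data.frame(population = p$name, region = r$name,
                 latitude = p$latitude, longitude = p$longitude,
                 n = p$n,
                 founder_k = if (is.null(p$founder_k)) NA_integer_
                             else as.integer(p$founder_k),
                 stringsAsFactors = FALSE)))))
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1   # degenerate concentration
  x / sum(x)
}

# Balding-Nichols compound draw: child frequencies around parent p with
# differentiation F; F = 0 returns the parent unchanged.
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  rdirichlet1(p * (1 - F) / F)
}

#' Simulate a haploid SSR dataset
#'
#' Draws allele frequencies down the configured hierarchy and samples
#' individuals, then applies (in this order) clonal copying, locus-to-locus
#' rank linkage and missingness. All randomness flows from
#' \code{config$seed}; identical configurations yield identical output.
#'
#' @param config a \code{\link{sim_config}}
#' @return a list with elements \code{data}
#'   (\code{\link{genotype_dataset}}), \code{sites} (data.frame),
#'   \code{mat} (data.frame sample_id/idiomorph) and \code{truth}, a list
#'   recording the latent state: per-locus allele inventories, ancestral /
#'   regional / final population frequencies, the clone map (index of the
#'   copied individual or NA), linkage event positions, the missing mask
#'   and the pre-failure idiomorph of every individual.
#' @export
simulate_ssr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- config_sites(config)
  pops <- sites$population
  P <- length(pops)
  rnames <- vapply(config$regions, `[[`, "", "name")
  L <- config$n_loci

  inventory <- list(); anc <- list(); regional <- list(); popfreq <- list()
  for (l in seq_len(L)) {
    K <- sample(config$alleles_range[1]:config$alleles_range[2], 1L)
    # dinucleotide-style ladder of fragment sizes
    start <- sample(80:180, 1L)
    inventory[[l]] <- start + 2L * (0:(K - 1L))
    anc[[l]] <- rdirichlet1(rep(1, K))
    regional[[l]] <- vapply(rnames, function(r)
      bn_draw(anc[[l]], config$F_region), numeric(K))
    popfreq[[l]] <- vapply(seq_len(P), function(i)
      bn_draw(regional[[l]][, sites$region[i]], config$F_pop), numeric(K))
    colnames(popfreq[[l]]) <- pops
  }

  # distance-decay mixing toward neighboring populations (isolation by
  # distance); applied before founder truncation so founder effects persist
  if (config$ibd_decay > 0 && P > 1L) {
    D <- geo_distance_matrix(sites$latitude, sites$longitude)
    W <- exp(-D / config$ibd_scale)
    diag(W) <- 0
    W <- sweep(W, 1, pmax(rowSums(W), .Machine$double.eps), "/")
    lam <- config$ibd_decay
    for (l in seq_len(L))
      popfreq[[l]] <- (1 - lam) * popfreq[[l]] +
        lam * popfreq[[l]] %*% t(W)
  }

  for (l in seq_len(L)) {
    for (i in seq_len(P)) {
      k <- sites$founder_k[i]
      if (!is.na(k)) {
        # founder event: truncate to the k most frequent alleles (founders
        # carry the common alleles; the rare tail is lost) and renormalize
        K <- nrow(popfreq[[l]])
        k <- min(k, K)
        keep <- order(popfreq[[l]][, i], decreasing = TRUE)[seq_len(k)]
        p <- numeric(K); p[keep] <- popfreq[[l]][keep, i]
        popfreq[[l]][, i] <- p / sum(p)
      }
    }
    if (!is.null(config$migration)) {  # directed admixture from region pools
      for (i in seq_len(P)) {
        r <- sites$region[i]
        m <- config$migration[, r]
        if (sum(m) > 0)
          popfreq[[l]][, i] <- (1 - sum(m)) * popfreq[[l]][, i] +
            as.numeric(regional[[l]] %*% m)
      }
    }
  }

  N <- sum(sites$n)
  ids <- unlist(lapply(seq_len(P), function(i)
    sprintf("%s_%02d", pops[i], seq_len(sites$n[i]))))
  popvec <- rep(pops, sites$n)
  calls <- matrix(NA_integer_, N, L,
                  dimnames = list(ids, paste0("Loc", seq_len(L))))
  for (i in seq_len(P)) {
    rows <- which(popvec == pops[i])
    for (l in seq_len(L))
      calls[rows, l] <- sample(inventory[[l]], length(rows), replace = TRUE,
                               prob = popfreq[[l]][, i])
  }

  # clonal copying within population
  clone_of <- rep(NA_integer_, N)
  if (config$clonality_rate > 0) {
    for (i in seq_len(P)) {
      rows <- which(popvec == pops[i])
      for (j in seq_along(rows)[-1]) {
        if (stats::runif(1) < config$clonality_rate) {
          src <- rows[sample.int(j - 1L, 1L)]
          calls[rows[j], ] <- calls[src, ]
          clone_of[rows[j]] <- src
        }
      }
    }
  }

  # rank linkage: locus l copies the frequency-rank of locus l-1
  linkage_events <- matrix(FALSE, N, L)
  if (config$linkage_rho > 0 && L > 1L) {
    ranks <- lapply(seq_len(L), function(l)
      lapply(seq_len(P), function(i)
        order(popfreq[[l]][, i], decreasing = TRUE)))
    for (n in seq_len(N)) {
      i <- match(popvec[n], pops)
      for (l in 2:L) {
        if (stats::runif(1) < config$linkage_rho) {
          prev_rank <- match(match(calls[n, l - 1L], inventory[[l - 1L]]),
                             ranks[[l - 1L]][[i]])
          pos <- min(prev_rank, length(inventory[[l]]))
          calls[n, l] <- inventory[[l]][ranks[[l]][[i]][pos]]
          linkage_events[n, l] <- TRUE
        }
      }
    }
  }

  miss <- matrix(stats::runif(N * L) < config$missing_rate, N, L)
  calls[miss] <- NA_integer_

  idio_latent <- ifelse(stats::runif(N) < config$mat_ratio,
                        "MAT1-1", "MAT1-2")
  idio <- ifelse(stats::runif(N) < config$mat_fail_rate, "NONE", idio_latent)
  mat <- data.frame(sample_id = ids, idiomorph = idio,
                    stringsAsFactors = FALSE)

  region_map <- structure(sites$region, names = sites$population)
  data <- genotype_dataset(calls, popvec, region_map,
                           sites = sites[, c("population", "region",
                                             "latitude", "longitude")])
  truth <- list(inventory = inventory, ancestral = anc,
                regional = regional, popfreq = popfreq,
                clone_of = clone_of, linkage_events = linkage_events,
                missing_mask = miss, idiomorph_latent = idio_latent,
                config = config)
  list(data = data, sites = data$sites, mat = mat, truth = truth)
}

#' Write a simulated dataset to canonical CSVs plus a truth file
#'
#' @param sim result of \code{\link{simulate_ssr}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$data, file.path(dir, "genotypes.csv"))
  utils::write.csv(sim$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$mat, file.path(dir, "mat.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "columnmajor")
  invisible(dir)
}
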