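EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix (km)
#'
#' Haversine distances on the mean Earth radius (6371.0088 km).
#'
#' @param lat,lon numeric vectors of decimal-degree coordinates
#' @return symmetric matrix of distances in km
#' @export
geo_distance_matrix <- function(lat, lon) {
  n <- length(lat)
  pts <- cbind(lon, lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    D[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = EARTH_RADIUS_KM)
  (D + t(D)) / 2
}

#' Edwards' chord genetic distance between populations
#'
#' \deqn{D_E(1,2) = \sqrt{1 - \frac{1}{L}\sum_l \sum_a
#'   \sqrt{p_{1la} \, p_{2la}}}}
#' Loci where either population has no scored call are excluded for that
#' pair, with L reduced accordingly; a pair with no shared scored locus
#' gets NA.
#'
#' @param freqs an \code{\link{allele_frequencies}} table
#' @return symmetric matrix of chord distances in [0, 1]
#' @export
edwards_distance <- function(freqs) {
  strata <- attr(freqs, "strata")
  S <- length(strata)
  D <- matrix(0, S, S, dimnames = list(strata, strata))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    sims <- vapply(freqs, function(l) {
      if (l$n[i] == 0L || l$n[j] == 0L) return(NA_real_)
      sum(sqrt(l$freq[, i] * l$freq[, j]))
    }, 0)
    sims <- sims[!is.na(sims)]
    D[i, j] <- D[j, i] <-
      if (length(sims) == 0L) NA_real_
      else sqrt(max(0, 1 - mean(sims)))
  }
  D
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation of the lower triangles of a genetic and a geographic
#' distance matrix, with significance from simultaneous row/column
#' permutations of one matrix (one-sided, positive association),
#' p = (b + 1)/(B + 1).
#'
#' @param gen,geo symmetric distance matrices over the same populations
#' @param n_perm permutations
#' @param seed integer seed
#' @return list: r, p, n_perm
#' @export
mantel_ibd <- function(gen, geo, n_perm = 999L, seed = 1L) {
  stopifnot(identical(dim(gen), dim(geo)))
  if (stats::sd(gen[lower.tri(gen)]) == 0 ||
      stats::sd(geo[lower.tri(geo)]) == 0)
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm))
  set.seed(seed)
  m <- vegan::mantel(stats::as.dist(geo), stats::as.dist(gen),
                     method = "pearson", permutations = n_perm)
  list(r = unname(m$statistic), p = unname(m$signif), n_perm = n_perm)
}

#' 2-D kernel density of (geographic, genetic) distance pairs
#'
#' Gaussian product-kernel density over the population-pair scatter, with
#' per-axis bandwidths from the normal reference rule and a floor for
#' degenerate axes. Used to check whether genetic differentiation forms a
#' single continuous cloud (a cline) or separate clouds (patchiness).
#'
#' @param gen,geo symmetric distance matrices
#' @param grid grid resolution per axis
#' @return list: x (geo grid), y (gen grid), z (density), h (bandwidths)
#' @export
distance_pair_kde <- function(gen, geo, grid = 100L) {
  gx <- geo[lower.tri(geo)]
  gy <- gen[lower.tri(gen)]
  keep <- is.finite(gx) & is.finite(gy)
  gx <- gx[keep]; gy <- gy[keep]
  if (length(gx) < 3L) stop("need at least 3 distance pairs")
  bw <- function(v) {
    h <- tryCatch(MASS::bandwidth.nrd(v), error = function(e) 0)
    if (!is.finite(h) || h <= 0)
      h <- max(stats::sd(v), 1e-3 * max(abs(v), 1)) # degenerate-axis floor
    h
  }
  h <- c(bw(gx), bw(gy))
  lims <- c(range(gx) + c(-3, 3) * h[1], range(gy) + c(-3, 3) * h[2])
  k <- MASS::kde2d(gx, gy, h = h, n = grid, lims = lims)
  list(x = k$x, y = k$y, z = k$z, h = h)
}

# site coordinates per individual, in the order of data$calls rows
individual_sites <- function(data) {
  if (is.null(data$sites))
    stop("dataset has no sites table; coordinates required")
  i <- match(as.character(data$population), data$sites$population)
  data.frame(site = as.character(data$population),
             latitude = data$sites$latitude[i],
             longitude = data$sites$longitude[i])
}

# per-locus site-composition machinery used by SAShA: with all individuals
# of a sampling site sharing its coordinates, every pairwise distance is a
# site-pair distance, so pair sums reduce to quadratic forms in per-site
# carrier counts.
site_pair_sum <- function(counts, S) {
  # counts: alleles x sites matrix; S: site x site distance matrix
  sum((counts %*% S) * counts) / 2
}

#' Spatial analysis of shared alleles (SAShA)
#'
#' Compares the geographic distances between pairs of individuals sharing
#' an allele (aggregated over alleles and loci; a pair sharing alleles at
#' several loci contributes once per shared allele) with the panmictic
#' expectation: the distances between all pairs of individuals scored at
#' the locus, aggregated over loci. Under panmixia the two distributions
#' coincide. The permutation null reassigns the allele column among scored
#' individuals within each locus; the one-sided p tests observed mean <
#' expected (spatial under-dispersion of shared alleles); a two-sided p is
#' also returned.
#'
#' @param data a \code{genpop_data} object with a sites table
#' @param n_perm permutations
#' @param seed integer seed
#' @param subset optional data.frame (locus, allele) restricting the
#'   observed side to those alleles (used for the geographically
#'   restricted subset); the expectation and the permutation null then use
#'   the same allele identities
#' @return list of class \code{"sasha_result"}: observed_mean_km,
#'   expected_mean_km, p (one-sided), p_two_sided, n_perm, observed /
#'   expected distance vectors (km), perm_means
#' @export
sasha <- function(data, n_perm = 1000L, seed = 1L, subset = NULL) {
  sites <- individual_sites(data)
  site_names <- unique(sites$site)
  S <- geo_distance_matrix(
    data$sites$latitude[match(site_names, data$sites$population)],
    data$sites$longitude[match(site_names, data$sites$population)])
  site_idx <- match(sites$site, site_names)
  nsite <- length(site_names)
  L <- ncol(data$calls)
  loci <- colnames(data$calls)

  keep_allele <- function(locus, alleles) {
    if (is.null(subset)) rep(TRUE, length(alleles))
    else alleles %in% subset$allele[subset$locus == locus]
  }

  obs_sum <- 0; obs_n <- 0; exp_sum <- 0; exp_n <- 0
  obs_dist <- list(); exp_dist <- list()
  per_locus <- vector("list", L)
  for (l in seq_len(L)) {
    x <- data$calls[, l]
    scored <- which(!is.na(x))
    if (length(scored) < 2L) next
    al <- sort(unique(x[scored]))
    keep <- keep_allele(loci[l], al)
    if (!any(keep)) next       # locus not involved in the requested subset
    cnt <- table(factor(x[scored], levels = al),
                 factor(site_idx[scored], levels = seq_len(nsite)))
    cnt <- matrix(as.numeric(cnt), nrow = length(al), ncol = nsite)
    use_sites <- seq_len(nsite)
    Ssub <- S
    sel <- cnt[keep, , drop = FALSE]
    obs_sum <- obs_sum + site_pair_sum(sel, Ssub)
    obs_n <- obs_n + sum(choose(rowSums(sel), 2))
    tot <- colSums(cnt)
    exp_sum <- exp_sum + site_pair_sum(matrix(tot, 1), Ssub)
    exp_n <- exp_n + choose(sum(tot), 2)
    # raw distance vectors (site distances expanded by pair counts)
    pair_counts <- function(cvec) {
      m <- tcrossprod(cvec)
      diag(m) <- cvec * (cvec - 1) / 2
      m[lower.tri(m)] <- 0
      m
    }
    dvals <- Ssub[upper.tri(Ssub, diag = TRUE)]
    od <- Reduce(`+`, lapply(seq_len(nrow(sel)), function(a) {
      pc <- pair_counts(sel[a, ])
      pc[upper.tri(pc, diag = TRUE)]
    }), accumulate = FALSE)
    if (!is.null(od)) obs_dist[[l]] <- rep(dvals, od)
    pcx <- pair_counts(tot)
    exp_dist[[l]] <- rep(dvals, pcx[upper.tri(pcx, diag = TRUE)])
    per_locus[[l]] <- list(scored = scored, alleles = al,
                           x = x[scored], use_sites = use_sites,
                           Ssub = Ssub, keep = keep)
  }
  observed_mean <- if (obs_n > 0) obs_sum / obs_n else NaN
  expected_mean <- if (exp_n > 0) exp_sum / exp_n else NaN

  perm_means <- numeric(0)
  p_one <- p_two <- NA_real_
  if (n_perm > 0L && obs_n > 0) {
    set.seed(seed)
    perm_means <- vapply(seq_len(n_perm), function(b) {
      tot_s <- 0; tot_n <- 0
      for (l in seq_len(L)) {
        pl <- per_locus[[l]]
        if (is.null(pl)) next
        xp <- pl$x[sample.int(length(pl$x))]
        cnt <- table(factor(xp, levels = pl$alleles),
                     factor(site_idx[pl$scored],
                            levels = pl$use_sites))
        cnt <- matrix(as.numeric(cnt), nrow = length(pl$alleles))
        sel <- cnt[pl$keep, , drop = FALSE]
        tot_s <- tot_s + site_pair_sum(sel, pl$Ssub)
        tot_n <- tot_n + sum(choose(rowSums(sel), 2))
      }
      if (tot_n > 0) tot_s / tot_n else NaN
    }, 0)
    p_one <- (sum(perm_means <= observed_mean + 1e-12, na.rm = TRUE) + 1) /
      (n_perm + 1)
    dev <- abs(perm_means - mean(perm_means, na.rm = TRUE))
    p_two <- (sum(dev >= abs(observed_mean -
                               mean(perm_means, na.rm = TRUE)) - 1e-12,
                  na.rm = TRUE) + 1) / (n_perm + 1)
  }
  structure(list(observed_mean_km = observed_mean,
                 expected_mean_km = expected_mean,
                 p = p_one, p_two_sided = p_two, n_perm = n_perm,
                 observed = unlist(obs_dist), expected = unlist(exp_dist),
                 perm_means = perm_means),
            class = "sasha_result")
}

#' @export
print.sasha_result <- function(x, ...) {
  cat(sprintf(
    "SAShA: observed mean %.1f km vs panmictic expectation %.1f km (p = %s)\n",
    x$observed_mean_km, x$expected_mean_km,
    ifelse(is.na(x$p), "NA", format(x$p, digits = 3))))
  invisible(x)
}

# azimuthal equidistant projection (km) of site coordinates about the
# centroid of all individuals
project_aeqd <- function(lat, lon, center = NULL) {
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  d <- geosphere::distHaversine(center, cbind(lon, lat), r = EARTH_RADIUS_KM)
  b <- geosphere::bearing(center, cbind(lon, lat)) * pi / 180
  b[is.na(b)] <- 0                      # points at the center
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Geographically restricted alleles by centroid bootstrap
#'
#' For every allele, the observed carrier centroid (mean planar x/y of its
#' carriers, azimuthal-equidistant projection about the data centroid, km)
#' is compared with a null distribution of centroids obtained by drawing
#' N_a individuals without replacement from all individuals scored at the
#' locus, n_boot times. The allele is flagged geographically restricted if
#' its observed centroid falls outside the per-axis 2.5/97.5 percentile
#' interval on at least one axis. An allele carried by every scored
#' individual has a degenerate null and is never flagged.
#'
#' @param data a \code{genpop_data} object with a sites table
#' @param n_boot bootstrap draws per allele (>= 200)
#' @param seed integer seed
#' @param with_replacement resample with replacement instead
#' @return data.frame of class \code{"gra_result"}: locus, allele,
#'   n_carriers, cx, cy, ci_x_lo, ci_x_hi, ci_y_lo, ci_y_hi, restricted
#' @export
detect_gra <- function(data, n_boot = 1000L, seed = 1L,
                       with_replacement = FALSE) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  sites <- individual_sites(data)
  xy <- project_aeqd(sites$latitude, sites$longitude)
  set.seed(seed)
  rows <- list()
  for (l in seq_len(ncol(data$calls))) {
    x <- data$calls[, l]
    scored <- which(!is.na(x))
    al <- sort(unique(x[scored]))
    for (a in al) {
      carriers <- scored[x[scored] == a]
      na <- length(carriers)
      cx <- mean(xy[carriers, 1]); cy <- mean(xy[carriers, 2])
      if (na >= length(scored)) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = colnames(data$calls)[l], allele = a, n_carriers = na,
          cx = cx, cy = cy, ci_x_lo = cx, ci_x_hi = cx, ci_y_lo = cy,
          ci_y_hi = cy, restricted = FALSE, stringsAsFactors = FALSE)
        next
      }
      cents <- vapply(seq_len(n_boot), function(b) {
        i <- scored[sample.int(length(scored), na,
                               replace = with_replacement)]
        c(mean(xy[i, 1]), mean(xy[i, 2]))
      }, numeric(2))
      qx <- stats::quantile(cents[1, ], c(0.025, 0.975), names = FALSE)
      qy <- stats::quantile(cents[2, ], c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = colnames(data$calls)[l], allele = a, n_carriers = na,
        cx = cx, cy = cy, ci_x_lo = qx[1], ci_x_hi = qx[2],
        ci_y_lo = qy[1], ci_y_hi = qy[2],
        restricted = cx < qx[1] || cx > qx[2] || cy < qy[1] || cy > qy[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gra_result", class(out))
  out
}
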