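#' One-hot allele encoding with mean-frequency imputation
#'
#' Individuals x alleles indicator matrix (1 if the individual carries the
#' allele at that locus). A missing call is replaced by the allele's mean
#' relative frequency computed on the whole set of individuals, so that
#' imputation adds no between-group signal. Columns are ordered by (locus,
#' allele ascending).
#'
#' @param data a \code{genpop_data} object
#' @return numeric matrix with rownames = sample ids and colnames
#'   \code{<locus>.<allele>}; attribute \code{locus} gives each column's
#'   locus
#' @export
one_hot_impute <- function(data) {
  calls <- data$calls
  blocks <- lapply(seq_len(ncol(calls)), function(l) {
    x <- calls[, l]
    alleles <- sort(unique(x[!is.na(x)]))
    if (length(alleles) == 0L) return(NULL)
    m <- matrix(0, nrow(calls), length(alleles),
                dimnames = list(rownames(calls),
                                paste0(colnames(calls)[l], ".", alleles)))
    scored <- which(!is.na(x))
    m[cbind(scored, match(x[scored], alleles))] <- 1
    glob <- colSums(m[scored, , drop = FALSE]) / length(scored)
    if (length(scored) < nrow(calls))
      m[is.na(x), ] <- matrix(glob, sum(is.na(x)), length(alleles),
                              byrow = TRUE)
    attr(m, "locus") <- rep(colnames(calls)[l], length(alleles))
    m
  })
  blocks <- Filter(Negate(is.null), blocks)
  out <- do.call(cbind, blocks)
  attr(out, "locus") <- unlist(lapply(blocks, attr, "locus"))
  out
}

# deterministic seed substream for stage/step names
derive_seed <- function(seed, name) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(name)) * 31L) %% 2147483629L
}

#' K-means cluster discovery on principal components with BIC selection
#'
#' Columns of X are centered (not scaled), principal components computed,
#' and k-means run on the leading PCs for K = 1..k_max with multiple
#' restarts. Model choice uses
#' \deqn{BIC(K) = n \ln(WSS_K / n) + K \ln(n)}
#' with WSS the total within-cluster sum of squares in PC space; ties break
#' toward smaller K.
#'
#' @param X matrix from \code{\link{one_hot_impute}} (or any numeric matrix)
#' @param k_max largest number of clusters to try
#' @param n_pca number of PCs to retain for the k-means step; default is
#'   the full rank of the centered matrix. Retaining (essentially) all
#'   components is deliberate: the BIC penalty is calibrated against the
#'   full within-cluster scatter, and discarding dimensions before cluster
#'   discovery makes k-means overfit K. Dimension reduction belongs to the
#'   discriminant step (\code{\link{dapc}}), not here.
#' @param n_starts k-means restarts per K
#' @param seed integer seed
#' @return list: \code{bic} (data.frame K, WSS, BIC), \code{k_opt},
#'   \code{cluster} (integer per individual), \code{n_pca},
#'   \code{pc_scores} (retained PC scores), \code{pca} (the prcomp fit)
#' @export
find_clusters <- function(X, k_max = 10L, n_pca = NULL, n_starts = 50L,
                          seed = 1L) {
  stopifnot(k_max >= 1L)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  rank <- sum(ev > max(ev[1], 1e-300) * 1e-9)
  if (is.null(n_pca)) n_pca <- rank
  if (n_pca > rank) {
    warning("n_pca reduced to the rank of centered X (", rank, ")")
    n_pca <- rank
  }
  S <- pca$x[, seq_len(n_pca), drop = FALSE]
  n <- nrow(S)
  k_max <- min(k_max, n - 1L)
  tot_ss <- sum(scale(S, scale = FALSE)^2)
  # relative floor so that exactly-separable solutions (WSS ~ 0 up to
  # round-off) tie and the tie-break selects the smallest such K
  wss_floor <- max(tot_ss, 1) * 1e-12
  rows <- lapply(seq_len(k_max), function(K) {
    set.seed(derive_seed(seed, paste0("kmeans", K)))
    if (K == 1L) {
      wss <- sum(scale(S, scale = FALSE)^2)
      cl <- rep(1L, n)
    } else {
      km <- tryCatch(stats::kmeans(S, centers = K, nstart = n_starts,
                                   iter.max = 100L),
                     error = function(e) NULL)
      if (is.null(km)) {
        # fewer distinct points than centers: a zero-WSS solution exists
        wss <- 0
        cl <- match(apply(S, 1, paste, collapse = ","),
                    unique(apply(S, 1, paste, collapse = ",")))
      } else {
        wss <- km$tot.withinss
        cl <- km$cluster
      }
    }
    list(K = K, WSS = wss,
         BIC = n * log(max(wss, wss_floor) / n) + K * log(n),
         cluster = cl)
  })
  bic <- data.frame(K = vapply(rows, `[[`, 0, "K"),
                    WSS = vapply(rows, `[[`, 0, "WSS"),
                    BIC = vapply(rows, `[[`, 0, "BIC"))
  k_opt <- bic$K[which.min(bic$BIC)]   # which.min takes the first = smaller K
  list(bic = bic, k_opt = k_opt, cluster = rows[[k_opt]]$cluster,
       n_pca = n_pca, pc_scores = S, pca = pca)
}

# Linear discriminant analysis with a ridge on the pooled within-class
# scatter (epsilon = 1e-8 * mean within variance), so perfectly separated
# clusters (zero within-class variance along some direction) remain
# analyzable. Discriminant vectors v solve W^-1 B v = lambda v and are
# scaled to unit within-class variance, making the within-class covariance
# in discriminant space the identity.
ridge_lda <- function(S, grp) {
  grp <- as.integer(factor(grp))
  K <- max(grp)
  n <- nrow(S); d <- ncol(S)
  mu <- rowsum(S, grp) / as.vector(table(grp))
  Sw <- matrix(0, d, d)
  for (k in seq_len(K)) {
    Xc <- sweep(S[grp == k, , drop = FALSE], 2, mu[k, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - K)
  eps <- 1e-8 * mean(diag(Sw)) + 1e-300
  Sw <- Sw + diag(eps, d)
  gm <- colMeans(S)
  Sb <- matrix(0, d, d)
  for (k in seq_len(K)) {
    dk <- mu[k, ] - gm
    Sb <- Sb + sum(grp == k) * tcrossprod(dk)
  }
  Sb <- Sb / n
  eW <- eigen(Sw, symmetric = TRUE)
  W_half_inv <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, eps)), d) %*%
    t(eW$vectors)
  M <- W_half_inv %*% Sb %*% W_half_inv
  eM <- eigen(M, symmetric = TRUE)
  r <- min(K - 1L, d)
  V <- W_half_inv %*% eM$vectors[, seq_len(r), drop = FALSE]
  # unit within-class variance per discriminant axis
  for (j in seq_len(r)) {
    s2 <- as.numeric(t(V[, j]) %*% Sw %*% V[, j])
    V[, j] <- V[, j] / sqrt(s2)
  }
  scores <- sweep(S, 2, gm) %*% V
  centers <- rowsum(scores, grp) / as.vector(table(grp))
  prior <- as.vector(table(grp)) / n
  # Gaussian posteriors with identity covariance in discriminant space
  d2 <- vapply(seq_len(K), function(k)
    rowSums(sweep(scores, 2, centers[k, ])^2), numeric(n))
  logp <- sweep(-0.5 * d2, 2, log(prior), "+")
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  list(scores = scores, vectors = V, centers = centers, posterior = post,
       eigenvalues = eM$values[seq_len(r)], epsilon = eps)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Fits linear discriminant functions to the retained principal components
#' using the cluster labels from \code{\link{find_clusters}} (or any
#' grouping), retaining K - 1 discriminant axes and Gaussian posterior
#' membership probabilities. With K = 1 the result contains the clustering
#' only.
#'
#' @param data a \code{genpop_data} object
#' @param clusters result of \code{\link{find_clusters}}, or NULL to run it
#'   with the remaining arguments
#' @param k_max,n_starts,seed passed to \code{\link{find_clusters}}
#'   when \code{clusters} is NULL
#' @param n_pca number of leading PCs fed to the discriminant step; default
#'   the smallest number explaining >= 90 percent of variance, capped at
#'   N/3 to keep posterior memberships from overfitting (the clustering
#'   step itself always sees the full rank, see
#'   \code{\link{find_clusters}})
#' @return object of class \code{"dapc_result"}: \code{bic}, \code{k_opt},
#'   \code{cluster}, \code{n_pca} (PCs used by the discriminant step),
#'   \code{coords} (individuals x (K-1) discriminant scores),
#'   \code{membership} (individuals x K posterior matrix, rows summing
#'   to 1), \code{cluster_by_population} (population x cluster count
#'   table)
#' @export
dapc <- function(data, clusters = NULL, k_max = 10L, n_pca = NULL,
                 n_starts = 50L, seed = 1L) {
  X <- one_hot_impute(data)
  if (is.null(clusters))
    clusters <- find_clusters(X, k_max = k_max, n_starts = n_starts,
                              seed = seed)
  K <- clusters$k_opt
  ev <- clusters$pca$sdev^2
  if (is.null(n_pca)) {
    cum <- cumsum(ev) / sum(ev)
    n_pca <- min(which(cum >= 0.9), max(1L, floor(nrow(X) / 3)))
  }
  n_pca <- min(n_pca, ncol(clusters$pc_scores))
  tab <- table(population = as.character(data$population),
               cluster = clusters$cluster)
  tab <- tab[levels(data$population), , drop = FALSE]
  if (K < 2L) {
    return(structure(list(bic = clusters$bic, k_opt = K,
                          cluster = clusters$cluster,
                          n_pca = n_pca, coords = NULL,
                          membership = matrix(1, nrow(X), 1,
                                              dimnames = list(rownames(X),
                                                              "1")),
                          cluster_by_population = tab),
                     class = "dapc_result"))
  }
  fit <- ridge_lda(clusters$pc_scores[, seq_len(n_pca), drop = FALSE],
                   clusters$cluster)
  rownames(fit$scores) <- rownames(X)
  rownames(fit$posterior) <- rownames(X)
  colnames(fit$posterior) <- seq_len(K)
  structure(list(bic = clusters$bic, k_opt = K, cluster = clusters$cluster,
                 n_pca = n_pca, coords = fit$scores,
                 membership = fit$posterior,
                 cluster_by_population = tab, lda = fit),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: %d retained PCs, K = %d (argmin BIC)\n",
              x$n_pca, x$k_opt))
  print(x$cluster_by_population)
  invisible(x)
}
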