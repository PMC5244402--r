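#' Construct a haploid multilocus genotype dataset
#'
#' The central container of the package: an N x L matrix of haploid allele
#' calls (integer fragment lengths in base pairs, \code{NA} = missing), with
#' each individual assigned to exactly one population and each population to
#' exactly one region. Optional population coordinates (decimal degrees,
#' WGS84) enable the spatial analyses.
#'
#' @param calls integer matrix, individuals x loci; rownames are sample ids,
#'   colnames are locus names. Positive integers or \code{NA}.
#' @param population character or factor of length \code{nrow(calls)}:
#'   population of each individual.
#' @param region named character vector mapping population name -> region
#'   name. Every population present in \code{population} must appear.
#' @param sites optional data.frame with columns \code{population},
#'   \code{region}, \code{latitude}, \code{longitude} (see
#'   \code{\link{read_sites}}).
#' @return an object of class \code{"genpop_data"}: a list with elements
#'   \code{calls}, \code{population} (factor), \code{region_of}
#'   (named character), \code{sites} (data.frame or NULL).
#' @export
genotype_dataset <- function(calls, population, region, sites = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("need at least one individual and one locus")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]),
               collapse = ", "))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  bad <- which(!is.na(calls) & calls <= 0L)
  if (length(bad))
    stop("allele calls must be positive integers or missing")
  population <- trimws(as.character(population))
  if (length(population) != nrow(calls))
    stop("'population' must have one entry per individual")
  pops <- unique(population)
  region <- structure(trimws(as.character(region)), names = trimws(names(region)))
  missing_pops <- setdiff(pops, names(region))
  if (length(missing_pops))
    stop("populations without a region assignment: ",
         paste(missing_pops, collapse = ", "))
  if (!is.null(sites)) {
    sites <- validate_sites(sites)
    unknown <- setdiff(pops, sites$population)
    if (length(unknown))
      stop("populations absent from sites table: ",
           paste(unknown, collapse = ", "))
  }
  structure(
    list(calls = calls,
         population = factor(population, levels = pops),
         region_of = region[pops],
         sites = sites),
    class = "genpop_data")
}

validate_sites <- function(sites) {
  need <- c("population", "region", "latitude", "longitude")
  if (!all(need %in% names(sites)))
    stop("sites table must have columns ", paste(need, collapse = ", "))
  sites$population <- trimws(as.character(sites$population))
  sites$region <- trimws(as.character(sites$region))
  sites$latitude <- as.numeric(sites$latitude)
  sites$longitude <- as.numeric(sites$longitude)
  if (any(abs(sites$latitude) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(abs(sites$longitude) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  if (anyDuplicated(sites$population))
    stop("duplicate population in sites table")
  sites[, need]
}

#' @export
print.genpop_data <- function(x, ...) {
  cat("Haploid multilocus genotype dataset\n")
  cat(sprintf("  %d individuals, %d loci, %d populations, %d regions\n",
              nrow(x$calls), ncol(x$calls), nlevels(x$population),
              length(unique(x$region_of))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci
#' @param data a \code{genpop_data} object
#' @return integer
#' @export
n_individuals <- function(data) nrow(data$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(data) ncol(data$calls)

#' Region of each individual
#' @param data a \code{genpop_data} object
#' @return character vector, one region name per individual
#' @export
region_of_individuals <- function(data)
  unname(data$region_of[as.character(data$population)])

#' Read a haploid genotype table
#'
#' Canonical dialect: CSV with header
#' \code{sample_id,population,<locus1>,...,<locusL>}, one row per individual,
#' integer allele sizes, 0 or empty cell = missing.  GenAlEx-style haploid
#' exports (\code{dialect = "genalex"}) carry two numeric header rows before
#' the column header and name the first two columns freely; they are imported
#' but never written.
#'
#' @param path path to the file
#' @param dialect \code{"canonical"} or \code{"genalex"}
#' @param sites optional sites table (data.frame or path) used both to
#'   cross-check population names and to attach coordinates/regions.
#' @return a \code{\link{genotype_dataset}}
#' @export
read_genotypes <- function(path, dialect = c("canonical", "genalex"),
                           sites = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "genalex") {
    raw <- utils::read.csv(path, header = FALSE, skip = 2,
                           colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
    names(raw) <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    names(raw)[1:2] <- c("sample_id", "population")
  } else {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
    if (ncol(raw) < 3L || names(raw)[1] != "sample_id" ||
        names(raw)[2] != "population")
      stop("malformed header: expected sample_id,population,<loci...> in ",
           path)
  }
  loci <- names(raw)[-(1:2)]
  calls <- matrix(NA_integer_, nrow(raw), length(loci),
                  dimnames = list(trimws(raw$sample_id), loci))
  for (j in seq_along(loci)) {
    v <- trimws(raw[[j + 2L]])
    v[v == ""] <- "0"
    num <- suppressWarnings(as.integer(v))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-integer allele call '%s' at row %d, column '%s'",
                   v[bad[1]], bad[1], loci[j]))
    num[num == 0L] <- NA_integer_
    calls[, j] <- num
  }
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids in ", path)
  if (is.character(sites)) sites <- read_sites(sites)
  pops <- trimws(raw$population)
  if (!is.null(sites)) {
    sites <- validate_sites(sites)
    region <- structure(sites$region, names = sites$population)
    unknown <- setdiff(unique(pops), sites$population)
    if (length(unknown))
      stop("populations in genotype file not present in sites table: ",
           paste(unknown, collapse = ", "))
  } else {
    # without a sites table all populations fall in one unnamed region
    region <- structure(rep("all", length(unique(pops))),
                        names = unique(pops))
  }
  genotype_dataset(calls, pops, region, sites = sites)
}

#' Write a genotype dataset in the canonical CSV dialect
#'
#' Missing calls are written as 0. \code{read_genotypes(write_genotypes(x))}
#' is lossless.
#'
#' @param data a \code{genpop_data} object
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_genotypes <- function(data, path) {
  m <- data$calls
  m[is.na(m)] <- 0L
  df <- data.frame(sample_id = rownames(m),
                   population = as.character(data$population),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sites table
#'
#' CSV with header \code{population,region,latitude,longitude}; coordinates
#' in decimal degrees (WGS84).
#'
#' @param path path to the CSV file
#' @return validated data.frame
#' @export
read_sites <- function(path) {
  validate_sites(utils::read.csv(path, strip.white = TRUE))
}

#' Read a mating-type table
#'
#' CSV with header \code{sample_id,idiomorph}; idiomorph one of
#' \code{MAT1-1}, \code{MAT1-2}, \code{NONE} (no amplification) or
#' \code{BOTH} (flags a heterothallism violation downstream).
#'
#' @param path path to the CSV file
#' @return data.frame with columns \code{sample_id}, \code{idiomorph}
#' @export
read_mat <- function(path) {
  mat <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("sample_id", "idiomorph") %in% names(mat)))
    stop("mat table must have columns sample_id, idiomorph")
  mat$sample_id <- trimws(as.character(mat$sample_id))
  mat$idiomorph <- trimws(as.character(mat$idiomorph))
  ok <- c("MAT1-1", "MAT1-2", "NONE", "BOTH")
  bad <- setdiff(unique(mat$idiomorph), ok)
  if (length(bad))
    stop("unknown idiomorph value(s): ", paste(bad, collapse = ", "))
  mat[, c("sample_id", "idiomorph")]
}

#' Per-population allele counts and frequencies
#'
#' Counts and relative frequencies of every allele at every locus, computed
#' over non-missing calls only, per population and pooled ("global").
#' A (population, locus) cell with no scored call is flagged empty
#' (\code{n = 0}) rather than treated as an error.
#'
#' @param data a \code{genpop_data} object
#' @param by stratification: \code{"population"} (default) or
#'   \code{"region"}
#' @return an object of class \code{"allele_freqs"}: a list with one entry
#'   per locus, each a list with \code{counts} (allele x stratum integer
#'   matrix, rownames = allele sizes), \code{freq} (same shape, columns
#'   summing to 1 where \code{n > 0}), \code{n} (non-missing calls per
#'   stratum) and \code{global} (pooled counts named by allele). Attribute
#'   \code{strata} holds stratum names.
#' @export
allele_frequencies <- function(data, by = c("population", "region")) {
  by <- match.arg(by)
  strata <- if (by == "population") as.character(data$population)
            else region_of_individuals(data)
  lev <- unique(strata)
  out <- lapply(seq_len(ncol(data$calls)), function(j) {
    x <- data$calls[, j]
    keep <- !is.na(x)
    alleles <- sort(unique(x[keep]))
    cnt <- matrix(0L, length(alleles), length(lev),
                  dimnames = list(as.character(alleles), lev))
    if (any(keep)) {
      tab <- table(factor(x[keep], levels = alleles),
                   factor(strata[keep], levels = lev))
      cnt[] <- as.integer(tab)
    }
    n <- colSums(cnt)
    freq <- sweep(cnt, 2, pmax(n, 1L), "/")
    freq[, n == 0L] <- NA_real_
    list(counts = cnt, freq = freq, n = n, global = rowSums(cnt))
  })
  names(out) <- colnames(data$calls)
  structure(out, strata = lev, by = by, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("Allele frequency table: %d loci, %d strata (%s)\n",
              length(x), length(attr(x, "strata")), attr(x, "by")))
  inv <- vapply(x, function(l) nrow(l$counts), 0L)
  cat("  alleles per locus: ", paste(inv, collapse = ", "), "\n", sep = "")
  invisible(x)
}
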