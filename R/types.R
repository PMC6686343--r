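#' @keywords internal
"_PACKAGE"

# Shared data containers. All are light S3 records over base matrices so that
# downstream statistics can index them directly; constructors validate the
# invariants once, at the boundary.

#' Construct a codominant genotype matrix
#'
#' Holds diploid codominant genotypes (e.g. microsatellites) for a set of
#' individuals, with a site label per individual. Allele pairs are unordered;
#' storage canonicalizes each call to (min, max). A missing call applies to
#' the whole locus, never to a single allele.
#'
#' @param individual_ids character vector of unique individual identifiers.
#' @param site_labels character vector, one site label per individual.
#' @param loci_ids character vector of unique locus identifiers.
#' @param allele1,allele2 integer matrices (individuals x loci) of
#'   non-negative allele codes; \code{NA} in both marks a missing call.
#' @return An object of class \code{"genotype_matrix"} with elements
#'   \code{ids}, \code{sites}, \code{loci}, \code{a1}, \code{a2} (after
#'   canonicalization \code{a1 <= a2} everywhere).
#' @export
genotype_matrix <- function(individual_ids, site_labels, loci_ids,
                            allele1, allele2) {
  individual_ids <- as.character(individual_ids)
  loci_ids <- as.character(loci_ids)
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(loci_ids))
    stop("duplicate locus ids")
  if (length(site_labels) != length(individual_ids))
    stop("site_labels must have one entry per individual")
  a1 <- as.matrix(allele1); a2 <- as.matrix(allele2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(individual_ids), length(loci_ids))) ||
      !all(dim(a2) == dim(a1)))
    stop("allele matrices must be individuals x loci")
  if (any(a1 < 0, na.rm = TRUE) || any(a2 < 0, na.rm = TRUE))
    stop("negative allele codes")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("missingness must apply to the whole call: ",
         sum(half), " half-missing cell(s)")
  # canonicalize unordered pair
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(individual_ids, loci_ids)
  scored <- rowSums(!is.na(lo))
  if (any(scored == 0))
    stop("individual(s) with no scored locus: ",
         paste(individual_ids[scored == 0], collapse = ", "))
  structure(list(ids = individual_ids, sites = as.character(site_labels),
                 loci = loci_ids, a1 = lo, a2 = hi),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", length(x$ids), "individuals x",
      length(x$loci), "loci;",
      length(unique(x$sites)), "site(s)\n")
  invisible(x)
}

#' Construct a dual-digest MS-AFLP band matrix
#'
#' Presence/absence bands per individual and locus for the two
#' methylation-sensitive digests (EcoRI/HpaII and EcoRI/MspI). The two digest
#' matrices must have identical shape; a cell scored in only one digest is
#' promoted to missing in both (with a warning), because every
#' methylation-state call needs both digests.
#'
#' @param individual_ids,loci_ids identifiers.
#' @param hpa,msp matrices (individuals x loci) with entries 0, 1 or \code{NA}.
#' @return An object of class \code{"band_matrix"} with elements \code{ids},
#'   \code{loci}, \code{hpa}, \code{msp}.
#' @export
band_matrix <- function(individual_ids, loci_ids, hpa, msp) {
  individual_ids <- as.character(individual_ids)
  loci_ids <- as.character(loci_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (anyDuplicated(loci_ids)) stop("duplicate locus ids")
  hpa <- as.matrix(hpa); msp <- as.matrix(msp)
  storage.mode(hpa) <- "integer"; storage.mode(msp) <- "integer"
  if (!all(dim(hpa) == c(length(individual_ids), length(loci_ids))) ||
      !all(dim(msp) == dim(hpa)))
    stop("hpa and msp must both be individuals x loci")
  ok <- function(m) all(m %in% c(0L, 1L) | is.na(m))
  if (!ok(hpa) || !ok(msp)) stop("band cells must be 0, 1 or NA")
  half <- xor(is.na(hpa), is.na(msp))
  if (any(half)) {
    warning(sum(half), " half-missing band cell(s) promoted to missing in both digests")
    hpa[half] <- NA_integer_
    msp[half] <- NA_integer_
  }
  dimnames(hpa) <- dimnames(msp) <- list(individual_ids, loci_ids)
  structure(list(ids = individual_ids, loci = loci_ids, hpa = hpa, msp = msp),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("MS-AFLP band matrix:", length(x$ids), "individuals x",
      length(x$loci), "loci (HPA + MSP digests);",
      sum(is.na(x$hpa)), "missing cell(s)\n")
  invisible(x)
}

#' Construct a parasite count table
#'
#' Non-negative integer counts per individual and parasite morphotype.
#' Unscreened individuals are simply absent rows; there are no missing cells.
#'
#' @param individual_ids character identifiers.
#' @param morphotype_names character names of the parasite morphotypes.
#' @param counts matrix (individuals x morphotypes) of non-negative integers.
#' @return An object of class \code{"parasite_table"}.
#' @export
parasite_table <- function(individual_ids, morphotype_names, counts) {
  individual_ids <- as.character(individual_ids)
  morphotype_names <- as.character(morphotype_names)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!all(dim(counts) == c(length(individual_ids), length(morphotype_names))))
    stop("counts must be individuals x morphotypes")
  if (anyNA(counts)) stop("parasite counts may not be missing")
  if (any(counts < 0)) stop("negative parasite counts")
  dimnames(counts) <- list(individual_ids, morphotype_names)
  structure(list(ids = individual_ids, morphotypes = morphotype_names,
                 counts = counts),
            class = "parasite_table")
}

#' @export
print.parasite_table <- function(x, ...) {
  cat("Parasite counts:", length(x$ids), "individuals x",
      length(x$morphotypes), "morphotype(s)\n")
  invisible(x)
}

#' Construct a cluster-membership (q-value) matrix
#'
#' Per-individual membership fractions over k >= 2 genetic clusters (selfing
#' lineages), as produced by Bayesian clustering or by the simulator's
#' pedigree-tracked ancestry. Rows whose sum deviates from 1 by at most
#' \code{renorm_tol} are renormalized; larger deviations are rejected.
#'
#' @param individual_ids character identifiers.
#' @param cluster_ids character cluster names (k >= 2).
#' @param q numeric matrix (individuals x clusters) of fractions in [0, 1].
#' @param renorm_tol maximum row-sum deviation from 1 that is silently
#'   renormalized (default 1e-3).
#' @return An object of class \code{"q_matrix"}.
#' @export
q_matrix <- function(individual_ids, cluster_ids, q, renorm_tol = 1e-3) {
  individual_ids <- as.character(individual_ids)
  cluster_ids <- as.character(cluster_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (length(cluster_ids) < 2) stop("need k >= 2 clusters")
  q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (!all(dim(q) == c(length(individual_ids), length(cluster_ids))))
    stop("q must be individuals x clusters")
  if (anyNA(q) || any(q < 0) || any(q > 1))
    stop("q values must lie in [0, 1]")
  rs <- rowSums(q)
  bad <- abs(rs - 1) > renorm_tol
  if (any(bad))
    stop("q row sum(s) deviate from 1 by more than ", renorm_tol, ": ",
         paste(individual_ids[bad], collapse = ", "))
  q <- q / rs
  dimnames(q) <- list(individual_ids, cluster_ids)
  structure(list(ids = individual_ids, clusters = cluster_ids, q = q),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("q-matrix:", length(x$ids), "individuals x",
      length(x$clusters), "clusters\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the shared scoring and testing parameters: the MS-AFLP replicate
#' error threshold used to separate methylation-susceptible from
#' non-methylated loci, the q-value threshold separating selfed from
#' outcrossed individuals, the number of permutations for randomization
#' tests, and the GeneMapper-style peak filters (sizing window and minimum
#' peak height) used when binarizing fragment peak tables.
#'
#' @param error_threshold MSL classification threshold on the frequency of
#'   methylation-indicative band patterns (default 0.05; comparison is
#'   strict, a locus must exceed it).
#' @param q_threshold minimum maximum-q for an individual to be classed as
#'   selfed (default 0.9, inclusive).
#' @param n_permutations permutations for AMOVA/Mantel tests (default 10000).
#' @param peak_min_size,peak_max_size fragment sizing window in base pairs
#'   (default 100-500 bp, half-open at the top).
#' @param peak_min_height minimum peak height in relative fluorescence units
#'   (default 100 RFU).
#' @param rng_seed optional integer seed used by permutation tests.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(error_threshold = 0.05,
                            q_threshold = 0.9,
                            n_permutations = 10000,
                            peak_min_size = 100,
                            peak_max_size = 500,
                            peak_min_height = 100,
                            rng_seed = NULL) {
  if (!(error_threshold > 0 && error_threshold < 1))
    stop("error_threshold must be in (0, 1)")
  if (!(q_threshold > 0 && q_threshold <= 1))
    stop("q_threshold must be in (0, 1]")
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  if (!(peak_min_size > 0 && peak_max_size > peak_min_size))
    stop("invalid peak sizing window")
  if (peak_min_height <= 0) stop("peak_min_height must be positive")
  structure(list(error_threshold = error_threshold,
                 q_threshold = q_threshold,
                 n_permutations = as.integer(n_permutations),
                 peak_min_size = peak_min_size,
                 peak_max_size = peak_max_size,
                 peak_min_height = peak_min_height,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}
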