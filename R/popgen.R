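# Microsatellite diversity statistics, individual homozygosity (HL),
# equilibrium selfing-rate estimation, and q-threshold classification.

.allele_freqs <- function(a1, a2) {
  # frequency table over both allele columns, NA-excluded
  av <- c(a1, a2)
  av <- av[!is.na(av)]
  if (!length(av)) return(numeric(0))
  tab <- table(av)
  as.numeric(tab) / sum(tab)
}

.locus_stats <- function(a1, a2) {
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n == 0) return(c(Na = NA, Ho = NA, He = NA, n = 0))
  p <- .allele_freqs(a1[ok], a2[ok])
  c(Na = length(p),
    Ho = mean(a1[ok] != a2[ok]),
    He = 1 - sum(p^2),
    n = n)
}

#' Per-locus and pooled diversity summary
#'
#' For each locus: number of distinct alleles (Na), observed heterozygosity
#' (Ho, fraction of heterozygous non-missing calls), expected heterozygosity
#' (He = 1 - sum p_a^2 from observed allele frequencies, uncorrected) and,
#' pooled over loci, the multilocus inbreeding coefficient
#' F_IS = 1 - mean(Ho)/mean(He). Optionally computed per group. An unbiased
#' small-sample He (Nei's n/(n-1) correction) is available behind
#' \code{unbiased}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param groups optional character/factor of group labels per individual
#'   (e.g. sites); when supplied, statistics are computed within each group.
#' @param unbiased logical; apply the n/(n-1) small-sample correction to He
#'   (default \code{FALSE}, matching GenAlEx's uncorrected He).
#' @return An object of class \code{"diversity_summary"}: a list with
#'   \code{per_locus} (data.frame locus, group, Na, Ho, He, n) and
#'   \code{pooled} (data.frame group, mean_Na, mean_Ho, mean_He, Fis, n).
#' @export
diversity_summary <- function(g, groups = NULL, unbiased = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(groups)) groups <- rep("all", length(g$ids))
  groups <- as.character(groups)
  stopifnot(length(groups) == length(g$ids))
  per <- NULL; pooled <- NULL
  for (grp in unique(groups)) {
    rows <- which(groups == grp)
    st <- t(vapply(seq_along(g$loci), function(j)
      .locus_stats(g$a1[rows, j], g$a2[rows, j]), c(Na = 0, Ho = 0, He = 0, n = 0)))
    empty <- st[, "n"] == 0
    if (any(empty))
      warning(sum(empty), " locus/loci with no scored call in group '", grp,
              "' excluded")
    if (unbiased) {
      nn <- st[, "n"]
      st[, "He"] <- ifelse(nn > 1, st[, "He"] * 2 * nn / (2 * nn - 1), st[, "He"])
    }
    per <- rbind(per, data.frame(locus = g$loci, group = grp,
                                 Na = st[, "Na"], Ho = st[, "Ho"],
                                 He = st[, "He"], n = st[, "n"],
                                 stringsAsFactors = FALSE))
    use <- !empty
    mHo <- mean(st[use, "Ho"]); mHe <- mean(st[use, "He"])
    fis <- if (mHe > 0) 1 - mHo / mHe else NA_real_
    pooled <- rbind(pooled, data.frame(group = grp,
                                       mean_Na = mean(st[use, "Na"]),
                                       mean_Ho = mHo, mean_He = mHe,
                                       Fis = fis, n = length(rows),
                                       stringsAsFactors = FALSE))
  }
  structure(list(per_locus = per, pooled = pooled),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  cat("Diversity summary (pooled over loci):\n")
  print(format(x$pooled, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Homozygosity by locus (HL)
#'
#' Individual homozygosity index weighting each locus by its expected
#' heterozygosity (Aparicio et al. 2006):
#' HL = sum(E_l over homozygous loci) / sum(E_l over all scored loci), with
#' E_l = 1 - sum p_a^2 computed from the full sample (focal individual
#' included). Missing loci are excluded from both sums; an individual with
#' no scored locus gets \code{NA}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return Named numeric vector of HL in [0, 1] per individual.
#' @export
homozygosity_by_locus <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  E <- vapply(seq_along(g$loci), function(j) {
    p <- .allele_freqs(g$a1[, j], g$a2[, j])
    if (!length(p)) NA_real_ else 1 - sum(p^2)
  }, 0)
  hl <- vapply(seq_along(g$ids), function(i) {
    ok <- !is.na(g$a1[i, ]) & !is.na(E)
    if (!any(ok)) return(NA_real_)
    hom <- ok & g$a1[i, ] == g$a2[i, ]
    tot <- sum(E[ok])
    if (tot == 0) return(NA_real_)
    sum(E[hom]) / tot
  }, 0)
  names(hl) <- g$ids
  hl
}

#' Equilibrium selfing-rate estimate from an inbreeding coefficient
#'
#' Moment estimator at inbreeding equilibrium: at mutation-drift equilibrium
#' under partial self-fertilization, F = s/(2 - s), hence s = 2F/(1 + F).
#'
#' @param f inbreeding coefficient(s) in [0, 1]; negative values are
#'   truncated to s = 0 with a warning.
#' @return An object of class \code{"selfing_estimate"}: data.frame with
#'   \code{s_hat} and \code{method}.
#' @export
selfing_rate_from_fis <- function(f) {
  s <- 2 * f / (1 + f)
  if (any(f < 0, na.rm = TRUE)) {
    warning("negative inbreeding coefficient(s) truncated to s = 0")
    s[f < 0] <- 0
  }
  structure(data.frame(s_hat = s, method = "equilibrium 2F/(1+F)",
                       stringsAsFactors = FALSE),
            class = c("selfing_estimate", "data.frame"))
}

#' Classify individuals as selfed or outcrossed from q-values
#'
#' An individual is assigned to its maximum-membership cluster (ties broken
#' by first cluster in column order) and classed SELFED iff max q >=
#' \code{threshold} (inclusive), otherwise OUTCROSSED -- a hybrid between
#' two selfing lineages.
#'
#' @param qm a \code{\link{q_matrix}}.
#' @param threshold classification threshold on max q (default 0.9).
#' @return data.frame with \code{id}, \code{assigned_lineage}, \code{max_q},
#'   \code{status} ("SELFED"/"OUTCROSSED").
#' @export
classify_inbreeding <- function(qm, threshold = 0.9) {
  stopifnot(inherits(qm, "q_matrix"))
  amax <- apply(qm$q, 1, which.max)   # which.max takes the first on ties
  mq <- qm$q[cbind(seq_along(qm$ids), amax)]
  data.frame(id = qm$ids,
             assigned_lineage = qm$clusters[amax],
             max_q = mq,
             status = ifelse(mq >= threshold, "SELFED", "OUTCROSSED"),
             stringsAsFactors = FALSE)
}
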