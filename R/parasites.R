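# Scaled parasite load, prevalence, and the rank-based group comparisons
# used on parasite and homozygosity data.

#' Scaled parasite load
#'
#' For each morphotype i the count per individual is divided by the maximum
#' count found across all individuals in the table (N_imax, pooled over all
#' sites); the individual's scaled load is the sum of these ratios over
#' morphotypes, so each morphotype contributes on [0, 1] and very abundant
#' types cannot dominate. Morphotypes with zero counts everywhere carry no
#' information and are dropped with a warning.
#'
#' @param t a \code{\link{parasite_table}}.
#' @return Named numeric vector of scaled loads per individual, in
#'   [0, n_morphotypes].
#' @export
scaled_parasite_load <- function(t) {
  stopifnot(inherits(t, "parasite_table"))
  if (length(t$ids) == 0) stop("empty parasite table")
  mx <- apply(t$counts, 2, max)
  if (any(mx == 0)) {
    warning("all-zero morphotype(s) dropped: ",
            paste(t$morphotypes[mx == 0], collapse = ", "))
  }
  keep <- mx > 0
  if (!any(keep)) {
    out <- rep(NA_real_, length(t$ids)); names(out) <- t$ids
    return(out)
  }
  load <- as.numeric(t$counts[, keep, drop = FALSE] %*% (1 / mx[keep]))
  names(load) <- t$ids
  load
}

#' Parasite prevalence
#'
#' Percentage of individuals with at least one parasite of the given
#' morphotype.
#'
#' @param t a \code{\link{parasite_table}}.
#' @param morphotype morphotype name (all morphotypes when \code{NULL}).
#' @return data.frame with \code{morphotype}, \code{n_infected}, \code{n},
#'   \code{fraction}, \code{percent}.
#' @export
prevalence <- function(t, morphotype = NULL) {
  stopifnot(inherits(t, "parasite_table"))
  if (length(t$ids) == 0) stop("empty parasite table")
  if (is.null(morphotype)) morphotype <- t$morphotypes
  if (!all(morphotype %in% t$morphotypes))
    stop("unknown morphotype: ",
         paste(setdiff(morphotype, t$morphotypes), collapse = ", "))
  n <- length(t$ids)
  inf <- vapply(morphotype, function(m) sum(t$counts[, m] > 0), 0L)
  data.frame(morphotype = morphotype, n_infected = inf, n = n,
             fraction = inf / n, percent = 100 * inf / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected rank-based H statistic with df = k - 1 and p-value from the
#' chi-square approximation (delegates to \code{stats::kruskal.test}). The
#' degenerate all-tied case is reported as H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups).
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(values) < 2) stop("need >= 2 observations")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) test for two groups
#'
#' U statistic for the first group, z from the normal approximation with tie
#' correction and continuity correction, and the two-sided p-value.
#'
#' @param values numeric observations.
#' @param groups labels with exactly two levels; the first level (factor
#'   order) is "group 1" for the U statistic.
#' @return list with \code{U}, \code{z}, \code{p}, \code{n1}, \code{n2}.
#' @export
mann_whitney <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  r <- rank(values)
  R1 <- sum(r[groups == levels(groups)[1]])
  U <- R1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2))
  cc <- sign(U - mu) * 0.5     # continuity correction toward the mean
  z <- (U - mu - cc) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, z = z, p = p, n1 = n1, n2 = n2)
}
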