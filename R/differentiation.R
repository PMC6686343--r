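# Distance matrices, one-level AMOVA with Phi-statistics and permutation
# tests, pairwise Phi, principal coordinates analysis, Mantel tests.
# Implemented from the Excoffier variance-component definitions; squared
# distances are used internally throughout.

#' Simple mismatch distance for binary (dominant) data
#'
#' d(i, j) = proportion of mismatching entries over the columns jointly
#' scored in both rows. Used for MSL loci (after methylated/unmethylated
#' recoding) and for NML/AFLP band-presence data.
#'
#' @param x binary matrix (individuals x loci) with \code{NA} for missing;
#'   row names are the individual ids.
#' @return An object of class \code{"dist_matrix"}: list with \code{ids},
#'   symmetric matrix \code{d}, \code{metric}.
#' @export
binary_distance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  # pairwise counts via cross-products: mismatches = x(1-y) + (1-x)y over
  # jointly observed columns
  joint <- obs %*% t(obs)
  agree11 <- x0 %*% t(x0)
  ones <- (obs & x == 1)
  obs0 <- (obs & x == 0)
  mism <- ones %*% t(obs0) + obs0 %*% t(ones)
  if (any(joint[upper.tri(joint)] == 0)) {
    bad <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)[1, ]
    stop("no jointly scored column for pair: ", ids[bad[1]], ", ", ids[bad[2]])
  }
  d <- mism / joint
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, metric = "binary mismatch"),
            class = "dist_matrix")
}

#' Allelic mismatch distance for codominant genotypes
#'
#' Per locus, the number of allelic mismatches between two diploid
#' genotypes is 2 minus the shared allele count (multiset intersection
#' size), i.e. 0, 1 or 2; d(i, j) is the mean over loci scored in both
#' individuals.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return A \code{"dist_matrix"}.
#' @export
msat_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$ids); L <- length(g$loci)
  d <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  a1 <- g$a1; a2 <- g$a2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) stop("no jointly scored locus for pair: ",
                         g$ids[i], ", ", g$ids[j])
      x1 <- a1[i, ok]; x2 <- a2[i, ok]; y1 <- a1[j, ok]; y2 <- a2[j, ok]
      # shared allele count per locus (calls are canonicalized min,max)
      both <- (x1 == y1) + (x2 == y2)
      cross <- pmax((x1 == y2) + 0L, (x2 == y1) + 0L)
      shared <- pmax(both, cross)
      # identical unordered pairs share 2; the pmax above covers
      # hom/het combinations since pairs are sorted
      d[i, j] <- d[j, i] <- mean(2 - shared)
    }
  }
  structure(list(ids = g$ids, d = d, metric = "allelic mismatch"),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix (", x$metric, "): ", length(x$ids),
      " individuals\n", sep = "")
  invisible(x)
}

.as_dist_matrix <- function(d) {
  if (inherits(d, "dist_matrix")) return(d)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  structure(list(ids = ids, d = d, metric = "user"), class = "dist_matrix")
}

# sum of squared distances within each group, divided by group size
.ss_within <- function(d2, idx_by_group) {
  s <- 0
  for (idx in idx_by_group) {
    if (length(idx) > 1)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

.phi_from_groups <- function(d2, idx_by_group, n, k, ss_total, nbar) {
  ssw <- .ss_within(d2, idx_by_group)
  ssa <- ss_total - ssw
  sig_b <- ssw / (n - k)
  sig_a <- (ssa / (k - 1) - sig_b) / nbar
  tot <- sig_a + sig_b
  if (tot == 0) return(c(NA, ssa, ssw, sig_a, sig_b))
  c(sig_a / tot, ssa, ssw, sig_a, sig_b)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style variance decomposition from squared inter-individual
#' distances: SS_total = sum_{i<j} d^2/N; SS_within = sum over groups of the
#' within-group pairwise d^2 divided by group size; sigma2_within =
#' SS_within/(N-k); sigma2_among = (SS_among/(k-1) - sigma2_within)/nbar
#' with nbar = (N - sum n_g^2/N)/(k-1). Phi_ST =
#' sigma2_among/(sigma2_among + sigma2_within). Negative variance
#' components are retained (Phi may be slightly negative). The permutation
#' p-value reassigns individuals to groups with sizes fixed:
#' p = (1 + #(Phi_perm >= Phi_obs))/(1 + n_perm), never zero.
#'
#' @param d a \code{"dist_matrix"} (or plain symmetric matrix).
#' @param groups group label per individual (>= 2 non-empty groups).
#' @param n_perm number of permutations (default 10000); 0 skips the test.
#' @param seed optional integer seed for the permutations.
#' @return An object of class \code{"amova"} with the degrees of freedom,
#'   sums of squares, variance components, percent variance, \code{phi_st},
#'   \code{p}, \code{n_perm} and \code{seed}.
#' @export
amova <- function(d, groups, n_perm = 10000, seed = NULL) {
  d <- .as_dist_matrix(d)
  groups <- as.character(groups)
  n <- length(d$ids)
  stopifnot(length(groups) == n)
  glev <- unique(groups)
  k <- length(glev)
  if (k < 2) stop("need >= 2 groups")
  sizes <- table(factor(groups, levels = glev))
  if (any(sizes == 0)) stop("empty group")
  d2 <- d$d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  nbar <- (n - sum(sizes^2) / n) / (k - 1)
  idx <- split(seq_len(n), factor(groups, levels = glev))
  obs <- .phi_from_groups(d2, idx, n, k, ss_total, nbar)
  phi <- obs[1]
  p <- NA_real_
  if (n_perm > 0 && !is.na(phi)) {
    if (!is.null(seed)) set.seed(seed)
    sz <- as.integer(sizes)
    ends <- cumsum(sz); starts <- c(1L, utils::head(ends, -1) + 1L)
    count <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      pid <- lapply(seq_len(k), function(gi) perm[starts[gi]:ends[gi]])
      ph <- .phi_from_groups(d2, pid, n, k, ss_total, nbar)[1]
      if (!is.na(ph) && ph >= phi) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_perm)
  }
  sig_a <- obs[4]; sig_b <- obs[5]
  pct <- if (is.na(phi)) c(NA, NA) else
    100 * c(sig_a, sig_b) / (sig_a + sig_b)
  structure(list(df_among = k - 1L, df_within = n - k,
                 ss_among = obs[2], ss_within = obs[3],
                 sigma2_among = sig_a, sigma2_within = sig_b,
                 percent_among = pct[1], percent_within = pct[2],
                 phi_st = phi, p = p, n_perm = n_perm, seed = seed,
                 n = n, k = k),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat("One-level AMOVA (", x$k, " groups, ", x$n, " individuals)\n", sep = "")
  tab <- data.frame(
    df = c(x$df_among, x$df_within),
    SS = c(x$ss_among, x$ss_within),
    sigma2 = c(x$sigma2_among, x$sigma2_within),
    percent = c(x$percent_among, x$percent_within),
    row.names = c("Among groups", "Within groups"))
  print(round(tab, digits))
  cat("Phi_ST =", format(x$phi_st, digits = digits))
  if (!is.na(x$p))
    cat(", p =", format(x$p, digits = digits),
        "(", x$n_perm, "permutations )")
  cat("\n")
  invisible(x)
}

#' Pairwise Phi_ST between groups
#'
#' \code{\link{amova}} restricted to each pair of groups. No
#' multiple-testing correction is applied (raw permutation p-values).
#'
#' @inheritParams amova
#' @return list with symmetric matrices \code{phi} and \code{p}.
#' @export
pairwise_phi <- function(d, groups, n_perm = 10000, seed = NULL) {
  d <- .as_dist_matrix(d)
  groups <- as.character(groups)
  glev <- unique(groups)
  k <- length(glev)
  if (k < 2) stop("need >= 2 groups")
  phi <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  pm <- phi
  diag(phi) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    rows <- which(groups %in% glev[c(i, j)])
    sub <- d$d[rows, rows, drop = FALSE]
    res <- amova(sub, groups[rows], n_perm = n_perm, seed = seed)
    phi[i, j] <- phi[j, i] <- res$phi_st
    pm[i, j] <- pm[j, i] <- res$p
  }
  list(phi = phi, p = pm)
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition. Axes
#' with positive eigenvalues are retained in descending order; negative
#' eigenvalues are reported, not corrected. Percent variance is relative to
#' the sum of positive eigenvalues.
#'
#' @param d a \code{"dist_matrix"} (or symmetric matrix); N >= 3.
#' @return An object of class \code{"pcoa"}: list with \code{coordinates}
#'   (individuals x positive axes), \code{eigenvalues} (all, descending),
#'   \code{percent} (per positive axis), \code{ids}.
#' @export
pcoa <- function(d) {
  d <- .as_dist_matrix(d)
  n <- length(d$ids)
  if (n < 3) stop("need N >= 3")
  a <- -0.5 * d$d^2
  rc <- rowMeans(a)
  b <- a - outer(rc, rc, "+") + mean(a)   # (I-11'/n) A (I-11'/n)
  e <- eigen(b, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- d$ids
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = ev,
                 percent = 100 * ev[pos] / sum(ev[pos]), ids = d$ids),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, digits = 4, ...) {
  cat("PCoA:", length(x$ids), "individuals,",
      ncol(x$coordinates), "positive axes\n")
  cat("  variance explained (%):",
      paste(round(utils::head(x$percent, 5), 2), collapse = ", "),
      if (length(x$percent) > 5) "...", "\n")
  invisible(x)
}

#' @export
plot.pcoa <- function(x, axes = c(1, 2), groups = NULL, ...) {
  xy <- x$coordinates[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(xy, col = col, pch = 19,
       xlab = sprintf("Axis %d (%.1f%%)", axes[1], x$percent[axes[1]]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2], x$percent[axes[2]]), ...)
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the vectorized upper triangles; the
#' one-tailed (positive association) permutation p-value jointly permutes
#' rows and columns of the second matrix:
#' p = (1 + #(r_perm >= r_obs))/(1 + n_perm).
#'
#' @param d1,d2 \code{"dist_matrix"} objects (or symmetric matrices) over
#'   the same individuals in the same order.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return An object of class \code{"mantel_test"}: list with \code{r},
#'   \code{p}, \code{n_perm}, \code{seed}, \code{n}.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL) {
  d1 <- .as_dist_matrix(d1); d2 <- .as_dist_matrix(d2)
  n <- length(d1$ids)
  if (length(d2$ids) != n) stop("matrices must match in size")
  if (!identical(d1$ids, d2$ids))
    stop("matrices must cover the same individuals in the same order")
  ut <- upper.tri(d1$d)
  v1 <- d1$d[ut]
  v2 <- d2$d[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in off-diagonal distances; r undefined")
  r <- stats::cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    rp <- stats::cor(v1, d2$d[perm, perm][ut])
    if (rp >= r) count <- count + 1L
  }
  structure(list(r = r, p = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, n = n),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, digits = 4, ...) {
  cat("Mantel test: r =", format(x$r, digits = digits),
      ", p =", format(x$p, digits = digits),
      "(", x$n_perm, "permutations, one-tailed )\n")
  invisible(x)
}
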