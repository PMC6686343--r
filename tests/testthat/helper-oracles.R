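# Independent oracles and small fixture builders, written from the bare
# definitions (naive loops, no shared code with the implementation).

# Variance components / Phi from explicit double loops over squared
# distances, following the one-level decomposition definitions directly.
oracle_amova_phi <- function(dmat, groups) {
  n <- nrow(dmat)
  glev <- unique(groups)
  k <- length(glev)
  d2 <- dmat^2
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in glev) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    s <- 0
    for (a in seq_len(ng - 1)) for (b in (a + 1):ng)
      s <- s + d2[idx[a], idx[b]]
    ss_within <- ss_within + s / ng
  }
  ss_among <- ss_total - ss_within
  sizes <- sapply(glev, function(g) sum(groups == g))
  nbar <- (n - sum(sizes^2) / n) / (k - 1)
  sig_b <- ss_within / (n - k)
  sig_a <- (ss_among / (k - 1) - sig_b) / nbar
  sig_a / (sig_a + sig_b)
}

# Tie-corrected Kruskal-Wallis H from the rank-sum formula.
oracle_kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  glev <- unique(groups)
  h <- 12 / (n * (n + 1)) *
    sum(sapply(glev, function(g) sum(r[groups == g])^2 / sum(groups == g))) -
    3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Mann-Whitney U for group 1 by counting pairs.
oracle_mw_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# All term sets by brute force: every subset of mains x interactions,
# optionally filtered by marginality, deduplicated.
oracle_enumerate_count <- function(mains, interactions, marginality) {
  all_terms <- c(mains, interactions)
  n <- length(all_terms)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- all_terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (marginality) {
      ok <- TRUE
      for (it in intersect(sel, interactions)) {
        parts <- strsplit(it, ":", fixed = TRUE)[[1]]
        if (!all(parts %in% sel)) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    count <- count + 1L
  }
  count
}

# Small genotype matrix from a list of per-individual locus calls, e.g.
# list(A = list(c(1, 2), c(3, 3)), B = ...); NULL call = missing.
make_geno <- function(calls, sites = NULL, loci = NULL) {
  ids <- names(calls)
  L <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("loc", seq_len(L))
  if (is.null(sites)) sites <- rep("s1", length(ids))
  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- a1
  for (i in seq_along(calls)) for (j in seq_len(L)) {
    cl <- calls[[i]][[j]]
    if (!is.null(cl) && !anyNA(cl)) { a1[i, j] <- cl[1]; a2[i, j] <- cl[2] }
  }
  genotype_matrix(ids, sites, loci, a1, a2)
}

# States object straight from a character matrix.
make_states <- function(states) {
  if (is.null(rownames(states)))
    rownames(states) <- paste0("i", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- paste0("l", seq_len(ncol(states)))
  structure(list(ids = rownames(states), loci = colnames(states),
                 states = states),
            class = "methylation_states")
}

# Band matrix from the four-pattern code: "U"=1/1, "H"=1/0, "I"=0/1,
# "A"=0/0, NA=missing.
make_bands <- function(pattern) {
  hpa <- matrix(NA_integer_, nrow(pattern), ncol(pattern))
  msp <- hpa
  hpa[pattern %in% c("U", "H")] <- 1L
  hpa[pattern %in% c("I", "A")] <- 0L
  msp[pattern %in% c("U", "I")] <- 1L
  msp[pattern %in% c("H", "A")] <- 0L
  if (is.null(rownames(pattern)))
    rownames(pattern) <- paste0("i", seq_len(nrow(pattern)))
  if (is.null(colnames(pattern)))
    colnames(pattern) <- paste0("l", seq_len(ncol(pattern)))
  band_matrix(rownames(pattern), colnames(pattern), hpa, msp)
}

# Minimal single-lineage simulation config (padded with an empty second
# lineage since a q-matrix needs two clusters).
one_lineage_config <- function(n, s, G, loci = 27, alleles = 6,
                               conc = 1, ...) {
  simulation_config(matrix(c(as.integer(n), 0L), 1, 2),
                    selfing_probability = s, n_generations = G,
                    n_msat_loci = loci, alleles_per_locus = alleles,
                    founder_concentration = conc, n_msap_loci = 4,
                    parasite_mean = array(1, c(1, 2, 1),
                                          list(NULL, NULL, "m")),
                    ...)
}
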