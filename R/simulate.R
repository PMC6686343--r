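# Forward-in-time simulator for mixed-mating (selfing/outcrossing)
# populations: K selfing lineages distributed over sites, pedigree-tracked
# ancestry fractions, negative-binomial parasite loads, and MS-AFLP band
# matrices whose methylation states respond to lineage, parasite load,
# inbreeding status and their interactions.

#' Simulation configuration
#'
#' @param occupancy integer matrix (sites x lineages) of individuals per
#'   lineage per site; row names are site labels, column names lineage
#'   labels. Zero-count lineages are allowed (their q-columns are emitted
#'   as structural zeros).
#' @param selfing_probability probability s that a reproduction event is
#'   self-fertilization (per offspring, per generation).
#' @param n_generations number of non-overlapping generations simulated
#'   forward from the founders.
#' @param n_msat_loci number of codominant microsatellite loci.
#' @param alleles_per_locus size of the global allele pool per locus.
#' @param founder_concentration Dirichlet concentration for lineage-specific
#'   founder allele frequencies (smaller = more skewed pools, stronger
#'   lineage divergence); \code{Inf} means exactly equal frequencies.
#' @param n_msap_loci number of MS-AFLP loci.
#' @param fraction_msl fraction of MS-AFLP loci that are truly
#'   methylation-susceptible.
#' @param lineage_baseline_logit numeric length-K baseline methylation
#'   log-odds per lineage.
#' @param effect_parasite slope (logit scale) of methylation probability on
#'   scaled parasite load.
#' @param effect_inbreeding additive effect (logit) of being outcrossed at
#'   the final generation.
#' @param interaction_lineage_parasite,interaction_lineage_inbreeding
#'   numeric length-K per-lineage deviations added to the parasite and
#'   inbreeding effects (lineage x parasite and lineage x inbreeding
#'   interactions).
#' @param interaction_parasite_inbreeding scalar parasite-by-inbreeding
#'   interaction (logit per unit scaled load, outcrossed individuals).
#' @param parasite_mean numeric array (sites x lineages x morphotypes) of
#'   negative-binomial mean counts; third dimension names the morphotypes.
#' @param parasite_dispersion negative-binomial size parameter (> 0).
#' @param ambiguous_prob probability an MS-AFLP cell is replaced by the
#'   uninformative (0,0) pattern.
#' @param missing_prob probability an MS-AFLP cell is missing in both
#'   digests.
#' @param rng_seed optional integer seed used by \code{\link{simulate_dataset}}.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(occupancy,
                              selfing_probability = 0.95,
                              n_generations = 15,
                              n_msat_loci = 27,
                              alleles_per_locus = 6,
                              founder_concentration = 0.3,
                              n_msap_loci = 381,
                              fraction_msl = 0.70,
                              lineage_baseline_logit = NULL,
                              effect_parasite = 0.4,
                              effect_inbreeding = -0.3,
                              interaction_lineage_parasite = NULL,
                              interaction_lineage_inbreeding = NULL,
                              interaction_parasite_inbreeding = 0,
                              parasite_mean = NULL,
                              parasite_dispersion = 1.5,
                              ambiguous_prob = 0.05,
                              missing_prob = 0.02,
                              rng_seed = NULL) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "integer"
  if (any(occupancy < 0) || sum(occupancy) < 2)
    stop("occupancy must be non-negative with total N >= 2")
  if (is.null(rownames(occupancy)))
    rownames(occupancy) <- paste0("site", seq_len(nrow(occupancy)))
  if (is.null(colnames(occupancy)))
    colnames(occupancy) <- paste0("L", seq_len(ncol(occupancy)))
  K <- ncol(occupancy)
  if (!(selfing_probability >= 0 && selfing_probability <= 1))
    stop("selfing_probability must be in [0, 1]")
  if (!(fraction_msl >= 0 && fraction_msl <= 1))
    stop("fraction_msl must be in [0, 1]")
  if (parasite_dispersion <= 0) stop("parasite_dispersion must be > 0")
  if (!(ambiguous_prob >= 0 && ambiguous_prob <= 1) ||
      !(missing_prob >= 0 && missing_prob <= 1))
    stop("probabilities must be in [0, 1]")
  if (is.null(lineage_baseline_logit))
    lineage_baseline_logit <- rep(stats::qlogis(0.45), K)
  if (is.null(interaction_lineage_parasite))
    interaction_lineage_parasite <- rep(0, K)
  if (is.null(interaction_lineage_inbreeding))
    interaction_lineage_inbreeding <- rep(0, K)
  stopifnot(length(lineage_baseline_logit) == K,
            length(interaction_lineage_parasite) == K,
            length(interaction_lineage_inbreeding) == K)
  if (is.null(parasite_mean)) {
    parasite_mean <- array(rep(c(2.7, 0.5, 0.1), each = nrow(occupancy) * K),
                           dim = c(nrow(occupancy), K, 3),
                           dimnames = list(rownames(occupancy),
                                           colnames(occupancy),
                                           c("bacterial_cysts",
                                             "protozoan_cysts", "nematodes")))
  }
  if (!identical(dim(parasite_mean)[1:2], dim(occupancy)) ||
      any(parasite_mean < 0))
    stop("parasite_mean must be a non-negative sites x lineages x morphotypes array")
  structure(list(occupancy = occupancy,
                 selfing_probability = selfing_probability,
                 n_generations = as.integer(n_generations),
                 n_msat_loci = as.integer(n_msat_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 founder_concentration = founder_concentration,
                 n_msap_loci = as.integer(n_msap_loci),
                 fraction_msl = fraction_msl,
                 lineage_baseline_logit = lineage_baseline_logit,
                 effect_parasite = effect_parasite,
                 effect_inbreeding = effect_inbreeding,
                 interaction_lineage_parasite = interaction_lineage_parasite,
                 interaction_lineage_inbreeding = interaction_lineage_inbreeding,
                 interaction_parasite_inbreeding = interaction_parasite_inbreeding,
                 parasite_mean = parasite_mean,
                 parasite_dispersion = parasite_dispersion,
                 ambiguous_prob = ambiguous_prob,
                 missing_prob = missing_prob,
                 rng_seed = rng_seed),
            class = "simulation_config")
}

#' Default study-design configuration
#'
#' Reproduces the sampling design of the motivating field study: three
#' isolated mangrove sites, six selfing lineages with occupancy
#' 14/25/22/7 (site 1, lineages 1, 2, 4, 6), 41/1 (site 2, lineages 3 and
#' 6) and 18 (site 3, lineage 5) -- 128 individuals in total -- genotyped at
#' 27 microsatellite loci and 381 MS-AFLP loci of which 70% are
#' methylation-susceptible, with a high selfing rate (s = 0.95).
#' Methylation baselines, effect sizes and parasite means are set to
#' realistic magnitudes for this design (see the methods vignette).
#'
#' @return A \code{\link{simulation_config}}.
#' @export
default_study_config <- function() {
  occ <- matrix(0L, 3, 6,
                dimnames = list(c("site1", "site2", "site3"),
                                paste0("L", 1:6)))
  occ["site1", c("L1", "L2", "L4", "L6")] <- c(14L, 25L, 22L, 7L)
  occ["site2", c("L3", "L6")] <- c(41L, 1L)
  occ["site3", "L5"] <- 18L
  site_mean <- rbind(bacterial_cysts = c(3.16, 2.66, 1.27),
                     protozoan_cysts = c(0, 1.52, 0.33),
                     nematodes       = c(0.16, 0.02, 0))
  mult <- c(1.3, 0.8, 1.0, 1.5, 0.7, 1.0)   # lineage differences in load
  pm <- array(0, dim = c(3, 6, 3),
              dimnames = list(rownames(occ), colnames(occ), rownames(site_mean)))
  for (m in 1:3) pm[, , m] <- outer(site_mean[m, ], mult)
  simulation_config(
    occupancy = occ,
    selfing_probability = 0.95,
    n_generations = 15,
    n_msat_loci = 27,
    alleles_per_locus = 6,
    founder_concentration = 0.3,
    n_msap_loci = 381,
    fraction_msl = 0.70,
    lineage_baseline_logit = stats::qlogis(c(0.44, 0.475, 0.43, 0.45, 0.38, 0.42)),
    effect_parasite = 0.4,
    effect_inbreeding = -0.3,
    interaction_lineage_parasite = c(0, -0.6, 0.5, -0.4, 0.6, -0.3),
    interaction_lineage_inbreeding = c(0, -0.4, 0.3, -0.5, 0.4, 0),
    interaction_parasite_inbreeding = -0.5,
    parasite_mean = pm,
    parasite_dispersion = 1.5)
}

.dirichlet_freqs <- function(n_alleles, concentration) {
  if (is.infinite(concentration)) return(rep(1 / n_alleles, n_alleles))
  g <- stats::rgamma(n_alleles, shape = concentration)
  while (sum(g) == 0) g <- stats::rgamma(n_alleles, shape = concentration)
  g / sum(g)
}

#' Simulate a complete mixed-mating dataset
#'
#' Forward-in-time, non-overlapping generations. Founders of each lineage
#' are drawn in Hardy-Weinberg proportions from lineage-specific allele
#' pools. Each generation an offspring derives from one parent of its
#' lineage by selfing (probability s; both gametes from the same parent, so
#' heterozygosity halves in expectation) or from two parents (probability
#' 1 - s; the partner is drawn from any lineage at the same site).
#' Lineage-ancestry fractions are tracked through the pedigree and emitted
#' as the q-matrix. Parasite counts are negative-binomial with configured
#' site x lineage x morphotype means. For methylation-susceptible MS-AFLP
#' loci, the per-individual methylation probability is
#' logistic(baseline(lineage) + b_p * scaled_load + b_i * outcrossed +
#' interactions); a methylated locus is hemimethylated or
#' internally-methylated with equal probability, an unmethylated locus shows
#' the HPA+/MSP+ pattern. Non-susceptible loci carry lineage-determined
#' constant bands. With configured probabilities any MS-AFLP cell becomes
#' the uninformative (0,0) pattern or missing.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed integer seed (defaults to \code{config$rng_seed}); the same
#'   seed yields bit-identical output.
#' @return A list of class \code{"selfmeth_dataset"} with elements
#'   \code{genotypes} (\code{\link{genotype_matrix}}), \code{bands}
#'   (\code{\link{band_matrix}}), \code{qmat} (\code{\link{q_matrix}}),
#'   \code{parasites} (\code{\link{parasite_table}}) and \code{truth}
#'   (per-individual lineage, ancestry, final-generation inbreeding status,
#'   realized inbreeding coefficient, true methylation states and
#'   probabilities, the true MSL locus set, and the configured effects).
#' @export
simulate_dataset <- function(config, seed = config$rng_seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  occ <- config$occupancy
  n_sites <- nrow(occ); K <- ncol(occ)
  L <- config$n_msat_loci; A <- config$alleles_per_locus
  sites <- rownames(occ); lineages <- colnames(occ)

  # lineage x locus founder allele pools (shared across sites so a lineage
  # spanning two sites has one gene pool)
  pools <- array(0, dim = c(K, L, A))
  for (l in seq_len(K)) for (j in seq_len(L))
    pools[l, j, ] <- .dirichlet_freqs(A, config$founder_concentration)

  pop <- vector("list", n_sites)
  for (st in seq_len(n_sites)) {
    lin <- rep(seq_len(K), occ[st, ])
    n <- length(lin)
    if (n == 0) { pop[[st]] <- NULL; next }
    a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
    for (l in unique(lin)) {
      rows <- which(lin == l)
      for (j in seq_len(L)) {
        draws <- sample.int(A, 2 * length(rows), replace = TRUE,
                            prob = pools[l, j, ])
        a1[rows, j] <- draws[seq_along(rows)]
        a2[rows, j] <- draws[length(rows) + seq_along(rows)]
      }
    }
    anc <- matrix(0, n, K); anc[cbind(seq_len(n), lin)] <- 1
    selfed <- rep(TRUE, n)
    s <- config$selfing_probability
    for (g in seq_len(config$n_generations)) {
      # first parent: uniform within the slot's lineage
      p1 <- integer(n)
      for (l in unique(lin)) {
        rows <- which(lin == l)
        p1[rows] <- rows[sample.int(length(rows), length(rows), replace = TRUE)]
      }
      self_ev <- stats::runif(n) < s
      if (n == 1) self_ev[] <- TRUE      # no partner available
      p2 <- p1
      if (any(!self_ev)) {
        out_rows <- which(!self_ev)
        cand <- sample.int(n, length(out_rows), replace = TRUE)
        clash <- cand == p1[out_rows]
        while (any(clash)) {
          cand[clash] <- sample.int(n, sum(clash), replace = TRUE)
          clash <- cand == p1[out_rows]
        }
        p2[out_rows] <- cand
      }
      pick <- matrix(stats::runif(n * L) < 0.5, n, L)
      g1 <- ifelse(pick, a1[p1, , drop = FALSE], a2[p1, , drop = FALSE])
      pick2 <- matrix(stats::runif(n * L) < 0.5, n, L)
      g2 <- ifelse(pick2, a1[p2, , drop = FALSE], a2[p2, , drop = FALSE])
      a1 <- g1; a2 <- g2
      anc <- (anc[p1, , drop = FALSE] + anc[p2, , drop = FALSE]) / 2
      selfed <- self_ev
    }
    pop[[st]] <- list(lin = lin, a1 = a1, a2 = a2, anc = anc, selfed = selfed)
  }

  keep <- which(!vapply(pop, is.null, logical(1)))
  n_tot <- sum(occ)
  ids <- unlist(lapply(keep, function(st)
    sprintf("%s_i%03d", sites[st], seq_len(sum(occ[st, ])))))
  site_of <- rep(sites[keep], vapply(pop[keep], function(p) length(p$lin), 1L))
  lin_of <- unlist(lapply(pop[keep], `[[`, "lin"))
  a1 <- do.call(rbind, lapply(pop[keep], `[[`, "a1"))
  a2 <- do.call(rbind, lapply(pop[keep], `[[`, "a2"))
  anc <- do.call(rbind, lapply(pop[keep], `[[`, "anc"))
  selfed <- unlist(lapply(pop[keep], `[[`, "selfed"))

  geno <- genotype_matrix(ids, site_of,
                          sprintf("msat%02d", seq_len(L)), a1, a2)

  # q-matrix from pedigree ancestry (pad a structural-zero column if K == 1,
  # since a membership matrix needs at least two clusters)
  qm <- anc
  qlin <- lineages
  if (K == 1) { qm <- cbind(qm, 0); qlin <- c(lineages, "L_none") }
  qmat <- q_matrix(ids, qlin, qm)

  # parasites
  morphs <- dimnames(config$parasite_mean)[[3]]
  site_idx <- match(site_of, sites)
  counts <- matrix(0L, n_tot, length(morphs))
  for (m in seq_along(morphs)) {
    mu <- config$parasite_mean[cbind(site_idx, lin_of, m)]
    counts[, m] <- stats::rnbinom(n_tot, size = config$parasite_dispersion,
                                  mu = mu)
  }
  paras <- parasite_table(ids, morphs, counts)
  load <- suppressWarnings(scaled_parasite_load(paras))
  if (all(is.na(load))) load <- rep(0, n_tot)

  # MS-AFLP: methylation-susceptible loci respond to lineage, load,
  # inbreeding status and interactions; the rest carry lineage-fixed bands
  n_msap <- config$n_msap_loci
  n_msl <- round(config$fraction_msl * n_msap)
  msap_loci <- sprintf("aflp%03d", seq_len(n_msap))
  msl_loci <- msap_loci[seq_len(n_msl)]
  out_ind <- as.numeric(!selfed)
  eta <- config$lineage_baseline_logit[lin_of] +
    (config$effect_parasite + config$interaction_lineage_parasite[lin_of]) * load +
    (config$effect_inbreeding + config$interaction_lineage_inbreeding[lin_of]) * out_ind +
    config$interaction_parasite_inbreeding * load * out_ind
  p_meth <- stats::plogis(eta)

  hpa <- matrix(NA_integer_, n_tot, n_msap)
  msp <- matrix(NA_integer_, n_tot, n_msap)
  true_states <- matrix(NA_character_, n_tot, n_msl,
                        dimnames = list(ids, msl_loci))
  if (n_msl > 0) {
    meth <- matrix(stats::runif(n_tot * n_msl), n_tot, n_msl) < p_meth
    hemi <- matrix(stats::runif(n_tot * n_msl) < 0.5, n_tot, n_msl)
    true_states[] <- "UNMETHYLATED"
    true_states[meth & hemi] <- "HEMI"
    true_states[meth & !hemi] <- "INTERNAL"
    hpa[, seq_len(n_msl)] <- ifelse(meth, ifelse(hemi, 1L, 0L), 1L)
    msp[, seq_len(n_msl)] <- ifelse(meth, ifelse(hemi, 0L, 1L), 1L)
  }
  if (n_msap > n_msl) {
    nml_cols <- (n_msl + 1):n_msap
    pres <- matrix(stats::runif(K * length(nml_cols)) < 0.5, K, length(nml_cols))
    band <- pres[lin_of, , drop = FALSE]
    hpa[, nml_cols] <- ifelse(band, 1L, 0L)
    msp[, nml_cols] <- ifelse(band, 1L, 0L)
  }
  u <- matrix(stats::runif(n_tot * n_msap), n_tot, n_msap)
  amb <- u < config$ambiguous_prob
  mis <- u >= config$ambiguous_prob &
    u < config$ambiguous_prob + config$missing_prob
  hpa[amb] <- 0L; msp[amb] <- 0L
  hpa[mis] <- NA_integer_; msp[mis] <- NA_integer_
  bands <- band_matrix(ids, msap_loci, hpa, msp)

  # realized inbreeding: deficit of the individual's heterozygosity relative
  # to its lineage founder-pool expectation
  exp_het <- vapply(seq_len(K), function(l)
    mean(1 - rowSums(pools[l, , , drop = FALSE][1, , ]^2)), 0)
  obs_het <- rowMeans(a1 != a2)
  realized_f <- 1 - obs_het / exp_het[lin_of]

  truth <- list(
    individuals = data.frame(
      id = ids, site = site_of, lineage = lineages[lin_of],
      status = ifelse(selfed, "SELFED", "OUTCROSSED"),
      realized_f = realized_f, scaled_load = load, p_methylation = p_meth,
      stringsAsFactors = FALSE),
    ancestry = { colnames(anc) <- lineages; rownames(anc) <- ids; anc },
    msl_loci = msl_loci,
    states = true_states,
    effects = config[c("lineage_baseline_logit", "effect_parasite",
                       "effect_inbreeding", "interaction_lineage_parasite",
                       "interaction_lineage_inbreeding",
                       "interaction_parasite_inbreeding")])

  structure(list(genotypes = geno, bands = bands, qmat = qmat,
                 parasites = paras, truth = truth, config = config),
            class = "selfmeth_dataset")
}

#' @export
print.selfmeth_dataset <- function(x, ...) {
  cat("Simulated mixed-mating dataset:", length(x$genotypes$ids),
      "individuals,", length(x$genotypes$loci), "microsatellite loci,",
      length(x$bands$loci), "MS-AFLP loci\n")
  tab <- table(x$truth$individuals$status)
  cat("  final-generation status:",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}
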