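# End-to-end driver: from a dataset (simulated or read from CSVs) to the
# full set of study-style reports -- diversity and selfing-rate tables,
# parasite summaries and rank tests, MSL/NML classification, AMOVA tables
# for every marker x grouping combination, PCoA, Mantel tests, and the
# methylation GLM model tables.

#' Run the full analysis pipeline
#'
#' @param dataset a \code{"selfmeth_dataset"} (from
#'   \code{\link{simulate_dataset}}) or a list with \code{genotypes},
#'   \code{bands}, \code{qmat}, \code{parasites}.
#' @param config a \code{\link{pipeline_config}}; its
#'   \code{n_permutations} drives the AMOVA and Mantel tests and its seed
#'   (plus \code{seed}) makes them reproducible.
#' @param seed integer seed for the permutation tests (defaults to
#'   \code{config$rng_seed}).
#' @param run_glm fit the methylation model tables (default \code{TRUE}).
#' @return An object of class \code{"selfmeth_study"}: list with
#'   \code{diversity} (per-site and overall Na/Ho/He/Fis, mean HL, selfing
#'   rate), \code{inbreeding} (classification and per-site selfed /
#'   outcrossed counts), \code{parasites} (summary, prevalence,
#'   Kruskal-Wallis among lineages, Mann-Whitney selfed vs outcrossed),
#'   \code{msap} (locus classification, group methylation percentages),
#'   \code{amova} (marker x grouping table of Phi_ST and p),
#'   \code{mantel}, \code{pcoa}, and \code{glm} (model tables for the
#'   all-sites and single-site scopes).
#' @export
run_study <- function(dataset, config = pipeline_config(),
                      seed = config$rng_seed, run_glm = TRUE) {
  g <- dataset$genotypes
  nperm <- config$n_permutations

  ## genetic diversity (per site and overall)
  div_site <- diversity_summary(g, groups = g$sites)
  div_all <- diversity_summary(g)
  hl <- homozygosity_by_locus(g)
  pooled <- rbind(div_site$pooled, div_all$pooled)
  pooled$group[nrow(pooled)] <- "all"
  pooled$mean_HL <- c(vapply(div_site$pooled$group, function(s)
    mean(hl[g$sites == s], na.rm = TRUE), 0), mean(hl, na.rm = TRUE))
  pooled$s_hat <- selfing_rate_from_fis(pmax(pooled$Fis, 0))$s_hat

  ## inbreeding classification
  ind <- classify_inbreeding(dataset$qmat, config$q_threshold)
  sites_of <- g$sites[match(ind$id, g$ids)]
  counts <- table(site = sites_of, status = ind$status)

  ## parasites
  paras <- dataset$parasites
  load <- scaled_parasite_load(paras)
  prev <- prevalence(paras)
  lin <- ind$assigned_lineage[match(paras$ids, ind$id)]
  kw_load <- kruskal_wallis(load, lin)
  kw_tab <- list(scaled_load = kw_load)
  if ("bacterial_cysts" %in% paras$morphotypes)
    kw_tab$bacterial_cysts <-
      kruskal_wallis(paras$counts[, "bacterial_cysts"], lin)
  status_of <- ind$status[match(paras$ids, ind$id)]
  mw <- list(
    total_load = mann_whitney(load, status_of),
    HL = mann_whitney(hl[match(paras$ids, g$ids)], status_of))

  ## MS-AFLP scoring
  states <- encode_states(dataset$bands)
  cls <- classify_loci(states, config$error_threshold)
  poly_msl <- cls$locus[cls$class == "MSL" & cls$polymorphic]
  grp_meth <- list(
    by_status = group_methylation_percentage(
      states, ind$status[match(states$ids, ind$id)], poly_msl),
    by_lineage = group_methylation_percentage(
      states, ind$assigned_lineage[match(states$ids, ind$id)], poly_msl))

  ## distance matrices
  d_msat <- msat_distance(g)
  d_msl <- binary_distance(methylation_binary(states, poly_msl))
  d_nml <- binary_distance(nml_as_aflp(dataset$bands, cls))

  ## AMOVA: marker x grouping (study Table-3 analog)
  groupings <- list(site = g$sites,
                    lineage = ind$assigned_lineage[match(g$ids, ind$id)],
                    status = ind$status[match(g$ids, ind$id)])
  markers <- list(microsatellites = d_msat, NML = d_nml, MSL = d_msl)
  am_rows <- NULL
  am_fits <- list()
  for (mk in names(markers)) for (gr in names(groupings)) {
    res <- amova(markers[[mk]], groupings[[gr]], n_perm = nperm, seed = seed)
    am_fits[[paste(mk, gr, sep = ".")]] <- res
    am_rows <- rbind(am_rows, data.frame(
      marker = mk, grouping = gr, df_among = res$df_among,
      pct_among = res$percent_among, phi_st = res$phi_st, p = res$p,
      stringsAsFactors = FALSE))
  }

  ## PCoA and Mantel
  pc <- lapply(markers, pcoa)
  mant <- list(
    msl_vs_nml = mantel_test(d_msl, d_nml, n_perm = nperm, seed = seed),
    msl_vs_msat = mantel_test(d_msl, d_msat, n_perm = nperm, seed = seed))

  ## methylation GLMs
  glms <- NULL
  if (run_glm) {
    glms <- list(
      all_sites = run_methylation_analysis(dataset, "all_sites",
                                           "scaled_load", config = config),
      site1 = run_methylation_analysis(dataset, "site1_only",
                                       "scaled_load", config = config))
    if ("bacterial_cysts" %in% paras$morphotypes)
      glms$bacterial_cysts <-
        run_methylation_analysis(dataset, "all_sites", "bacterial_cysts",
                                 config = config)
  }

  structure(list(diversity = pooled, inbreeding = list(table = ind,
                                                       counts = counts),
                 parasites = list(prevalence = prev, scaled_load = load,
                                  kruskal_wallis = kw_tab,
                                  mann_whitney = mw),
                 msap = list(classification = cls,
                             n_polymorphic_msl = length(poly_msl),
                             group_methylation = grp_meth),
                 amova = list(table = am_rows, fits = am_fits),
                 mantel = mant, pcoa = pc, glm = glms,
                 config = config, seed = seed),
            class = "selfmeth_study")
}

#' @export
print.selfmeth_study <- function(x, digits = 3, ...) {
  cat("==== Mixed-mating diversity / methylation / parasite study ====\n\n")
  cat("-- Genetic diversity (microsatellites) --\n")
  print(format(x$diversity, digits = digits), row.names = FALSE)
  cat("\n-- Inbreeding classification (q >= ",
      x$config$q_threshold, ") --\n", sep = "")
  print(x$inbreeding$counts)
  cat("\n-- Parasite prevalence (%) --\n")
  print(format(x$parasites$prevalence, digits = digits), row.names = FALSE)
  kw <- x$parasites$kruskal_wallis$scaled_load
  cat("Kruskal-Wallis, scaled load among lineages: H =",
      round(kw$H, 2), ", df =", kw$df, ", p =", signif(kw$p, 3), "\n")
  cat("\n-- MS-AFLP locus classification --\n")
  print(x$msap$classification)
  cat("\n-- AMOVA (Phi_ST) --\n")
  tab <- x$amova$table
  tab[c("pct_among", "phi_st", "p")] <-
    lapply(tab[c("pct_among", "phi_st", "p")], function(c) round(c, 4))
  print(tab, row.names = FALSE)
  cat("\n-- Mantel tests --\n")
  for (nm in names(x$mantel)) {
    cat(nm, ": ")
    print(x$mantel[[nm]])
  }
  if (!is.null(x$glm)) {
    cat("\n-- Methylation GLM (all sites, scaled load) --\n")
    print(x$glm$all_sites$table, top = 5)
  }
  invisible(x)
}

#' Write a simulated dataset to CSV files
#'
#' Writes the four tables (genotypes, band matrix, q-matrix, parasite
#' counts) in the package's CSV dialects plus the truth record as JSON (if
#' the jsonlite package is available) into a directory.
#'
#' @param dataset a \code{"selfmeth_dataset"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.csv"))
  write_band_matrix(dataset$bands, file.path(dir, "bands.csv"))
  write_qmatrix(dataset$qmat, file.path(dir, "qmatrix.csv"))
  write_parasites(dataset$parasites, file.path(dir, "parasites.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- dataset$truth
    tr$states <- NULL              # large; regenerate by reseeding instead
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE)
  }
  invisible(dir)
}
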