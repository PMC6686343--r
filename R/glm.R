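# Binomial-link modelling of per-individual methylation proportion with
# exhaustive candidate enumeration and AICc-based multimodel comparison.

#' Fit a binomial GLM on (successes, trials) counts
#'
#' Logit-link binomial GLM fitted by iteratively reweighted least squares
#' (via \code{stats::glm}) on the per-individual (methylated, scored) count
#' pair. The log-likelihood includes the binomial combinatorial constant
#' (it cancels in AICc differences).
#'
#' @param terms character vector of model terms (e.g.
#'   \code{c("lineage", "parasite", "lineage:parasite")}); empty for the
#'   intercept-only model.
#' @param data data.frame containing \code{methylated}, \code{scored} and
#'   the predictor columns.
#' @return An object of class \code{"binom_fit"}: list with
#'   \code{terms}, \code{coefficients} (estimate, SE, z, p),
#'   \code{loglik}, \code{k} (estimated parameters), \code{n},
#'   \code{aicc}, \code{deviance}, \code{pearson_overdispersion}
#'   (Pearson chi-square / residual df), \code{separation},
#'   \code{converged}, and the underlying \code{fit}.
#' @export
fit_binomial <- function(terms, data) {
  stopifnot(all(c("methylated", "scored") %in% colnames(data)))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(
    paste("cbind(methylated, scored - methylated) ~", rhs))
  fit <- stats::glm(form, family = stats::binomial(link = "logit"),
                    data = data,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (!fit$converged) warning("IRLS did not converge in 100 iterations")
  ll <- as.numeric(stats::logLik(fit))
  k <- length(cf)
  n <- nrow(data)
  sm <- summary(fit)$coefficients
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  df_res <- fit$df.residual
  structure(list(terms = terms,
                 coefficients = data.frame(
                   term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   z = sm[, 3], p = sm[, 4],
                   row.names = NULL, stringsAsFactors = FALSE),
                 loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n),
                 deviance = stats::deviance(fit),
                 pearson_overdispersion = if (df_res > 0) pearson / df_res
                                          else NA_real_,
                 separation = any(abs(cf) > 15),
                 converged = fit$converged,
                 fit = fit),
            class = "binom_fit")
}

#' @export
print.binom_fit <- function(x, digits = 4, ...) {
  cat("Binomial GLM (logit link): ~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("logLik =", format(x$loglik, digits = digits),
      " k =", x$k, " n =", x$n,
      " AICc =", format(x$aicc, digits = digits), "\n")
  if (x$separation) cat("warning: possible complete separation\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1). Undefined when
#' n <= k + 1 (returned as \code{NA} with a warning; such models are
#' excluded from model tables).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (number of binomial observations).
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1 (n = ", n, ", k = ", k, ")")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate candidate model term sets
#'
#' All subsets of the main effects crossed with all subsets of the
#' candidate two-way interactions. Under marginality (the default) an
#' interaction enters only when both of its main effects are present. The
#' enumeration is deduplicated and deterministically ordered (by number of
#' terms, then lexicographically).
#'
#' @param main_terms character vector of candidate main effects (at most 6).
#' @param interactions character vector of candidate interactions as
#'   \code{"A:B"}; default all pairs of \code{main_terms}.
#' @param marginality require both main effects for an interaction
#'   (default \code{TRUE}).
#' @return List of character vectors (each one model's terms), first the
#'   intercept-only model \code{character(0)}.
#' @export
enumerate_models <- function(main_terms,
                             interactions = NULL,
                             marginality = TRUE) {
  if (length(main_terms) > 6) stop("more than 6 candidate terms")
  if (anyDuplicated(main_terms)) stop("duplicate main terms")
  if (is.null(interactions)) {
    interactions <- character(0)
    if (length(main_terms) >= 2) {
      cmb <- utils::combn(main_terms, 2)
      interactions <- paste(cmb[1, ], cmb[2, ], sep = ":")
    }
  }
  subsets <- function(v) {
    out <- list(character(0))
    for (x in v) out <- c(out, lapply(out, c, x))
    out
  }
  models <- list()
  for (ms in subsets(main_terms)) {
    cand_int <- if (marginality) {
      keep <- vapply(strsplit(interactions, ":", fixed = TRUE),
                     function(p) all(p %in% ms), TRUE)
      interactions[keep]
    } else interactions
    for (is_ in subsets(cand_int)) models <- c(models, list(c(ms, is_)))
  }
  keys <- vapply(models, function(m) paste(sort(m), collapse = "|"), "")
  models <- models[!duplicated(keys)]
  ord <- order(lengths(models),
               vapply(models, function(m) paste(sort(m), collapse = "|"), ""))
  models[ord]
}

#' Rank fitted models by AICc
#'
#' Computes delta AICc against the best model, Akaike weights
#' w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2), and the evidence ratio of
#' the best model over each model (w_best/w_i = exp(delta_i/2)).
#'
#' @param fits list of \code{"binom_fit"} objects; fits with undefined AICc
#'   are excluded with a warning.
#' @return An object of class \code{"model_table"}: data.frame sorted by
#'   AICc with \code{model}, \code{k}, \code{loglik}, \code{aicc},
#'   \code{delta_aicc}, \code{weight}, \code{evidence_ratio}; the sorted
#'   fits are kept in \code{attr(, "fits")}.
#' @export
model_table <- function(fits) {
  if (inherits(fits, "binom_fit")) fits <- list(fits)
  av <- vapply(fits, function(f) f$aicc, 0)
  if (any(is.na(av))) {
    warning(sum(is.na(av)), " model(s) with undefined AICc excluded")
    fits <- fits[!is.na(av)]
    av <- av[!is.na(av)]
  }
  if (!length(fits)) stop("no successful fit")
  ord <- order(av)
  fits <- fits[ord]; av <- av[ord]
  delta <- av - av[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(intercept)", ""),
    k = vapply(fits, function(f) f$k, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aicc = av, delta_aicc = delta, weight = w,
    evidence_ratio = exp(delta / 2),
    stringsAsFactors = FALSE)
  attr(tab, "fits") <- fits
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, digits = 4, top = 10, ...) {
  cat("Model comparison (", nrow(x), " candidates, sorted by AICc):\n",
      sep = "")
  show <- utils::head(as.data.frame(x), top)
  show[-1] <- lapply(show[-1], function(c) round(c, digits))
  print(show, row.names = FALSE)
  if (nrow(x) > top) cat("... and", nrow(x) - top, "more\n")
  invisible(x)
}

#' @export
summary.model_table <- function(object, ...) {
  best <- attr(object, "fits")[[1]]
  cat("Best model by AICc (weight ",
      round(object$weight[1], 3), "):\n", sep = "")
  print(best)
  if (nrow(object) > 1)
    cat("Second model: delta AICc =", round(object$delta_aicc[2], 3),
        ", evidence ratio =", round(object$evidence_ratio[2], 3), "\n")
  invisible(object)
}

#' Methylation-proportion GLM analysis
#'
#' Assembles the per-individual binomial response (methylated, scored) over
#' the polymorphic methylation-susceptible loci, together with the
#' predictors -- selfing lineage (argmax-q assignment; outcrossed
#' individuals keep their argmax lineage), inbreeding status (selfed vs
#' outcrossed by the q-threshold), sampling site, and either the scaled
#' parasite load or the raw count of the dominant morphotype -- then fits
#' every candidate model (all main-effect subsets with the
#' lineage x parasite, lineage x inbreeding and parasite x inbreeding
#' two-way interactions under marginality) and ranks them by AICc.
#'
#' @param dataset a \code{"selfmeth_dataset"} from
#'   \code{\link{simulate_dataset}}, or any list with elements
#'   \code{bands}, \code{qmat}, \code{parasites}, \code{genotypes}.
#' @param scope \code{"all_sites"} (site enters as a main effect when >= 2
#'   sites are present) or \code{"site1_only"} (restrict to one site and
#'   drop the site term).
#' @param predictor \code{"scaled_load"} or the name of a single morphotype
#'   (e.g. \code{"bacterial_cysts"}) whose raw counts are used instead.
#' @param site which site \code{"site1_only"} restricts to (default the
#'   first site label in order of appearance).
#' @param config a \code{\link{pipeline_config}} (error and q thresholds).
#' @return An object of class \code{"methylation_analysis"}: list with
#'   \code{table} (a \code{\link{model_table}}), \code{best}
#'   (\code{"binom_fit"}), \code{data} (the assembled model frame) and
#'   \code{scope}/\code{predictor} tags.
#' @export
run_methylation_analysis <- function(dataset,
                                     scope = c("all_sites", "site1_only"),
                                     predictor = "scaled_load",
                                     site = NULL,
                                     config = pipeline_config()) {
  scope <- match.arg(scope)
  states <- encode_states(dataset$bands)
  cls <- classify_loci(states, config$error_threshold)
  poly_msl <- cls$locus[cls$class == "MSL" & cls$polymorphic]
  if (!length(poly_msl)) stop("no polymorphic methylation-susceptible locus")
  prop <- methylation_proportion(states, poly_msl)
  ind <- classify_inbreeding(dataset$qmat, config$q_threshold)
  if (predictor == "scaled_load") {
    par_val <- scaled_parasite_load(dataset$parasites)
  } else {
    if (!predictor %in% dataset$parasites$morphotypes)
      stop("unknown predictor morphotype: ", predictor)
    par_val <- dataset$parasites$counts[, predictor]
    names(par_val) <- dataset$parasites$ids
  }
  sites <- dataset$genotypes$sites
  names(sites) <- dataset$genotypes$ids
  ids <- Reduce(intersect, list(prop$id, ind$id, names(par_val), names(sites)))
  if (!length(ids)) stop("no individual shared across inputs")
  df <- data.frame(
    id = ids,
    methylated = prop$methylated[match(ids, prop$id)],
    scored = prop$scored[match(ids, prop$id)],
    lineage = factor(ind$assigned_lineage[match(ids, ind$id)]),
    inbreeding = factor(ind$status[match(ids, ind$id)],
                        levels = c("SELFED", "OUTCROSSED")),
    parasite = as.numeric(par_val[ids]),
    site = factor(sites[ids]),
    stringsAsFactors = FALSE)
  df <- df[df$scored > 0, ]
  if (scope == "site1_only") {
    if (is.null(site)) site <- as.character(df$site[1])
    df <- df[df$site == site, ]
    df$site <- droplevels(df$site)
  }
  df$lineage <- droplevels(df$lineage)
  df$inbreeding <- droplevels(df$inbreeding)

  mains <- "parasite"
  if (nlevels(df$lineage) >= 2) mains <- c("lineage", mains)
  else warning("fewer than 2 lineages in scope; lineage term dropped")
  if (nlevels(df$inbreeding) >= 2) mains <- c(mains, "inbreeding")
  if (scope == "all_sites" && nlevels(df$site) >= 2) mains <- c(mains, "site")
  ints <- c("lineage:parasite", "lineage:inbreeding", "parasite:inbreeding")
  ints <- ints[vapply(strsplit(ints, ":", fixed = TRUE),
                      function(p) all(p %in% mains), TRUE)]
  specs <- enumerate_models(mains, interactions = ints, marginality = TRUE)
  fits <- list()
  for (sp in specs) {
    f <- tryCatch(suppressWarnings(fit_binomial(sp, df)),
                  error = function(e) NULL)
    if (!is.null(f) && !is.na(f$aicc)) fits <- c(fits, list(f))
  }
  tab <- model_table(fits)
  structure(list(table = tab, best = attr(tab, "fits")[[1]], data = df,
                 scope = scope, predictor = predictor,
                 n_candidates = length(specs)),
            class = "methylation_analysis")
}

#' @export
print.methylation_analysis <- function(x, ...) {
  cat("Methylation GLM analysis (scope: ", x$scope,
      ", predictor: ", x$predictor, ", n = ", nrow(x$data), ")\n", sep = "")
  print(x$table, top = 5)
  cat("\nBest model coefficients:\n")
  print(x$best)
  invisible(x)
}
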