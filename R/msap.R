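# Dual-digest (HpaII/MspI) band-pattern scoring: methylation states, the
# MSL/NML locus partition, methylation summaries, replicate error rate.

.STATE_LEVELS <- c("UNMETHYLATED", "HEMI", "INTERNAL", "AMBIGUOUS")

#' Encode dual-digest band patterns into methylation states
#'
#' Cellwise mapping of the HpaII/MspI isoschizomer patterns:
#' HPA+/MSP+ (1,1) -> UNMETHYLATED, HPA+/MSP- (1,0) -> HEMI (hemimethylated
#' external cytosine), HPA-/MSP+ (0,1) -> INTERNAL (internal cytosine
#' methylation), HPA-/MSP- (0,0) -> AMBIGUOUS (hypermethylation
#' indistinguishable from absence of the target). Missing band cells give
#' missing states.
#'
#' @param b a \code{\link{band_matrix}}.
#' @return An object of class \code{"methylation_states"}: list with
#'   \code{ids}, \code{loci} and a character \code{states} matrix with
#'   entries in UNMETHYLATED/HEMI/INTERNAL/AMBIGUOUS or \code{NA}.
#' @export
encode_states <- function(b) {
  stopifnot(inherits(b, "band_matrix"))
  code <- b$hpa * 2L + b$msp              # 3,2,1,0 -> states
  states <- matrix(NA_character_, length(b$ids), length(b$loci),
                   dimnames = list(b$ids, b$loci))
  states[which(code == 3L)] <- "UNMETHYLATED"
  states[which(code == 2L)] <- "HEMI"
  states[which(code == 1L)] <- "INTERNAL"
  states[which(code == 0L)] <- "AMBIGUOUS"
  structure(list(ids = b$ids, loci = b$loci, states = states),
            class = "methylation_states")
}

#' @export
print.methylation_states <- function(x, ...) {
  cat("Methylation states:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  print(table(factor(x$states, levels = .STATE_LEVELS), useNA = "ifany"))
  invisible(x)
}

#' Partition loci into methylation-susceptible (MSL) and non-methylated (NML)
#'
#' A locus is methylation-susceptible iff the frequency of
#' methylation-indicative patterns (HEMI or INTERNAL) across all scored
#' (non-missing) cells -- AMBIGUOUS cells count in the denominator --
#' strictly exceeds the replicate error threshold; otherwise it is a
#' non-methylated locus usable as a neutral AFLP genetic marker. A retained
#' MSL locus is polymorphic iff at least two distinct non-missing states
#' occur. Loci with no scored cell are dropped with a warning.
#'
#' @param m a \code{"methylation_states"} object from
#'   \code{\link{encode_states}}.
#' @param error_threshold replicate error rate (default 0.05); the
#'   comparison is strict ("exceeds").
#' @return An object of class \code{"locus_classification"}: data.frame with
#'   \code{locus}, \code{class} ("MSL"/"NML"), \code{meth_freq},
#'   \code{polymorphic}, \code{n_scored}; dropped loci recorded in
#'   \code{attr(, "dropped")}.
#' @export
classify_loci <- function(m, error_threshold = 0.05) {
  stopifnot(inherits(m, "methylation_states"))
  st <- m$states
  scored <- colSums(!is.na(st))
  meth <- colSums(st == "HEMI" | st == "INTERNAL", na.rm = TRUE)
  drop <- scored == 0
  if (any(drop))
    warning(sum(drop), " locus/loci with all cells missing dropped: ",
            paste(utils::head(m$loci[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ...")
  keep <- which(!drop)
  freq <- meth[keep] / scored[keep]
  cls <- ifelse(freq > error_threshold, "MSL", "NML")
  poly <- vapply(keep, function(j)
    length(unique(st[!is.na(st[, j]), j])) >= 2, TRUE)
  out <- data.frame(locus = m$loci[keep], class = cls, meth_freq = freq,
                    polymorphic = poly, n_scored = scored[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- m$loci[drop]
  class(out) <- c("locus_classification", "data.frame")
  out
}

#' @export
print.locus_classification <- function(x, ...) {
  tab <- table(x$class)
  cat("Locus classification:", nrow(x), "loci retained (",
      paste(names(tab), tab, collapse = ", "), ");",
      length(attr(x, "dropped")), "dropped\n")
  cat("  polymorphic MSL:", sum(x$polymorphic[x$class == "MSL"]), "\n")
  invisible(x)
}

#' Extract the NML loci as binary AFLP genetic markers
#'
#' Non-methylated loci carry no methylation signal; their band presence is a
#' plain dominant AFLP genotype. The HPA profile is used (the two digests
#' agree at NML loci up to error).
#'
#' @param b a \code{\link{band_matrix}}.
#' @param classification a \code{\link{classify_loci}} result.
#' @return Binary matrix (individuals x NML loci) with \code{NA} for
#'   missing.
#' @export
nml_as_aflp <- function(b, classification) {
  stopifnot(inherits(b, "band_matrix"))
  nml <- classification$locus[classification$class == "NML"]
  b$hpa[, nml, drop = FALSE]
}

#' Binary methylated/unmethylated recoding of MSL loci
#'
#' HEMI and INTERNAL collapse to 1 (methylated), UNMETHYLATED to 0;
#' AMBIGUOUS cells become \code{NA} by default (the (0,0) pattern confounds
#' hypermethylation with absence of the target) or 0 if
#' \code{ambiguous_as_unmethylated}.
#'
#' @param m a \code{"methylation_states"} object.
#' @param loci which loci to keep (default all).
#' @param ambiguous_as_unmethylated treat AMBIGUOUS as unmethylated instead
#'   of missing (default \code{FALSE}).
#' @return Binary matrix (individuals x loci) with \code{NA} for excluded
#'   cells.
#' @export
methylation_binary <- function(m, loci = m$loci,
                               ambiguous_as_unmethylated = FALSE) {
  st <- m$states[, loci, drop = FALSE]
  out <- matrix(NA_integer_, nrow(st), ncol(st), dimnames = dimnames(st))
  out[st == "UNMETHYLATED"] <- 0L
  out[st == "HEMI" | st == "INTERNAL"] <- 1L
  if (ambiguous_as_unmethylated) out[st == "AMBIGUOUS"] <- 0L
  out
}

#' Per-individual proportion of methylated loci
#'
#' Over the given loci (typically the polymorphic MSL), the proportion of
#' loci scored methylated (HEMI or INTERNAL) out of the loci observed for
#' that individual. By default AMBIGUOUS cells are excluded from the
#' denominator along with missing cells; set \code{include_ambiguous} to
#' count them as unmethylated instead.
#'
#' @param m a \code{"methylation_states"} object.
#' @param loci loci to include (default all; pass the polymorphic MSL set
#'   for the standard analysis).
#' @param include_ambiguous count AMBIGUOUS cells as unmethylated in the
#'   denominator (default \code{FALSE}).
#' @return data.frame with \code{id}, \code{methylated}, \code{scored},
#'   \code{proportion} (NA when no locus scored).
#' @export
methylation_proportion <- function(m, loci = m$loci,
                                   include_ambiguous = FALSE) {
  bin <- methylation_binary(m, loci,
                            ambiguous_as_unmethylated = include_ambiguous)
  meth <- rowSums(bin == 1L, na.rm = TRUE)
  scored <- rowSums(!is.na(bin))
  data.frame(id = m$ids, methylated = meth, scored = scored,
             proportion = ifelse(scored > 0, meth / scored, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group methylation percentage
#'
#' Pooled over a group's cells. The default \code{"ratio"} reading follows
#' the classical group-percentage formula literally: 100 x (HEMI +
#' INTERNAL) / (UNMETHYLATED + AMBIGUOUS). The \code{"proportion"} reading
#' instead divides by all scored cells: 100 x (HEMI + INTERNAL) / (all
#' non-missing cells).
#'
#' @param m a \code{"methylation_states"} object.
#' @param groups group label per individual.
#' @param loci loci to include (default all).
#' @param reading \code{"ratio"} (default) or \code{"proportion"}.
#' @return data.frame with \code{group}, \code{percent}, counts per state
#'   class.
#' @export
group_methylation_percentage <- function(m, groups, loci = m$loci,
                                         reading = c("ratio", "proportion")) {
  reading <- match.arg(reading)
  groups <- as.character(groups)
  stopifnot(length(groups) == length(m$ids))
  st <- m$states[, loci, drop = FALSE]
  out <- NULL
  for (grp in unique(groups)) {
    rows <- which(groups == grp)
    if (!length(rows)) stop("empty group: ", grp)
    s <- st[rows, , drop = FALSE]
    n_meth <- sum(s == "HEMI" | s == "INTERNAL", na.rm = TRUE)
    n_unmeth <- sum(s == "UNMETHYLATED", na.rm = TRUE)
    n_amb <- sum(s == "AMBIGUOUS", na.rm = TRUE)
    denom <- if (reading == "ratio") n_unmeth + n_amb
             else n_meth + n_unmeth + n_amb
    if (denom == 0) stop("zero denominator in group: ", grp)
    out <- rbind(out, data.frame(group = grp,
                                 percent = 100 * n_meth / denom,
                                 n_methylated = n_meth,
                                 n_unmethylated = n_unmeth,
                                 n_ambiguous = n_amb,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Replicate scoring error rate
#'
#' Reproducibility of MS-AFLP genotyping: the number of individual x locus
#' cells whose band pattern differs between original and replicate profiles
#' (a mismatch in either digest counts once), divided by (number of shared
#' loci x number of replicated individuals). Cells missing in either copy
#' are not counted as mismatches.
#'
#' @param original,replicate \code{\link{band_matrix}} objects; replicate
#'   individuals must be a subset of the originals.
#' @return list with \code{rate}, \code{n_mismatch}, \code{n_loci},
#'   \code{n_individuals}.
#' @export
replicate_error_rate <- function(original, replicate) {
  stopifnot(inherits(original, "band_matrix"), inherits(replicate, "band_matrix"))
  if (!all(replicate$ids %in% original$ids))
    stop("replicate individuals must be a subset of the originals")
  loci <- intersect(original$loci, replicate$loci)
  if (!length(loci)) stop("no shared loci between original and replicate")
  ids <- replicate$ids
  diff_h <- original$hpa[ids, loci, drop = FALSE] !=
    replicate$hpa[ids, loci, drop = FALSE]
  diff_m <- original$msp[ids, loci, drop = FALSE] !=
    replicate$msp[ids, loci, drop = FALSE]
  mism <- sum(diff_h | diff_m, na.rm = TRUE)
  list(rate = mism / (length(loci) * length(ids)),
       n_mismatch = mism, n_loci = length(loci), n_individuals = length(ids))
}
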