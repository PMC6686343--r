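# CSV readers/writers. All dialects are UTF-8, comma-delimited, header
# required; no sniffing. Errors name the offending file and row.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Read a codominant genotype table
#'
#' Dialect: first column the individual id, second the site label, then two
#' columns per locus holding the integer allele codes. The locus name is the
#' first column name of each pair with a trailing \code{"_1"}/\code{".1"}
#' stripped. The pair \code{0,0} is the missing-call sentinel (GenAlEx
#' convention).
#'
#' @param path CSV file path.
#' @return A \code{\link{genotype_matrix}}.
#' @seealso \code{\link{write_genotypes}}
#' @export
read_genotypes <- function(path) {
  df <- .read_csv(path)
  if (ncol(df) < 4)
    stop(path, ": need id, site and at least one locus column pair")
  acols <- df[, -(1:2), drop = FALSE]
  if (ncol(acols) %% 2 != 0)
    stop(path, ": odd number of allele columns (", ncol(acols), ")")
  idx1 <- seq(1, ncol(acols), by = 2)
  loci <- sub("([._]1|[._]a)$", "", colnames(acols)[idx1])
  a1 <- as.matrix(acols[, idx1, drop = FALSE])
  a2 <- as.matrix(acols[, idx1 + 1, drop = FALSE])
  suppressWarnings({ storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer" })
  if (anyNA(a1) != anyNA(a2) || anyNA(a1) || anyNA(a2))
    stop(path, ": non-integer or empty allele cell(s)")
  if (any(a1 < 0) || any(a2 < 0)) {
    bad <- which(a1 < 0 | a2 < 0, arr.ind = TRUE)[1, 1]
    stop(path, ": negative allele code at data row ", bad)
  }
  miss <- a1 == 0L & a2 == 0L
  half0 <- xor(a1 == 0L, a2 == 0L)
  if (any(half0)) {
    bad <- which(half0, arr.ind = TRUE)[1, 1]
    stop(path, ": single-allele 0 sentinel at data row ", bad,
         " (missing calls must be 0,0)")
  }
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_matrix(df[[1]], df[[2]], loci, a1, a2)
}

#' Write a codominant genotype table
#'
#' Inverse of \code{\link{read_genotypes}}; missing calls are written as the
#' \code{0,0} sentinel.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(g, path) {
  a1 <- g$a1; a2 <- g$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  out <- data.frame(id = g$ids, site = g$sites, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(g$loci)) {
    out[[paste0(g$loci[j], "_1")]] <- a1[, j]
    out[[paste0(g$loci[j], "_2")]] <- a2[, j]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an MS-AFLP band matrix
#'
#' Dialect: columns \code{id}, \code{digest} (\code{"HPA"} or \code{"MSP"}),
#' then one column per locus with cells 0, 1 or empty (missing). One row per
#' individual x digest; an individual missing one digest row entirely gets
#' missing cells there (and the half-missing cells are then promoted to
#' missing in both digests by \code{\link{band_matrix}}).
#'
#' @param path CSV file path.
#' @return A \code{\link{band_matrix}}.
#' @export
read_band_matrix <- function(path) {
  df <- .read_csv(path)
  if (ncol(df) < 3 || !all(c("id", "digest") %in% colnames(df)[1:2]))
    stop(path, ": expected columns id, digest, then loci")
  dig <- toupper(df$digest)
  if (!all(dig %in% c("HPA", "MSP")))
    stop(path, ": digest must be HPA or MSP (row ",
         which(!dig %in% c("HPA", "MSP"))[1], ")")
  loci <- colnames(df)[-(1:2)]
  ids <- unique(df$id)
  cells <- as.matrix(df[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(cells) <- "integer")
  if (any(!(cells %in% c(0L, 1L)) & !is.na(cells))) {
    bad <- which(!(cells %in% c(0L, 1L)) & !is.na(cells), arr.ind = TRUE)[1, 1]
    stop(path, ": non-binary band cell at data row ", bad)
  }
  pick <- function(which_digest) {
    m <- matrix(NA_integer_, length(ids), length(loci),
                dimnames = list(ids, loci))
    sel <- dig == which_digest
    if (any(duplicated(df$id[sel])))
      stop(path, ": duplicate ", which_digest, " row for an individual")
    m[df$id[sel], ] <- cells[sel, , drop = FALSE]
    m
  }
  band_matrix(ids, loci, pick("HPA"), pick("MSP"))
}

#' Write an MS-AFLP band matrix
#'
#' Inverse of \code{\link{read_band_matrix}}.
#'
#' @param b a \code{\link{band_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_band_matrix <- function(b, path) {
  rows <- rbind(
    data.frame(id = b$ids, digest = "HPA", b$hpa, check.names = FALSE),
    data.frame(id = b$ids, digest = "MSP", b$msp, check.names = FALSE))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a parasite count table
#'
#' Dialect: column \code{id}, then one non-negative integer count column per
#' morphotype. No missing cells are allowed (unscreened individuals are
#' absent rows).
#'
#' @param path CSV file path.
#' @return A \code{\link{parasite_table}}.
#' @export
read_parasites <- function(path) {
  df <- .read_csv(path)
  if (ncol(df) < 2) stop(path, ": expected id plus count columns")
  counts <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "integer")
  if (anyNA(counts))
    stop(path, ": missing or non-integer count at data row ",
         which(rowSums(is.na(counts)) > 0)[1])
  if (any(counts < 0))
    stop(path, ": negative count at data row ",
         which(rowSums(counts < 0) > 0)[1])
  parasite_table(df[[1]], colnames(df)[-1], counts)
}

#' Write a parasite count table
#' @param t a \code{\link{parasite_table}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_parasites <- function(t, path) {
  utils::write.csv(data.frame(id = t$ids, t$counts, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cluster-membership (q-value) matrix
#'
#' Dialect: column \code{id}, then one membership-fraction column per
#' cluster. Rows off 1 by at most 1e-3 are renormalized; beyond that the
#' file is rejected.
#'
#' @param path CSV file path.
#' @return A \code{\link{q_matrix}}.
#' @export
read_qmatrix <- function(path) {
  df <- .read_csv(path)
  if (ncol(df) < 3) stop(path, ": expected id plus >= 2 cluster columns")
  q <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(q) <- "double"
  q_matrix(df[[1]], colnames(df)[-1], q)
}

#' Write a q-matrix
#' @param qm a \code{\link{q_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_qmatrix <- function(qm, path) {
  utils::write.csv(data.frame(id = qm$ids, qm$q, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Binarize a fragment peak table into a band matrix
#'
#' Applies GeneMapper-style filters to raw fragment peaks: a band is present
#' (1) at a locus bin iff at least one peak of that individual and digest has
#' height >= \code{peak_min_height} RFU, size inside the analysis window
#' [\code{peak_min_size}, \code{peak_max_size}) and size inside the bin's
#' half-open interval [low, high). Individuals with no peaks at all in a
#' digest get missing at every locus of that digest (then promoted to missing
#' in both digests).
#'
#' @param peaks data.frame with columns \code{individual_id}, \code{digest}
#'   ("HPA"/"MSP"), \code{size} (bp, positive), \code{height} (RFU, positive).
#' @param config a \code{\link{pipeline_config}}.
#' @param locus_bins data.frame with columns \code{label}, \code{low},
#'   \code{high}: disjoint half-open intervals inside the analysis window.
#' @return A \code{\link{band_matrix}}.
#' @export
binarize_peaks <- function(peaks, config = pipeline_config(), locus_bins) {
  need <- c("individual_id", "digest", "size", "height")
  if (!all(need %in% colnames(peaks)))
    stop("peaks must have columns: ", paste(need, collapse = ", "))
  if (any(peaks$size <= 0) || any(peaks$height <= 0))
    stop("fragment sizes and peak heights must be positive")
  bins <- as.data.frame(locus_bins)
  if (!all(c("label", "low", "high") %in% colnames(bins)))
    stop("locus_bins must have columns label, low, high")
  if (any(bins$low >= bins$high)) stop("empty locus bin(s)")
  if (any(bins$low < config$peak_min_size) ||
      any(bins$high > config$peak_max_size))
    stop("locus bin(s) outside the analysis range [",
         config$peak_min_size, ", ", config$peak_max_size, ")")
  o <- order(bins$low)
  if (any(bins$high[o][-nrow(bins)] > bins$low[o][-1]))
    stop("overlapping locus bins")
  dig <- toupper(peaks$digest)
  if (!all(dig %in% c("HPA", "MSP"))) stop("digest must be HPA or MSP")
  ids <- unique(as.character(peaks$individual_id))
  keep <- peaks$height >= config$peak_min_height &
    peaks$size >= config$peak_min_size & peaks$size < config$peak_max_size
  score <- function(which_digest) {
    m <- matrix(NA_integer_, length(ids), nrow(bins),
                dimnames = list(ids, bins$label))
    sel_dig <- dig == which_digest
    # any peak record at all (even filtered-out) means the digest ran
    m[unique(as.character(peaks$individual_id[sel_dig])), ] <- 0L
    sel <- sel_dig & keep
    if (any(sel)) {
      sz <- peaks$size[sel]
      pid <- as.character(peaks$individual_id[sel])
      for (bidx in seq_len(nrow(bins))) {
        hit <- sz >= bins$low[bidx] & sz < bins$high[bidx]
        if (any(hit)) m[unique(pid[hit]), bidx] <- 1L
      }
    }
    m
  }
  band_matrix(ids, bins$label, score("HPA"), score("MSP"))
}
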