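# Core NPP transforms: self-score normalization and per-genome Z-scoring.
#
# Whole-genome mode normalizes each protein's per-genome top bit score by
# its self-score (the top BLAST score of the protein against its own
# genome), giving conservation values in [0, 1]. Each genome column is then
# standardized against the distribution of normalized scores of all
# retained proteins in that genome, which adjusts for the genome's overall
# evolutionary distance from the query genome.

#' Normalize bit scores by the query protein's self-score
#'
#' Divides every score in a protein's row by that protein's self-score, the
#' entry in the query-genome column (the top within-genome BLAST score,
#' which may come from a close paralog). Missing cells become 0 — complete
#' absence of a detectable homolog is treated as total divergence — and
#' values are capped at 1 (a cross-genome score can exceed the self-score
#' in rare duplicated-domain cases).
#'
#' @param matrix Raw score matrix after filtering.
#' @param manifest A [genome_manifest()]; its query genome column supplies
#'   the self-scores.
#' @return Numeric matrix of the same shape with values in `[0, 1]`; the
#'   query-genome column is identically 1.
#' @export
normalize_by_self <- function(matrix, manifest) {
  qg <- query_genome(manifest)
  if (!qg %in% colnames(matrix))
    npp_stop("query genome '%s' is not a column of the matrix", qg)
  self <- matrix[, qg]
  bad <- is.na(self) | self <= 0
  if (any(bad))
    npp_stop("cannot normalize: missing or zero self-score for protein(s) %s",
             paste(utils::head(rownames(matrix)[bad], 10), collapse = ", "))
  out <- matrix / self
  out[is.na(out)] <- 0
  out[out > 1] <- 1
  out
}

#' Per-genome mean and standard deviation of normalized scores
#'
#' Computes, for every genome column, the mean and the population standard
#' deviation (divide by n, not n - 1) over all retained proteins, zeros
#' included. These statistics define the Z-transform and are the quantities
#' reused by sequence-submission mode.
#'
#' @param matrix Normalized matrix ([normalize_by_self()] or the sequence
#'   analogue).
#' @return Object of class `genome_stats`: a `data.frame` with columns
#'   `genome_id`, `mean`, `sd`, `n`.
#' @export
compute_genome_stats <- function(matrix) {
  if (nrow(matrix) < 2) npp_stop("need at least 2 proteins to compute stats")
  mu <- colMeans(matrix)
  sd <- sqrt(colMeans(sweep(matrix, 2, mu)^2))
  zero <- sd <= 0
  if (any(zero))
    npp_stop("zero-variance genome column(s): %s (Z-score undefined)",
             paste(colnames(matrix)[zero], collapse = ", "))
  structure(data.frame(genome_id = colnames(matrix), mean = unname(mu),
                       sd = unname(sd), n = nrow(matrix),
                       stringsAsFactors = FALSE),
            class = c("genome_stats", "data.frame"))
}

#' Z-score a normalized matrix with given per-genome statistics
#'
#' Standardizes every genome column: `z = (value - mean_g) / sd_g`, using
#' the supplied statistics rather than recomputing them, so the same
#' transform can be applied to a stored matrix and to a new query profile.
#' A column whose stats carry `sd = NA` (a constant column, such as the
#' query-genome column of a self-normalized matrix, which is identically 1)
#' is mapped to Z = 0: it shows no deviation from its genome-wide
#' expectation for any protein.
#'
#' @param matrix Normalized matrix.
#' @param stats A `genome_stats` table covering every column of `matrix`.
#' @return Numeric matrix of Z-scores, same shape and dimnames.
#' @export
zscore_matrix <- function(matrix, stats) {
  missing_g <- setdiff(colnames(matrix), stats$genome_id)
  if (length(missing_g) > 0)
    npp_stop("no statistics for genome(s): %s",
             paste(missing_g, collapse = ", "))
  idx <- match(colnames(matrix), stats$genome_id)
  mu <- stats$mean[idx]
  sd <- stats$sd[idx]
  z <- sweep(matrix, 2, mu)
  const <- is.na(sd)
  sd[const] <- 1
  z <- sweep(z, 2, sd, `/`)
  z[, const] <- 0
  z
}

#' Read / write per-genome statistics as TSV
#'
#' 4-column tab-separated table with header: `genome_id`, `mean`, `sd`, `n`.
#' `NA` in the `sd` column marks a constant column (see [zscore_matrix()]).
#'
#' @param stats A `genome_stats` table.
#' @param path File path.
#' @return `read_genome_stats()` returns the `genome_stats` table;
#'   `write_genome_stats()` returns `path` invisibly.
#' @export
write_genome_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_genome_stats
#' @export
read_genome_stats <- function(path) {
  if (!file.exists(path)) npp_stop("stats file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  df$genome_id <- as.character(df$genome_id)
  structure(df, class = c("genome_stats", "data.frame"))
}
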