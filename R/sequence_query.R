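# Sequence-submission mode: profile a single query sequence against the
# precomputed database.
#
# When the query is a user-submitted sequence rather than a protein of the
# query genome, there is no self-score, so the workflow changes in two
# places: bit scores are normalized by the highest score among the genome
# hits, and Z-scores are computed from the precomputed per-genome mean and
# standard deviation (the statistics of the whole-genome build), not from
# the single profile itself.

#' Normalize per-genome scores by the best genome hit
#'
#' Divides every present top bit score by the maximum present score, so the
#' best-matching genome normalizes to exactly 1; missing genomes become 0.
#'
#' @param raw_scores Named numeric vector of per-genome top bit scores,
#'   `NA` for genomes without a surviving hit.
#' @return Named numeric vector in `[0, 1]` over the same genomes.
#' @export
normalize_by_max <- function(raw_scores) {
  present <- !is.na(raw_scores)
  if (!any(present) || max(raw_scores[present]) <= 0)
    npp_stop("no homologs above threshold: nothing to normalize")
  out <- raw_scores / max(raw_scores[present])
  out[!present] <- 0
  out
}

#' Z-score a single profile with precomputed genome statistics
#'
#' Applies the stored per-genome transform `z = (value - mean_g) / sd_g`
#' to a normalized single-query profile. Constant columns (`sd = NA` in the
#' stats) map to Z = 0, consistently with [zscore_matrix()].
#'
#' @param normalized Named numeric vector of normalized per-genome values.
#' @param stats A `genome_stats` table covering every genome in the profile.
#' @return Named numeric vector of Z-scores.
#' @export
zscore_with_stats <- function(normalized, stats) {
  missing_g <- setdiff(names(normalized), stats$genome_id)
  if (length(missing_g) > 0)
    npp_stop("no statistics for genome(s): %s",
             paste(missing_g, collapse = ", "))
  idx <- match(names(normalized), stats$genome_id)
  mu <- stats$mean[idx]
  sd <- stats$sd[idx]
  const <- is.na(sd)
  sd[const] <- 1
  z <- (normalized - mu) / sd
  z[const] <- 0
  z
}

#' Rank database profiles against a submitted sequence's scores
#'
#' Full sequence-mode workflow after BLAST: filter low scores (< threshold),
#' normalize by the best genome hit, Z-score with the precomputed genome
#' statistics, then rank the stored Z-profiles by Pearson correlation with
#' permutation significance, exactly as in whole-genome mode.
#'
#' @param raw_scores Named numeric vector of per-genome top bit scores for
#'   the single query (`NA` = no hit).
#' @param stats Precomputed `genome_stats` from the whole-genome build.
#' @param zmatrix Precomputed Z-score matrix to search.
#' @param k Number of hits to return.
#' @param n_shuffles,seed Permutation-null controls, as in
#'   [top_k_similar()].
#' @param score_threshold Low-score filter applied before normalization
#'   (default 50, the same cutoff as the whole-genome workflow).
#' @param label Free-text label for the query (used in output tables).
#' @return An `npp_hits` data frame (see [top_k_similar()]), with the query
#'   Z-profile in attribute `query_profile`.
#' @export
query_by_sequence <- function(raw_scores, stats, zmatrix, k = 50,
                              n_shuffles = 1000, seed = NULL,
                              score_threshold = 50, label = "query") {
  raw_scores[!is.na(raw_scores) & raw_scores < score_threshold] <- NA_real_
  if (all(is.na(raw_scores)))
    npp_stop("no homologs above threshold %.1f", score_threshold)
  norm <- normalize_by_max(raw_scores)
  norm <- norm[colnames(zmatrix)]
  if (anyNA(names(norm)))
    npp_stop("raw_scores do not cover the matrix genomes")
  names(norm) <- colnames(zmatrix)
  z <- zscore_with_stats(norm, stats)
  hits <- rank_profiles(z, label, zmatrix, k, n_shuffles = n_shuffles,
                        seed = seed)
  attr(hits, "query_profile") <- z
  attr(hits, "query_normalized") <- norm
  hits
}

#' Read the query label from a FASTA file
#'
#' Sequence-mode input arrives as a FASTA file; only the header label is
#' needed here (the sequence itself is consumed by the external BLASTP run
#' that produces the tabular hit files).
#' @param path FASTA file path.
#' @return First word of the first header line.
#' @export
fasta_label <- function(path) {
  if (!file.exists(path)) npp_stop("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, ">")]
  if (length(hdr) == 0) npp_stop("%s: no FASTA header line", path)
  sub("^>\\s*(\\S+).*$", "\\1", hdr[1])
}

#' Collect per-genome top scores for a single query from BLAST files
#'
#' Reads one 12-column BLAST tabular file per genome (the single submitted
#' sequence searched against each genome), selects the top hit per genome,
#' and returns the per-genome score vector for [query_by_sequence()].
#'
#' @param paths Named character vector: genome id -> BLAST tabular file.
#' @param manifest A [genome_manifest()]; genomes without a file or without
#'   hits get `NA`.
#' @return Named numeric vector over the manifest genomes.
#' @export
single_query_scores <- function(paths, manifest) {
  gids <- genome_ids(manifest)
  unknown <- setdiff(names(paths), gids)
  if (length(unknown) > 0)
    npp_stop("genome(s) not in manifest: %s", paste(unknown, collapse = ", "))
  scores <- stats::setNames(rep(NA_real_, length(gids)), gids)
  for (g in names(paths)) {
    hits <- read_blast_tab(paths[[g]], g)
    top <- select_top_hits(hits)
    if (nrow(top) > 1)
      npp_stop("%s: hit file contains more than one query id", paths[[g]])
    if (nrow(top) == 1) scores[g] <- top$bit_score
  }
  scores
}
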