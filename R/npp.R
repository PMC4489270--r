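# The npp object: a fitted normalized-phylogenetic-profile database.
#
# npp() runs the whole-genome workflow once over a raw top-hit score matrix
# and stores every derived product: the filtered raw matrix, the
# self-score-normalized matrix, the per-genome statistics and the Z-score
# matrix. Queries (by protein name or by a submitted sequence's per-genome
# scores) are then served by predict().

#' Fit normalized phylogenetic profiles
#'
#' Runs the four-step whole-genome workflow on a raw score matrix:
#' (i) the matrix already holds the top BLAST hit per (protein, genome);
#' (ii) scores below `score_threshold` are removed and proteins with
#' homologs in fewer than `min_fraction` of the genomes are dropped;
#' (iii) scores are normalized by each protein's self-score;
#' (iv) every genome column is Z-scored against the population of
#' normalized scores in that genome.
#'
#' The query-genome column normalizes to exactly 1 for every protein, so it
#' has no variance; its statistics are stored with `sd = NA` and its
#' Z-scores are 0 by convention (see [zscore_matrix()]). It still occupies
#' its position in every profile so that profile comparisons span the full
#' genome panel.
#'
#' @param scores Raw score matrix (proteins x genomes, `NA` = no hit), as
#'   from [build_raw_matrix()] or [generate_module_matrix()].
#' @param manifest A [genome_manifest()]; its column order must match.
#' @param score_threshold Low-score filter cutoff (default 50).
#' @param min_fraction Sparse-query filter: minimum fraction of genomes
#'   with a surviving hit (default 0.25).
#' @return An object of class `npp` with components `raw` (filtered raw
#'   scores), `normalized`, `stats`, `z`, `manifest`, `removed` (ids of
#'   dropped proteins), `score_threshold`, `min_fraction`, `call`.
#' @examples
#' spec <- fixture_spec(n_proteins = 30, n_genomes = 20, seed = 7)
#' raw <- generate_module_matrix(spec)
#' fit <- npp(raw, attr(raw, "manifest"))
#' fit
#' head(predict(fit, "p0001", k = 3, seed = 1))
#' @export
npp <- function(scores, manifest, score_threshold = 50, min_fraction = 0.25) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  if (!identical(colnames(scores), genome_ids(manifest)))
    npp_stop("matrix columns do not match the manifest genome order")
  filtered <- filter_low_scores(scores, score_threshold)
  filtered <- filter_sparse_queries(filtered, min_fraction)
  removed <- attr(filtered, "removed")
  attr(filtered, "removed") <- NULL
  normalized <- normalize_by_self(filtered, manifest)
  qg <- query_genome(manifest)
  other <- setdiff(colnames(normalized), qg)
  stats <- compute_genome_stats(normalized[, other, drop = FALSE])
  stats <- rbind(stats,
                 data.frame(genome_id = qg, mean = 1, sd = NA_real_,
                            n = nrow(normalized)))
  stats <- stats[match(colnames(normalized), stats$genome_id), ]
  rownames(stats) <- NULL
  class(stats) <- c("genome_stats", "data.frame")
  z <- zscore_matrix(normalized, stats)
  structure(list(raw = filtered, normalized = normalized, stats = stats,
                 z = z, manifest = manifest, removed = removed,
                 score_threshold = score_threshold,
                 min_fraction = min_fraction, call = match.call()),
            class = "npp")
}

#' @export
print.npp <- function(x, ...) {
  cat("Normalized phylogenetic profiles\n")
  cat(sprintf("  proteins: %d retained (%d removed by sparse-query filter)\n",
              nrow(x$z), length(x$removed)))
  cat(sprintf("  genomes:  %d (query genome: %s)\n",
              ncol(x$z), query_genome(x$manifest)))
  cat(sprintf("  filters:  bit score >= %.1f, homologs in >= %.0f%% of genomes\n",
              x$score_threshold, 100 * x$min_fraction))
  invisible(x)
}

#' @export
summary.npp <- function(object, ...) {
  tx <- table(object$manifest$taxon)
  structure(list(n_proteins = nrow(object$z), n_removed = length(object$removed),
                 n_genomes = ncol(object$z), taxa = tx,
                 query_genome = query_genome(object$manifest),
                 stats = object$stats,
                 mean_presence = mean(!is.na(object$raw))),
            class = "summary.npp")
}

#' @export
print.summary.npp <- function(x, ...) {
  cat("Normalized phylogenetic profiles\n")
  cat(sprintf("  %d proteins x %d genomes (query genome %s); %d proteins removed\n",
              x$n_proteins, x$n_genomes, x$query_genome, x$n_removed))
  cat(sprintf("  mean homolog presence: %.1f%%\n", 100 * x$mean_presence))
  cat("  genomes per taxon:\n")
  for (t in names(x$taxa)) cat(sprintf("    %-10s %d\n", t, x$taxa[[t]]))
  cat("  per-genome normalized-score statistics:\n")
  s <- x$stats[!is.na(x$stats$sd), ]
  cat(sprintf("    mean in [%.3f, %.3f], sd in [%.3f, %.3f]\n",
              min(s$mean), max(s$mean), min(s$sd), max(s$sd)))
  invisible(x)
}

#' Query a fitted profile database
#'
#' Ranks profiles against either a protein of the query genome (`query`, by
#' identifier) or a submitted sequence's per-genome top bit scores
#' (`newdata`, a named numeric vector; sequence mode). Returns the top `k`
#' most similar profiles with Pearson `r` and permutation Z-score.
#'
#' @param object An [npp()] fit.
#' @param query Protein identifier present in the fit (whole-genome mode).
#' @param newdata Named per-genome raw score vector (sequence mode);
#'   exactly one of `query` and `newdata` must be given.
#' @param k Number of hits (default 50; server presets 50/100/150/200).
#' @param n_shuffles Permutation-null shuffles per pair (default 1000).
#' @param seed Master seed for the permutation null.
#' @param label Query label for sequence mode output.
#' @param ... Unused.
#' @return An `npp_hits` data frame (`rank`, `protein_id`, `r`, `z`,
#'   `n_shuffles`) carrying the query profile, the hit profiles, and the
#'   manifest as attributes, ready for [write_results_table()] and
#'   [plot.npp_hits()].
#' @export
predict.npp <- function(object, query = NULL, newdata = NULL, k = 50,
                        n_shuffles = 1000, seed = NULL, label = NULL, ...) {
  if (is.null(query) == is.null(newdata))
    npp_stop("supply exactly one of 'query' (protein id) or 'newdata' (scores)")
  if (!is.null(query)) {
    if (!query %in% rownames(object$z)) {
      near <- utils::head(agrep(query, rownames(object$z), value = TRUE,
                                max.distance = 0.3), 5)
      npp_stop("protein '%s' not found%s", query,
               if (length(near) > 0)
                 paste0("; nearest matches: ", paste(near, collapse = ", "))
               else "")
    }
    hits <- top_k_similar(query, object$z, k = k, n_shuffles = n_shuffles,
                          seed = seed)
    attr(hits, "query_normalized") <- object$normalized[query, ]
    attr(hits, "query_profile") <- object$z[query, ]
  } else {
    hits <- query_by_sequence(newdata, object$stats, object$z, k = k,
                              n_shuffles = n_shuffles, seed = seed,
                              score_threshold = object$score_threshold,
                              label = if (is.null(label)) "query" else label)
  }
  attr(hits, "manifest") <- object$manifest
  attr(hits, "normalized_hits") <-
    object$normalized[hits$protein_id, , drop = FALSE]
  hits
}

#' @export
print.npp_hits <- function(x, ...) {
  cat(sprintf("Top %d profiles most similar to '%s' (%d shuffles)\n",
              nrow(x), attr(x, "query"), x$n_shuffles[1]))
  print.data.frame(cbind(x[, c("rank", "protein_id")],
                         r = round(x$r, 4), z = round(x$z, 2)),
                   row.names = FALSE)
  invisible(x)
}

#' Conservation line plot of selected profiles
#'
#' Plots normalized conservation (0 to 1) across the genome panel for the
#' chosen proteins, species along the x-axis in manifest order with taxon
#' boundaries marked — the line-plot rendering of profiles.
#'
#' @param x An [npp()] fit.
#' @param proteins Character vector of protein ids to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.npp <- function(x, proteins = rownames(x$normalized)[1], ...) {
  bad <- setdiff(proteins, rownames(x$normalized))
  if (length(bad) > 0)
    npp_stop("unknown protein(s): %s", paste(bad, collapse = ", "))
  m <- t(x$normalized[proteins, , drop = FALSE])
  op <- graphics::par(mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(m, type = "l", lty = 1, lwd = 2, ylim = c(0, 1),
                    xaxt = "n", xlab = "", ylab = "relative conservation",
                    ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = x$manifest$species,
                 las = 2, cex.axis = 0.5)
  graphics::abline(v = taxon_boundaries(x$manifest) + 0.5, col = "grey60",
                   lty = 2)
  graphics::legend("topright", legend = proteins, lty = 1, lwd = 2,
                   col = seq_along(proteins), cex = 0.7, bty = "n")
  invisible(x)
}
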