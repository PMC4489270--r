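# BLAST tabular input, top-hit selection and raw score matrix assembly.
#
# The pipeline consumes standard 12-column tabular BLASTP output (one file
# per subject genome, all proteins of the query genome searched against it).
# Field 11 is the e-value, field 12 the bit score; the bit score is the
# similarity measure used throughout, the e-value is carried for provenance
# only.

#' Read a 12-column BLAST tabular hit file
#'
#' Parses outfmt-6-style tab-separated BLAST output. Lines starting with `#`
#' are skipped. Each data line must have at least 12 tab-separated fields;
#' the e-value is taken from field 11 and the bit score from field 12.
#'
#' @param path Path to the tabular file.
#' @param genome_id Identifier of the subject genome the file was searched
#'   against (BLAST output does not carry it; it comes from the manifest).
#' @return `data.frame` with one row per hit, in file order: `query_id`,
#'   `subject_id`, `evalue`, `bit_score`, `genome_id`. An empty file (or a
#'   file of comments only) yields a zero-row frame.
#' @examples
#' f <- tempfile()
#' writeLines("q1\ts9\t88.0\t100\t1\t0\t1\t100\t1\t100\t1e-50\t197.0", f)
#' read_blast_tab(f, "g1")
#' @export
read_blast_tab <- function(path, genome_id) {
  if (!file.exists(path)) npp_stop("BLAST file not found: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bit_score = numeric(),
                      genome_id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- line_no[which(nf < 12)[1]]
    npp_stop("%s: line %d has %d fields, expected >= 12",
             path, bad, nf[which(nf < 12)[1]])
  }
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 11L)))
  bit_score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 12L)))
  for (col in list(c(11L, "e-value"), c(12L, "bit score"))) {
    vals <- if (col[1] == "11") evalue else bit_score
    if (anyNA(vals)) {
      bad <- line_no[which(is.na(vals))[1]]
      npp_stop("%s: line %d: field %s does not parse as a number (%s)",
               path, bad, col[1], col[2])
    }
  }
  if (any(bit_score < 0) || any(evalue < 0))
    npp_stop("%s: negative e-value or bit score", path)
  hits <- data.frame(query_id = vapply(fields, `[`, "", 1L),
                     subject_id = vapply(fields, `[`, "", 2L),
                     evalue = evalue, bit_score = bit_score,
                     genome_id = genome_id, stringsAsFactors = FALSE)
  if (any(!nzchar(hits$query_id)) || any(!nzchar(hits$subject_id)))
    npp_stop("%s: empty query or subject identifier", path)
  hits
}

#' Select the top hit per (query protein, genome)
#'
#' For every (query, genome) pair, keeps the hit with the maximum bit score.
#' Ties are broken by input order: the first line with the maximal score
#' wins, so results are deterministic for identical input files. The subject
#' identifier of the winning hit is retained for provenance.
#'
#' @param hits Hit `data.frame` as returned by [read_blast_tab()] (rows from
#'   several files may be concatenated).
#' @return `data.frame` with columns `query_id`, `genome_id`, `subject_id`,
#'   `bit_score`, one row per observed (query, genome) pair.
#' @export
select_top_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(query_id = character(), genome_id = character(),
                      subject_id = character(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(hits$query_id, hits$genome_id, sep = "\x1f")
  # order by key, then descending score, then original position: the first
  # row per key is the top hit with first-occurrence tie-breaking
  ord <- order(key, -hits$bit_score, seq_len(nrow(hits)))
  first <- !duplicated(key[ord])
  sel <- hits[ord[first], c("query_id", "genome_id", "subject_id", "bit_score")]
  rownames(sel) <- NULL
  sel
}

#' Assemble the raw score matrix
#'
#' Builds the proteins x genomes grid of top-hit bit scores. Rows follow
#' `protein_ids`, columns follow the manifest order. Pairs absent from
#' `top_hits` are `NA` (missing): at this stage a missing cell means "no
#' hit", which is kept distinct from a true score until normalization.
#'
#' @param top_hits Output of [select_top_hits()].
#' @param protein_ids Ordered character vector of query-proteome ids
#'   (defines row order; proteins without any hit get an all-`NA` row).
#' @param manifest A [genome_manifest()].
#' @return Numeric matrix with `rownames` = proteins, `colnames` = genomes,
#'   `NA` for missing cells.
#' @export
build_raw_matrix <- function(top_hits, protein_ids, manifest) {
  if (length(protein_ids) == 0) npp_stop("protein_ids is empty")
  if (anyDuplicated(protein_ids))
    npp_stop("duplicate protein ids: %s",
             paste(unique(protein_ids[duplicated(protein_ids)]),
                   collapse = ", "))
  gids <- genome_ids(manifest)
  unknown <- setdiff(unique(top_hits$genome_id), gids)
  if (length(unknown) > 0)
    npp_stop("genome(s) not in manifest: %s", paste(unknown, collapse = ", "))
  unknown_p <- setdiff(unique(top_hits$query_id), protein_ids)
  if (length(unknown_p) > 0)
    npp_stop("hit query protein(s) not in protein_ids: %s",
             paste(utils::head(unknown_p, 5), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(protein_ids), ncol = length(gids),
              dimnames = list(protein_ids, gids))
  if (nrow(top_hits) > 0)
    m[cbind(top_hits$query_id, top_hits$genome_id)] <- top_hits$bit_score
  m
}

#' Remove low-similarity scores
#'
#' Cells with bit score strictly below `threshold` become missing (`NA`);
#' scores equal to the threshold survive. No rows or columns are dropped.
#'
#' @param matrix Raw score matrix ([build_raw_matrix()]).
#' @param threshold Non-negative bit-score cutoff; the default of 50 is the
#'   standard low-score filter of the workflow.
#' @return Matrix of the same shape with sub-threshold cells set to `NA`.
#' @export
filter_low_scores <- function(matrix, threshold = 50) {
  if (threshold < 0) npp_stop("threshold must be >= 0")
  matrix[!is.na(matrix) & matrix < threshold] <- NA_real_
  matrix
}

#' Drop query proteins without homologs across enough genomes
#'
#' Removes rows whose fraction of non-missing cells falls below
#' `min_fraction`. This implements the sparse-query filter: proteins that
#' lack homologs across a portion of the genome panel carry too little
#' signal for profile comparison.
#'
#' @param matrix Raw score matrix (typically after [filter_low_scores()]).
#' @param min_fraction Minimum fraction of genomes with a surviving hit,
#'   in `[0, 1]`. Default 0.25.
#' @return The filtered matrix, with attribute `removed` holding the ids of
#'   dropped proteins.
#' @export
filter_sparse_queries <- function(matrix, min_fraction = 0.25) {
  if (min_fraction < 0 || min_fraction > 1)
    npp_stop("min_fraction must be in [0, 1]")
  frac <- rowMeans(!is.na(matrix))
  drop <- frac < min_fraction
  if (all(drop))
    npp_stop(paste("all %d proteins have homologs in fewer than %.0f%% of",
                   "genomes; lower min_fraction"),
             nrow(matrix), 100 * min_fraction)
  out <- matrix[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(matrix)[drop]
  out
}

#' Read / write a score matrix as TSV
#'
#' Proteins x genomes table: first column `protein_id`, one column per
#' genome (header = genome ids), missing cells written as `NA`. Used for
#' raw, normalized and Z-score matrices alike.
#'
#' @param matrix Numeric matrix with protein rownames and genome colnames.
#' @param path File path.
#' @return `read_score_matrix()` returns the matrix; `write_score_matrix()`
#'   returns `path` invisibly.
#' @export
write_score_matrix <- function(matrix, path) {
  df <- data.frame(protein_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) npp_stop("matrix file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a 3-column protein annotation table
#'
#' Optional gene name / description annotations used in results tables:
#' tab-separated columns `protein_id`, `gene_name`, `description` with a
#' header line.
#' @param path File path.
#' @return `data.frame` with those three character columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) npp_stop("annotation file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("protein_id", "gene_name", "description")
  if (!all(need %in% names(df)))
    npp_stop("annotation file must have columns: %s",
             paste(need, collapse = ", "))
  df[, need]
}
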