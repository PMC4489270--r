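# Genome manifest: the ordered genome panel with taxon grouping.

#' Construct a genome manifest
#'
#' The manifest fixes the genome panel used throughout an analysis: its order
#' defines the column order of every score matrix, and the taxon/subtaxon
#' grouping drives the heatmap layout (genomes are grouped into major taxa
#' such as Animals, Fungi, Plants and Protists, and subtaxa within them).
#'
#' @param entries `data.frame` with columns `genome_id`, `species`, `taxon`,
#'   `subtaxon` (character). Row order is significant and preserved.
#' @param query_genome_id Identifier of the query genome (the genome whose
#'   full protein set is profiled); must be present in `entries$genome_id`.
#' @return An object of class `genome_manifest`: the entries `data.frame`
#'   with a `query_genome_id` attribute.
#' @examples
#' m <- genome_manifest(
#'   data.frame(genome_id = c("g1", "g2"), species = c("Homo", "Mus"),
#'              taxon = "Animals", subtaxon = "Mammals"),
#'   query_genome_id = "g1")
#' query_genome(m)
#' @export
genome_manifest <- function(entries, query_genome_id) {
  required <- c("genome_id", "species", "taxon", "subtaxon")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0)
    npp_stop("manifest is missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries[, required], stringsAsFactors = FALSE)
  for (cl in required) entries[[cl]] <- as.character(entries[[cl]])
  if (anyDuplicated(entries$genome_id))
    npp_stop("duplicate genome_id in manifest: %s",
             paste(unique(entries$genome_id[duplicated(entries$genome_id)]),
                   collapse = ", "))
  if (!query_genome_id %in% entries$genome_id)
    npp_stop("query genome '%s' is not in the manifest", query_genome_id)
  rownames(entries) <- NULL
  structure(entries, query_genome_id = query_genome_id,
            class = c("genome_manifest", "data.frame"))
}

#' Query genome of a manifest
#' @param manifest A [genome_manifest()].
#' @return The query genome identifier (length-1 character).
#' @export
query_genome <- function(manifest) attr(manifest, "query_genome_id")

#' Genome identifiers of a manifest, in panel order
#' @inheritParams query_genome
#' @return Character vector of genome ids.
#' @export
genome_ids <- function(manifest) manifest$genome_id

#' Read / write a genome manifest as TSV
#'
#' The file format is a 4-column tab-separated table with a header line:
#' `genome_id`, `species`, `taxon`, `subtaxon`.
#'
#' @param path File path.
#' @param query_genome_id Query genome identifier (not stored in the TSV).
#' @return `read_genome_manifest()` returns a [genome_manifest()];
#'   `write_genome_manifest()` returns `path` invisibly.
#' @export
read_genome_manifest <- function(path, query_genome_id) {
  if (!file.exists(path)) npp_stop("manifest file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  genome_manifest(df, query_genome_id)
}

#' @rdname read_genome_manifest
#' @param manifest A [genome_manifest()].
#' @export
write_genome_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Indices of taxon group boundaries
#'
#' Returns the column positions after which a vertical separator should be
#' drawn on the heatmap, i.e. where `taxon` changes between adjacent genomes.
#' @inheritParams query_genome
#' @return Integer vector (possibly empty) of boundary positions.
#' @export
taxon_boundaries <- function(manifest) {
  tx <- manifest$taxon
  which(tx[-length(tx)] != tx[-1])
}
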