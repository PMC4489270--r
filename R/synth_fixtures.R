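# Synthetic fixtures with the statistical structure the NPP workflow
# assumes: genome panels with taxon grouping, raw score matrices with
# planted co-evolving modules, correlated profile pairs, and toy BLAST
# tabular files that exercise the production parsers end to end.
#
# The generative model mimics the biology the method targets: proteins that
# work together are lost or diverge together. Each planted module shares a
# latent per-genome conservation pattern and clade-level loss events
# (entire subtaxa dropped at once); background proteins evolve
# independently. Per-genome baseline conservation falls with taxonomic
# distance from the query genome, giving every genome column its own score
# distribution — the situation per-genome Z-scoring is designed to correct.

#' Specification for a synthetic score-matrix fixture
#'
#' @param n_proteins Number of query proteins (default 100).
#' @param n_genomes Size of the genome panel (default 86).
#' @param module_sizes Integer vector: sizes of planted co-evolving modules
#'   (default one module of 5); their sum must not exceed `n_proteins`.
#' @param within_module_r Target pairwise correlation of the latent
#'   conservation signal within a module, in (0, 1); default 0.9.
#' @param presence_prob Probability that a (protein, subtaxon) clade retains
#'   the ortholog; shared loss events hit whole subtaxa (default 0.85).
#' @param score_range Bit-score range `(min, max)`; self-scores are drawn
#'   near the top, and scores that fall below the workflow's low-score
#'   cutoff end up filtered, as in real data (default `c(50, 1000)`).
#' @param seed Integer master seed; every random draw flows from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 100, n_genomes = 86, module_sizes = 5,
                         within_module_r = 0.9, presence_prob = 0.85,
                         score_range = c(50, 1000), seed = 1) {
  stopifnot(n_proteins >= 2, n_genomes >= 3,
            sum(module_sizes) <= n_proteins,
            within_module_r > 0, within_module_r < 1,
            presence_prob >= 0, presence_prob <= 1,
            length(score_range) == 2, score_range[1] >= 0,
            score_range[2] > score_range[1])
  structure(list(n_proteins = n_proteins, n_genomes = n_genomes,
                 module_sizes = as.integer(module_sizes),
                 within_module_r = within_module_r,
                 presence_prob = presence_prob,
                 score_range = score_range, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Synthetic genome panel with taxon grouping
#'
#' Builds a manifest of `n_genomes` synthetic genomes split across the four
#' major eukaryotic taxa used for display grouping (Animals, Fungi, Plants,
#' Protists), each with subtaxa. The first genome is the query genome.
#'
#' @param n_genomes Panel size (default 86).
#' @return A [genome_manifest()].
#' @export
synthetic_manifest <- function(n_genomes = 86) {
  stopifnot(n_genomes >= 4)
  taxa <- c(Animals = 0.40, Fungi = 0.25, Plants = 0.15, Protists = 0.20)
  counts <- pmax(floor(taxa * n_genomes), 1L)
  while (sum(counts) < n_genomes) counts[1] <- counts[1] + 1L
  while (sum(counts) > n_genomes) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  subtaxa <- list(Animals = c("Vertebrates", "Insects", "Nematodes"),
                  Fungi = c("Ascomycetes", "Basidiomycetes"),
                  Plants = c("LandPlants", "GreenAlgae"),
                  Protists = c("Alveolates", "Excavates"))
  rows <- do.call(rbind, lapply(names(counts), function(tx) {
    k <- counts[[tx]]
    st <- rep(subtaxa[[tx]], length.out = k)
    data.frame(taxon = tx, subtaxon = sort(st), stringsAsFactors = FALSE)
  }))
  rows$genome_id <- sprintf("g%03d", seq_len(nrow(rows)))
  rows$species <- sprintf("%s_species_%03d", tolower(rows$taxon),
                          seq_len(nrow(rows)))
  genome_manifest(rows[, c("genome_id", "species", "taxon", "subtaxon")],
                  query_genome_id = rows$genome_id[1])
}

#' Generate a profile pair with a target correlation
#'
#' Draws two length-`n` vectors from a standard bivariate normal with
#' correlation `target_r` (`b = r a + sqrt(1 - r^2) e`). The sample
#' correlation fluctuates around `target_r` with the usual
#' `(1 - r^2)/sqrt(n)` spread.
#'
#' @param n Profile length (>= 3).
#' @param target_r True correlation, `|target_r| < 1`.
#' @param seed Optional seed; the same seed reproduces the same pair.
#' @return List with numeric vectors `a` and `b`.
#' @export
generate_correlated_pair <- function(n, target_r, seed = NULL) {
  stopifnot(n >= 3, abs(target_r) < 1)
  with_seed(seed, {
    a <- stats::rnorm(n)
    b <- target_r * a + sqrt(1 - target_r^2) * stats::rnorm(n)
    list(a = a, b = b)
  })
}

#' Generate a raw score matrix with planted co-evolving modules
#'
#' Simulates the top-hit bit-score table of a query proteome against a
#' genome panel. Module members share a latent per-genome conservation
#' signal (pairwise latent correlation `within_module_r`) and clade-level
#' loss events; background proteins are independent. Conservation is pushed
#' through a logistic link around each genome's baseline (which decreases
#' with taxonomic distance from the query genome) and scaled by a
#' per-protein self-score. The query-genome column always holds the
#' self-score.
#'
#' @param spec A [fixture_spec()].
#' @param manifest Optional [genome_manifest()]; defaults to
#'   [synthetic_manifest()] of the requested size.
#' @return Raw score matrix (`NA` = ortholog lost) with attributes
#'   `module` (integer vector: module index per protein, 0 = background)
#'   and `manifest`.
#' @export
generate_module_matrix <- function(spec, manifest = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(manifest)) manifest <- synthetic_manifest(spec$n_genomes)
  gids <- genome_ids(manifest)
  qg <- query_genome(manifest)
  np <- spec$n_proteins
  ng <- length(gids)
  pid <- sprintf("p%04d", seq_len(np))
  module <- integer(np)
  j <- 1L
  for (m in seq_along(spec$module_sizes)) {
    module[j:(j + spec$module_sizes[m] - 1L)] <- m
    j <- j + spec$module_sizes[m]
  }
  w <- spec$within_module_r
  with_seed(spec$seed, {
    # genome baseline conservation, falling with distance from the query
    base_by_taxon <- c(Animals = 0.65, Fungi = 0.5, Plants = 0.4,
                       Protists = 0.3)
    b <- base_by_taxon[manifest$taxon] + stats::runif(ng, -0.08, 0.08)
    b[is.na(b)] <- 0.5  # unknown taxon label: neutral baseline
    alpha <- stats::qlogis(pmin(pmax(b, 0.05), 0.95))
    # latent conservation signal
    latent <- matrix(stats::rnorm(length(spec$module_sizes) * ng),
                     nrow = length(spec$module_sizes))
    x <- matrix(stats::rnorm(np * ng), np, ng)
    in_mod <- module > 0
    if (any(in_mod))
      x[in_mod, ] <- sqrt(w) * latent[module[in_mod], , drop = FALSE] +
        sqrt(1 - w) * x[in_mod, , drop = FALSE]
    u <- stats::plogis(matrix(alpha, np, ng, byrow = TRUE) + 1.5 * x)
    # clade-level shared loss: whole subtaxa drop the ortholog together
    lost <- matrix(FALSE, np, ng)
    clades <- split(seq_len(ng), manifest$subtaxon)
    for (cl in clades) {
      ev <- stats::runif(length(spec$module_sizes)) > spec$presence_prob
      drop_bg <- stats::runif(np) > spec$presence_prob
      drop <- ifelse(in_mod, ev[pmax(module, 1L)], drop_bg)
      lost[drop, cl] <- TRUE
    }
    self <- stats::runif(np, 0.6 * spec$score_range[2], spec$score_range[2])
    raw <- round(self * u, 1)
    raw[lost] <- NA_real_
    dimnames(raw) <- list(pid, gids)
    raw[, qg] <- round(self, 1)  # self-score column is never lost
    structure(raw, module = module, manifest = manifest)
  })
}

#' Write a score matrix as toy per-genome BLAST tabular files
#'
#' Emits one 12-column tabular file per genome such that parsing them with
#' [read_blast_tab()], selecting top hits and rebuilding the matrix
#' reproduces the input exactly. Sub-optimal decoy hit lines (at 60% of the
#' top score) are interleaved to exercise top-hit selection; bit scores are
#' printed with 17 significant digits so doubles round-trip bit-for-bit.
#'
#' @param matrix Raw score matrix.
#' @param out_dir Output directory (created if needed).
#' @param manifest A [genome_manifest()] covering the matrix columns; taken
#'   from the matrix attribute when omitted.
#' @param decoys Add sub-optimal second hit lines (default `TRUE`).
#' @return Named character vector: genome id -> file path, invisibly.
#' @export
write_toy_blast_files <- function(matrix, out_dir, manifest = NULL,
                                  decoys = TRUE) {
  if (is.null(manifest)) manifest <- attr(matrix, "manifest")
  if (is.null(manifest)) npp_stop("a genome manifest is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in colnames(matrix)) {
    lines <- c(sprintf("# synthetic BLASTP tabular output, genome %s", g))
    for (p in rownames(matrix)) {
      s <- matrix[p, g]
      if (is.na(s)) next
      mk <- function(subj, score) {
        sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.17g",
                p, subj, 35 + 60 * min(1, score / max(matrix, na.rm = TRUE)),
                120L, 40L, 3L, 1L, 120L, 1L, 120L,
                10^(-pmin(180, score / 2)), score)
      }
      lines <- c(lines, mk(sprintf("%s|best|%s", g, p), s))
      if (decoys && s > 0)
        lines <- c(lines, mk(sprintf("%s|decoy|%s", g, p), 0.6 * s))
    }
    path <- file.path(out_dir, paste0(g, ".tsv"))
    writeLines(lines, path)
    paths[g] <- path
  }
  invisible(paths)
}

#' Rebuild a raw score matrix from per-genome BLAST files
#'
#' Convenience inverse of [write_toy_blast_files()] (and entry point for
#' real BLAST output): parses every file, selects top hits and assembles
#' the matrix over the manifest panel.
#'
#' @param paths Named character vector: genome id -> BLAST tabular file.
#' @param protein_ids Ordered protein ids (matrix rows).
#' @param manifest A [genome_manifest()].
#' @return Raw score matrix.
#' @export
read_blast_dir <- function(paths, protein_ids, manifest) {
  hits <- do.call(rbind, lapply(names(paths), function(g)
    read_blast_tab(paths[[g]], g)))
  if (is.null(hits))
    hits <- data.frame(query_id = character(), subject_id = character(),
                       evalue = numeric(), bit_score = numeric(),
                       genome_id = character())
  build_raw_matrix(select_top_hits(hits), protein_ids, manifest)
}
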