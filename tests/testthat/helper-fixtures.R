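# Shared fixtures built in code. The packaged toy BLAST set lives under
# inst/extdata and exercises the production parsers.

extdata <- function(...) {
  system.file("extdata", ..., package = "npprofile", mustWork = TRUE)
}

toy_manifest <- function() {
  read_genome_manifest(extdata("manifest.tsv"), query_genome_id = "g1")
}

toy_blast_paths <- function() {
  files <- list.files(extdata("blast"), pattern = "\\.tsv$",
                      full.names = TRUE)
  stats::setNames(files, sub("\\.tsv$", "", basename(files)))
}

# raw matrix of the packaged toy set (pA, pB, pC x g1..g4), unfiltered
toy_raw_matrix <- function() {
  read_blast_dir(toy_blast_paths(), c("pA", "pB", "pC"), toy_manifest())
}

# a small in-code manifest for matrix-level tests
mini_manifest <- function(n = 3) {
  genome_manifest(
    data.frame(genome_id = paste0("g", seq_len(n)),
               species = paste0("sp", seq_len(n)),
               taxon = rep(c("Animals", "Fungi"), length.out = n),
               subtaxon = rep(c("Vertebrates", "Ascomycetes"),
                              length.out = n)),
    query_genome_id = "g1")
}

# random raw matrix with a guaranteed self-score column
random_raw_matrix <- function(np, ng, seed) {
  set.seed(seed)
  m <- matrix(round(stats::runif(np * ng, 20, 500), 1), np, ng,
              dimnames = list(sprintf("p%02d", seq_len(np)),
                              paste0("g", seq_len(ng))))
  m[, 1] <- pmax(m[, 1], apply(m, 1, max))  # self-score is the row maximum
  m[sample(length(m), size = floor(0.1 * length(m)))] <- NA
  m[, 1][is.na(m[, 1])] <- 300
  m
}

# Monte-Carlo standard error of a sampled permutation Z, from the exact
# null moments (delta method on z = (r_obs - mean)/sd)
perm_z_se <- function(a, b, n_shuffles) {
  null <- exhaustive_null(a, b)
  mu <- mean(null)
  s <- sqrt(mean((null - mu)^2))
  m3 <- mean((null - mu)^3)
  m4 <- mean((null - mu)^4)
  z <- (pearson_r(a, b) - mu) / s
  sqrt((1 + z^2 * (m4 / s^4 - 1) / 4 + z * m3 / s^3) / n_shuffles)
}
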