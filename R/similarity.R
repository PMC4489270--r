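# Profile similarity: Pearson correlation between Z-score profiles and a
# species-shuffling permutation null for significance.
#
# Significance of an observed correlation r is estimated under a naive null
# of randomly shuffled species: the entries of one profile are permuted
# N times (default 1000), a null distribution of correlation coefficients
# is collected, and the observed r is reported as a Z-score against the
# empirical mean and spread of that distribution. The null mean is about
# -1/(n-1), not exactly 0, which is why r is standardized against the
# empirical moments rather than an assumed zero mean.

#' Pearson correlation between two profiles
#'
#' Standard product-moment coefficient with explicit contract checks:
#' vectors must have equal length >= 3 and nonzero variance.
#'
#' @param a,b Numeric profile vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))  # 9 / sqrt(84)
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) npp_stop("profiles have different lengths")
  if (length(a) < 3) npp_stop("profiles must have length >= 3")
  if (anyNA(a) || anyNA(b)) npp_stop("profiles must not contain NA")
  if (pop_sd(a) == 0 || pop_sd(b) == 0)
    npp_stop("undefined correlation: zero-variance profile")
  stats::cor(a, b)
}

#' Permutation-test Z-score for a profile correlation
#'
#' Shuffles the entries of `b` uniformly at random `n_shuffles` times
#' (sampling among all permutations with replacement; the identity is not
#' excluded), computes the Pearson coefficient of `a` against each shuffle,
#' and returns the observed coefficient standardized against the empirical
#' mean and population standard deviation of those null coefficients:
#' `z = (r_obs - mean(r_null)) / sd(r_null)`.
#'
#' @param a,b Numeric profile vectors (see [pearson_r()] for the contract).
#' @param n_shuffles Number of random shuffles (>= 2); default 1000.
#' @param seed Optional integer seed; when given, the result is
#'   deterministic and the caller's RNG state is left untouched.
#' @return Permutation Z-score (length-1 numeric).
#' @seealso [exhaustive_permutation_z()] for the exact small-n reference.
#' @export
permutation_z <- function(a, b, n_shuffles = 1000, seed = NULL) {
  r_obs <- pearson_r(a, b)
  if (n_shuffles < 2) npp_stop("n_shuffles must be >= 2")
  n <- length(a)
  az <- a - mean(a); az <- az / sqrt(sum(az^2))
  bz <- b - mean(b); bz <- bz / sqrt(sum(bz^2))
  r_null <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) sum(az * bz[sample.int(n)]), numeric(1))
  })
  s <- pop_sd(r_null)
  if (s == 0) npp_stop("degenerate permutation null: sd(r_null) = 0")
  (r_obs - mean(r_null)) / s
}

#' Exact permutation null distribution of the correlation
#'
#' Enumerates all `n!` permutations of `b` (limited to `n <= 7`) and
#' returns the full vector of null Pearson coefficients. This is the exact
#' reference the sampled null of [permutation_z()] converges to.
#'
#' @inheritParams pearson_r
#' @return Numeric vector of length `n!`.
#' @export
exhaustive_null <- function(a, b) {
  if (length(a) != length(b)) npp_stop("profiles have different lengths")
  n <- length(a)
  if (n > 7) npp_stop("exhaustive null is limited to length <= 7")
  if (pop_sd(a) == 0 || pop_sd(b) == 0)
    npp_stop("undefined correlation: zero-variance profile")
  az <- a - mean(a); az <- az / sqrt(sum(az^2))
  bz <- b - mean(b); bz <- bz / sqrt(sum(bz^2))
  perms <- all_perms(n)
  as.vector(matrix(bz[perms], nrow(perms), n) %*% az)
}

#' Exact permutation Z-score (small-n oracle)
#'
#' Computes the permutation Z-score over the complete set of `n!`
#' permutations instead of a random sample; used as the convergence
#' reference for [permutation_z()].
#'
#' @inheritParams pearson_r
#' @return Exact permutation Z-score.
#' @examples
#' exhaustive_permutation_z(c(1, 2, 3), c(1, 2, 3))  # sqrt(2)
#' @export
exhaustive_permutation_z <- function(a, b) {
  r_obs <- pearson_r(a, b)
  r_null <- exhaustive_null(a, b)
  s <- pop_sd(r_null)
  if (s == 0) npp_stop("degenerate permutation null: sd(r_null) = 0")
  (r_obs - mean(r_null)) / s
}

# Shared ranking engine: correlate one Z-profile against every row of a
# Z-matrix, rank by r (descending, ties by protein id), attach permutation
# Z-scores for the top k. `exclude` drops the query's own row in
# whole-genome mode.
rank_profiles <- function(query_profile, query_label, zmatrix, k,
                          n_shuffles = 1000, seed = NULL,
                          exclude = character()) {
  ids <- setdiff(rownames(zmatrix), exclude)
  if (length(ids) == 0) npp_stop("no candidate profiles to rank")
  if (k < 1 || k > length(ids))
    npp_stop("k must be between 1 and %d", length(ids))
  cand <- zmatrix[ids, , drop = FALSE]
  # row-wise Pearson r against the query profile, vectorized
  qc <- query_profile - mean(query_profile)
  qn <- sqrt(sum(qc^2))
  if (qn == 0) npp_stop("query profile has zero variance")
  cc <- cand - rowMeans(cand)
  cn <- sqrt(rowSums(cc^2))
  r <- as.vector(cc %*% qc) / (cn * qn)
  undef <- cn == 0
  if (any(undef)) {
    warning(sprintf("skipping %d zero-variance profile(s): %s",
                    sum(undef),
                    paste(utils::head(ids[undef], 5), collapse = ", ")),
            call. = FALSE)
    ids <- ids[!undef]
    r <- r[!undef]
    cand <- cand[!undef, , drop = FALSE]
    if (k > length(ids)) npp_stop("fewer than k defined correlations")
  }
  ord <- order(-r, ids)
  top <- ord[seq_len(k)]
  z <- vapply(top, function(i) {
    permutation_z(query_profile, cand[i, ], n_shuffles = n_shuffles,
                  seed = if (is.null(seed)) NULL
                         else pair_seed(seed, query_label, ids[i]))
  }, numeric(1))
  res <- data.frame(rank = seq_len(k), protein_id = ids[top], r = r[top],
                    z = z, n_shuffles = n_shuffles,
                    stringsAsFactors = FALSE)
  structure(res, query = query_label, class = c("npp_hits", "data.frame"))
}

#' Top-k most similar phylogenetic profiles
#'
#' Ranks every other protein in the Z-matrix by Pearson correlation with the
#' query's Z-profile, returns the `k` best (r descending, ties broken by
#' protein id ascending), each with its species-shuffling permutation
#' Z-score. The query's own profile is excluded from the ranking; display
#' code puts it back as the top row.
#'
#' @param query_id Protein identifier present in `zmatrix`.
#' @param zmatrix Z-score matrix (proteins x genomes).
#' @param k Number of hits to return, `1 <= k < nrow(zmatrix)`. The server
#'   presets are 50, 100, 150 and 200, but any positive integer works.
#' @param n_shuffles Shuffles per pair for the permutation null.
#' @param seed Master seed; each (query, subject) pair derives its own
#'   reproducible stream from it, so results do not depend on evaluation
#'   order.
#' @return An `npp_hits` data frame: `rank`, `protein_id`, `r`, `z`,
#'   `n_shuffles`, with the query id stored in attribute `query`.
#' @export
top_k_similar <- function(query_id, zmatrix, k = 50, n_shuffles = 1000,
                          seed = NULL) {
  if (!query_id %in% rownames(zmatrix))
    npp_stop("query protein '%s' is not in the matrix", query_id)
  rank_profiles(zmatrix[query_id, ], query_id, zmatrix, k,
                n_shuffles = n_shuffles, seed = seed, exclude = query_id)
}

#' Calibrate the correlation-to-Z rule of thumb
#'
#' Simulates profile pairs of length `n_species` from a bivariate normal
#' with each requested true correlation, runs the permutation test on every
#' pair, and reports the mean and spread of the resulting Z-scores. This
#' reproduces the working calibration of the method: a marginal correlation
#' of about 0.5 maps to Z near 5, and a very strong correlation of about
#' 0.95 maps to Z near 8, usable as rough significance cutoffs.
#'
#' @param r Numeric vector of true correlations in `(-1, 1)`.
#' @param n_species Profile length (number of genomes); default 86.
#' @param n_pairs Replicate pairs per correlation; default 200.
#' @param n_shuffles Shuffles per pair; default 1000.
#' @param seed Master seed for reproducibility.
#' @return `data.frame` with columns `r`, `mean_z`, `sd_z`, `n_pairs`,
#'   `n_species`, `n_shuffles`.
#' @export
calibrate_z <- function(r, n_species = 86, n_pairs = 200, n_shuffles = 1000,
                        seed = 1) {
  stopifnot(all(abs(r) < 1), n_pairs >= 1)
  rows <- lapply(seq_along(r), function(j) {
    zs <- vapply(seq_len(n_pairs), function(i) {
      sub <- pair_seed(seed, sprintf("calibrate_r%.6f", r[j]), i)
      pr <- generate_correlated_pair(n_species, r[j], seed = sub)
      permutation_z(pr$a, pr$b, n_shuffles = n_shuffles,
                    seed = pair_seed(sub, "null", i))
    }, numeric(1))
    data.frame(r = r[j], mean_z = mean(zs), sd_z = stats::sd(zs),
               n_pairs = n_pairs, n_species = n_species,
               n_shuffles = n_shuffles)
  })
  do.call(rbind, rows)
}
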