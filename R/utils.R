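# Internal helpers: seeded RNG scoping, deterministic pair seeds, permutations.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded operations do not perturb the global random stream. With
#' `seed = NULL` the expression runs against the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Deterministic per-pair seed derived from a master seed
#'
#' Hashes the (query, subject) identifier pair into 0..(2^31 - 2) so that
#' each pair gets its own reproducible permutation stream, independent of
#' the order in which pairs are evaluated.
#' @noRd
pair_seed <- function(master_seed, query_id, subject_id) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(paste(query_id, subject_id, sep = "\x1f"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

#' All permutations of 1..n as an n! x n matrix
#'
#' Recursive enumeration, guarded to n <= 7 (5040 rows); only used by the
#' exact permutation-null oracle.
#' @noRd
all_perms <- function(n) {
  stopifnot(n >= 1)
  if (n > 7) stop("exhaustive enumeration is limited to n <= 7", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row:(row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Stop with a message assembled sprintf-style
#' @noRd
npp_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Population standard deviation (divide by n)
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
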