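# BLAST tabular parsing, top-hit selection and raw-matrix assembly.

test_that("read_blast_tab maps fields, skips comments and preserves order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# BLASTP 2.x",
               "q1\ts9\t88.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\t197.0",
               "q1\ts2\t70.0\t90\t20\t2\t1\t90\t1\t90\t1e-20\t88.5",
               "q2\ts3\t60.0\t80\t30\t3\t1\t80\t1\t80\t1e-10\t55.0"), f)
  hits <- read_blast_tab(f, "g1")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_id, c("q1", "q1", "q2"))
  expect_equal(hits$bit_score, c(197.0, 88.5, 55.0))
  expect_equal(hits$evalue, c(1e-50, 1e-20, 1e-10))
  expect_equal(hits$subject_id[1], "s9")
  expect_true(all(hits$genome_id == "g1"))
})

test_that("comment-only and empty files parse to zero hits", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# BLASTP 2.x", "# Query: q1"), f)
  expect_equal(nrow(read_blast_tab(f, "g1")), 0)
  writeLines(character(0), f)
  expect_equal(nrow(read_blast_tab(f, "g1")), 0)
})

test_that("malformed lines are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts9\t88.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\t197.0",
               "q1\ts2\tonly\tthree"), f)
  expect_error(read_blast_tab(f, "g1"), "line 2")
  writeLines("q1\ts9\t88.0\t100\t5\t1\t1\t100\t1\t100\t1e-50\tnot_a_number",
             f)
  expect_error(read_blast_tab(f, "g1"), "line 1")
})

test_that("select_top_hits keeps the per-pair maximum, oracle-checked", {
  set.seed(11)
  hits <- data.frame(
    query_id = sample(paste0("q", 1:2), 60, replace = TRUE),
    subject_id = paste0("s", 1:60),
    evalue = stats::runif(60), bit_score = round(stats::runif(60, 10, 300), 1),
    genome_id = sample(paste0("g", 1:3), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  top <- select_top_hits(hits)
  expect_equal(nrow(top), nrow(unique(hits[, c("query_id", "genome_id")])))
  # naive grouping oracle
  for (i in seq_len(nrow(top))) {
    grp <- hits[hits$query_id == top$query_id[i] &
                  hits$genome_id == top$genome_id[i], ]
    expect_equal(top$bit_score[i], max(grp$bit_score))
  }
})

test_that("top-hit ties go to the first line in input order", {
  hits <- data.frame(query_id = "q1", subject_id = c("sFirst", "sSecond"),
                     evalue = c(1e-9, 1e-9), bit_score = c(50, 50),
                     genome_id = "g1", stringsAsFactors = FALSE)
  top <- select_top_hits(hits)
  expect_equal(top$bit_score, 50)
  expect_equal(top$subject_id, "sFirst")
})

test_that("build_raw_matrix lays out rows/columns and marks missing cells", {
  man <- mini_manifest(3)
  top <- data.frame(query_id = c("p1", "p1", "p2", "p2"),
                    genome_id = c("g1", "g2", "g1", "g3"),
                    subject_id = "s", bit_score = c(100, 60, 200, 70),
                    stringsAsFactors = FALSE)
  m <- build_raw_matrix(top, c("p1", "p2"), man)
  expect_equal(dim(m), c(2, 3))
  expect_equal(sum(is.na(m)), 2)
  expect_equal(m["p1", "g2"], 60)
  expect_true(is.na(m["p1", "g3"]))
  # degenerate: no hits at all
  empty <- build_raw_matrix(top[0, ], c("p1", "p2"), man)
  expect_true(all(is.na(empty)))
  # contract errors
  expect_error(build_raw_matrix(top, c("p1", "p1"), man), "duplicate")
  top$genome_id[1] <- "gX"
  expect_error(build_raw_matrix(top, c("p1", "p2"), man), "gX")
})

test_that("filter_low_scores removes strictly-below cells only", {
  m <- matrix(c(20, 49, 50, 197), 2, 2,
              dimnames = list(c("p1", "p2"), c("g1", "g2")))
  f <- filter_low_scores(m, 50)
  expect_true(is.na(f["p1", "g1"]) && is.na(f["p2", "g1"]))
  expect_equal(f["p1", "g2"], 50)
  expect_equal(f["p2", "g2"], 197)
  # boundary: 49.9 goes, 50.0 stays
  m2 <- matrix(c(49.9, 50.0), 1, 2,
               dimnames = list("p", c("g1", "g2")))
  f2 <- filter_low_scores(m2)
  expect_true(is.na(f2[1, 1]))
  expect_equal(f2[1, 2], 50)
  # threshold 0 is the identity
  expect_equal(filter_low_scores(m, 0), m)
})

test_that("filter_low_scores is idempotent and monotone in the threshold", {
  for (seed in 1:5) {
    m <- random_raw_matrix(8, 6, seed)
    f50 <- filter_low_scores(m, 50)
    expect_equal(filter_low_scores(f50, 50), f50)
    f80 <- filter_low_scores(m, 80)
    # raising the threshold never adds a present cell
    expect_true(all(is.na(f80[is.na(f50)])))
  }
})

test_that("filter_sparse_queries drops rows below the presence fraction", {
  m <- matrix(NA_real_, 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("g", 1:4)))
  m[1, 1] <- 100                 # presence 0.25
  m[2, 1:2] <- 100               # presence 0.5
  m[3, ] <- 100                  # presence 1
  f <- filter_sparse_queries(m, 0.5)
  expect_equal(rownames(f), c("p2", "p3"))
  expect_equal(attr(f, "removed"), "p1")
  expect_equal(nrow(filter_sparse_queries(m, 0)), 3)
  expect_error(filter_sparse_queries(m[1:2, , drop = FALSE], 1),
               "min_fraction")
  # single-genome presence below cutoff
  expect_false("p1" %in% rownames(filter_sparse_queries(m, 0.3)))
})

test_that("score matrices round-trip through TSV, missing cells included", {
  for (seed in c(3, 7)) {
    m <- random_raw_matrix(6, 5, seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_score_matrix(m, f)
    expect_equal(read_score_matrix(f), m)
  }
})

test_that("the packaged toy BLAST set parses into the expected matrix", {
  m <- toy_raw_matrix()
  expect_equal(dim(m), c(3, 4))
  expect_equal(m["pA", ], c(g1 = 200, g2 = 100, g3 = 50, g4 = 49.9))
  expect_equal(m["pB", "g2"], 150)   # decoy line at 90 must not win
  expect_true(is.na(m["pC", "g2"]))
})
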