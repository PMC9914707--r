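make_hit_row <- function(qid, sid, pid, len) {
  paste(qid, sid, pid, len, 2, 0, 1, len, 1, len, 1e-50, 500, sep = "\t")
}

test_that("read_hits parses the 12-column tabular dialect and derives MAG ids", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("repseq4", "bin.33_00012", 99.342, 304),
               make_hit_row("repseq5", "bin.53_00007", 100, 66)), path)
  hits <- read_hits(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$percent_identity, c(99.342, 100))
  expect_equal(hits$alignment_length, c(304L, 66L))
  expect_equal(hits$mag_id, c("bin.33", "bin.53"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(h0 <- read_hits(empty), "empty")
  expect_equal(nrow(h0), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("q", "s_1", 99, 100),
               "only\tfour\tfields\there"), bad)
  expect_error(read_hits(bad), "line 2")
})

test_that("hit files round-trip through write_hits and read_hits", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("q1", "binA_1", 98.5, 410),
               make_hit_row("q2", "binB_2", 100, 250)), path)
  hits <- read_hits(path)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path2)
  expect_equal(read_hits(path2), hits)
})

test_that("align_local matches a quadratic affine-gap DP oracle on short pairs", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_dna_str(sample(20:50, 1))
    b <- random_dna_str(sample(20:50, 1))
    hit <- align_local(a, b, both_strands = FALSE)
    expect_equal(hit$bit_score, sw_score_oracle(a, b),
                 info = paste("pair", i))
  }
  # planted segment: score, identity and length forced by construction
  seg <- random_dna_str(60)
  subj <- paste0(random_dna_str(40), seg, random_dna_str(40))
  hit <- align_local(seg, subj)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$alignment_length, 60L)
  expect_equal(hit$bit_score, 120)
})

test_that("align_local finds reverse-complement hits when strand search is on", {
  seg <- random_dna_str(100)
  subj <- paste0(random_dna_str(30), seg, random_dna_str(30))
  fwd <- align_local(seg, subj)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  both <- align_local(rc, subj, both_strands = TRUE)
  expect_equal(both$percent_identity, fwd$percent_identity)
  expect_equal(both$alignment_length, fwd$alignment_length)
  off <- align_local(rc, subj, both_strands = FALSE)
  expect_lt(off$alignment_length, 100L)
  expect_error(align_local("", "ACGT"), "empty")
})

test_that("link_hits applies the strict length/identity filter", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("q1", "binA_1", 100, 430),
               make_hit_row("q2", "binB_1", 100, 66),     # length fail
               make_hit_row("q3", "binC_1", 99.0, 500),   # boundary: strict
               make_hit_row("q4", "binD_1", 98.0, 400),   # identity fail
               make_hit_row("q5", "binE_1", 99.5, 300)),  # boundary: strict
             path)
  links <- link_hits(read_hits(path))
  expect_equal(links$accepted,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("link_hits keeps the best hit per pair and flags many-to-many links", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(make_hit_row("q1", "binA_1", 99.2, 400),
               make_hit_row("q1", "binA_2", 99.8, 350),  # better identity
               make_hit_row("q1", "binB_1", 99.5, 420),
               make_hit_row("q2", "binB_2", 99.6, 410)), path)
  links <- link_hits(read_hits(path), taxonomy_map = data.frame(
    repseq_id = c("q1", "q2"), taxonomy = c("g_X", "g_Y")))
  expect_equal(nrow(links), 3)  # one row per (mag, query) pair
  a <- links[links$mag_id == "binA" & links$repseq_id == "q1", ]
  expect_equal(a$percent_identity, 99.8)
  # binB is linked by two queries, q1 by two MAGs: all flagged
  expect_true(all(links$multi_link[links$accepted]))
  expect_equal(links$taxonomy[links$repseq_id == "q2"], "g_Y")
})

test_that("filter monotonicity: raising either cutoff never gains links", {
  set.seed(21)
  hits <- data.frame(
    query_id = paste0("q", 1:40), subject_id = paste0("bin", 1:40, "_1"),
    mag_id = paste0("bin", 1:40),
    percent_identity = runif(40, 90, 100),
    alignment_length = sample(50:500, 40),
    mismatches = 0, gap_opens = 0, q_start = 1, q_end = 1,
    s_start = 1, s_end = 1, evalue = NA_real_, bit_score = 0,
    stringsAsFactors = FALSE)
  n_acc <- function(len, pid)
    sum(link_hits(hits, min_length = len, min_identity = pid)$accepted)
  for (len in c(100, 300, 400))
    expect_gte(n_acc(len, 95), n_acc(len, 99))
  for (pid in c(95, 99))
    expect_gte(n_acc(100, pid), n_acc(300, pid))
})
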