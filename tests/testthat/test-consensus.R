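test_that("identical members reproduce their sequence with no corrections", {
  set.seed(21)
  s1 <- rand_dna(20); s2 <- rand_dna(20)
  fam <- make_family(5, m1_seq = s1, m2_seq = s2)
  cons <- build_consensus(fam)
  expect_equal(cons$mate1$seq, s1)
  expect_equal(cons$mate2$seq, s2)
  expect_equal(nrow(cons$corrected), 0L)
  expect_equal(cons$depth, 5L)
  expect_equal(phred_to_int_t(cons$mate1$qual), rep(37L, 20))
})

test_that("a high-quality minority mismatch is out-voted and recorded", {
  set.seed(22)
  s1 <- rand_dna(20)
  substr(s1, 10, 10) <- "A"
  fam <- make_family(5, m1_seq = s1,
                     edits = list(list(member = 2, mate = 1, pos = 10,
                                       base = "G", qual = 30)))
  cons <- build_consensus(fam)
  expect_equal(substr(cons$mate1$seq, 10, 10), "A")
  expect_equal(nrow(cons$corrected), 1L)
  expect_equal(cons$corrected$column, 10L)
  expect_equal(cons$corrected$from, "A")
  expect_equal(cons$corrected$to, "G")
  expect_equal(cons$corrected$pair_name, "p02")
  # brute-force column count: 4 x A(37) vs 1 x G(30)
  expect_equal(cons$mate1$column_counts[1, 10], 4)  # A row
  expect_equal(cons$mate1$column_counts[3, 10], 1)  # G row
})

test_that("low-quality mismatches neither vote nor count as PCR errors", {
  s1 <- paste(rep("A", 20), collapse = "")
  fam <- make_family(5, m1_seq = s1,
                     edits = list(list(member = 2, mate = 1, pos = 10,
                                       base = "G", qual = 10)))
  cons <- build_consensus(fam)
  expect_equal(substr(cons$mate1$seq, 10, 10), "A")
  expect_equal(nrow(cons$corrected), 0L)   # exempt, not a PCR error
  expect_equal(cons$mate1$column_counts[3, 10], 0)

  # a column where EVERY base is low-quality falls back to plain majority
  fam2 <- make_family(5, m1_seq = s1,
                      edits = lapply(1:5, function(m)
                        list(member = m, mate = 1, pos = 4,
                             base = if (m <= 3) "T" else "C", qual = 8 + m)))
  cons2 <- build_consensus(fam2)
  expect_equal(substr(cons2$mate1$seq, 4, 4), "T")  # 3 T vs 2 C
  q <- phred_to_int_t(cons2$mate1$qual)
  expect_equal(q[4], 11L)  # best T base: members 1..3 have qual 9,10,11
})

test_that("column ties break by summed quality, then lexicographically", {
  s1 <- paste(rep("A", 20), collapse = "")
  # depth 6: 3 x C(qual 30) vs 3 x T(qual 35) at column 7 -> T wins on quality
  fam <- make_family(6, m1_seq = s1,
                     edits = lapply(1:6, function(m)
                       list(member = m, mate = 1, pos = 7,
                            base = if (m <= 3) "C" else "T",
                            qual = if (m <= 3) 30 else 35)))
  cons <- build_consensus(fam)
  expect_equal(substr(cons$mate1$seq, 7, 7), "T")
  # equal counts and equal summed quality -> lexicographically smallest
  fam2 <- make_family(6, m1_seq = s1,
                      edits = lapply(1:6, function(m)
                        list(member = m, mate = 1, pos = 7,
                             base = if (m <= 3) "T" else "C", qual = 30)))
  cons2 <- build_consensus(fam2)
  expect_equal(substr(cons2$mate1$seq, 7, 7), "C")
})

test_that("consensus qualities take the best agreeing eligible voter", {
  s1 <- paste(rep("A", 20), collapse = "")
  fam <- make_family(5, m1_seq = s1,
                     edits = list(list(member = 1, mate = 1, pos = 3,
                                       base = "A", qual = 20),
                                  list(member = 2, mate = 1, pos = 3,
                                       base = "A", qual = 35),
                                  list(member = 3, mate = 1, pos = 3,
                                       base = "A", qual = 22),
                                  list(member = 4, mate = 1, pos = 3,
                                       base = "A", qual = 21),
                                  list(member = 5, mate = 1, pos = 3,
                                       base = "A", qual = 23)))
  cons <- build_consensus(fam)
  expect_equal(phred_to_int_t(cons$mate1$qual)[3], 35L)
  q <- assign_consensus_quals(s1, fam$m1_seq, fam$m1_qual)
  expect_equal(q[3], 35L)
  expect_equal(q[5], 37L)
})

test_that("member order never changes the consensus", {
  set.seed(23)
  s1 <- rand_dna(30); s2 <- rand_dna(30)
  fam <- make_family(7, m1_seq = s1, m2_seq = s2,
                     edits = list(list(member = 3, mate = 1, pos = 5,
                                       base = "T", qual = 33),
                                  list(member = 6, mate = 2, pos = 12,
                                       base = "A", qual = 31)))
  cons <- build_consensus(fam)
  for (rep in 1:3) {
    perm <- fam[sample.int(nrow(fam)), ]
    cons2 <- build_consensus(perm)
    expect_identical(cons2$mate1$seq, cons$mate1$seq)
    expect_identical(cons2$mate2$seq, cons$mate2$seq)
    expect_identical(cons2$mate1$qual, cons$mate1$qual)
    reord <- function(d) {
      d <- d[order(d$pair_name, d$mate, d$column), ]
      rownames(d) <- NULL
      d
    }
    expect_identical(reord(cons2$corrected), reord(cons$corrected))
  }
})

test_that("shallow families are rejected and odd lengths are routed or excluded", {
  fam <- make_family(4)
  expect_error(build_consensus(fam), "below threshold")

  # one member of deviant length does not vote, but the family still builds
  set.seed(24)
  s1 <- rand_dna(20)
  fam2 <- make_family(6, m1_seq = s1)
  fam2$m1_seq[2] <- substr(s1, 1, 15)
  fam2$m1_qual[2] <- strrep("F", 15)
  fam2$m1_cigar[2] <- "15M"
  cons <- build_consensus(fam2)
  expect_equal(cons$mate1$seq, s1)
  expect_equal(cons$n_nonvoting, 1L)

  # no strict plurality length: the family is routed to the low-depth path
  fam3 <- make_family(6, m1_seq = s1)
  for (i in 1:3) {
    fam3$m1_seq[i] <- substr(s1, 1, 15)
    fam3$m1_qual[i] <- strrep("F", 15)
    fam3$m1_cigar[i] <- "15M"
  }
  expect_null(build_consensus(fam3))
})

test_that("indel-bearing members are excluded from positional voting", {
  set.seed(25)
  s1 <- rand_dna(20)
  fam <- make_family(6, m1_seq = s1)
  fam$m1_cigar[4] <- "10M1I9M"  # same length, shifted columns
  cons <- build_consensus(fam)
  expect_equal(cons$mate1$seq, s1)
  expect_equal(cons$n_nonvoting, 1L)
})

test_that("consensus recovers truth more often than best-read selection", {
  set.seed(2600)
  n_fam <- 1000L; depth <- 5L; len <- 30L; err <- 0.01
  cons_hit <- 0L; best_hit <- 0L
  for (i in seq_len(n_fam)) {
    truth <- rand_dna(len)
    fam <- make_family(depth, m1_seq = truth, m2_seq = truth)
    for (m in seq_len(depth)) {
      nerr <- rbinom(1, len, err)
      if (nerr > 0) {
        at <- sample.int(len, nerr)
        s <- strsplit(fam$m1_seq[m], "")[[1]]
        s[at] <- vapply(s[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        fam$m1_seq[m] <- paste(s, collapse = "")
      }
    }
    cons <- build_consensus(fam)
    if (identical(cons$mate1$seq, truth)) cons_hit <- cons_hit + 1L
    best <- select_representative(fam)
    if (identical(best$m1_seq, truth)) best_hit <- best_hit + 1L
  }
  expect_gt(cons_hit, best_hit)
  expect_gt(cons_hit / n_fam, 0.99)
})
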