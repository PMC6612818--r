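test_that("an exact substring aligns full-length with an all-match CIGAR", {
  set.seed(11)
  q <- rand_dna(30)
  t <- paste0(rand_dna(7), q, rand_dna(5))
  res <- sw_align(q, t)
  expect_equal(res$score, 2 * 30)
  expect_equal(res$cigar, "30M")
  expect_equal(res$target_start, 8)
  expect_equal(res$query_start, 1)
  expect_error(sw_align("", "ACGT"), "empty")
  expect_error(sw_align("ACGT", ""), "empty")
})

test_that("single-mismatch and single-deletion alignments score as expected", {
  set.seed(12)
  q <- rand_dna(30)
  tchars <- strsplit(q, "")[[1]]
  tchars[15] <- setdiff(c("A", "C", "G", "T"), tchars[15])[1]
  t <- paste(tchars, collapse = "")
  res <- sw_align(q, t)
  expect_equal(res$score, 56)  # 29 matches * 2 - 2, mismatch kept inside
  orc <- sw_oracle(q, t)
  expect_equal(res$score, orc$score)
  expect_equal(res$cigar, orc$cigar)

  # query missing one interior base relative to the target
  t2 <- paste0(substr(q, 1, 14), "A", substr(q, 15, 30))
  res2 <- sw_align(q, t2)
  orc2 <- sw_oracle(q, t2)
  expect_equal(res2$score, orc2$score)
  expect_equal(res2$cigar, orc2$cigar)
})

test_that("scores and CIGARs match the independent DP oracle on random instances", {
  set.seed(4242)
  for (i in 1:150) {
    nq <- sample(5:80, 1); nt <- sample(5:80, 1)
    q <- rand_dna(nq)
    # half the time, derive the target from the query with edits so that
    # alignments are non-trivial
    t <- if (i %% 2 == 0) rand_dna(nt) else {
      x <- strsplit(q, "")[[1]]
      nmut <- sample(0:4, 1)
      if (nmut > 0) {
        at <- sample(seq_along(x), nmut)
        x[at] <- sample(c("A", "C", "G", "T"), nmut, TRUE)
      }
      if (runif(1) < 0.5 && length(x) > 6) x <- x[-sample(seq_along(x), 1)]
      paste(c(sample(c("A","C","G","T"), 3, TRUE), x,
              sample(c("A","C","G","T"), 3, TRUE)), collapse = "")
    }
    res <- sw_align(q, t)
    orc <- sw_oracle(q, t)
    expect_equal(res$score, orc$score, info = sprintf("i=%d score", i))
    expect_equal(res$cigar, orc$cigar, info = sprintf("i=%d cigar", i))
    if (res$score > 0) {
      expect_equal(res$target_start, orc$target_start,
                   info = sprintf("i=%d tstart", i))
    }
  }
})

test_that("appending matching flanks never decreases the optimal score", {
  set.seed(77)
  for (i in 1:40) {
    q <- rand_dna(sample(10:40, 1))
    t <- rand_dna(sample(10:40, 1))
    base <- sw_align(q, t)$score
    flank <- rand_dna(sample(1:10, 1))
    ext <- sw_align(paste0(flank, q), paste0(flank, t))$score
    expect_gte(ext, base)
  }
})

test_that("realign_pair regenerates positions and CIGARs against the window", {
  set.seed(13)
  ref <- c(sim1 = rand_dna(500))
  frag <- substr(ref[["sim1"]], 201, 260)
  pair <- make_pair(m1_pos = 200L, m2_pos = 240L,
                    m1_seq = substr(frag, 1, 20),
                    m2_seq = substr(frag, 41, 60),
                    m1_qual = strrep("F", 20), m2_qual = strrep("F", 20))
  out <- realign_pair(pair, ref, min_score = 10L)
  expect_equal(out$m1_pos, 200L)
  expect_equal(out$m1_cigar, "20M")
  expect_equal(out$m2_pos, 240L)
  expect_equal(attr(out, "realign_kept"), 0L)

  # a 1 bp deletion relative to the reference gives exactly one 1D
  del <- paste0(substr(frag, 1, 9), substr(frag, 11, 20))
  pair2 <- make_pair(m1_pos = 200L, m2_pos = 240L, m1_seq = del,
                     m2_seq = substr(frag, 41, 60),
                     m1_qual = strrep("F", 19), m2_qual = strrep("F", 20))
  out2 <- realign_pair(pair2, ref, min_score = 10L)
  orc <- sw_oracle(del, substr(ref[["sim1"]], 151, 269))  # same window
  expect_equal(out2$m1_cigar, orc$cigar)
  expect_equal(lengths(regmatches(out2$m1_cigar,
                                  gregexpr("1D", out2$m1_cigar))), 1L)

  # window clipped at the contig start: no negative coordinates
  pair3 <- make_pair(m1_pos = 2L, m2_pos = 30L,
                     m1_seq = substr(ref[["sim1"]], 3, 22),
                     m2_seq = substr(ref[["sim1"]], 31, 50),
                     m1_qual = strrep("F", 20), m2_qual = strrep("F", 20))
  out3 <- realign_pair(pair3, ref, min_score = 10L)
  expect_gte(out3$m1_pos, 0L)
  expect_equal(out3$m1_pos, 2L)

  expect_error(realign_pair(make_pair(chrom = "nope"), ref), "contig")

  # an unattainable score floor keeps the original alignment
  out4 <- realign_pair(pair, ref, min_score = 10000L)
  expect_equal(attr(out4, "realign_kept"), 2L)
  expect_equal(out4$m1_cigar, pair$m1_cigar)
})
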