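# Fixture builders. Simulated datasets are cached per session so several
# test files can share one build.

.fixture_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, config) {
  if (is.null(.fixture_cache[[name]])) {
    dir <- file.path(tempdir(), paste0("pecr_fix_", name))
    unlink(dir, recursive = TRUE)
    .fixture_cache[[name]] <- simulate_reads(config, dir)
  }
  .fixture_cache[[name]]
}

# ~400 fragments on 2.5 kb: quick I/O, grouping and scoring checks.
fix_small <- function() {
  cached_sim("small", sim_config(ref_length = 2500L, n_fragments = 400L,
                                 n_orphans = 3L, seed = 301L))
}

# ~1500 fragments on 3 kb: end-to-end pipeline and determinism checks.
fix_mid <- function() {
  cached_sim("mid", sim_config(ref_length = 3000L, n_fragments = 1500L,
                               seed = 302L))
}

# One cached full pipeline run on the mid fixture.
mid_run <- function() {
  if (is.null(.fixture_cache$mid_run)) {
    sim <- fix_mid()
    .fixture_cache$mid_run <- run_pec(sim$bam, sim$ref_fasta)
  }
  .fixture_cache$mid_run
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# One read pair row in the pec_pairs layout.
make_pair <- function(pair_name = "p1", chrom = "sim1", m1_pos = 100L,
                      m2_pos = 180L, m1_seq = strrep("A", 20),
                      m2_seq = strrep("C", 20),
                      m1_qual = strrep("F", nchar(m1_seq)),   # Phred 37
                      m2_qual = strrep("F", nchar(m2_seq)),
                      m1_cigar = sprintf("%dM", nchar(m1_seq)),
                      m2_cigar = sprintf("%dM", nchar(m2_seq)),
                      m1_reverse = FALSE, m2_reverse = TRUE,
                      m1_mapq = 60L, m2_mapq = 60L) {
  data.frame(pair_name = pair_name, chrom = chrom, m1_pos = m1_pos,
             m2_pos = m2_pos, m1_reverse = m1_reverse,
             m2_reverse = m2_reverse, m1_cigar = m1_cigar,
             m2_cigar = m2_cigar, m1_seq = m1_seq, m2_seq = m2_seq,
             m1_qual = m1_qual, m2_qual = m2_qual, m1_mapq = m1_mapq,
             m2_mapq = m2_mapq)
}

# A family of n copies of the same pair, optionally with per-member edits.
# edits: list of lists(member, mate, pos, base, qual).
make_family <- function(n, m1_seq = strrep("A", 20), m2_seq = strrep("C", 20),
                        edits = list(), base_qual = 37L, prefix = "p") {
  rows <- lapply(seq_len(n), function(i) {
    make_pair(pair_name = sprintf("%s%02d", prefix, i), m1_seq = m1_seq,
              m2_seq = m2_seq,
              m1_qual = int_to_phred_t(rep(base_qual, nchar(m1_seq))),
              m2_qual = int_to_phred_t(rep(base_qual, nchar(m2_seq))))
  })
  fam <- do.call(rbind, rows)
  for (e in edits) {
    scol <- sprintf("m%d_seq", e$mate); qcol <- sprintf("m%d_qual", e$mate)
    s <- fam[[scol]][e$member]
    substr(s, e$pos, e$pos) <- e$base
    fam[[scol]][e$member] <- s
    if (!is.null(e$qual)) {
      q <- utf8ToInt(fam[[qcol]][e$member]) - 33L
      q[e$pos] <- e$qual
      fam[[qcol]][e$member] <- intToUtf8(q + 33L)
    }
  }
  attr(fam, "depth") <- n
  fam
}

# test-side Phred helpers (independent of package internals)
int_to_phred_t <- function(v) intToUtf8(v + 33L)
phred_to_int_t <- function(s) utf8ToInt(s) - 33L

# Compare the recovered family partition with the truth partition: both are
# reduced to sorted member-name signatures.
partition_signature <- function(members_list) {
  unname(sort(vapply(members_list, function(x) paste(sort(x), collapse = ","),
                     character(1))))
}
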