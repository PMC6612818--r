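test_that("zero-noise simulation reproduces fragments exactly", {
  cfg <- sim_config(ref_length = 1500L, n_fragments = 60L,
                    pcr_error_rate = 0, seq_error_rate = 0, hotspot_n = 0L,
                    seed = 51L)
  sim <- simulate_reads(cfg, file.path(tempdir(), "sim_zero"))
  expect_equal(nrow(sim$truth$errors), 0L)
  p <- read_pairs(sim$bam)
  fr <- sim$truth$fragments[match(
    sim$truth$pairs$fragment_id[match(p$pair_name, sim$truth$pairs$pair_name)],
    sim$truth$fragments$fragment_id), ]
  for (i in seq_len(nrow(p))) {
    expect_identical(p$m1_seq[i],
                     substr(sim$truth$reference, fr$start[i], fr$start[i] + 99L))
    expect_identical(p$m2_seq[i],
                     substr(sim$truth$reference, fr$end[i] - 99L, fr$end[i]))
  }
})

test_that("a fixed seed reproduces the dataset exactly", {
  cfg <- sim_config(ref_length = 1500L, n_fragments = 80L, seed = 52L)
  s1 <- simulate_reads(cfg, file.path(tempdir(), "sim_det1"))
  s2 <- simulate_reads(cfg, file.path(tempdir(), "sim_det2"))
  expect_identical(readLines(s1$ref_fasta), readLines(s2$ref_fasta))
  for (tab in c("fragments", "pairs", "errors", "hotspots")) {
    expect_identical(
      readLines(file.path(s1$truth_dir, sprintf("truth_%s.tsv", tab))),
      readLines(file.path(s2$truth_dir, sprintf("truth_%s.tsv", tab))))
  }
  p1 <- read_pairs(s1$bam); p2 <- read_pairs(s2$bam)
  attributes(p1) <- attributes(p1)["names"]
  attributes(p2) <- attributes(p2)["names"]
  expect_identical(p1, p2)
})

test_that("fragment and depth statistics match the configured model", {
  cfg <- sim_config(ref_length = 6000L, n_fragments = 4000L, seed = 53L)
  sim <- cached_sim("stats", cfg)
  fr <- sim$truth$fragments
  se_len <- 20 / sqrt(nrow(fr))
  expect_lt(abs(mean(fr$len) - 177), 3 * se_len + 0.5)  # +0.5 for truncation
  expect_lt(abs(sd(fr$len) - 20), 2)
  # duplicate depth: mean 6, strongly overdispersed
  se_d <- sd(fr$depth) / sqrt(nrow(fr))
  expect_lt(abs(mean(fr$depth) - 6), 3 * se_d)
  expect_gt(var(fr$depth), 2 * mean(fr$depth))
  expect_equal(sum(fr$depth), nrow(sim$truth$pairs))
  # coordinate-collided fragments share a family id
  key <- paste(fr$start, fr$end)
  expect_equal(length(unique(fr$family_id)), length(unique(key)))
})

test_that("truth tables fully reconstruct every emitted read", {
  sim <- fix_small()
  p <- read_pairs(sim$bam)
  tr <- sim$truth
  set.seed(54)
  for (i in sample.int(nrow(p), 50)) {
    fid <- tr$pairs$fragment_id[match(p$pair_name[i], tr$pairs$pair_name)]
    f <- tr$fragments[tr$fragments$fragment_id == fid, ]
    errs <- tr$errors[tr$errors$pair_name == p$pair_name[i], , drop = FALSE]
    for (mate in 1:2) {
      base <- if (mate == 1) substr(tr$reference, f$start, f$start + 99L) else
        substr(tr$reference, f$end - 99L, f$end)
      chars <- strsplit(base, "")[[1]]
      fa <- tr$frag_alleles[[match(fid, tr$fragments$fragment_id)]]
      if (!is.null(fa)) {
        off <- fa$pos - f$start + 1L
        ro <- if (mate == 1) off else off - (f$len - 100L)
        keep <- ro >= 1 & ro <= 100
        chars[ro[keep]] <- fa$alt[keep]
      }
      me <- errs[errs$mate == mate, , drop = FALSE]
      if (nrow(me)) for (j in seq_len(nrow(me))) chars[me$read_pos[j]] <- me$to[j]
      got <- p[[sprintf("m%d_seq", mate)]][i]
      expect_identical(got, paste(chars, collapse = ""))
    }
  }
})

test_that("uncorrected reads show the configured high-quality error rate", {
  cfg <- sim_config(ref_length = 4000L, n_fragments = 1200L,
                    pcr_error_rate = 5e-3, seq_error_rate = 0, hotspot_n = 0L,
                    seed = 55L)
  sim <- simulate_reads(cfg, file.path(tempdir(), "sim_rate"))
  p <- read_pairs(sim$bam)
  p$depth <- 1L  # score every duplicate as its own record
  m <- score_against_truth(p, sim$truth, threshold = 99L)
  n <- m$n_scored
  expected <- 5e-3
  # molecule errors in the mate-overlap region are observed twice, which
  # inflates the variance of the rate estimate by up to ~25%
  se <- sqrt(expected * (1 - expected) / n) * sqrt(1.25)
  expect_lt(abs(m$residual_rate - expected), 3 * se)
})

test_that("spiked variants reach their configured allele fraction", {
  cfg <- sim_config(ref_length = 3000L, n_fragments = 1500L, hotspot_n = 0L,
                    spike_variants = data.frame(pos = 1500L, alt = "X",
                                                vaf = 0.3),
                    pcr_error_rate = 0, seq_error_rate = 0, seed = 56L)
  cfg$spike_variants$alt <- "T"  # ensure a legal base
  sim <- simulate_reads(cfg, file.path(tempdir(), "sim_vaf"))
  fr <- sim$truth$fragments
  cov <- which(fr$start <= 1500L & fr$end >= 1500L)
  carrier <- vapply(cov, function(i) {
    fa <- sim$truth$frag_alleles[[i]]
    !is.null(fa) && 1500L %in% fa$pos
  }, logical(1))
  phat <- mean(carrier)
  se <- sqrt(0.3 * 0.7 / length(cov))
  expect_lt(abs(phat - 0.3), 3 * se)
  # carried allele appears verbatim in the emitted reads
  expect_equal(nrow(sim$truth$variants), 1L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(pcr_error_rate = 1.5), "rates")
  expect_error(sim_config(ref_length = 0), "positive")
  expect_error(sim_config(frag_sigma = 0), "positive")
  expect_error(sim_config(spike_variants = data.frame(pos = 1, alt = "A",
                                                      vaf = 2)), "VAF")
})
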