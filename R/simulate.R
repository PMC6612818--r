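#' Simulation configuration for truth-annotated cfDNA-style read sets
#'
#' Defaults emulate a targeted cfDNA sequencing panel: an 8 kb target, 10^4
#' original fragments (~220-fold fragment coverage), fragment lengths normal
#' with mean 177 bp and SD 20 bp, paired 100 bp reads, and PCR-duplicate
#' depths of `1 + NegBinom(size, mu)` with mean 6 — strongly overdispersed,
#' as PCR jackpotting produces a few very deep amplicon sets alongside many
#' singletons. Random PCR errors hit each duplicate independently at
#' `pcr_error_rate` per base and carry high base qualities (Phred 30-40);
#' sequencer miscalls carry Phred below 20 so the low-quality exemption path
#' is exercised. Hotspot loci model context-driven systematic errors: the
#' same substitution recurring independently in duplicates across all
#' families covering the locus, at a low per-duplicate rate, so it appears
#' as a corrected minority error in many deep families and as an
#' uncorrectable error in singletons. The substitution spectrum is enriched
#' for G>T and C>T changes by default.
#'
#' @param ref_length reference length in bp.
#' @param n_fragments number of original cfDNA fragments.
#' @param frag_mu,frag_sigma fragment-length mean and SD in bp.
#' @param read_length paired-read length in bp.
#' @param dup_depth_mean,dup_depth_size mean and negative-binomial size of
#'   the duplicate-depth distribution `1 + NB(size, mu = mean - 1)`.
#' @param pcr_error_rate per-base, per-duplicate substitution probability.
#' @param seq_error_rate per-base sequencer miscall probability (Phred < 20).
#' @param hotspot_n,hotspot_rate number of hotspot loci (evenly spaced on
#'   the reference) and their per-duplicate recurrence probability.
#' @param hotspot_spec optional explicit `data.frame(pos, to, rate)`
#'   overriding `hotspot_n`/`hotspot_rate` (`pos` 1-based; `to` may be `NA`
#'   to draw from the spectrum).
#' @param early_cycle_rate per-family probability of a shared early-PCR-cycle
#'   error copied into ~half the members (stresses the consensus; default 0).
#' @param spike_variants optional `data.frame(pos, alt, vaf)` of true
#'   variants carried by fragments at the given allele fractions.
#' @param base_qual default Phred of correctly sequenced bases.
#' @param n_orphans reads emitted with an unmapped mate (pass-through test).
#' @param seed RNG seed fixing the entire output.
#' @return A list of class `pec_sim_config`.
#' @export
sim_config <- function(ref_length = 8000L, n_fragments = 10000L,
                       frag_mu = 177, frag_sigma = 20, read_length = 100L,
                       dup_depth_mean = 6, dup_depth_size = 0.5,
                       pcr_error_rate = 1e-3, seq_error_rate = 2e-3,
                       hotspot_n = 5L, hotspot_rate = 0.01,
                       hotspot_spec = NULL, early_cycle_rate = 0,
                       spike_variants = NULL, base_qual = 37L,
                       n_orphans = 0L, seed = 1177L) {
  rates <- c(pcr_error_rate, seq_error_rate, hotspot_rate, early_cycle_rate)
  if (any(rates < 0 | rates > 1)) stop("sim_config(): rates must be in [0, 1]")
  if (ref_length <= 0 || n_fragments <= 0 || read_length <= 0 ||
      frag_sigma <= 0) {
    stop("sim_config(): lengths and sigma must be positive")
  }
  if (!is.null(spike_variants) && any(spike_variants$vaf < 0 |
                                      spike_variants$vaf > 1)) {
    stop("sim_config(): spike VAFs must be in [0, 1]")
  }
  out <- as.list(environment())
  class(out) <- "pec_sim_config"
  out
}

# Draw substitution targets with a spectrum enriched for G>T and C>T.
SUB_WEIGHTS <- list(
  A = c(C = 1, G = 1, T = 1),
  C = c(A = 1, G = 1, T = 3),
  G = c(A = 1, C = 1, T = 3),
  T = c(A = 1, C = 1, G = 1)
)

draw_substitution <- function(from) {
  vapply(from, function(b) {
    w <- SUB_WEIGHTS[[b]]
    sample(names(w), 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an aligned, truth-annotated cfDNA-style read set
#'
#' Generates a random reference, places fragments and PCR-duplicate read
#' pairs on it, injects PCR, sequencer, hotspot (and optionally shared
#' early-cycle) errors, and writes a reference FASTA, a coordinate-sorted
#' indexed BAM (reads are placed at their true coordinates, not re-aligned)
#' and plain-text truth tables. Every emitted base is reconstructable from
#' the truth tables.
#'
#' The truth family partition (`family_id`) groups fragments by identical
#' start/end coordinates: distinct fragments that collide (in the
#' birthday-model sense) are deliberately assigned one family, since no
#' barcode-free method can distinguish them.
#'
#' @param config a `pec_sim_config` from [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `ref_fasta`, `bam`, `truth_dir` paths and
#'   the in-memory `truth` list (`reference`, `fragments`, `pairs`,
#'   `errors`, `hotspots`, `variants`, `config`).
#' @export
simulate_reads <- function(config, dir) {
  stopifnot(inherits(config, "pec_sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  rl <- config$read_length
  chrom <- "sim1"

  refv <- sample(BASES, config$ref_length, replace = TRUE)
  ref <- paste(refv, collapse = "")

  hs <- config$hotspot_spec
  if (is.null(hs)) {
    if (config$hotspot_n > 0L) {
      pos <- round(seq(0.15, 0.85, length.out = config$hotspot_n) *
                     config$ref_length)
      hs <- data.frame(pos = as.integer(pos), to = NA_character_,
                       rate = config$hotspot_rate)
    } else {
      hs <- data.frame(pos = integer(0), to = character(0), rate = numeric(0))
    }
  }
  if (nrow(hs)) {
    hs$from <- refv[hs$pos]
    miss <- is.na(hs$to)
    hs$to[miss] <- draw_substitution(hs$from[miss])
  } else hs$from <- character(0)

  maxlen <- as.integer(ceiling(config$frag_mu + 6 * config$frag_sigma))
  n <- config$n_fragments
  len <- as.integer(pmin(pmax(round(rnorm(n, config$frag_mu,
                                          config$frag_sigma)), rl), maxlen))
  start <- 1L + as.integer(floor(runif(n) * (config$ref_length - len + 1L)))
  end <- start + len - 1L
  depth <- 1L + rnbinom(n, size = config$dup_depth_size,
                        mu = config$dup_depth_mean - 1)
  fragment_id <- sprintf("frag%06d", seq_len(n))
  fam_key <- paste(start, end)
  family_id <- match(fam_key, unique(fam_key))

  # fragment-level spiked variants
  frag_alleles <- vector("list", n)
  var_truth <- data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), vaf = numeric(0))
  if (!is.null(config$spike_variants) && nrow(config$spike_variants)) {
    sv <- config$spike_variants
    var_truth <- data.frame(pos = as.integer(sv$pos), ref = refv[sv$pos],
                            alt = sv$alt, vaf = sv$vaf)
    for (v in seq_len(nrow(sv))) {
      cov <- which(start <= sv$pos[v] & end >= sv$pos[v])
      carrier <- cov[runif(length(cov)) < sv$vaf[v]]
      for (f in carrier) {
        frag_alleles[[f]] <- rbind(frag_alleles[[f]],
                                   data.frame(pos = as.integer(sv$pos[v]),
                                              alt = sv$alt[v]))
      }
    }
  }

  base_qual_str <- int_to_phred(rep(config$base_qual, rl))
  total <- sum(depth)
  out_name <- character(total); out_s1 <- character(total)
  out_s2 <- character(total); out_q1 <- character(total)
  out_q2 <- character(total); out_pos1 <- integer(total)
  out_pos2 <- integer(total); out_frag <- character(total)
  err_list <- vector("list", total)
  idx <- 0L

  for (f in seq_len(n)) {
    fs <- start[f]; fl <- len[f]
    fchars0 <- refv[fs:(fs + fl - 1L)]
    if (!is.null(frag_alleles[[f]])) {
      fa <- frag_alleles[[f]]
      fchars0[fa$pos - fs + 1L] <- fa$alt
    }
    d <- depth[f]
    hcov <- which(hs$pos >= fs & hs$pos <= fs + fl - 1L)

    shared <- NULL
    if (config$early_cycle_rate > 0 && d >= 2L &&
        runif(1) < config$early_cycle_rate) {
      shared <- list(off = sample.int(fl, 1L), carriers = runif(d) < 0.5)
      shared$to <- draw_substitution(fchars0[shared$off])
    }

    n_pcr <- rbinom(d, fl, config$pcr_error_rate)
    hhit <- if (length(hcov)) {
      matrix(runif(d * length(hcov)) < hs$rate[hcov], nrow = d)
    } else NULL
    n_seq1 <- rbinom(d, rl, config$seq_error_rate)
    n_seq2 <- rbinom(d, rl, config$seq_error_rate)

    for (j in seq_len(d)) {
      idx <- idx + 1L
      pname <- sprintf("%s:d%02d", fragment_id[f], j)
      errs <- NULL

      mol_off <- integer(0); mol_to <- character(0); mol_type <- character(0)
      if (n_pcr[j] > 0L) {
        off <- sample.int(fl, n_pcr[j])
        mol_off <- c(mol_off, off)
        mol_to <- c(mol_to, draw_substitution(fchars0[off]))
        mol_type <- c(mol_type, rep("pcr", n_pcr[j]))
      }
      if (!is.null(hhit) && any(hhit[j, ])) {
        hk <- hcov[hhit[j, ]]
        mol_off <- c(mol_off, hs$pos[hk] - fs + 1L)
        mol_to <- c(mol_to, hs$to[hk])
        mol_type <- c(mol_type, rep("hotspot", length(hk)))
      }
      if (!is.null(shared) && shared$carriers[j]) {
        mol_off <- c(mol_off, shared$off)
        mol_to <- c(mol_to, shared$to)
        mol_type <- c(mol_type, "early_cycle")
      }
      # later entries never overwrite earlier ones at the same offset
      if (length(mol_off) > 1L) {
        keep <- !duplicated(mol_off)
        mol_off <- mol_off[keep]; mol_to <- mol_to[keep]
        mol_type <- mol_type[keep]
      }
      # drop no-op substitutions (hotspot 'to' equal to a spiked allele etc.)
      if (length(mol_off)) {
        real <- fchars0[mol_off] != mol_to
        mol_off <- mol_off[real]; mol_to <- mol_to[real]
        mol_type <- mol_type[real]
      }

      fchars <- fchars0
      equal1 <- sum(n_seq1[j]) == 0L; equal2 <- sum(n_seq2[j]) == 0L
      if (length(mol_off)) {
        fchars[mol_off] <- mol_to
        equal1 <- equal1 && !any(mol_off <= rl)
        equal2 <- equal2 && !any(mol_off > fl - rl)
      }

      s1 <- fchars[1:rl]
      s2 <- fchars[(fl - rl + 1L):fl]
      q1 <- rep(config$base_qual, rl); q2 <- rep(config$base_qual, rl)
      if (length(mol_off)) {
        mq <- sample(30:40, length(mol_off), replace = TRUE)
        in1 <- mol_off <= rl
        in2 <- mol_off > fl - rl
        q1[mol_off[in1]] <- mq[in1]
        q2[mol_off[in2] - (fl - rl)] <- mq[in2]
        if (any(in1)) {
          errs <- rbind(errs, data.frame(
            pair_name = pname, mate = 1L, read_pos = mol_off[in1],
            ref_pos = fs + mol_off[in1] - 1L, from = fchars0[mol_off[in1]],
            to = mol_to[in1], type = mol_type[in1], qual = mq[in1]))
        }
        if (any(in2)) {
          errs <- rbind(errs, data.frame(
            pair_name = pname, mate = 2L,
            read_pos = mol_off[in2] - (fl - rl),
            ref_pos = fs + mol_off[in2] - 1L, from = fchars0[mol_off[in2]],
            to = mol_to[in2], type = mol_type[in2], qual = mq[in2]))
        }
      }
      # sequencer miscalls, per mate, always low quality
      for (mate in 1:2) {
        ns <- if (mate == 1L) n_seq1[j] else n_seq2[j]
        if (ns == 0L) next
        sp <- sample.int(rl, ns)
        sq <- sample(2:19, ns, replace = TRUE)
        if (mate == 1L) {
          old <- s1[sp]; s1[sp] <- draw_substitution(old)
          real <- s1[sp] != old
          q1[sp] <- sq
          if (any(real)) errs <- rbind(errs, data.frame(
            pair_name = pname, mate = 1L, read_pos = sp[real],
            ref_pos = fs + sp[real] - 1L, from = old[real],
            to = s1[sp][real], type = "seq", qual = sq[real]))
        } else {
          old <- s2[sp]; s2[sp] <- draw_substitution(old)
          real <- s2[sp] != old
          q2[sp] <- sq
          if (any(real)) errs <- rbind(errs, data.frame(
            pair_name = pname, mate = 2L, read_pos = sp[real],
            ref_pos = fs + (fl - rl) + sp[real] - 1L, from = old[real],
            to = s2[sp][real], type = "seq", qual = sq[real]))
        }
        if (mate == 1L) equal1 <- FALSE else equal2 <- FALSE
      }

      out_name[idx] <- pname
      out_frag[idx] <- fragment_id[f]
      out_pos1[idx] <- fs - 1L                 # 0-based
      out_pos2[idx] <- fs + fl - rl - 1L
      out_s1[idx] <- if (equal1 && is.null(frag_alleles[[f]]))
        substr(ref, fs, fs + rl - 1L) else paste(s1, collapse = "")
      out_s2[idx] <- if (equal2 && is.null(frag_alleles[[f]]))
        substr(ref, fs + fl - rl, fs + fl - 1L) else paste(s2, collapse = "")
      out_q1[idx] <- if (all(q1 == config$base_qual)) base_qual_str else
        int_to_phred(q1)
      out_q2[idx] <- if (all(q2 == config$base_qual)) base_qual_str else
        int_to_phred(q2)
      err_list[[idx]] <- errs
    }
  }

  pairs <- data.frame(
    pair_name = out_name, chrom = chrom,
    m1_pos = out_pos1, m2_pos = out_pos2,
    m1_reverse = FALSE, m2_reverse = TRUE,
    m1_cigar = sprintf("%dM", rl), m2_cigar = sprintf("%dM", rl),
    m1_seq = out_s1, m2_seq = out_s2, m1_qual = out_q1, m2_qual = out_q2,
    m1_mapq = 60L, m2_mapq = 60L
  )

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, config$ref_length))
  lines <- pairs_to_sam_lines(pairs)
  if (config$n_orphans > 0L) {
    opos <- 1L + as.integer(floor(runif(config$n_orphans) *
                                    (config$ref_length - rl)))
    oseq <- vapply(opos, function(p) substr(ref, p, p + rl - 1L), character(1))
    lines <- c(lines, sprintf("orph%03d\t73\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                              seq_len(config$n_orphans), chrom, opos, rl,
                              oseq, base_qual_str))
  }

  ref_fasta <- file.path(dir, "ref.fa")
  writeLines(c(sprintf(">%s", chrom),
               substring(ref, seq(1, nchar(ref), 70),
                         pmin(seq(1, nchar(ref), 70) + 69, nchar(ref)))),
             ref_fasta)
  bam <- file.path(dir, "reads.bam")
  sam_to_bam(c(header, lines), bam)

  errors <- do.call(rbind, err_list[!vapply(err_list, is.null, logical(1))])
  if (is.null(errors)) {
    errors <- data.frame(pair_name = character(0), mate = integer(0),
                         read_pos = integer(0), ref_pos = integer(0),
                         from = character(0), to = character(0),
                         type = character(0), qual = integer(0))
  }
  truth <- list(
    reference = ref, chrom = chrom,
    fragments = data.frame(fragment_id = fragment_id, family_id = family_id,
                           chrom = chrom, start = start, end = end,
                           len = len, depth = depth),
    pairs = data.frame(pair_name = out_name, fragment_id = out_frag,
                       family_id = family_id[match(out_frag, fragment_id)]),
    errors = errors, hotspots = hs, variants = var_truth,
    frag_alleles = frag_alleles, config = config
  )
  has_alleles <- !vapply(frag_alleles, is.null, logical(1))
  allele_tab <- if (any(has_alleles)) {
    do.call(rbind, lapply(which(has_alleles), function(f) {
      data.frame(fragment_id = fragment_id[f], pos = frag_alleles[[f]]$pos,
                 alt = frag_alleles[[f]]$alt)
    }))
  } else data.frame(fragment_id = character(0), pos = integer(0),
                    alt = character(0))
  truth$alleles <- allele_tab
  for (tab in c("fragments", "pairs", "errors", "hotspots", "variants",
                "alleles")) {
    write.table(truth[[tab]], file.path(dir, sprintf("truth_%s.tsv", tab)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(ref_fasta = ref_fasta, bam = bam, truth_dir = dir,
                 truth = truth))
}

#' Reload simulation truth written by [simulate_reads()]
#'
#' Rebuilds the in-memory truth list from a simulation output directory so
#' corrected datasets can be scored in a separate session (or from the
#' command line).
#'
#' @param dir directory containing `ref.fa` and the `truth_*.tsv` tables.
#' @return A truth list as produced by [simulate_reads()].
#' @export
read_truth <- function(dir) {
  ref_fasta <- file.path(dir, "ref.fa")
  if (!file.exists(ref_fasta)) stop("read_truth(): no ref.fa in ", dir)
  ref <- load_reference(ref_fasta)
  rd <- function(name) read.table(file.path(dir, sprintf("truth_%s.tsv", name)),
                                  sep = "\t", header = TRUE,
                                  colClasses = NA, stringsAsFactors = FALSE)
  fragments <- rd("fragments")
  alleles <- rd("alleles")
  frag_alleles <- vector("list", nrow(fragments))
  if (nrow(alleles)) {
    for (g in split(alleles, alleles$fragment_id)) {
      i <- match(g$fragment_id[1], fragments$fragment_id)
      frag_alleles[[i]] <- data.frame(pos = g$pos, alt = g$alt)
    }
  }
  list(reference = unname(ref[1]), chrom = names(ref)[1],
       fragments = fragments, pairs = rd("pairs"), errors = rd("errors"),
       hotspots = rd("hotspots"), variants = rd("variants"),
       frag_alleles = frag_alleles)
}
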