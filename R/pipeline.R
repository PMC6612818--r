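# Vectorised realignment of every record (both mates) against its local
# reference window; same semantics as realign_pair(), avoiding per-row
# data.frame overhead.
realign_all <- function(pairs, reference, window_margin = 50L,
                        min_score = 30L, match = 2L, mismatch = -2L,
                        gap_open = -3L, gap_extend = -1L) {
  kept <- 0L
  for (mate in 1:2) {
    scol <- sprintf("m%d_seq", mate); pcol <- sprintf("m%d_pos", mate)
    ccol <- sprintf("m%d_cigar", mate)
    seqs <- pairs[[scol]]; pos <- pairs[[pcol]]; cigs <- pairs[[ccol]]
    spans <- vapply(cigs, cigar_ref_span, integer(1), USE.NAMES = FALSE)
    spans[spans == 0L] <- nchar(seqs)[spans == 0L]
    for (i in seq_along(seqs)) {
      refseq <- reference[[pairs$chrom[i]]]
      wstart <- max(1L, pos[i] + 1L - window_margin)
      wend <- min(nchar(refseq), pos[i] + spans[i] + window_margin)
      res <- sw_align_cpp(seqs[i], substr(refseq, wstart, wend),
                          as.integer(match), as.integer(mismatch),
                          as.integer(gap_open), as.integer(gap_extend))
      if (res$score >= min_score && !is.na(res$cigar)) {
        pos[i] <- wstart - 1L + res$target_start - 1L
        cigs[i] <- res$cigar
      } else {
        kept <- kept + 1L
      }
    }
    pairs[[pcol]] <- pos
    pairs[[ccol]] <- cigs
  }
  attr(pairs, "realign_kept") <- kept
  pairs
}

#' Run the full PCR error-correction pipeline
#'
#' Orchestrates all stages on an aligned, coordinate-sorted BAM: group read
#' pairs into PCR-duplicate families by unclipped 5' coordinates and
#' orientation; build a quality-aware consensus for every family at or above
#' `min_dup_depth` while flagging trusted/untrusted k-mers; merge flags into
#' the global error-k-mer catalogue; select the highest-quality
#' representative of every low-depth family and intrinsically polish it
#' (downgrade bases localised by error-k-mer intersections to `flag_qual`);
#' realign every surviving record with Smith-Waterman; and write one output
#' pair per family (plus untouched orphans) to BAM, with `XD:i` duplicate
#' depth and `XP:Z` polished-position tags.
#'
#' @param bam_in input BAM (coordinate-sorted, indexed, paired-end).
#' @param ref_fasta reference FASTA.
#' @param bam_out optional output BAM path; omit to skip writing.
#' @param min_dup_depth duplicate-depth threshold for consensus (default 5).
#' @param min_base_qual Phred threshold below which bases neither vote nor
#'   count as PCR errors (default 20).
#' @param flag_qual Phred assigned to polished bases (default 5).
#' @param k k-mer length for the error catalogue (default 21).
#' @param window_margin reference margin for realignment windows (default 50).
#' @param sw_min_score keep the original alignment below this score.
#' @param match,mismatch,gap_open,gap_extend Smith-Waterman scoring.
#' @param realign set `FALSE` to skip the realignment stage.
#' @param verbose print per-stage progress to stderr.
#' @return Invisibly, a list of class `pec_run`: `pairs` (corrected records
#'   with `depth` and polished-position columns), `error_kmers`, and
#'   `report` (input/exclusion counts, family depth histogram, counts of
#'   consensus corrections by substitution type, error-k-mer and polished
#'   base counts, realignment stats, and the configuration used).
#' @export
run_pec <- function(bam_in, ref_fasta, bam_out = NULL, min_dup_depth = 5L,
                    min_base_qual = 20L, flag_qual = 5L, k = 21L,
                    window_margin = 50L, sw_min_score = 30L, match = 2L,
                    mismatch = -2L, gap_open = -3L, gap_extend = -1L,
                    realign = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pec] ", sprintf(...))

  say("reading %s", bam_in)
  pairs <- read_pairs(bam_in)
  fams <- group_pairs(pairs)
  sp <- split_by_depth(fams, min_dup_depth)
  say("%d pairs in %d families (%d high-depth, %d low-depth)",
      nrow(pairs), length(fams), length(sp$high_depth), length(sp$low_depth))

  cons_rows <- list(); tables <- list(); corrected <- list()
  routed <- list()
  for (fam in sp$high_depth) {
    cons <- build_consensus(fam, min_base_qual, min_dup_depth)
    if (is.null(cons)) {  # no plurality length: representative path
      routed[[length(routed) + 1L]] <- fam
      next
    }
    tables[[length(tables) + 1L]] <- flag_family_kmers(fam, cons, k)
    row <- consensus_to_pair(cons)
    row$depth <- cons$depth
    cons_rows[[length(cons_rows) + 1L]] <- row
    if (nrow(cons$corrected)) {
      corrected[[length(corrected) + 1L]] <- cons$corrected
    }
  }
  error_set <- merge_error_kmers(tables)
  say("%d error k-mers from %d consensus families",
      length(error_set$kmers), length(tables))

  low <- c(sp$low_depth, routed)
  low_rows <- lapply(low, function(fam) {
    rep <- select_representative(fam)
    rep$depth <- nrow(fam)
    polish_read(rep, error_set, k, flag_qual)
  })

  keep_cols <- c(names(empty_pairs_df()), "depth", "m1_polished", "m2_polished")
  out <- do.call(rbind, c(
    lapply(cons_rows, function(r) {
      r$m1_polished <- ""; r$m2_polished <- ""; r[, keep_cols, drop = FALSE]
    }),
    lapply(low_rows, function(r) r[, keep_cols, drop = FALSE])
  ))
  if (is.null(out)) {
    out <- empty_pairs_df()
    out$depth <- integer(0); out$m1_polished <- character(0)
    out$m2_polished <- character(0)
  }
  out <- out[order(out$chrom, out$m1_pos, out$pair_name), , drop = FALSE]
  rownames(out) <- NULL

  realign_kept <- 0L
  if (realign && nrow(out)) {
    say("realigning %d records", nrow(out))
    reference <- load_reference(ref_fasta)
    out <- realign_all(out, reference, window_margin, sw_min_score,
                       match, mismatch, gap_open, gap_extend)
    realign_kept <- attr(out, "realign_kept")
  }

  corr <- if (length(corrected)) do.call(rbind, corrected) else NULL
  spectrum <- if (!is.null(corr)) {
    table(factor(paste0(corr$from, ">", corr$to)))
  } else table(character(0))
  count_pol <- function(s) if (is.na(s) || !nzchar(s)) 0L else
    length(strsplit(s, ",", fixed = TRUE)[[1]])
  n_polished <- sum(vapply(low_rows, function(r) {
    count_pol(r$m1_polished) + count_pol(r$m2_polished)
  }, numeric(1)))

  report <- list(
    n_input_pairs = nrow(pairs),
    exclusions = attr(pairs, "exclusions"),
    n_orphans_passed = nrow(attr(pairs, "orphans") %||% empty_orphans_df()),
    n_families = length(fams),
    depth_histogram = depth_histogram(fams),
    n_consensus = length(cons_rows),
    n_low_depth = length(low),
    n_routed_no_plurality = length(routed),
    n_corrected_errors = if (is.null(corr)) 0L else nrow(corr),
    substitution_spectrum = spectrum,
    n_error_kmers = length(error_set$kmers),
    n_polished_bases = n_polished,
    realign_kept = realign_kept,
    config = list(min_dup_depth = min_dup_depth,
                  min_base_qual = min_base_qual, flag_qual = flag_qual,
                  k = k, window_margin = window_margin,
                  sw_min_score = sw_min_score, match = match,
                  mismatch = mismatch, gap_open = gap_open,
                  gap_extend = gap_extend, realign = realign)
  )

  if (!is.null(bam_out)) {
    say("writing %s", bam_out)
    write_pairs(out, attr(pairs, "header"), bam_out,
                orphans = attr(pairs, "orphans"))
  }
  res <- list(pairs = out, error_kmers = error_set, report = report)
  class(res) <- "pec_run"
  invisible(res)
}

#' @export
print.pec_run <- function(x, ...) {
  r <- x$report
  cat("PCR error-correction run\n")
  cat(sprintf("  input pairs:        %d\n", r$n_input_pairs))
  cat(sprintf("  duplicate families: %d (consensus %d, representative %d)\n",
              r$n_families, r$n_consensus, r$n_low_depth))
  cat(sprintf("  corrected PCR errors: %d\n", r$n_corrected_errors))
  cat(sprintf("  error k-mers:       %d\n", r$n_error_kmers))
  cat(sprintf("  polished bases:     %d\n", r$n_polished_bases))
  invisible(x)
}
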