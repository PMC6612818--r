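#' Smith-Waterman local alignment
#'
#' Optimal local alignment of `query` against `target` under affine-gap
#' scoring (a gap of length `g` costs `gap_open + g * gap_extend`), with a
#' deterministic traceback (diagonal preferred over up over left; gap
#' openings preferred over extensions on ties; maximal cell with smallest
#' query then target index).
#'
#' @param query,target non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; defaults
#'   `+2/-2/-3/-1`.
#' @return A list with `score`, 1-based `query_start`, `query_end`,
#'   `target_start`, `target_end`, and a SAM `cigar` (M/I/D, with S soft
#'   clips covering unaligned query flanks). If no positive-scoring local
#'   alignment exists, `score` is 0 and the remaining fields are `NA`.
#' @export
#' @examples
#' sw_align("ACGTACGT", "TTACGTACGTTT")
sw_align <- function(query, target, match = 2L, mismatch = -2L,
                     gap_open = -3L, gap_extend = -1L) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("sw_align(): empty query or target")
  }
  sw_align_cpp(query, target, as.integer(match), as.integer(mismatch),
               as.integer(gap_open), as.integer(gap_extend))
}

#' Load a reference FASTA as a named vector of chromosome sequences
#'
#' @param fasta_path path to a FASTA file.
#' @return Named character vector, one uppercase sequence per contig (names
#'   truncated at the first whitespace, as in SAM `@SQ` lines).
#' @export
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("load_reference(): no such file: ", fasta_path)
  }
  ss <- Biostrings::readDNAStringSet(fasta_path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Realign both mates of a read pair to their local reference windows
#'
#' Each mate is realigned independently with [sw_align()] against the
#' reference window `[orig_start - window_margin, orig_end + window_margin]`
#' (clipped to the contig). The mate's position and CIGAR are replaced by the
#' Smith-Waterman result, with unaligned flanks soft-clipped; sequence and
#' qualities are untouched. If the alignment score falls below `min_score`
#' the original position and CIGAR are kept and the event is counted in the
#' `realign_kept` attribute.
#'
#' @param pair a one-row read-pair `data.frame` as produced by [read_pairs()].
#' @param reference named character vector from [load_reference()].
#' @param window_margin bp of reference context added on each side (default 50).
#' @param min_score keep the original alignment below this score (default 30).
#' @inheritParams sw_align
#' @return The updated one-row `data.frame`; attribute `realign_kept` gives
#'   the number of mates whose original alignment was kept.
#' @export
realign_pair <- function(pair, reference, window_margin = 50L, min_score = 30L,
                         match = 2L, mismatch = -2L, gap_open = -3L,
                         gap_extend = -1L) {
  chrom <- pair$chrom[1]
  if (!chrom %in% names(reference)) {
    stop("realign_pair(): contig not in reference: ", chrom)
  }
  refseq <- reference[[chrom]]
  clen <- nchar(refseq)
  kept <- 0L
  for (mate in 1:2) {
    seq <- pair[[sprintf("m%d_seq", mate)]][1]
    pos0 <- pair[[sprintf("m%d_pos", mate)]][1]     # 0-based leftmost
    cig <- pair[[sprintf("m%d_cigar", mate)]][1]
    span <- cigar_ref_span(cig)
    if (span == 0L) span <- nchar(seq)
    wstart <- max(1L, pos0 + 1L - window_margin)    # 1-based window
    wend <- min(clen, pos0 + span + window_margin)
    res <- sw_align(seq, substr(refseq, wstart, wend), match, mismatch,
                    gap_open, gap_extend)
    if (res$score >= min_score && !is.na(res$cigar)) {
      pair[[sprintf("m%d_pos", mate)]] <- wstart - 1L + res$target_start - 1L
      pair[[sprintf("m%d_cigar", mate)]] <- res$cigar
    } else {
      kept <- kept + 1L
    }
  }
  attr(pair, "realign_kept") <- kept
  pair
}
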