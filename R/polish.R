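#' Select the representative read pair of a low-depth family
#'
#' The member with the highest summed Phred quality over both mates
#' represents the original cfDNA molecule (MarkDuplicates-style selection);
#' exact ties go to the lexicographically smallest `pair_name`.
#'
#' @param family family `data.frame` from [group_pairs()].
#' @return The selected one-row `data.frame`.
#' @export
select_representative <- function(family) {
  if (nrow(family) == 0L) stop("select_representative(): empty family")
  qs <- vapply(seq_len(nrow(family)), function(i) {
    sum(phred_to_int(family$m1_qual[i])) + sum(phred_to_int(family$m2_qual[i]))
  }, numeric(1))
  best <- which(qs == max(qs))
  if (length(best) > 1L) best <- best[order(family$pair_name[best])[1]]
  out <- family[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Flagged read positions for one sequence given the error-k-mer set.
# Each maximal run of consecutive k-windows found in the error set localises
# candidate error bases to the intersection of the windows' spans: a run of
# starts [s, e] gives positions [e, s + k - 1] (a single base for a
# full-length run of k windows). Runs longer than k (several nearby errors
# merged) have an empty formal intersection; the span between the crossed
# endpoints is flagged instead, which contains every contributing error.
error_kmer_spans <- function(seq, error_kmers, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  km <- seq_kmers(seq, k)
  # constructors attach a hash environment so per-read lookups do not
  # re-hash the whole set, as %in% would
  env <- attr(error_kmers, "env")
  hit <- if (!is.null(env)) {
    vapply(km, function(x) !is.null(env[[x]]), logical(1), USE.NAMES = FALSE)
  } else {
    km %in% error_kmers
  }
  hit <- hit & !grepl("N", km, fixed = TRUE)
  if (!any(hit)) return(integer(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flagged <- integer(0)
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    lo <- min(e, s + k - 1L); hi <- max(e, s + k - 1L)
    flagged <- c(flagged, seq.int(lo, hi))
  }
  sort(unique(flagged))
}

#' Intrinsically polish a low-depth representative read pair
#'
#' Flags probable systematic errors in a representative read by intersecting
#' the spans of its k-windows that belong to the global error-k-mer set, and
#' downgrades the base quality at flagged positions to `flag_qual` (default
#' Phred 5). Sequence bases are never changed: downstream tools simply
#' ignore the flagged bases through their quality cutoffs. Positions whose
#' quality is already below `flag_qual` are left untouched. Mates shorter
#' than `k` are returned unchanged with a warning.
#'
#' @param pair one-row `data.frame` from [select_representative()].
#' @param error_set `pec_error_kmers` from [merge_error_kmers()].
#' @param k k-mer length; must equal `error_set$k`.
#' @param flag_qual Phred value assigned to flagged bases (default 5).
#' @return The pair with updated qualities and `m1_polished`/`m2_polished`
#'   columns (comma-separated 1-based flagged read positions, `""` if none).
#' @export
polish_read <- function(pair, error_set, k = error_set$k, flag_qual = 5L) {
  if (!is.na(error_set$k) && k != error_set$k) {
    stop("polish_read(): k = ", k, " does not match error set k = ", error_set$k)
  }
  warned <- FALSE
  for (mate in 1:2) {
    scol <- sprintf("m%d_seq", mate); qcol <- sprintf("m%d_qual", mate)
    pcol <- sprintf("m%d_polished", mate)
    seq <- pair[[scol]][1]
    if (nchar(seq) < k) {
      if (!warned) {
        warning("polish_read(): read shorter than k = ", k, "; left unchanged")
        warned <- TRUE
      }
      pair[[pcol]] <- ""
      next
    }
    flagged <- error_kmer_spans(seq, error_set$kmers, k)
    q <- phred_to_int(pair[[qcol]][1])
    flagged <- flagged[q[flagged] >= flag_qual]
    if (length(flagged)) {
      q[flagged] <- flag_qual
      pair[[qcol]] <- int_to_phred(q)
    }
    pair[[pcol]] <- paste(flagged, collapse = ",")
  }
  pair
}
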