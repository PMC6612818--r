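#' Flag a family's k-mers as trusted or untrusted
#'
#' Every k-mer of the family consensus is trusted. Every k-length window of a
#' voting member that contains at least one corrected PCR-error position
#' (a voting-eligible mismatch against the consensus) is untrusted. Windows
#' whose only mismatches are low-quality (below the voting threshold) are
#' neither trusted nor untrusted, and windows containing `N` are skipped.
#' Reads are stored in reference-forward orientation (as in BAM `SEQ`), so
#' k-mers are compared in that single convention without canonicalisation.
#'
#' @param family family `data.frame` from [group_pairs()].
#' @param consensus its `pec_consensus` from [build_consensus()].
#' @param k k-mer length (default 21).
#' @return List of class `pec_kmer_flags` with elements `k`, `trusted`,
#'   `untrusted` (character sets). If `k` exceeds the read length an empty
#'   table is returned with a warning.
#' @export
flag_family_kmers <- function(family, consensus, k = 21L) {
  trusted <- character(0)
  untrusted <- character(0)
  short <- FALSE
  for (mate in 1:2) {
    cseq <- consensus[[sprintf("mate%d", mate)]]$seq
    if (nchar(cseq) < k) { short <- TRUE; next }
    km <- seq_kmers(cseq, k)
    trusted <- c(trusted, km[!grepl("N", km, fixed = TRUE)])

    corr <- consensus$corrected
    corr <- corr[corr$mate == mate, , drop = FALSE]
    if (nrow(corr) == 0L) next
    n <- nchar(cseq)
    for (pn in unique(corr$pair_name)) {
      cols <- corr$column[corr$pair_name == pn]
      seq <- family[[sprintf("m%d_seq", mate)]][family$pair_name == pn]
      starts <- unique(unlist(lapply(cols, function(p) {
        seq.int(max(1L, p - k + 1L), min(p, n - k + 1L))
      })))
      starts <- starts[starts >= 1L]
      if (!length(starts)) next
      w <- substring(seq, starts, starts + k - 1L)
      untrusted <- c(untrusted, w[!grepl("N", w, fixed = TRUE)])
    }
  }
  if (short && length(trusted) == 0L && length(untrusted) == 0L) {
    warning("flag_family_kmers(): k = ", k, " exceeds read length; empty table")
  }
  out <- list(k = as.integer(k), trusted = unique(trusted),
              untrusted = unique(untrusted))
  class(out) <- "pec_kmer_flags"
  out
}

#' Merge per-family k-mer flag tables into the global error-k-mer set
#'
#' An error k-mer is one that was flagged untrusted in at least one family
#' and trusted in none: `(union of untrusted) minus (union of trusted)`.
#' These recurrent, never-validated patterns drive intrinsic polishing of
#' low-depth reads.
#'
#' @param tables list of `pec_kmer_flags` tables sharing the same `k`.
#' @return List of class `pec_error_kmers` with `k` and the sorted `kmers`
#'   character set (disjoint from every trusted set by construction).
#' @export
merge_error_kmers <- function(tables) {
  ks <- unique(vapply(tables, function(t) t$k, integer(1)))
  if (length(ks) > 1L) stop("merge_error_kmers(): mixed k: ",
                            paste(ks, collapse = ", "))
  trusted <- unique(unlist(lapply(tables, `[[`, "trusted")))
  untrusted <- unique(unlist(lapply(tables, `[[`, "untrusted")))
  new_error_kmers(if (length(ks)) ks else NA_integer_,
                  sort(setdiff(untrusted, trusted)))
}

# Constructor: stores the sorted set plus a hash environment for O(1)
# membership tests during polishing.
new_error_kmers <- function(k, kmers) {
  kmers <- as.character(kmers %||% character(0))
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, length(kmers)))
  for (km in kmers) env[[km]] <- TRUE
  attr(kmers, "env") <- env
  out <- list(k = as.integer(k), kmers = kmers)
  class(out) <- "pec_error_kmers"
  out
}

#' Write an error-k-mer set to a plain-text file (one k-mer per line)
#' @param error_set a `pec_error_kmers` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_error_kmers <- function(error_set, path) {
  writeLines(error_set$kmers, path)
  invisible(path)
}

#' Load an error-k-mer set written by [write_error_kmers()]
#' @param path input file.
#' @return A `pec_error_kmers` object (`k` inferred from the k-mer length).
#' @export
read_error_kmers <- function(path) {
  km <- readLines(path)
  km <- km[nzchar(km)]
  if (length(km) && length(unique(nchar(km))) != 1L) {
    stop("read_error_kmers(): mixed k-mer lengths in ", path)
  }
  new_error_kmers(if (length(km)) nchar(km[1]) else NA_integer_,
                  sort(unique(km)))
}
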