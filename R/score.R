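#' MarkDuplicates-style baseline: keep the highest-quality read per family
#'
#' For every duplicate family, retains the member with the highest summed
#' base quality (no consensus, no polishing). This is the conventional
#' de-duplication baseline that consensus correction is measured against.
#'
#' @param families list from [group_pairs()].
#' @return A `pec_pairs`-shaped `data.frame` with a `depth` column.
#' @export
best_read_dedup <- function(families) {
  out <- lapply(families, function(f) {
    r <- select_representative(f)
    r$depth <- nrow(f)
    r
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- empty_pairs_df(); res$depth <- integer(0)
  }
  rownames(res) <- NULL
  res
}

#' Score corrected output against simulation truth
#'
#' Compares each output record's bases with the true sequence of the
#' fragment it represents (reference plus any spiked alleles), restricted to
#' bases the downstream caller would use (output Phred >= `min_qual`), and
#' evaluates hotspot flagging on low-depth representatives.
#'
#' @param result a `data.frame` of corrected pairs carrying `depth` (and,
#'   for polished records, `m1_polished`/`m2_polished`) — e.g. the `pairs`
#'   element of [run_pec()]'s result or the output of [best_read_dedup()].
#' @param truth truth list from [simulate_reads()].
#' @param min_qual quality cutoff defining scored bases (default 20).
#' @param threshold duplicate-depth threshold separating consensus from
#'   representative records (default 5).
#' @return List of metrics: overall/high-depth/low-depth residual mismatch
#'   rates (`residual_rate`, `residual_rate_high`, `residual_rate_low`),
#'   mismatch and base counts, `hotspot_recall` (flagged fraction of hotspot
#'   errors carried by low-depth representatives; `NA` if none),
#'   `n_hotspot_carriers`, `family_count_agreement`.
#' @export
score_against_truth <- function(result, truth, min_qual = 20L, threshold = 5L) {
  if (nrow(result) == 0L) stop("score_against_truth(): empty result")
  fragment_of <- truth$pairs$fragment_id[match(result$pair_name,
                                               truth$pairs$pair_name)]
  if (anyNA(fragment_of)) {
    stop("score_against_truth(): result contains pair names absent from truth")
  }
  fi <- match(fragment_of, truth$fragments$fragment_id)
  fs <- truth$fragments$start[fi]
  fe <- truth$fragments$end[fi]

  mism <- integer(nrow(result)); scored <- integer(nrow(result))
  for (i in seq_len(nrow(result))) {
    tchars <- strsplit(substr(truth$reference, fs[i], fe[i]), "")[[1]]
    fa <- truth$frag_alleles[[fi[i]]]
    if (!is.null(fa)) tchars[fa$pos - fs[i] + 1L] <- fa$alt
    fl <- length(tchars)
    for (mate in 1:2) {
      seq <- result[[sprintf("m%d_seq", mate)]][i]
      rln <- nchar(seq)
      tm <- if (mate == 1L) tchars[seq_len(min(rln, fl))] else
        tchars[max(1L, fl - rln + 1L):fl]
      sc <- strsplit(seq, "")[[1]][seq_along(tm)]
      q <- phred_to_int(result[[sprintf("m%d_qual", mate)]][i])[seq_along(tm)]
      use <- q >= min_qual
      scored[i] <- scored[i] + sum(use)
      mism[i] <- mism[i] + sum(sc[use] != tm[use])
    }
  }
  high <- result$depth >= threshold
  rate <- function(sel) {
    if (sum(scored[sel]) == 0L) return(NA_real_)
    sum(mism[sel]) / sum(scored[sel])
  }

  # hotspot flagging on low-depth representatives
  hot <- truth$errors[truth$errors$type == "hotspot", , drop = FALSE]
  low_names <- result$pair_name[!high]
  hot <- hot[hot$pair_name %in% low_names, , drop = FALSE]
  recall <- NA_real_
  if (nrow(hot)) {
    ri <- match(hot$pair_name, result$pair_name)
    flagged <- vapply(seq_len(nrow(hot)), function(j) {
      pol <- result[[sprintf("m%d_polished", hot$mate[j])]]
      if (is.null(pol)) return(FALSE)
      p <- pol[ri[j]]
      if (is.na(p) || !nzchar(p)) return(FALSE)
      hot$read_pos[j] %in% as.integer(strsplit(p, ",")[[1]])
    }, logical(1))
    recall <- mean(flagged)
  }

  list(
    residual_rate = rate(rep(TRUE, nrow(result))),
    residual_rate_high = rate(high),
    residual_rate_low = rate(!high),
    n_mismatch = sum(mism), n_scored = sum(scored),
    hotspot_recall = recall, n_hotspot_carriers = nrow(hot),
    n_records = nrow(result),
    n_truth_families = length(unique(truth$pairs$family_id)),
    family_count_agreement =
      nrow(result) == length(unique(truth$pairs$family_id))
  )
}
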