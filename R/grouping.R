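#' Unclipped 5' coordinates and orientation class of each pair
#'
#' Computes, per pair, the duplicate key used for PCR-family grouping: the
#' unclipped 5' coordinate of the forward- and reverse-oriented mate plus the
#' orientation class (`FR`, `RF`, `FF`, `RR`). Leading/trailing soft and hard
#' clips are arithmetically removed (MarkDuplicates semantics) because
#' clipping varies among true duplicates of one fragment.
#'
#' @param pairs a `pec_pairs` `data.frame`.
#' @return `pairs` with columns `fwd5`, `rev5` (0-based), `orientation` and
#'   `family_key` appended.
#' @export
duplicate_key <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$fwd5 <- integer(0); pairs$rev5 <- integer(0)
    pairs$orientation <- character(0); pairs$family_key <- character(0)
    return(pairs)
  }
  five_prime <- function(pos, cigar, reverse) {
    ucig <- unique(cigar)
    lclip <- vapply(ucig, cigar_clip, integer(1), side = "left")
    rclip <- vapply(ucig, cigar_clip, integer(1), side = "right")
    span <- vapply(ucig, cigar_ref_span, integer(1))
    i <- match(cigar, ucig)
    ifelse(reverse, pos + span[i] - 1L + rclip[i], pos - lclip[i])
  }
  p1 <- five_prime(pairs$m1_pos, pairs$m1_cigar, pairs$m1_reverse)
  p2 <- five_prime(pairs$m2_pos, pairs$m2_cigar, pairs$m2_reverse)

  opposite <- pairs$m1_reverse != pairs$m2_reverse
  fwd <- ifelse(opposite, ifelse(pairs$m1_reverse, p2, p1), pmin(p1, p2))
  rev <- ifelse(opposite, ifelse(pairs$m1_reverse, p1, p2), pmax(p1, p2))
  ori <- ifelse(opposite, ifelse(fwd <= rev, "FR", "RF"),
                ifelse(pairs$m1_reverse, "RR", "FF"))
  # canonical convention: key coordinates stored low,high
  lo <- pmin(fwd, rev); hi <- pmax(fwd, rev)
  pairs$fwd5 <- lo
  pairs$rev5 <- hi
  pairs$orientation <- ori
  pairs$family_key <- sprintf("%s:%d:%d:%s", pairs$chrom, lo, hi, ori)
  pairs
}

#' Group read pairs into PCR-duplicate families
#'
#' Partitions pairs by shared duplicate key (contig, unclipped 5' ends,
#' orientation class). Every retained pair belongs to exactly one family;
#' members are sorted by `pair_name` and families by key, so the result is
#' invariant under input order.
#'
#' @param pairs a `pec_pairs` `data.frame`.
#' @return Named list of family `data.frame`s (class `pec_families`); each
#'   element carries attributes `key` (list with `chrom`, `fwd5`, `rev5`,
#'   `orientation`) and `depth`.
#' @export
group_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    out <- list()
    class(out) <- c("pec_families", "list")
    return(out)
  }
  if (is.null(pairs$family_key)) pairs <- duplicate_key(pairs)
  ord <- order(pairs$chrom, pairs$fwd5, pairs$rev5, pairs$orientation,
               pairs$pair_name)
  pairs <- pairs[ord, , drop = FALSE]
  fams <- split(pairs, factor(pairs$family_key,
                              levels = unique(pairs$family_key)))
  fams <- lapply(fams, function(f) {
    rownames(f) <- NULL
    attr(f, "key") <- list(chrom = f$chrom[1], fwd5 = f$fwd5[1],
                           rev5 = f$rev5[1], orientation = f$orientation[1])
    attr(f, "depth") <- nrow(f)
    f
  })
  class(fams) <- c("pec_families", "list")
  fams
}

#' Split families at the consensus duplicate-depth threshold
#'
#' Families with duplicate depth at or above `threshold` take the consensus
#' (DeDuplicates) path; the rest take the representative + intrinsic
#' polishing path.
#'
#' @param families list from [group_pairs()].
#' @param threshold minimum depth for consensus building (default 5; must be
#'   >= 2, a consensus over fewer members is undefined).
#' @return List with elements `high_depth` and `low_depth`, disjoint and
#'   exhaustive.
#' @export
split_by_depth <- function(families, threshold = 5L) {
  if (threshold < 2L) {
    stop("split_by_depth(): threshold must be >= 2 (consensus undefined below)")
  }
  depths <- vapply(families, nrow, integer(1))
  list(
    high_depth = families[depths >= threshold],
    low_depth  = families[depths < threshold]
  )
}

#' Duplicate-depth histogram of a family list
#' @param families list from [group_pairs()].
#' @return `table` of family depths.
#' @export
depth_histogram <- function(families) {
  table(vapply(families, nrow, integer(1)))
}
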