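BASES <- c("A", "C", "G", "T")

# Insertion/deletion profile of a CIGAR: the subsequence of I/D operations
# with their lengths at unclipped query offsets. Members can only vote in a
# positional consensus if their columns correspond, i.e. equal length and
# equal indel profile; clip differences alone do not matter.
indel_profile <- function(cigar) {
  ops <- cigar_ops(cigar)
  if (nrow(ops) == 0L) return("")
  qoff <- 0L
  out <- character(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("I", "D")) out <- c(out, sprintf("%d%s%d", qoff, op, len))
    if (op %in% c("M", "I", "S", "=", "X")) qoff <- qoff + len
  }
  paste(out, collapse = ";")
}

plurality <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return(NULL)  # no strict plurality
  names(tab)[1]
}

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' Consensus qualities for a consensus sequence over family members
#'
#' Per column, the consensus quality is the maximum Phred among
#' voting-eligible member bases (quality >= `min_base_qual`, not `N`) that
#' agree with the consensus base, capped at 93. Columns with no eligible
#' agreeing voter fall back to the best available base matching the
#' consensus, and to Phred 2 if none exists.
#'
#' @param consensus_seq consensus DNA string of length `L`.
#' @param member_seqs character vector of member sequences (each length `L`).
#' @param member_quals list or vector of Phred+33 quality strings.
#' @param min_base_qual voting-eligibility threshold (default 20).
#' @return Integer Phred vector of length `L`.
#' @export
assign_consensus_quals <- function(consensus_seq, member_seqs, member_quals,
                                   min_base_qual = 20L) {
  L <- nchar(consensus_seq)
  cons <- strsplit(consensus_seq, "")[[1]]
  seqm <- do.call(rbind, strsplit(member_seqs, ""))
  qualm <- do.call(rbind, lapply(member_quals, phred_to_int))
  consm <- matrix(cons, nrow = nrow(seqm), ncol = L, byrow = TRUE)
  agree <- seqm == consm
  elig <- agree & qualm >= min_base_qual & seqm != "N"
  q1 <- qualm; q1[!elig] <- -1L
  q2 <- qualm; q2[!agree] <- -1L
  best1 <- apply(q1, 2, max)
  best2 <- apply(q2, 2, max)
  out <- ifelse(best1 >= 0L, best1, ifelse(best2 >= 0L, best2, 2L))
  pmin(as.integer(out), 93L)
}

#' Build the consensus read pair of a high-depth PCR-duplicate family
#'
#' Per-column, quality-aware majority vote over the family members, per mate:
#' at each read position the most common allele among voting-eligible bases
#' (Phred >= `min_base_qual`, not `N`) becomes the consensus base. Ties go to
#' the allele with the larger summed Phred among its supporters, then to the
#' lexicographically smallest base. Member bases that disagree with the
#' consensus while voting-eligible are recorded as corrected PCR errors;
#' low-quality mismatches are deliberately neither corrected nor counted
#' (the base caller has already flagged them, and downstream tools handle
#' them through the quality string).
#'
#' Members whose mate length differs from the family plurality length, or
#' whose CIGAR indel profile differs from the plurality profile, do not vote
#' (positional columns would not correspond) and are counted in
#' `n_nonvoting`. If a mate has no strict plurality length the family cannot
#' be assembled positionally and `NULL` is returned so the caller can route
#' it to the representative path.
#'
#' @param family one family `data.frame` from [group_pairs()].
#' @param min_base_qual Phred threshold for voting eligibility (default 20).
#' @param min_depth minimum duplicate depth; families below it are an error
#'   (they belong on the low-depth path; default 5).
#' @return A list of class `pec_consensus`: per mate `seq`, `qual`
#'   (Phred+33 string), `column_counts` (4 x L allele-count matrix over
#'   eligible bases), `pos`, `cigar` (modal over voters), plus `corrected`
#'   (data.frame mate/column/from/to/pair_name), `depth`, `name` (first
#'   member's pair name), `n_nonvoting`. Or `NULL` if no plurality length.
#' @export
build_consensus <- function(family, min_base_qual = 20L, min_depth = 5L) {
  depth <- nrow(family)
  if (depth < min_depth) {
    stop("build_consensus(): family depth ", depth, " below threshold ",
         min_depth, "; use the representative path")
  }
  mates <- vector("list", 2L)
  corrected <- list()
  n_nonvoting <- 0L
  for (mate in 1:2) {
    seqs <- family[[sprintf("m%d_seq", mate)]]
    quals <- family[[sprintf("m%d_qual", mate)]]
    lens <- nchar(seqs)
    Lc <- plurality(lens)
    if (is.null(Lc)) return(NULL)
    L <- as.integer(Lc)
    cand <- which(lens == L)
    profs <- vapply(family[[sprintf("m%d_cigar", mate)]][cand],
                    indel_profile, character(1), USE.NAMES = FALSE)
    prof <- plurality(profs) %||% min(profs)
    voters <- cand[profs == prof]
    n_nonvoting <- n_nonvoting + (depth - length(voters))

    seqm <- do.call(rbind, strsplit(seqs[voters], ""))
    qualm <- do.call(rbind, lapply(quals[voters], phred_to_int))
    elig <- seqm != "N" & qualm >= min_base_qual

    count4 <- function(fun) {  # 4 x L, rows in BASES order
      t(matrix(vapply(BASES, fun, numeric(L)), nrow = L, ncol = 4L))
    }
    cnt <- count4(function(b) colSums(seqm == b & elig))
    qsum <- count4(function(b) colSums(qualm * (seqm == b & elig)))
    score <- cnt * 1e6 + qsum
    # fallback for columns with no eligible voter: plain majority of all
    # non-N bases, quality-sum then lexicographic tie-break
    cnt2 <- count4(function(b) colSums(seqm == b))
    qsum2 <- count4(function(b) colSums(qualm * (seqm == b)))
    none <- colSums(cnt) == 0
    score[, none] <- cnt2[, none, drop = FALSE] * 1e6 + qsum2[, none, drop = FALSE]
    idx <- max.col(t(score), ties.method = "first")
    cons <- BASES[idx]
    cons[colSums(cnt2) == 0] <- "N"  # every member is N here

    cq <- assign_consensus_quals(paste(cons, collapse = ""), seqs[voters],
                                 quals[voters], min_base_qual)

    consm <- matrix(cons, nrow = length(voters), ncol = L, byrow = TRUE)
    mism <- which(elig & seqm != consm, arr.ind = TRUE)
    if (nrow(mism)) {
      corrected[[mate]] <- data.frame(
        mate = mate, column = as.integer(mism[, 2]),
        from = consm[mism], to = seqm[mism],
        pair_name = family$pair_name[voters][mism[, 1]]
      )
    }
    mates[[mate]] <- list(
      seq = paste(cons, collapse = ""), qual = int_to_phred(cq),
      column_counts = cnt,
      voters = family$pair_name[voters],
      pos = as.integer(modal_value(family[[sprintf("m%d_pos", mate)]][voters])),
      cigar = modal_value(family[[sprintf("m%d_cigar", mate)]][voters]),
      reverse = family[[sprintf("m%d_reverse", mate)]][voters][1],
      mapq = max(family[[sprintf("m%d_mapq", mate)]][voters])
    )
  }
  out <- list(
    mate1 = mates[[1]], mate2 = mates[[2]],
    corrected = if (length(corrected)) do.call(rbind, corrected) else
      data.frame(mate = integer(0), column = integer(0), from = character(0),
                 to = character(0), pair_name = character(0)),
    depth = depth, name = family$pair_name[1], n_nonvoting = n_nonvoting,
    chrom = family$chrom[1]
  )
  class(out) <- "pec_consensus"
  out
}

# One output pair row for a consensus (same columns as pec_pairs).
consensus_to_pair <- function(cons) {
  data.frame(
    pair_name = cons$name, chrom = cons$chrom,
    m1_pos = cons$mate1$pos, m2_pos = cons$mate2$pos,
    m1_reverse = cons$mate1$reverse, m2_reverse = cons$mate2$reverse,
    m1_cigar = cons$mate1$cigar, m2_cigar = cons$mate2$cigar,
    m1_seq = cons$mate1$seq, m2_seq = cons$mate2$seq,
    m1_qual = cons$mate1$qual, m2_qual = cons$mate2$qual,
    m1_mapq = cons$mate1$mapq, m2_mapq = cons$mate2$mapq
  )
}
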