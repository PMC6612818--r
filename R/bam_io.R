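#' Read aligned paired-end records from a BAM file
#'
#' Loads primary, mapped, paired records and assembles them into one row per
#' read pair. Secondary, supplementary, QC-fail, duplicate-flagged and
#' unmapped records are dropped and counted; pairs whose mates map to
#' different contigs, and reads whose mate is unmapped or missing, are set
#' aside as orphans (available via `attr(x, "orphans")`) so the pipeline can
#' pass them through unmodified.
#'
#' @param bam_path path to a coordinate-sorted, indexed BAM.
#' @param region optional `GRanges`-style restriction passed to
#'   `Rsamtools::ScanBamParam(which = )`.
#' @return A `data.frame` of class `pec_pairs` with columns `pair_name`,
#'   `chrom`, and per mate (`m1_`/`m2_`, mate 1 = SAM first-in-pair):
#'   `pos` (0-based leftmost), `reverse`, `cigar`, `seq`, `qual`
#'   (Phred+33 string), `mapq`. Attributes: `header` (SAM header lines),
#'   `exclusions` (named counts), `orphans` (single-end records).
#' @export
read_pairs <- function(bam_path, region = NULL) {
  if (!file.exists(bam_path)) stop("read_pairs(): no such file: ", bam_path)
  idx <- paste0(bam_path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam_path)
  if (!file.exists(idx) && !file.exists(idx2)) {
    stop("read_pairs(): missing BAM index (expected ", idx, ")")
  }

  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "seq", "qual")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what)
  } else {
    Rsamtools::ScanBamParam(what = what, which = region)
  }
  raw <- Rsamtools::scanBam(bam_path, param = param)
  rec <- list(
    qname = unlist(lapply(raw, `[[`, "qname")),
    flag  = unlist(lapply(raw, `[[`, "flag")),
    rname = as.character(unlist(lapply(raw, function(x) as.character(x$rname)))),
    pos   = unlist(lapply(raw, `[[`, "pos")),
    mapq  = unlist(lapply(raw, `[[`, "mapq")),
    cigar = unlist(lapply(raw, `[[`, "cigar")),
    mrnm  = as.character(unlist(lapply(raw, function(x) as.character(x$mrnm)))),
    seq   = unlist(lapply(raw, function(x) as.character(x$seq))),
    qual  = unlist(lapply(raw, function(x) as.character(x$qual)))
  )
  n <- length(rec$flag)
  rec$qname <- as.character(rec$qname %||% character(0))

  hdr <- sam_header_lines(bam_path)

  bit <- function(b) bitwAnd(rec$flag, b) != 0L
  excl <- c(
    unmapped      = 0L, secondary = 0L, supplementary = 0L,
    qc_fail       = 0L, dup_flagged = 0L, orphaned = 0L
  )
  if (n == 0L) {
    out <- empty_pairs_df()
    attr(out, "header") <- hdr
    attr(out, "exclusions") <- excl
    attr(out, "orphans") <- empty_orphans_df()
    class(out) <- c("pec_pairs", "data.frame")
    return(out)
  }

  drop_sec <- bit(0x100); drop_sup <- bit(0x800)
  drop_qc <- bit(0x200); drop_dup <- bit(0x400); drop_unm <- bit(0x4)
  excl["secondary"] <- sum(drop_sec)
  excl["supplementary"] <- sum(drop_sup & !drop_sec)
  excl["qc_fail"] <- sum(drop_qc & !drop_sec & !drop_sup)
  excl["dup_flagged"] <- sum(drop_dup & !drop_sec & !drop_sup & !drop_qc)
  keepable <- !(drop_sec | drop_sup | drop_qc | drop_dup)
  excl["unmapped"] <- sum(drop_unm & keepable)
  keep <- keepable & !drop_unm

  df <- data.frame(
    qname = rec$qname[keep], flag = rec$flag[keep], chrom = rec$rname[keep],
    pos = rec$pos[keep] - 1L, mapq = rec$mapq[keep], cigar = rec$cigar[keep],
    mrnm = rec$mrnm[keep], seq = rec$seq[keep], qual = rec$qual[keep]
  )

  # orphan = mate unmapped, mate on another contig, or mate record absent
  is_first <- bitwAnd(df$flag, 0x40) != 0L
  mate_unm <- bitwAnd(df$flag, 0x8) != 0L
  cnt <- table(df$qname)
  complete <- df$qname %in% names(cnt)[cnt == 2L]
  paired_ok <- complete & !mate_unm &
    (is.na(df$mrnm) | df$mrnm == "=" | df$mrnm == df$chrom)
  # both mates must individually qualify
  ok_by_name <- tapply(paired_ok, df$qname, all)
  good <- as.logical(ok_by_name[df$qname]) &
    as.logical(tapply(is_first, df$qname, sum)[df$qname] == 1L)
  good[is.na(good)] <- FALSE

  orph <- df[!good, , drop = FALSE]
  excl["orphaned"] <- length(unique(orph$qname))
  df <- df[good, , drop = FALSE]

  m1 <- df[bitwAnd(df$flag, 0x40) != 0L, , drop = FALSE]
  m2 <- df[bitwAnd(df$flag, 0x80) != 0L, , drop = FALSE]
  m2 <- m2[match(m1$qname, m2$qname), , drop = FALSE]

  out <- data.frame(
    pair_name = m1$qname, chrom = m1$chrom,
    m1_pos = m1$pos, m2_pos = m2$pos,
    m1_reverse = bitwAnd(m1$flag, 0x10) != 0L,
    m2_reverse = bitwAnd(m2$flag, 0x10) != 0L,
    m1_cigar = m1$cigar, m2_cigar = m2$cigar,
    m1_seq = m1$seq, m2_seq = m2$seq,
    m1_qual = m1$qual, m2_qual = m2$qual,
    m1_mapq = m1$mapq, m2_mapq = m2$mapq
  )
  out <- out[order(out$chrom, out$m1_pos, out$pair_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "header") <- hdr
  attr(out, "exclusions") <- excl
  attr(out, "orphans") <- orph
  class(out) <- c("pec_pairs", "data.frame")
  out
}

empty_pairs_df <- function() {
  data.frame(
    pair_name = character(0), chrom = character(0),
    m1_pos = integer(0), m2_pos = integer(0),
    m1_reverse = logical(0), m2_reverse = logical(0),
    m1_cigar = character(0), m2_cigar = character(0),
    m1_seq = character(0), m2_seq = character(0),
    m1_qual = character(0), m2_qual = character(0),
    m1_mapq = integer(0), m2_mapq = integer(0)
  )
}

empty_orphans_df <- function() {
  data.frame(
    qname = character(0), flag = integer(0), chrom = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    mrnm = character(0), seq = character(0), qual = character(0)
  )
}

sam_header_lines <- function(bam_path) {
  h <- Rsamtools::scanBamHeader(bam_path)[[1]]$text
  if (length(h) == 0L) return(character(0))
  vapply(seq_along(h), function(i) {
    paste(c(names(h)[i], h[[i]]), collapse = "\t")
  }, character(1))
}

# One SAM line per mate for a pairs data.frame. `depth` and the per-mate
# polished-position columns (m1_polished/m2_polished, comma-separated 1-based
# read positions) become XD:i / XP:Z auxiliary tags when present.
pairs_to_sam_lines <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  span1 <- vapply(pairs$m1_cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  span2 <- vapply(pairs$m2_cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
  proper <- pairs$m1_reverse != pairs$m2_reverse
  left1 <- pairs$m1_pos <= pairs$m2_pos
  lo <- pmin(pairs$m1_pos, pairs$m2_pos)
  hi <- pmax(pairs$m1_pos + span1, pairs$m2_pos + span2)
  tlen1 <- ifelse(left1, hi - lo, -(hi - lo))

  flag1 <- 0x1 + 0x40 + ifelse(proper, 0x2, 0L) +
    ifelse(pairs$m1_reverse, 0x10, 0L) + ifelse(pairs$m2_reverse, 0x20, 0L)
  flag2 <- 0x1 + 0x80 + ifelse(proper, 0x2, 0L) +
    ifelse(pairs$m2_reverse, 0x10, 0L) + ifelse(pairs$m1_reverse, 0x20, 0L)

  tags <- function(mate) {
    t <- rep("", nrow(pairs))
    if (!is.null(pairs$depth)) t <- paste0(t, "\tXD:i:", pairs$depth)
    pol <- pairs[[sprintf("m%d_polished", mate)]]
    if (!is.null(pol)) {
      has <- !is.na(pol) & nzchar(pol)
      t[has] <- paste0(t[has], "\tXP:Z:", pol[has])
    }
    t
  }
  line <- function(mate, flag, tlen) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s%s",
            pairs$pair_name, flag, pairs$chrom,
            pairs[[sprintf("m%d_pos", mate)]] + 1L,
            pairs[[sprintf("m%d_mapq", mate)]],
            pairs[[sprintf("m%d_cigar", mate)]],
            pairs[[sprintf("m%d_pos", 3L - mate)]] + 1L, tlen,
            pairs[[sprintf("m%d_seq", mate)]],
            pairs[[sprintf("m%d_qual", mate)]], tags(mate))
  }
  c(line(1L, flag1, tlen1), line(2L, flag2, -tlen1))
}

#' Read a corrected BAM including its depth and polishing tags
#'
#' Like [read_pairs()], additionally recovering the `XD:i` duplicate-depth
#' and `XP:Z` polished-position tags written by [write_pairs()]/[run_pec()]
#' into `depth`, `m1_polished` and `m2_polished` columns, so corrected
#' output can be scored with [score_against_truth()] in a later session.
#'
#' @inheritParams read_pairs
#' @return A `pec_pairs` `data.frame` with the three extra columns.
#' @export
read_corrected_pairs <- function(bam_path) {
  p <- read_pairs(bam_path)
  raw <- Rsamtools::scanBam(bam_path, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = c("XD", "XP")))[[1]]
  fill <- function(x, n) if (is.null(x)) rep(NA, n) else x
  n <- length(raw$qname)
  xd <- fill(raw$tag$XD, n); xp <- fill(raw$tag$XP, n)
  first <- bitwAnd(raw$flag, 0x40) != 0L
  i1 <- match(p$pair_name, raw$qname[first])
  i2 <- match(p$pair_name, raw$qname[!first])
  p$depth <- as.integer(xd[first][i1])
  pol <- function(x) ifelse(is.na(x), "", x)
  p$m1_polished <- pol(xp[first][i1])
  p$m2_polished <- pol(xp[!first][i2])
  p
}

#' Write read pairs to a coordinate-sorted, indexed BAM
#'
#' Records are re-sorted by coordinate before writing. When present, the
#' `depth` column is emitted as an `XD:i` tag (duplicate depth of the
#' family each record represents) and `m1_polished`/`m2_polished` columns as
#' `XP:Z` tags (comma-separated 1-based read positions whose quality was
#' downgraded by intrinsic polishing).
#'
#' @param pairs a `pec_pairs` `data.frame` (see [read_pairs()]).
#' @param header character vector of SAM header lines (at least the `@SQ`
#'   lines for every contig used).
#' @param bam_path output path; `.bai` index written alongside.
#' @param orphans optional single-end records (as in `attr(pairs, "orphans")`)
#'   appended unmodified.
#' @return `bam_path`, invisibly.
#' @export
write_pairs <- function(pairs, header, bam_path, orphans = NULL) {
  dir <- dirname(bam_path)
  if (!dir.exists(dir)) stop("write_pairs(): no such directory: ", dir)
  if (!any(grepl("^@SQ", header))) {
    stop("write_pairs(): header lacks @SQ lines")
  }
  body <- pairs_to_sam_lines(pairs)
  if (!is.null(orphans) && nrow(orphans)) {
    body <- c(body, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                            orphans$qname, orphans$flag, orphans$chrom,
                            orphans$pos + 1L, orphans$mapq, orphans$cigar,
                            ifelse(is.na(orphans$mrnm), "*", orphans$mrnm),
                            0L, 0L, orphans$seq, orphans$qual))
  }
  sam_to_bam(c(header, body), bam_path)
  invisible(bam_path)
}

# Write SAM text lines, convert to BAM, coordinate-sort and index.
sam_to_bam <- function(lines, bam_path) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(lines, sam)
  tmp <- tempfile()
  bam <- Rsamtools::asBam(sam, tmp, overwrite = TRUE, indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam, tempfile())
  unlink(bam)
  file.copy(sorted, bam_path, overwrite = TRUE)
  unlink(sorted)
  Rsamtools::indexBam(bam_path)
  invisible(bam_path)
}
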