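#' @useDynLib pecr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm rbinom rnbinom rnorm runif setNames
#' @importFrom utils write.table read.table
NULL

# Phred+33 string <-> integer vector. Qualities are stored as SAM-encoded
# strings throughout; convert only where arithmetic is needed.
phred_to_int <- function(q) {
  if (nchar(q) == 0L) return(integer(0))
  utf8ToInt(q) - 33L
}

int_to_phred <- function(v) {
  if (length(v) == 0L) return("")
  intToUtf8(pmin(pmax(as.integer(v), 0L), 93L) + 33L)
}

revcomp <- function(s) {
  vapply(s, function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }, character(1), USE.NAMES = FALSE)
}

# Parse a CIGAR string into an op/length table. "*" yields zero rows.
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(0), op = character(0)))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op  = sub("^\\d+", "", toks)
  )
}

# Reference bases consumed by an alignment.
cigar_ref_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# Soft/hard clipped bases at the left (leading) or right (trailing) edge.
cigar_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  ops <- cigar_ops(cigar)
  if (nrow(ops) == 0L) return(0L)
  if (side == "right") ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
  clip <- 0L
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("S", "H")) clip <- clip + ops$len[i] else break
  }
  clip
}

# All k-length windows of a sequence, in read order. Windows are indexed by
# their 1-based start; window i spans read positions [i, i + k - 1].
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
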