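# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation.

# Smith-Waterman-Gotoh by straightforward O(nm) dynamic programming in R,
# with the same declared conventions as the package (gap of length g costs
# open + g*extend; diagonal > up > left; gap open preferred over extend on
# ties; traceback origin = max cell at smallest query then target index).
sw_oracle <- function(query, target, match = 2, mismatch = -2,
                      gap_open = -3, gap_extend = -1) {
  n <- nchar(query); m <- nchar(target)
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # ends in D (consumes target)
  F <- matrix(NEG, n + 1, m + 1)  # ends in I (consumes query)
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                             E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                             F[i, j + 1] + gap_extend)
      s <- if (q[i] == t[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, F[i + 1, j + 1], E[i + 1, j + 1])
    }
  }
  best <- max(H)
  if (best <= 0) return(list(score = 0, cigar = NA_character_))
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- unname(hit[1, 1]) - 1L; j <- unname(hit[1, 2]) - 1L
  bi <- i; bj <- j
  ops <- character(0); state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i + 1, j + 1] == 0) break
      s <- if (q[i] == t[j]) match else mismatch
      if (H[i + 1, j + 1] == H[i, j] + s) {
        ops <- c(ops, "M"); i <- i - 1L; j <- j - 1L
      } else if (H[i + 1, j + 1] == F[i + 1, j + 1]) state <- "F"
      else state <- "E"
    } else if (state == "F") {
      ops <- c(ops, "I")
      open <- F[i + 1, j + 1] == H[i, j + 1] + gap_open + gap_extend
      i <- i - 1L
      if (open) state <- "H"
    } else {
      ops <- c(ops, "D")
      open <- E[i + 1, j + 1] == H[i + 1, j] + gap_open + gap_extend
      j <- j - 1L
      if (open) state <- "H"
    }
  }
  ops <- rev(ops)
  r <- rle(ops)
  cig <- paste0(r$lengths, r$values, collapse = "")
  pre <- if (i > 0) sprintf("%dS", i) else ""
  post <- if (n - bi > 0) sprintf("%dS", n - bi) else ""
  list(score = best, cigar = paste0(pre, cig, post),
       query_start = i + 1L, query_end = bi,
       target_start = j + 1L, target_end = bj)
}

# Exhaustive enumeration of the fixed-length collision probability for small
# integer M: every one of the L^M equally likely start-position placements.
enum_collision <- function(M, L) {
  grids <- do.call(expand.grid, rep(list(seq_len(L)), M))
  mean(apply(grids, 1, function(x) any(duplicated(x))))
}

# Falling-factorial product form (independent of the log-gamma route).
prod_collision <- function(M, L) 1 - prod((L - seq_len(M) + 1) / L)

# Monte-Carlo fragment-placement oracle for the length-averaged collision
# probability: per locus draw an integer length from the (rounded) normal,
# an integer fragment count with mean M_L (floor + Bernoulli on the
# fractional part), place the fragments uniformly over the L start offsets,
# and record whether any two coincide.
mc_collision <- function(D, mu, sigma, n_loci = 1e5) {
  L <- pmax(1L, as.integer(round(rnorm(n_loci, mu, sigma))))
  M <- D * dnorm(L, mu, sigma)
  m <- floor(M) + (runif(n_loci) < (M - floor(M)))
  collide <- logical(n_loci)
  key <- paste(L, m)
  for (k in unique(key)) {
    idx <- which(key == k)
    Lk <- L[idx[1]]; mk <- m[idx[1]]
    if (mk < 2) next
    draws <- matrix(sample.int(Lk, mk * length(idx), replace = TRUE),
                    nrow = mk)
    collide[idx] <- apply(draws, 2, anyDuplicated) > 0
  }
  mean(collide)
}

# Brute-force count of k-windows of a length-n read that contain position i.
windows_containing <- function(i, k, n) {
  starts <- seq_len(max(0L, n - k + 1L))
  sum(vapply(starts, function(s) i >= s && i <= s + k - 1L, logical(1)))
}
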