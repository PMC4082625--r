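# Independent brute-force oracles used to check the fast implementations.
# They re-derive results from first principles and share no code with the
# package internals.

# ---- synteny-block oracle ---------------------------------------------------
# A contiguous (in reference order) run of markers is a valid block iff all
# markers share the chromosome pair and strand relation, target starts are
# strictly monotone in the direction implied by the strand relation, and all
# consecutive gaps are within the limit on both genomes. Blocks are the
# greedy left-to-right maximal valid runs with >= min_markers markers.
oracle_valid_run <- function(sub, idx, max_gap) {
  s <- sub[idx, , drop = FALSE]
  if (any(is.na(s$tgt_chrom))) return(FALSE)
  if (length(unique(s$tgt_chrom)) > 1L) return(FALSE)
  rel <- s$ref_strand == s$tgt_strand
  if (length(unique(rel)) > 1L) return(FALSE)
  if (nrow(s) == 1L) return(TRUE)
  d <- diff(s$tgt_start)
  if (any(d == 0)) return(FALSE)
  if (rel[1] && any(d < 0)) return(FALSE)
  if (!rel[1] && any(d > 0)) return(FALSE)
  for (t in seq_len(nrow(s) - 1L)) {
    if (s$ref_start[t + 1] - s$ref_end[t] > max_gap) return(FALSE)
    tg <- max(0, max(s$tgt_start[t], s$tgt_start[t + 1]) -
                min(s$tgt_end[t], s$tgt_end[t + 1]))
    if (tg > max_gap) return(FALSE)
  }
  TRUE
}

oracle_hsbs <- function(orth, min_markers = 2, max_gap = 4e6) {
  out <- list()
  for (ch in unique(orth$ref_chrom)) {
    sub <- orth[orth$ref_chrom == ch, ]
    sub <- sub[order(sub$ref_start), ]
    i <- 1L
    while (i <= nrow(sub)) {
      j <- i
      while (j + 1L <= nrow(sub) &&
             oracle_valid_run(sub, i:(j + 1L), max_gap)) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_markers && !any(is.na(sub$tgt_chrom[i:j]))) {
        s <- sub[i:j, ]
        rel <- s$ref_strand[1] == s$tgt_strand[1]
        ori <- if (nrow(s) >= 2L) {
          if (s$tgt_start[2] > s$tgt_start[1]) "same" else "inverted"
        } else if (rel) "same" else "inverted"
        out[[length(out) + 1L]] <- data.frame(
          ref_chrom = ch, ref_start = min(s$ref_start),
          ref_end = max(s$ref_end), tgt_chrom = s$tgt_chrom[1],
          orientation = ori, marker_count = nrow(s),
          marker_str = paste(s$gene_id, collapse = ","))
      }
      i <- j + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), tgt_chrom = character(),
                      orientation = character(), marker_count = integer(),
                      marker_str = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$ref_chrom, res$ref_start), ]
}

# ---- tandem-repeat oracle ---------------------------------------------------
# Enumerate every (start, period) pair, count complete copies by direct
# substring comparison, keep period-maximal left-anchored records, then apply
# the same deterministic selection (longest, then smallest period, then
# leftmost) used for reporting.
oracle_tandem <- function(s, min_period = 2, max_period = 100,
                          min_copies = 2) {
  s <- toupper(s)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  cand <- list()
  for (k in min_period:min(max_period, floor(n / min_copies))) {
    for (a in 1:(n - k * min_copies + 1L)) {
      if (n - a + 1L < k * min_copies) next
      unit <- ch[a:(a + k - 1L)]
      if (any(unit == "N")) next
      copies <- 1L
      while (a + (copies + 1L) * k - 1L <= n &&
             !any(ch[(a + copies * k):(a + (copies + 1L) * k - 1L)] == "N") &&
             all(ch[(a + copies * k):(a + (copies + 1L) * k - 1L)] == unit)) {
        copies <- copies + 1L
      }
      if (copies < min_copies) next
      # left-anchored: a run that can be extended one position to the left
      # (position a-1 still matches its period-mate) is not maximal
      if (a - 1L >= 1L && ch[a - 1L] != "N" && ch[a - 1L] == ch[a - 1L + k]) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = a - 1L, end = a - 1L + copies * k, period = k,
        copy_number = copies)
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = numeric(), end = numeric(),
                      period = integer(), copy_number = integer(),
                      motif = character()))
  }
  cc <- unique(do.call(rbind, cand))
  cc <- cc[order(-(cc$end - cc$start), cc$period, cc$start), ]
  keep <- rep(FALSE, nrow(cc))
  ks <- numeric(0); ke <- numeric(0)
  for (i in seq_len(nrow(cc))) {
    if (!any(pmax(0, pmin(cc$end[i], ke) - pmax(cc$start[i], ks)) > 0)) {
      keep[i] <- TRUE
      ks <- c(ks, cc$start[i]); ke <- c(ke, cc$end[i])
    }
  }
  cc <- cc[keep, ]
  cc$motif <- vapply(seq_len(nrow(cc)), function(i) {
    u <- substr(s, cc$start[i] + 1L, cc$start[i] + cc$period[i])
    dd <- paste0(u, u)
    min(vapply(seq_len(nchar(u)),
               function(j) substr(dd, j, j + nchar(u) - 1L), character(1)))
  }, character(1))
  cc[order(cc$start), ]
}

# TRUE when the fast finder and the oracle emit identical call sets.
same_calls <- function(s) {
  got <- find_tandem_repeats(s)
  exp <- oracle_tandem(s)
  identical(as.numeric(got$start), as.numeric(exp$start)) &&
    identical(as.numeric(got$end), as.numeric(exp$end)) &&
    identical(as.integer(got$period), as.integer(exp$period)) &&
    identical(as.integer(got$copy_number), as.integer(exp$copy_number)) &&
    identical(as.character(got$motif), as.character(exp$motif))
}

# ---- hypergeometric tail oracle ---------------------------------------------
# Direct summation of the hypergeometric mass: probability of x or more
# term-positive genes among n drawn from N of which K are positive.
oracle_hyper_tail <- function(x, K, n, N) {
  if (x <= max(0, n + K - N)) return(1)
  xs <- x:min(K, n)
  if (length(xs) == 0L) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

oracle_ease <- function(k, K, n, N) {
  if (k == 0) return(1)
  oracle_hyper_tail(k - 1, K, n - 1, N)
}
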