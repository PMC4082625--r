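#' Find exact tandem repeats in a DNA sequence
#'
#' Scans one sequence for perfect tandem repeats with unit (period) sizes
#' between `min_period` and `max_period` bp. For each period k, maximal runs
#' of positions matching the position k bases earlier are located; a run is
#' reported when it contains at least `min_copies` complete copies of the
#' unit, trimmed to whole copies so that `end - start = period * copies`.
#' Any N terminates a run. Calls overlapping across periods are reduced to
#' the highest-scoring one: longest span wins, ties go to the smallest
#' period, then the leftmost start. Homopolymer runs are reported at the
#' smallest admissible period. The reported motif is the lexicographically
#' least rotation of the repeat unit.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive), or
#'   anything coercible via `as.character()` (e.g. a `DNAString`).
#' @param min_period,max_period Repeat-unit bounds in bp (defaults 2 and
#'   100).
#' @param min_copies Minimum complete copies (default 2).
#' @return Tibble: `start`, `end` (0-based half-open), `period`,
#'   `copy_number`, `motif`.
#' @export
find_tandem_repeats <- function(sequence, min_period = 2, max_period = 100,
                                min_copies = 2) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  empty <- tibble(start = numeric(), end = numeric(), period = integer(),
                  copy_number = integer(), motif = character())
  if (n < min_period * min_copies) return(empty)
  x <- utf8ToInt(s)
  is_n <- x == utf8ToInt("N")
  cand <- list()
  for (k in seq(min_period, min(max_period, floor(n / min_copies)))) {
    idx <- seq(k + 1L, n)
    m <- x[idx] == x[idx - k] & !is_n[idx] & !is_n[idx - k]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths + k >= k * min_copies)
    for (h in hit) {
      j <- starts[h] + k            # 1-based seq position of first match
      len <- r$lengths[h] + k       # full repeat span incl. first copy
      copies <- len %/% k
      a <- j - k                    # 1-based start of the repeat region
      cand[[length(cand) + 1L]] <- c(a - 1L, a - 1L + copies * k, k, copies)
    }
  }
  if (length(cand) == 0L) return(empty)
  cc <- do.call(rbind, cand)
  res <- tibble(start = cc[, 1], end = cc[, 2], period = as.integer(cc[, 3]),
                copy_number = as.integer(cc[, 4])) |>
    arrange(dplyr::desc(.data$end - .data$start), .data$period, .data$start)
  keep <- logical(nrow(res))
  kept_start <- numeric(0); kept_end <- numeric(0)
  for (i in seq_len(nrow(res))) {
    if (!any(overlaps(res$start[i], res$end[i], kept_start, kept_end))) {
      keep[i] <- TRUE
      kept_start <- c(kept_start, res$start[i])
      kept_end <- c(kept_end, res$end[i])
    }
  }
  res <- res[keep, ]
  res$motif <- vapply(seq_len(nrow(res)), function(i) {
    canonical_rotation(substr(s, res$start[i] + 1L, res$start[i] +
                                res$period[i]))
  }, character(1))
  arrange(res, .data$start)
}

# Lexicographically least rotation of a string.
canonical_rotation <- function(unit) {
  k <- nchar(unit)
  if (k <= 1L) return(unit)
  doubled <- paste0(unit, unit)
  rots <- vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L),
                 character(1))
  min(rots)
}
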