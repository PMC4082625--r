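# Internal helpers shared across modules.

# Subsystem seeds are derived from one global seed by fixed offsets so that
# partial reruns (e.g. only the meiosis simulator) are reproducible on their
# own. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset * 1009L) %% 2147483629)
}

# Run `expr` under a local RNG state seeded with `seed`; NULL leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Length of the overlap between [s1,e1) and [s2,e2); vectorised.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# TRUE where [s1,e1) and [s2,e2) share at least one bp.
overlaps <- function(s1, e1, s2, e2) {
  overlap_bp(s1, e1, s2, e2) > 0
}

# Any-overlap of each interval in `x` against the set in `y` (same chrom
# semantics handled by caller via the chrom columns).
interval_hits_any <- function(chrom, start, end, set) {
  if (nrow(set) == 0L || length(chrom) == 0L) return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    same <- set$chrom == chrom[i]
    any(same & overlaps(start[i], end[i], set$start[same], set$end[same]))
  }, logical(1))
}

# Union of possibly-overlapping intervals within one chromosome.
union_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                        default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select(-dplyr::any_of("grp")) |>
    dplyr::select("chrom", "start", "end", dplyr::everything())
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("%s is missing required column(s): %s",
                         what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
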