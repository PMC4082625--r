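#' Merge EBR sets from two detectors
#'
#' EBRs from the two sets that overlap by at least 1 bp on the same
#' chromosome are merged into a single record whose bounds are, by default,
#' the intersection (the narrower consensus) and whose detector is
#' `"merged"`. Non-overlapping EBRs pass through with their provenance.
#' Merging a set with itself returns it unchanged (all detector `merged`).
#'
#' @param set_a,set_b EBR tibbles in the same genome's coordinates.
#' @param rule `"intersection"` (default) or `"union"` bounds for merged
#'   records.
#' @return Combined EBR tibble.
#' @export
merge_ebr_sets <- function(set_a, set_b,
                           rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  a <- as_tibble(set_a); b <- as_tibble(set_b)
  if (nrow(a) > 0L && nrow(b) > 0L &&
      "genome" %in% names(a) && "genome" %in% names(b) &&
      length(union(unique(a$genome), unique(b$genome))) > 1L) {
    abort("cannot merge EBR sets from different genomes")
  }
  if (nrow(a) == 0L) return(b)
  if (nrow(b) == 0L) return(a)
  pairs <- inner_join(
    a |> mutate(.ia = row_number()),
    b |> mutate(.ib = row_number()) |>
      select(".ib", chrom_b = "chrom", start_b = "start", end_b = "end"),
    by = dplyr::join_by("chrom" == "chrom_b", "start" < "end_b",
                        "end" > "start_b"))
  merged <- pairs |>
    mutate(start = if (rule == "intersection") pmax(.data$start,
                                                    .data$start_b)
           else pmin(.data$start, .data$start_b),
           end = if (rule == "intersection") pmin(.data$end, .data$end_b)
           else pmax(.data$end, .data$end_b),
           detector = "merged") |>
    select(-"start_b", -"end_b")
  pass_a <- a |> mutate(.ia = row_number()) |>
    filter(!.data$.ia %in% pairs$.ia) |> select(-".ia")
  pass_b <- b |> mutate(.ib = row_number()) |>
    filter(!.data$.ib %in% pairs$.ib) |> select(-".ib")
  bind_rows(merged |> select(-".ia", -".ib"), pass_a, pass_b) |>
    distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start)
}

#' Build telomeric and centromeric region masks
#'
#' Telomeric/subtelomeric masks are the `telomere_bp` (default 2 Mbp) at each
#' chromosome end; centromeric/pericentromeric masks extend
#' `centromere_flank_bp` (default 2 Mbp) on each side of every N-run,
#' including the run itself. Overlapping mask intervals of the same label are
#' unioned.
#'
#' @param assembly List with `chrom_lengths` (named numeric) and `n_runs`
#'   (tibble `chrom`, `start`, `end`).
#' @param telomere_bp,centromere_flank_bp Mask extents in bp.
#' @return Tibble: `chrom`, `start`, `end`, `label`
#'   (`telomeric`/`centromeric`).
#' @export
build_region_masks <- function(assembly, telomere_bp = 2e6,
                               centromere_flank_bp = 2e6) {
  lens <- assembly$chrom_lengths
  n_runs <- assembly$n_runs %||% tibble(chrom = character(),
                                        start = numeric(), end = numeric())
  short <- names(lens)[lens < 2 * telomere_bp]
  if (length(short)) {
    warn(sprintf("chromosome(s) shorter than 2 x telomere_bp, fully telomeric: %s",
                 paste(short, collapse = ", ")))
  }
  telo <- purrr::map_dfr(names(lens), function(ch) {
    L <- lens[[ch]]
    tibble(chrom = ch,
           start = c(0, max(L - telomere_bp, 0)),
           end = c(min(telomere_bp, L), L))
  }) |> union_intervals() |> mutate(label = "telomeric")
  cen <- if (nrow(n_runs) == 0L) {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           label = character())
  } else {
    n_runs |>
      mutate(start = pmax(0, .data$start - centromere_flank_bp),
             end = pmin(lens[.data$chrom], .data$end + centromere_flank_bp)) |>
      select("chrom", "start", "end") |>
      union_intervals() |> mutate(label = "centromeric")
  }
  bind_rows(telo, cen) |> arrange(.data$chrom, .data$start)
}

#' Exclude EBRs overlapping masked regions or labelled as gaps
#'
#' Any overlap with a telomeric or centromeric mask excludes an EBR
#' (conservative criterion); EBRs already labelled `gap` stay excluded.
#' Telomeric takes precedence over centromeric when an EBR overlaps both.
#' All remaining EBRs get status `retained`.
#'
#' @param ebrs EBR tibble.
#' @param masks Output of [build_region_masks()].
#' @return The EBR tibble with an updated `status` column.
#' @export
filter_ebrs <- function(ebrs, masks) {
  if (nrow(ebrs) == 0L) return(ebrs)
  telo <- masks |> filter(.data$label == "telomeric")
  cen <- masks |> filter(.data$label == "centromeric")
  ebrs |>
    mutate(
      hit_t = interval_hits_any(.data$chrom, .data$start, .data$end, telo),
      hit_c = interval_hits_any(.data$chrom, .data$start, .data$end, cen),
      status = dplyr::case_when(
        .data$status == "gap" ~ "gap",
        .data$hit_t ~ "telomeric",
        .data$hit_c ~ "centromeric",
        TRUE ~ "retained")) |>
    select(-"hit_t", -"hit_c")
}

#' Retained EBRs only
#' @param ebrs EBR tibble after [filter_ebrs()].
#' @return Rows with status `retained`.
#' @export
retained_ebrs <- function(ebrs) filter(ebrs, .data$status == "retained")
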