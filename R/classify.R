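#' Classify rearrangements behind retained EBRs
#'
#' Each retained EBR is interpreted through its two flanking synteny blocks:
#' \itemize{
#'   \item \strong{inversion} — the flanking blocks lie on the same target
#'     chromosome with opposite orientations; the two EBRs bounding the
#'     inverted block are grouped into one rearrangement whose region is the
#'     inverted block's span.
#'   \item \strong{fusion / fission} — the flanks map to different target
#'     chromosomes and the genome-wide chromosome counts differ (fewer target
#'     chromosomes: fusion; more: fission).
#'   \item \strong{translocation} — chromosome-pair change without a change
#'     in chromosome count.
#'   \item \strong{indel} — flanks share target chromosome and orientation
#'     but the target-side gap is a small fraction of the reference-side gap
#'     (sequence present in only one genome).
#'   \item \strong{complex} — anything else, including EBRs missing a flank.
#' }
#' Size classes follow the 1.4 Mbp convention: rearranged regions larger than
#' 1.4 Mbp are `macro`, the rest (including exactly 1.4 Mbp) `micro`.
#'
#' @param hsbs HSB table from [detect_hsbs()] (reference direction).
#' @param ebrs Retained EBR tibble with `flank_left`/`flank_right`.
#' @param macro_threshold_bp Macro/micro boundary (default 1.4 Mbp).
#' @param indel_gap_ratio Maximum target-gap / reference-gap ratio for an
#'   indel call (default 0.5: the reference-side gap must be at least twice
#'   the target-side gap, the target-side gap being ordinary intergenic
#'   distance when sequence was deleted).
#' @return Tibble: `rearr_id`, `type`, `size_class`, `chrom`,
#'   `region_start`, `region_end`, `span_bp`, `member_ebrs` (list-column).
#' @export
classify_rearrangements <- function(hsbs, ebrs,
                                    macro_threshold_bp = 1.4e6,
                                    indel_gap_ratio = 0.5) {
  if (nrow(ebrs) == 0L) {
    return(tibble(rearr_id = character(), type = character(),
                  size_class = character(), chrom = character(),
                  region_start = numeric(), region_end = numeric(),
                  span_bp = numeric(), member_ebrs = list()))
  }
  h <- hsbs
  get_hsb <- function(id) h[match(id, h$hsb_id), ]
  n_ref_chrom <- dplyr::n_distinct(h$ref_chrom)
  n_tgt_chrom <- dplyr::n_distinct(h$tgt_chrom)

  rows <- purrr::pmap(ebrs, function(ebr_id, chrom, start, end,
                                     flank_left, flank_right,
                                     genome = "ref", ...) {
    L <- get_hsb(flank_left); R <- get_hsb(flank_right)
    if (nrow(L) == 0L || nrow(R) == 0L || is.na(L$hsb_id) || is.na(R$hsb_id)) {
      return(tibble(type = "complex", chrom = chrom, region_start = start,
                    region_end = end, member_ebrs = list(ebr_id),
                    inv_block = NA_character_))
    }
    if (L$tgt_chrom != R$tgt_chrom) {
      type <- if (n_tgt_chrom > n_ref_chrom) "fission"
      else if (n_tgt_chrom < n_ref_chrom) "fusion"
      else "translocation"
      # types are polarized with the pipeline's reference genome treated as
      # ancestral: an EBR detected in the target-as-reference direction sees
      # the same event with the opposite polarity
      if (identical(genome, "tgt")) {
        type <- c(fission = "fusion", fusion = "fission",
                  translocation = "translocation")[[type]]
      }
      return(tibble(type = type, chrom = chrom, region_start = start,
                    region_end = end, member_ebrs = list(ebr_id),
                    inv_block = NA_character_))
    }
    if (L$orientation != R$orientation) {
      blk <- if (L$orientation == "inverted") L else R
      return(tibble(type = "inversion", chrom = chrom,
                    region_start = blk$ref_start, region_end = blk$ref_end,
                    member_ebrs = list(ebr_id), inv_block = blk$hsb_id))
    }
    ref_gap <- end - start
    t_gap <- max(0, max(L$tgt_start, R$tgt_start) -
                   min(L$tgt_end, R$tgt_end))
    if (ref_gap > 0 && t_gap <= indel_gap_ratio * ref_gap) {
      return(tibble(type = "indel", chrom = chrom, region_start = start,
                    region_end = end, member_ebrs = list(ebr_id),
                    inv_block = NA_character_))
    }
    tibble(type = "complex", chrom = chrom, region_start = start,
           region_end = end, member_ebrs = list(ebr_id),
           inv_block = NA_character_)
  })
  res <- bind_rows(rows)
  # group the two EBRs flanking one inverted block into one rearrangement
  inv_rows <- res |> filter(.data$type == "inversion")
  inv <- if (nrow(inv_rows) == 0L) inv_rows |> select(-"inv_block") else {
    inv_rows |>
      group_by(.data$inv_block, .data$chrom, .data$type) |>
      summarise(region_start = min(.data$region_start),
                region_end = max(.data$region_end),
                member_ebrs = list(unlist(.data$member_ebrs)),
                .groups = "drop") |>
      select(-"inv_block")
  }
  oth <- res |> filter(.data$type != "inversion") |> select(-"inv_block")
  bind_rows(inv, oth) |>
    mutate(span_bp = .data$region_end - .data$region_start,
           size_class = if_else(.data$span_bp > macro_threshold_bp,
                                "macro", "micro"),
           rearr_id = sprintf("rearr%03d", row_number())) |>
    select("rearr_id", "type", "size_class", "chrom", "region_start",
           "region_end", "span_bp", "member_ebrs") |>
    arrange(.data$chrom, .data$region_start)
}

#' Inner-edge span between two breakpoint intervals
#'
#' Distance from the end of the proximal EBR to the start of the distal EBR,
#' the convention for quoting the extent of a rearranged region bounded by
#' two breakpoint intervals on one chromosome. Inputs in bp, result in Mbp.
#'
#' @param interval_1,interval_2 Numeric length-2 vectors `c(start, end)` in
#'   bp; order of the two intervals is immaterial.
#' @return Span in Mbp.
#' @export
rearrangement_span <- function(interval_1, interval_2) {
  stopifnot(length(interval_1) == 2L, length(interval_2) == 2L)
  if (interval_1[1] > interval_2[1]) {
    tmp <- interval_1; interval_1 <- interval_2; interval_2 <- tmp
  }
  if (interval_2[1] < interval_1[2]) {
    abort("breakpoint intervals overlap; span is undefined")
  }
  (interval_2[1] - interval_1[2]) / 1e6
}
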