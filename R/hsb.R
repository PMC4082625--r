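#' Detect homologous synteny blocks from an ortholog table
#'
#' Greedy chaining over markers sorted by reference coordinate. The current
#' block is extended while the next marker (i) shares the block's chromosome
#' pair, (ii) continues the block's monotone target order, (iii) matches the
#' block's strand relation, and (iv) lies within `max_marker_gap_bp` of the
#' previous marker on both genomes. A block's orientation is fixed by its
#' first two markers (`same`: target ascending with equal strands;
#' `inverted`: target descending with opposite strands); a later
#' contradiction closes the block. Blocks with fewer than `min_markers`
#' markers are discarded.
#'
#' @param orthologs Tibble with columns `gene_id`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `ref_strand`, `tgt_chrom`, `tgt_start`, `tgt_end`,
#'   `tgt_strand` (0-based half-open bp). Rows with NA target coordinates
#'   (reference genes with no target ortholog, e.g. deleted sequence) close
#'   the open chain: they mark synteny disrupted in this direction.
#' @param min_markers Minimum markers per block (default 2: a single
#'   out-of-order marker cannot found a block).
#' @param max_marker_gap_bp Maximum within-block gap between consecutive
#'   markers on either genome (default 4 Mbp).
#' @param drop_discordant_singletons If `TRUE`, markers whose strand relation
#'   disagrees with both neighbours (which agree with each other) are removed
#'   before chaining.
#' @return Tibble of class `synrec_hsbs`: `hsb_id`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `tgt_chrom`, `tgt_start`, `tgt_end`, `orientation`,
#'   `marker_count`, `marker_ids` (list-column).
#' @export
detect_hsbs <- function(orthologs, min_markers = 2,
                        max_marker_gap_bp = 4e6,
                        drop_discordant_singletons = FALSE) {
  orth <- as_tibble(orthologs)
  cols <- c("gene_id", "ref_chrom", "ref_start", "ref_end", "ref_strand",
            "tgt_chrom", "tgt_start", "tgt_end", "tgt_strand")
  stopifnot_cols(orth, cols, "ortholog table")
  if (anyDuplicated(orth$gene_id)) {
    abort("ortholog table contains duplicated gene_id values")
  }
  if (nrow(orth) == 0L || all(is.na(orth$tgt_chrom))) return(empty_hsbs())
  orth <- orth |>
    arrange(.data$ref_chrom, .data$ref_start) |>
    mutate(rel = .data$ref_strand == .data$tgt_strand)

  if (drop_discordant_singletons && nrow(orth) >= 3L) {
    orth <- orth |>
      group_by(.data$ref_chrom) |>
      filter(!(!is.na(lag(.data$rel)) & !is.na(lead(.data$rel)) &
                 lag(.data$rel) == lead(.data$rel) &
                 .data$rel != lag(.data$rel))) |>
      ungroup()
  }

  blocks <- list()
  for (ch in unique(orth$ref_chrom)) {
    sub <- orth |> filter(.data$ref_chrom == ch)
    n <- nrow(sub)
    chain <- integer()  # indices into sub
    dir <- 0L           # 0 undetermined, +1 ascending, -1 descending
    emit <- function(idx) {
      if (length(idx) < min_markers) return(invisible())
      cs <- sub[idx, ]
      ori <- if (nrow(cs) >= 2L) {
        if (cs$tgt_start[2] > cs$tgt_start[1]) "same" else "inverted"
      } else if (cs$rel[1]) "same" else "inverted"
      blocks[[length(blocks) + 1L]] <<- tibble(
        ref_chrom = cs$ref_chrom[1],
        ref_start = min(cs$ref_start), ref_end = max(cs$ref_end),
        tgt_chrom = cs$tgt_chrom[1],
        tgt_start = min(cs$tgt_start), tgt_end = max(cs$tgt_end),
        orientation = ori, marker_count = nrow(cs),
        marker_ids = list(cs$gene_id))
    }
    for (i in seq_len(n)) {
      if (is.na(sub$tgt_chrom[i])) {
        # marker with no ortholog in the target genome: evidence of
        # disrupted synteny in this direction — close the open chain
        emit(chain)
        chain <- integer()
        dir <- 0L
        next
      }
      if (length(chain) == 0L) {
        chain <- i
        next
      }
      p <- chain[length(chain)]
      step <- sign(sub$tgt_start[i] - sub$tgt_start[p])
      t_gap <- max(0, max(sub$tgt_start[i], sub$tgt_start[p]) -
                     min(sub$tgt_end[i], sub$tgt_end[p]))
      ok <- sub$tgt_chrom[i] == sub$tgt_chrom[p] &&
        sub$rel[i] == sub$rel[chain[1]] &&
        step != 0L &&
        (dir == 0L || step == dir) &&
        (dir != 0L || (step == 1L) == sub$rel[i]) &&
        (sub$ref_start[i] - sub$ref_end[p]) <= max_marker_gap_bp &&
        t_gap <= max_marker_gap_bp
      if (ok) {
        if (dir == 0L) dir <- step
        chain <- c(chain, i)
      } else {
        emit(chain)
        chain <- i
        dir <- 0L
      }
    }
    emit(chain)
  }
  if (length(blocks) == 0L) return(empty_hsbs())
  bind_rows(blocks) |>
    arrange(.data$ref_chrom, .data$ref_start) |>
    mutate(hsb_id = sprintf("hsb%04d", row_number())) |>
    select("hsb_id", dplyr::everything()) |>
    structure(class = c("synrec_hsbs", class(tibble())))
}

empty_hsbs <- function() {
  tibble(hsb_id = character(), ref_chrom = character(), ref_start = numeric(),
         ref_end = numeric(), tgt_chrom = character(), tgt_start = numeric(),
         tgt_end = numeric(), orientation = character(),
         marker_count = integer(), marker_ids = list()) |>
    structure(class = c("synrec_hsbs", class(tibble())))
}

empty_ebrs <- function() {
  tibble(ebr_id = character(), genome = character(), chrom = character(),
         start = numeric(), end = numeric(), flank_left = character(),
         flank_right = character(), detector = character(),
         status = character())
}

#' Derive evolutionary breakpoint regions between consecutive synteny blocks
#'
#' For each reference chromosome, the interval between the end of one HSB and
#' the start of the next is an EBR candidate. Candidates larger than
#' `max_ebr_bp` (default 4 Mbp) are labelled `gap` and excluded from the
#' retained set downstream. Intervals between a chromosome end and the
#' first/last HSB are terminal segments, not EBRs, and are not emitted.
#'
#' @param hsbs Output of [detect_hsbs()].
#' @param chrom_lengths Named numeric of chromosome lengths for the genome the
#'   HSB coordinates live in (or an assembly list with a `chrom_lengths`
#'   element).
#' @param max_ebr_bp Size threshold separating EBRs from assembly-scale gaps.
#' @param genome Label recorded in the `genome` column (`"ref"` or `"tgt"`).
#' @return EBR tibble: `ebr_id`, `genome`, `chrom`, `start`, `end`,
#'   `flank_left`, `flank_right`, `detector`, `status`
#'   (`candidate` or `gap`).
#' @export
derive_ebrs <- function(hsbs, chrom_lengths, max_ebr_bp = 4e6,
                        genome = "ref") {
  if (is.list(chrom_lengths) && !is.null(chrom_lengths$chrom_lengths)) {
    chrom_lengths <- chrom_lengths$chrom_lengths
  }
  if (nrow(hsbs) == 0L) return(empty_ebrs())
  bad <- hsbs |> filter(!.data$ref_chrom %in% names(chrom_lengths) |
                          .data$ref_start < 0 |
                          .data$ref_end > chrom_lengths[.data$ref_chrom])
  if (nrow(bad) > 0L) {
    abort(sprintf("HSB(s) outside chromosome bounds: %s",
                  paste(bad$hsb_id, collapse = ", ")))
  }
  res <- hsbs |>
    arrange(.data$ref_chrom, .data$ref_start) |>
    group_by(.data$ref_chrom) |>
    mutate(next_start = lead(.data$ref_start),
           next_id = lead(.data$hsb_id)) |>
    ungroup() |>
    filter(!is.na(.data$next_start)) |>
    mutate(start = .data$ref_end, end = .data$next_start)
  if (any(res$end < res$start)) abort("overlapping HSBs: cannot derive EBRs")
  res |>
    mutate(genome = genome, chrom = .data$ref_chrom,
           flank_left = .data$hsb_id, flank_right = .data$next_id,
           detector = "chain",
           status = if_else(.data$end - .data$start > max_ebr_bp,
                            "gap", "candidate"),
           ebr_id = sprintf("%s_ebr%04d", genome,
                            dplyr::row_number())) |>
    select("ebr_id", "genome", "chrom", "start", "end", "flank_left",
           "flank_right", "detector", "status")
}

#' Tighten EBR bounds to the innermost flanking markers
#'
#' Replaces each EBR's bounds by the innermost coordinates of the nearest
#' orthologous markers of its two flanking HSBs (the end of the left flank's
#' last marker, the start of the right flank's first marker). Bounds are
#' never widened; EBRs missing a flank are returned unchanged and flagged.
#'
#' @param ebrs EBR tibble (with `flank_left`/`flank_right` HSB ids).
#' @param hsbs The HSB table the flanks refer to.
#' @return The EBR tibble with updated `start`/`end`, `detector` set to
#'   `"narrowed"` where tightening applied, and a logical `flagged` column
#'   marking EBRs with a missing flank.
#' @export
narrow_ebrs <- function(ebrs, hsbs) {
  if (nrow(ebrs) == 0L) return(mutate(ebrs, flagged = logical()))
  key <- hsbs |> select("hsb_id", "ref_start", "ref_end")
  out <- ebrs |>
    left_join(key |> rename(l_start = "ref_start", l_end = "ref_end"),
              by = c(flank_left = "hsb_id")) |>
    left_join(key |> rename(r_start = "ref_start", r_end = "ref_end"),
              by = c(flank_right = "hsb_id")) |>
    mutate(flagged = is.na(.data$l_end) | is.na(.data$r_start),
           new_start = pmax(.data$start, .data$l_end, na.rm = TRUE),
           new_end = pmin(.data$end, .data$r_start, na.rm = TRUE),
           changed = !.data$flagged &
             (.data$new_start > .data$start | .data$new_end < .data$end),
           start = if_else(.data$flagged, .data$start, .data$new_start),
           end = if_else(.data$flagged, .data$end, .data$new_end),
           detector = if_else(.data$changed, "narrowed", .data$detector))
  out |> select(-"l_start", -"l_end", -"r_start", -"r_end", -"new_start",
                -"new_end", -"changed")
}

# Swap reference and target roles of an ortholog table.
swap_orthologs <- function(orth) {
  orth |>
    rename(ref_chrom = "tgt_chrom", ref_start = "tgt_start",
           ref_end = "tgt_end", ref_strand = "tgt_strand",
           tgt_chrom = "ref_chrom", tgt_start = "ref_start",
           tgt_end = "ref_end", tgt_strand = "ref_strand") |>
    filter(!is.na(.data$ref_chrom))
}

#' Run the full detection pipeline in both reference directions
#'
#' Executes detect -> derive -> narrow twice, once with each genome as the
#' reference, so breakpoint regions are obtained in each genome's own
#' coordinates.
#'
#' @param orthologs Ortholog table as for [detect_hsbs()].
#' @param ref_lengths,tgt_lengths Named chromosome-length vectors (or
#'   assembly lists) for the two genomes.
#' @inheritParams detect_hsbs
#' @param max_ebr_bp Size threshold separating EBRs from gaps.
#' @return List with `ref_hsbs`, `tgt_hsbs`, `ref_ebrs`, `tgt_ebrs`.
#' @export
dual_reference_run <- function(orthologs, ref_lengths, tgt_lengths,
                               min_markers = 2, max_marker_gap_bp = 4e6,
                               max_ebr_bp = 4e6,
                               drop_discordant_singletons = FALSE) {
  run_one <- function(orth, lens, genome) {
    hsbs <- detect_hsbs(orth, min_markers, max_marker_gap_bp,
                        drop_discordant_singletons)
    ebrs <- derive_ebrs(hsbs, lens, max_ebr_bp, genome = genome)
    list(hsbs = hsbs, ebrs = narrow_ebrs(ebrs, hsbs))
  }
  fwd <- run_one(orthologs, ref_lengths, "ref")
  rev <- run_one(swap_orthologs(as_tibble(orthologs)), tgt_lengths, "tgt")
  list(ref_hsbs = fwd$hsbs, tgt_hsbs = rev$hsbs,
       ref_ebrs = fwd$ebrs, tgt_ebrs = rev$ebrs)
}
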