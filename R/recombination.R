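#' Relative MLH1 focus positions along the synaptonemal complex
#'
#' Expresses every focus as a signed percentage from the centromere: negative
#' on the p-arm (short side, before the centromere), positive on the q-arm.
#' Two conventions are returned: `rel_pos_sc`, the distance from the
#' centromere as a percentage of total SC length, and `rel_pos_arm`, the
#' distance as a percentage of the containing arm's length (so the q-arm
#' telomere is +100). A focus exactly at the centromere is assigned to the
#' q-arm (position 0). Positions are binned into 10% intervals of total SC
#' length.
#'
#' @param cells SC table from [simulate_meiotic_cells()] or
#'   [read_foci_csv()].
#' @return Tibble: `cell_id`, `sc_id`, `focus_um`, `rel_pos_sc`,
#'   `rel_pos_arm`, `bin` (lower edge of the signed 10% bin).
#' @export
relative_positions <- function(cells) {
  stopifnot_cols(cells, c("cell_id", "sc_id", "sc_length_um",
                          "centromere_um", "foci_um"), "cells")
  cells |>
    select("cell_id", "sc_id", "sc_length_um", "centromere_um", "foci_um") |>
    tidyr::unnest_longer("foci_um", values_to = "focus_um") |>
    filter(!is.na(.data$focus_um)) |>
    mutate(
      rel_pos_sc = (.data$focus_um - .data$centromere_um) /
        .data$sc_length_um * 100,
      rel_pos_arm = if_else(
        .data$focus_um >= .data$centromere_um,
        (.data$focus_um - .data$centromere_um) /
          (.data$sc_length_um - .data$centromere_um) * 100,
        -(.data$centromere_um - .data$focus_um) / .data$centromere_um * 100),
      bin = floor(.data$rel_pos_sc / 10) * 10) |>
    mutate(bin = pmin(.data$bin, 90)) |>
    select(-"sc_length_um", -"centromere_um")
}

#' Autosomal genetic map length in centimorgans
#'
#' Mean total foci per cell multiplied by 50 map units (1 crossover = 50 cM).
#'
#' @param cells SC table; all SCs of a cell contribute.
#' @return Genetic length in cM.
#' @export
genetic_length <- function(cells) {
  if (nrow(cells) == 0L) abort("need at least one cell")
  per_cell <- cells |>
    group_by(.data$cell_id) |>
    summarise(foci = sum(lengths(.data$foci_um)), .groups = "drop")
  mean(per_cell$foci) * 50
}

# Per-cell interval table for one SC; intervals are [lo_um, hi_um).
resolve_intervals <- function(cells, sc, intervals) {
  sub <- cells |> filter(.data$sc_id == sc)
  if (nrow(sub) == 0L) abort(sprintf("no SCs with sc_id '%s'", sc))
  if (is.null(intervals)) {
    return(sub |> mutate(lo_um = 0, hi_um = Inf))
  }
  if (is.numeric(intervals) && length(intervals) == 2L) {
    return(sub |> mutate(lo_um = intervals[1], hi_um = intervals[2]))
  }
  sub |> inner_join(as_tibble(intervals), by = "cell_id")
}

#' Crossover density within a chromosomal region
#'
#' Pooled MLH1 foci per micrometre inside a region of one SC across cells:
#' total foci falling in the interval divided by total interval length.
#' Per-cell densities are retained for rank tests. Intervals are closed on
#' the left, open on the right; lengths are clipped to the SC.
#'
#' @param cells SC table.
#' @param sc `sc_id` of the bivalent to analyse.
#' @param intervals `NULL` (whole SC), a numeric `c(lo_um, hi_um)` applied to
#'   every cell, or a per-cell tibble (`cell_id`, `lo_um`, `hi_um`) as
#'   produced by [delimit_inversion()].
#' @param label Region label recorded in the result.
#' @return Object of class `synrec_density`: list with `label`,
#'   `foci_per_um`, `n_cells`, `total_foci`, `total_um` and a `per_cell`
#'   tibble (`cell_id`, `foci`, `length_um`, `density`).
#' @export
co_density <- function(cells, sc, intervals = NULL, label = "whole") {
  sub <- resolve_intervals(cells, sc, intervals)
  per_cell <- sub |>
    mutate(length_um = pmin(.data$hi_um, .data$sc_length_um) -
             pmax(.data$lo_um, 0),
           foci = purrr::pmap_int(list(.data$foci_um, .data$lo_um,
                                       .data$hi_um),
                                  function(f, lo, hi) {
                                    sum(f >= lo & f < hi)
                                  })) |>
    group_by(.data$cell_id) |>
    summarise(foci = sum(.data$foci), length_um = sum(.data$length_um),
              .groups = "drop") |>
    mutate(density = .data$foci / .data$length_um)
  total_um <- sum(per_cell$length_um)
  if (total_um <= 0) abort("total region length is zero")
  structure(list(label = label,
                 foci_per_um = sum(per_cell$foci) / total_um,
                 n_cells = nrow(per_cell),
                 total_foci = sum(per_cell$foci),
                 total_um = total_um,
                 per_cell = per_cell), class = "synrec_density")
}

#' @export
print.synrec_density <- function(x, ...) {
  cat(sprintf("CO density [%s]: %.3f MLH1 foci/um (%d foci / %.1f um, %d cells)\n",
              x$label, x$foci_per_um, x$total_foci, x$total_um, x$n_cells))
  invisible(x)
}

#' @rdname tidy.synrec_test
#' @export
tidy.synrec_density <- function(x, ...) {
  tibble(label = x$label, foci_per_um = x$foci_per_um, n_cells = x$n_cells,
         total_foci = x$total_foci, total_um = x$total_um)
}

#' Delimit an inversion on each SC from marker positions
#'
#' Returns the per-cell interval between two named markers; `"centromere"`
#' names the centromere, anything else a BAC marker id. Cells missing a
#' marker are excluded listwise and counted in the `n_excluded` attribute.
#' For a pericentric inversion the two markers are BACs on opposite arms and
#' the interval spans the centromere.
#'
#' @param cells SC table.
#' @param sc `sc_id` of the bivalent.
#' @param proximal_marker,distal_marker Marker names.
#' @return Tibble (`cell_id`, `lo_um`, `hi_um`) with attribute `n_excluded`.
#' @export
delimit_inversion <- function(cells, sc, proximal_marker, distal_marker) {
  sub <- cells |> filter(.data$sc_id == sc)
  if (nrow(sub) == 0L) abort(sprintf("no SCs with sc_id '%s'", sc))
  pos_of <- function(row_i, marker) {
    if (identical(marker, "centromere")) return(sub$centromere_um[row_i])
    bm <- sub$bac_markers[[row_i]]
    if (!is.null(bm) && marker %in% names(bm)) unname(bm[[marker]])
    else NA_real_
  }
  p <- vapply(seq_len(nrow(sub)), pos_of, numeric(1),
              marker = proximal_marker)
  d <- vapply(seq_len(nrow(sub)), pos_of, numeric(1), marker = distal_marker)
  ok <- !is.na(p) & !is.na(d)
  out <- tibble(cell_id = sub$cell_id[ok],
                lo_um = pmin(p[ok], d[ok]), hi_um = pmax(p[ok], d[ok]))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Density in a simulated inversion on a collinear chromosome
#'
#' Maps a proportional span (fractions of SC length, anchored at the same
#' relative position as an observed inversion) onto every SC of a collinear
#' bivalent and measures the crossover density there — the control for the
#' centromeric/positional effect when testing suppression inside real
#' inversions.
#'
#' @param cells SC table (collinear chromosome).
#' @param sc `sc_id` of the collinear bivalent.
#' @param proportional_span Numeric `c(lo, hi)` with `0 <= lo < hi <= 1`.
#' @return A `synrec_density`.
#' @export
simulated_inversion_control <- function(cells, sc, proportional_span) {
  if (length(proportional_span) != 2L || any(proportional_span < 0) ||
      any(proportional_span > 1) ||
      proportional_span[1] >= proportional_span[2]) {
    abort("proportional_span must be an increasing pair within [0, 1]")
  }
  sub <- cells |> filter(.data$sc_id == sc)
  if (nrow(sub) == 0L) abort(sprintf("no SCs with sc_id '%s'", sc))
  iv <- sub |>
    mutate(lo_um = proportional_span[1] * .data$sc_length_um,
           hi_um = proportional_span[2] * .data$sc_length_um) |>
    select("cell_id", "lo_um", "hi_um")
  co_density(cells, sc, iv, label = "simulated_inversion")
}

#' Pericentromeric crossover density per arm
#'
#' Density within the region extending `fraction` (default 30%) of each arm
#' from the centromere towards the telomere.
#'
#' @param cells SC table.
#' @param sc `sc_id` of the bivalent.
#' @param fraction Fraction of each arm (default 0.30).
#' @return Named list of two `synrec_density` objects: `p_arm`, `q_arm`.
#' @export
pericentromeric_density <- function(cells, sc, fraction = 0.30) {
  sub <- cells |> filter(.data$sc_id == sc)
  if (nrow(sub) == 0L) abort(sprintf("no SCs with sc_id '%s'", sc))
  p_iv <- sub |>
    mutate(lo_um = .data$centromere_um - fraction * .data$centromere_um,
           hi_um = .data$centromere_um) |>
    select("cell_id", "lo_um", "hi_um")
  q_iv <- sub |>
    mutate(lo_um = .data$centromere_um,
           hi_um = .data$centromere_um +
             fraction * (.data$sc_length_um - .data$centromere_um)) |>
    select("cell_id", "lo_um", "hi_um")
  list(p_arm = co_density(cells, sc, p_iv, label = "pericentromeric_p"),
       q_arm = co_density(cells, sc, q_iv, label = "pericentromeric_q"))
}

#' Rank test on per-cell crossover densities
#'
#' Mann-Whitney U for two groups, Kruskal-Wallis for three or more. Groups
#' are `synrec_density` objects (their per-cell densities are used) or plain
#' numeric vectors.
#'
#' @param ... Two or more groups, optionally named.
#' @param alternative Passed to [wilcox.test()] for the two-group case
#'   (default `"two.sided"`).
#' @return A `synrec_test`.
#' @export
compare_densities <- function(..., alternative = "two.sided") {
  gr <- list(...)
  gr <- gr[!vapply(gr, is.null, logical(1))]
  vals <- lapply(gr, function(g) {
    if (inherits(g, "synrec_density")) g$per_cell$density else as.numeric(g)
  })
  if (length(vals) < 2L) abort("need at least two groups")
  if (any(lengths(vals) == 0L)) abort("empty group in density comparison")
  nm <- names(gr) %||% paste0("group", seq_along(gr))
  nm[nm == ""] <- paste0("group", which(nm == ""))
  ht <- if (length(vals) == 2L) {
    suppressWarnings(wilcox.test(vals[[1]], vals[[2]],
                                 alternative = alternative))
  } else {
    kruskal.test(vals)
  }
  new_synrec_test(ht, n = lengths(vals), n_names = nm,
                  value = "foci_per_um")
}

#' Cumulative crossover distribution along one SC
#'
#' Cumulative frequency of focus positions in signed 10% bins of SC length
#' (position 0 = centromere, p-arm negative), restricted to SCs carrying
#' exactly `co_class` foci (`"2"`, `"3"`) or to all SCs (`"all"`).
#'
#' @param cells SC table.
#' @param sc `sc_id` of the bivalent.
#' @param co_class `"all"`, `2` or `3`.
#' @return Tibble of class `synrec_recmap`: `bin` (lower edge, %),
#'   `frequency`, `cumulative`; attributes `sc`, `co_class`, `n_sc`,
#'   `n_foci`, `flagged` (TRUE when no qualifying SCs).
#' @export
cumulative_distribution <- function(cells, sc, co_class = "all") {
  co_class <- as.character(co_class)
  sub <- cells |> filter(.data$sc_id == sc)
  if (co_class != "all") {
    sub <- sub |> filter(lengths(.data$foci_um) == as.integer(co_class))
  }
  bins <- seq(-100, 90, by = 10)
  if (nrow(sub) == 0L) {
    out <- tibble(bin = bins, frequency = 0, cumulative = 0)
    return(structure(out, class = c("synrec_recmap", class(out)),
                     sc = sc, co_class = co_class, n_sc = 0L, n_foci = 0L,
                     flagged = TRUE))
  }
  rel <- relative_positions(sub)
  counts <- table(factor(rel$bin, levels = bins))
  freq <- as.numeric(counts) / max(1L, nrow(rel))
  out <- tibble(bin = bins, frequency = freq, cumulative = cumsum(freq))
  structure(out, class = c("synrec_recmap", class(out)),
            sc = sc, co_class = co_class, n_sc = nrow(sub),
            n_foci = nrow(rel), flagged = FALSE)
}

#' Table-style summary of one bivalent's recombination features
#'
#' N (cells), mean SC length, mean foci per SC, pooled foci/um for the whole
#' SC and optionally inside/outside a marker-delimited region.
#'
#' @param cells SC table.
#' @param sc `sc_id`.
#' @param inversion Optional per-cell interval tibble (see
#'   [delimit_inversion()]).
#' @return One-row tibble.
#' @export
recombination_summary <- function(cells, sc, inversion = NULL) {
  sub <- cells |> filter(.data$sc_id == sc)
  whole <- co_density(cells, sc)
  base <- tibble(sc_id = sc, n_cells = nrow(sub),
                 mean_sc_um = mean(sub$sc_length_um),
                 foci_per_sc = mean(lengths(sub$foci_um)),
                 foci_per_um = whole$foci_per_um)
  if (is.null(inversion)) return(base)
  inside <- co_density(cells, sc, inversion, label = "inside_inv")
  out_iv <- anti_intervals(sub, inversion)
  outside <- co_density(cells, sc, out_iv, label = "outside_inv")
  base |> mutate(inside_inv = inside$foci_per_um,
                 outside_inv = outside$foci_per_um)
}

# Complement of per-cell intervals within each SC, as a two-piece interval
# list flattened to per-cell rows (one row per complement piece).
anti_intervals <- function(sub, intervals) {
  iv <- as_tibble(intervals)
  sub |> inner_join(iv, by = "cell_id") |>
    mutate(lo1 = 0, hi1 = pmax(0, .data$lo_um),
           lo2 = pmin(.data$hi_um, .data$sc_length_um),
           hi2 = .data$sc_length_um + 1e-9) |>
    select("cell_id", "lo1", "hi1", "lo2", "hi2") |>
    tidyr::pivot_longer(-"cell_id", names_to = c(".value", "piece"),
                        names_pattern = "(lo|hi)(\\d)") |>
    filter(.data$hi > .data$lo) |>
    select("cell_id", lo_um = "lo", hi_um = "hi")
}
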