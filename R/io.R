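# Readers and writers for the plain-text interchange formats. All genomic
# coordinates are 0-based half-open on disk (BED semantics); human-readable
# report tables are converted to 1-based inclusive in one place
# (`to_report_coords()`).

#' Write / read an ortholog table (TSV)
#'
#' Columns: gene_id, ref_chrom, ref_start, ref_end, ref_strand, tgt_chrom,
#' tgt_start, tgt_end, tgt_strand. Coordinates 0-based half-open.
#'
#' @param orthologs Ortholog tibble.
#' @param path File path.
#' @return `read_ortholog_tsv` returns the tibble; the writer returns `path`
#'   invisibly.
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  cols <- c("gene_id", "ref_chrom", "ref_start", "ref_end", "ref_strand",
            "tgt_chrom", "tgt_start", "tgt_end", "tgt_strand")
  stopifnot_cols(orthologs, cols, "ortholog table")
  readr::write_tsv(orthologs[, cols], path)
  invisible(path)
}

#' @rdname write_ortholog_tsv
#' @export
read_ortholog_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", ref_chrom = "c", ref_start = "d",
                           ref_end = "d", ref_strand = "c", tgt_chrom = "c",
                           tgt_start = "d", tgt_end = "d", tgt_strand = "c"))
  bad <- which(!is.na(out$ref_start) & !is.na(out$ref_end) &
                 out$ref_start >= out$ref_end)
  if (length(bad)) {
    abort(sprintf("malformed ortholog row(s) (start >= end): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  out
}

#' Write / read BED intervals
#'
#' BED6 when `name`/`score`/`strand` columns are present, BED3 otherwise.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path File path.
#' @return Reader returns a tibble; writer returns `path` invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot_cols(intervals, c("chrom", "start", "end"), "intervals")
  df <- as_tibble(intervals)
  out <- tibble(chrom = df$chrom, start = format(df$start, scientific = FALSE,
                                                 trim = TRUE),
                end = format(df$end, scientific = FALSE, trim = TRUE))
  if (all(c("name") %in% names(df))) {
    out$name <- df$name
    out$score <- if ("score" %in% names(df)) df$score else 0
    out$strand <- if ("strand" %in% names(df)) df$strand else "."
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  out <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(out)[1:3] <- c("chrom", "start", "end")
  if (ncol(out) >= 6L) names(out)[4:6] <- c("name", "score", "strand")
  if (any(out$start > out$end)) {
    abort(sprintf("malformed BED row(s): %s",
                  paste(head(which(out$start > out$end), 5), collapse = ", ")))
  }
  out
}

#' Write / read genome sequences as FASTA
#'
#' Thin wrappers over Biostrings; sequences are exchanged as named character
#' vectors.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return Reader returns a named character vector; writer returns `path`
#'   invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA IO")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA IO")
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read synaptonemal-complex measurements (CSV)
#'
#' One row per SC per cell; focus positions and BAC markers are
#' semicolon-separated within a cell (`marker:pos` pairs for BACs).
#'
#' @param cells SC tibble as from [simulate_meiotic_cells()].
#' @param path File path.
#' @return Reader returns the SC tibble (list-columns restored); writer
#'   returns `path` invisibly.
#' @export
write_foci_csv <- function(cells, path) {
  flat <- cells |>
    mutate(focus_positions = purrr::map_chr(.data$foci_um, function(f) {
      paste(format(f, digits = 10, trim = TRUE), collapse = ";")
    }),
    bac = purrr::map_chr(.data$bac_markers, function(b) {
      if (is.null(b) || length(b) == 0L) return("")
      paste(sprintf("%s:%s", names(b), format(unname(b), digits = 10,
                                              trim = TRUE)),
            collapse = ";")
    })) |>
    select("cell_id", "sc_id", "sc_length_um", "centromere_um",
           "focus_positions", bac_markers = "bac")
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_foci_csv
#' @export
read_foci_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            cell_id = "i", sc_id = "c", sc_length_um = "d",
                            centromere_um = "d", focus_positions = "c",
                            bac_markers = "c"))
  out <- flat |>
    mutate(
      foci_um = purrr::map(.data$focus_positions, function(s) {
        if (is.na(s) || s == "") numeric() else as.numeric(strsplit(s, ";")[[1]])
      }),
      bac_markers = purrr::map(.data$bac_markers, function(s) {
        if (is.na(s) || s == "") return(setNames(numeric(), character()))
        parts <- strsplit(strsplit(s, ";")[[1]], ":")
        setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                 vapply(parts, `[[`, character(1), 1))
      })) |>
    select("cell_id", "sc_id", "sc_length_um", "centromere_um", "foci_um",
           "bac_markers")
  bad <- which(vapply(out$foci_um, function(f) any(is.na(f)), logical(1)))
  if (length(bad)) {
    abort(sprintf("malformed focus positions in row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  class(out) <- c("synrec_cells", class(out))
  out
}

#' Write / read gene-term annotations (TSV)
#'
#' @param annotations Tibble `gene_id`, `term_id`.
#' @param path File path.
#' @return Reader returns the tibble; writer returns `path` invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  stopifnot_cols(annotations, c("gene_id", "term_id"), "annotations")
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", term_id = "c"))
}

#' Convert half-open 0-based intervals to 1-based inclusive report form
#'
#' @param df Tibble with `start`/`end` columns.
#' @return The tibble with `start` incremented (end unchanged), for
#'   human-readable reports only.
#' @export
to_report_coords <- function(df) {
  mutate(df, start = .data$start + 1)
}
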