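#' Tile chromosomes into non-overlapping windows and count features
#'
#' Splits each chromosome into `window_bp` windows (the last window may be
#' shorter and is retained), then accumulates per window the base pairs
#' covered by tandem repeats (clipped to the window, so a repeat spanning a
#' boundary contributes to both windows) and the number of genes
#' intersecting the window (any-overlap presence/absence, so a gene spanning
#' a boundary is counted in both windows).
#'
#' @param assembly List with `chrom_lengths` (named numeric), or a named
#'   numeric vector of chromosome lengths.
#' @param trs Tandem-repeat intervals (`chrom`, `start`, `end`); may be
#'   empty/NULL.
#' @param genes Gene intervals (`chrom`, `start`, `end`); may be empty/NULL.
#' @param window_bp Window width (default 100 Kbp).
#' @return Tibble: `chrom`, `start`, `end`, `tr_bp`, `tr_bp_norm` (tr_bp
#'   rescaled to a full window for the trailing short window), `gene_count`.
#' @export
window_scan <- function(assembly, trs = NULL, genes = NULL,
                        window_bp = 100e3) {
  lens <- if (is.list(assembly)) assembly$chrom_lengths else assembly
  trs <- if (is.null(trs)) tibble(chrom = character(), start = numeric(),
                                  end = numeric()) else as_tibble(trs)
  genes <- if (is.null(genes)) tibble(chrom = character(), start = numeric(),
                                      end = numeric()) else as_tibble(genes)
  purrr::map_dfr(names(lens), function(ch) {
    L <- lens[[ch]]
    starts <- seq(0, by = window_bp, length.out = ceiling(L / window_bp))
    w <- tibble(chrom = ch, start = starts,
                end = pmin(starts + window_bp, L))
    nw <- nrow(w)
    tr_bp <- numeric(nw); gc <- integer(nw)
    tsub <- trs |> filter(.data$chrom == ch)
    for (i in seq_len(nrow(tsub))) {
      i0 <- max(1L, tsub$start[i] %/% window_bp + 1L)
      i1 <- min(nw, (tsub$end[i] - 1) %/% window_bp + 1L)
      for (j in i0:i1) {
        tr_bp[j] <- tr_bp[j] + overlap_bp(tsub$start[i], tsub$end[i],
                                          w$start[j], w$end[j])
      }
    }
    gsub <- genes |> filter(.data$chrom == ch)
    for (i in seq_len(nrow(gsub))) {
      i0 <- max(1L, gsub$start[i] %/% window_bp + 1L)
      i1 <- min(nw, (gsub$end[i] - 1) %/% window_bp + 1L)
      gc[i0:i1] <- gc[i0:i1] + 1L
    }
    w |> mutate(tr_bp = tr_bp,
                tr_bp_norm = tr_bp * window_bp / (.data$end - .data$start),
                gene_count = gc)
  })
}

#' Label windows by genomic region class
#'
#' Assigns each window one label by any-overlap with precedence
#' telomere > centromere > EBR > HSB. Windows overlapping none of the
#' feature sets get label `NA` and are excluded from group comparisons.
#'
#' @param windows Output of [window_scan()].
#' @param masks Output of [build_region_masks()].
#' @param hsbs HSB table (columns `ref_chrom`/`ref_start`/`ref_end` or
#'   `chrom`/`start`/`end`).
#' @param ebrs EBR tibble (`chrom`, `start`, `end`), typically the retained
#'   set.
#' @return `windows` with a `label` column.
#' @export
label_windows <- function(windows, masks, hsbs, ebrs) {
  as_iv <- function(x) {
    if (is.null(x) || nrow(x) == 0L) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    if ("ref_chrom" %in% names(x)) {
      x <- x |> select(chrom = "ref_chrom", start = "ref_start",
                       end = "ref_end")
    }
    select(as_tibble(x), "chrom", "start", "end")
  }
  telo <- as_iv(filter(masks, .data$label == "telomeric"))
  cen <- as_iv(filter(masks, .data$label == "centromeric"))
  hi <- as_iv(hsbs); ei <- as_iv(ebrs)
  windows |>
    mutate(
      label = dplyr::case_when(
        interval_hits_any(.data$chrom, .data$start, .data$end, telo) ~
          "telomere",
        interval_hits_any(.data$chrom, .data$start, .data$end, cen) ~
          "centromere",
        interval_hits_any(.data$chrom, .data$start, .data$end, ei) ~ "EBR",
        interval_hits_any(.data$chrom, .data$start, .data$end, hi) ~ "HSB",
        TRUE ~ NA_character_))
}

#' Nonparametric comparison of window statistics between region classes
#'
#' Mann-Whitney U (two groups) or Kruskal-Wallis (more than two) on a window
#' statistic across region labels.
#'
#' @param windows Labelled window tibble.
#' @param value Column to compare: `"tr_bp"`, `"tr_bp_norm"` or
#'   `"gene_count"`.
#' @param groups Character vector of labels to compare (>= 2); defaults to
#'   all non-NA labels present.
#' @return Object of class `synrec_test` with `method`, `statistic`,
#'   `p.value` and per-group `n`; see [tidy()].
#' @export
compare_window_groups <- function(windows,
                                  value = c("tr_bp", "tr_bp_norm",
                                            "gene_count"),
                                  groups = NULL) {
  value <- match.arg(value)
  stopifnot_cols(windows, c("label", value), "windows")
  if (is.null(groups)) {
    groups <- sort(unique(windows$label[!is.na(windows$label)]))
  }
  if (length(groups) < 2L) abort("need at least two groups to compare")
  dat <- windows |> filter(.data$label %in% groups)
  n_by <- table(factor(dat$label, levels = groups))
  if (any(n_by == 0L)) {
    abort(sprintf("group(s) with zero windows: %s",
                  paste(names(n_by)[n_by == 0L], collapse = ", ")))
  }
  v <- dat[[value]]
  g <- factor(dat$label, levels = groups)
  ht <- if (length(groups) == 2L) {
    suppressWarnings(wilcox.test(v ~ g))
  } else {
    kruskal.test(v ~ g)
  }
  new_synrec_test(ht, n = as.integer(n_by), n_names = groups,
                  value = value)
}

new_synrec_test <- function(ht, n, n_names, value) {
  structure(list(method = ht$method,
                 statistic = unname(ht$statistic),
                 statistic_name = names(ht$statistic),
                 p.value = ht$p.value,
                 n = setNames(n, n_names),
                 value = value), class = "synrec_test")
}

#' @export
print.synrec_test <- function(x, ...) {
  cat(x$method, "on", x$value, "\n")
  cat("  n:", paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  cat(sprintf("  %s = %.4g, p = %.4g\n", x$statistic_name, x$statistic,
              x$p.value))
  invisible(x)
}

#' Tidy a synrec comparison test
#' @param x A `synrec_test`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `p.value`, `value`,
#'   `n_total`.
#' @export
tidy.synrec_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p.value = x$p.value,
         value = x$value, n_total = sum(x$n))
}

#' Glance at a synrec comparison test
#' @inheritParams tidy.synrec_test
#' @return One-row tibble with per-group sizes and the p-value.
#' @export
glance.synrec_test <- function(x, ...) {
  bind_cols(as_tibble(as.list(setNames(as.integer(x$n),
                                       paste0("n_", names(x$n))))),
            tibble(statistic = x$statistic, p.value = x$p.value))
}

#' Mean gene density of a region class
#'
#' Arithmetic mean of per-window gene counts over windows carrying `label`,
#' i.e. genes per window (genes per 100 Kbp at the default window size).
#'
#' @param windows Labelled window tibble.
#' @param label Region label (`"EBR"`, `"HSB"`, ...).
#' @return Numeric scalar.
#' @export
mean_gene_density <- function(windows, label) {
  sel <- windows$gene_count[!is.na(windows$label) & windows$label == label]
  if (length(sel) == 0L) {
    abort(sprintf("no windows labelled '%s'", label))
  }
  mean(sel)
}
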