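#' Configuration for the synthetic genome-pair generator
#'
#' Bundles every knob of [simulate_genome_pair()]. The generator builds an
#' "ancestral" genome A (chromosome lengths, a centromeric N-run per
#' chromosome, a gene complement), applies a script of rearrangement events to
#' derive genome B, and emits the ortholog table plus the ground-truth
#' breakpoint regions the events imply in both genomes' coordinates.
#'
#' @param n_chromosomes Number of chromosomes in genome A.
#' @param chrom_length_bp Chromosome length(s) in bp; recycled to
#'   `n_chromosomes`.
#' @param n_genes Total number of genes placed on genome A.
#' @param gene_spacing_model `"uniform"` or `"clustered"` placement of gene
#'   starts.
#' @param rearrangements Event table built with [rearrangement()] /
#'   [bind_rows()]; may be empty (collinear genomes).
#' @param tr_rate_by_region Named numeric: expected tandem-repeat bp per
#'   100-Kbp window for the labels `telomere`, `centromere`, `HSB`, `EBR`.
#'   Used by [simulate_window_landscape()] and sequence planting.
#' @param gene_rate_by_region Named numeric: expected genes per 100-Kbp window
#'   by label (defaults follow densities typical of breakpoint-rich vs
#'   conserved primate regions: 1.48 vs 0.73 genes/100 Kbp).
#' @param centromere_rel_pos Relative position of the centromeric N-run.
#' @param centromere_n_bp Length of the centromeric N-run (default 500 Kbp).
#' @param gene_length_bp Range (min, max) of simulated gene lengths.
#' @param genes Optional explicit gene table (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`) overriding random placement; coordinates 0-based
#'   half-open.
#' @param seed Integer seed; identical seed + config gives identical output.
#' @return A list of class `synrec_genome_config`.
#' @export
genome_config <- function(n_chromosomes = 2,
                          chrom_length_bp = 30e6,
                          n_genes = 400,
                          gene_spacing_model = c("uniform", "clustered"),
                          rearrangements = NULL,
                          tr_rate_by_region = c(telomere = 5000,
                                                centromere = 6000,
                                                HSB = 1500, EBR = 1600),
                          gene_rate_by_region = c(telomere = 0.9,
                                                  centromere = 0.4,
                                                  HSB = 0.73, EBR = 1.48),
                          centromere_rel_pos = 0.4,
                          centromere_n_bp = 500e3,
                          gene_length_bp = c(2e3, 10e3),
                          genes = NULL,
                          seed = 1L) {
  gene_spacing_model <- match.arg(gene_spacing_model)
  lens <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  if (any(lens <= 0)) abort("all chromosome lengths must be > 0")
  if (n_genes <= 0 && is.null(genes)) abort("n_genes must be > 0")
  if (centromere_rel_pos <= 0 || centromere_rel_pos >= 1) {
    abort("centromere_rel_pos must lie in (0, 1)")
  }
  if (is.null(rearrangements)) rearrangements <- rearrangement()[0, ]
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = lens,
                 n_genes = as.integer(n_genes),
                 gene_spacing_model = gene_spacing_model,
                 rearrangements = as_tibble(rearrangements),
                 tr_rate_by_region = tr_rate_by_region,
                 gene_rate_by_region = gene_rate_by_region,
                 centromere_rel_pos = centromere_rel_pos,
                 centromere_n_bp = centromere_n_bp,
                 gene_length_bp = gene_length_bp,
                 genes = genes,
                 seed = as.integer(seed)),
            class = "synrec_genome_config")
}

#' Describe one rearrangement event
#'
#' Intervals are 0-based half-open bp ranges on the *ancestral* genome A.
#' Supported kinds: `inversion` (reverse a segment in place), `indel`
#' (delete `[start, end)` from genome B), `fission` (split `chrom` at
#' `start`), `fusion` (append `chrom2` after `chrom`), `translocation`
#' (move `[start, end)` from `chrom` to position `pos` on `chrom2`;
#' `pos = NA` appends at the end).
#'
#' @param kind Event type.
#' @param chrom,chrom2 Chromosome identifiers.
#' @param start,end Interval bounds (bp) where applicable.
#' @param pos Insertion point for translocations.
#' @return One-row tibble (or an empty prototype when called with no
#'   arguments).
#' @export
rearrangement <- function(kind = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          chrom2 = NA_character_, pos = NA_real_) {
  if (length(kind) == 0L) {
    return(tibble(kind = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  chrom2 = character(), pos = numeric()))
  }
  kind <- match.arg(kind, c("inversion", "indel", "fission", "fusion",
                            "translocation"))
  tibble(kind = kind, chrom = as.character(chrom),
         start = as.numeric(start)[1] %||% NA_real_,
         end = as.numeric(end)[1] %||% NA_real_,
         chrom2 = as.character(chrom2), pos = as.numeric(pos))
}

validate_events <- function(events, chrom_lengths) {
  if (nrow(events) == 0L) return(invisible(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$chrom %in% names(chrom_lengths)) {
      abort(sprintf("event %d references unknown chromosome '%s'", i, ev$chrom))
    }
    L <- chrom_lengths[[ev$chrom]]
    if (ev$kind %in% c("inversion", "indel", "translocation")) {
      if (is.na(ev$start) || is.na(ev$end) || ev$start >= ev$end) {
        abort(sprintf("event %d (%s) needs a non-empty interval", i, ev$kind))
      }
      if (ev$start < 0 || ev$end > L) {
        abort(sprintf("event %d (%s) lies outside chromosome '%s'",
                      i, ev$kind, ev$chrom))
      }
    }
    if (ev$kind == "fission" &&
        (is.na(ev$start) || ev$start <= 0 || ev$start >= L)) {
      abort(sprintf("event %d (fission) point must be interior to '%s'",
                    i, ev$chrom))
    }
    if (ev$kind %in% c("fusion", "translocation") &&
        (is.na(ev$chrom2) || !ev$chrom2 %in% names(chrom_lengths))) {
      abort(sprintf("event %d (%s) references unknown chrom2", i, ev$kind))
    }
  }
  iv <- events |> filter(.data$kind %in% c("inversion", "indel",
                                           "translocation"))
  if (nrow(iv) > 1L) {
    for (i in seq_len(nrow(iv) - 1L)) for (j in seq(i + 1L, nrow(iv))) {
      if (iv$chrom[i] == iv$chrom[j] &&
          overlaps(iv$start[i], iv$end[i], iv$start[j], iv$end[j])) {
        abort(sprintf(
          "overlapping events on %s: [%g,%g) and [%g,%g) — not supported",
          iv$chrom[i], iv$start[i], iv$end[i], iv$start[j], iv$end[j]))
      }
    }
  }
  invisible(events)
}

# ---- segment-list genome model ----------------------------------------------
# Genome B is held as a named list of tibbles; each tibble is the ordered,
# oriented list of ancestral segments making up one derived chromosome.

new_segments <- function(chrom_lengths) {
  lapply(setNames(names(chrom_lengths), names(chrom_lengths)), function(ch) {
    tibble(src_chrom = ch, src_start = 0, src_end = chrom_lengths[[ch]],
           orient = 1L)
  })
}

# Split the segment containing ancestral position `pos` of `src_chrom`
# (across all derived chromosomes) so that `pos` becomes a boundary.
split_at <- function(segs, src_chrom, pos) {
  for (bc in names(segs)) {
    s <- segs[[bc]]
    hit <- which(s$src_chrom == src_chrom & s$src_start < pos &
                   pos < s$src_end)
    if (length(hit)) {
      i <- hit[1]
      a <- s[i, ]; b <- s[i, ]
      a$src_end <- pos; b$src_start <- pos
      pieces <- if (s$orient[i] == 1L) bind_rows(a, b) else bind_rows(b, a)
      segs[[bc]] <- bind_rows(s[seq_len(i - 1L), ], pieces,
                              s[seq(i + 1L, length.out = nrow(s) - i), ])
    }
  }
  segs
}

# Indices (within derived chromosome `bc`) of segments fully inside the
# ancestral interval [start, end) of src_chrom.
inside_idx <- function(segs, src_chrom, start, end) {
  for (bc in names(segs)) {
    s <- segs[[bc]]
    idx <- which(s$src_chrom == src_chrom & s$src_start >= start &
                   s$src_end <= end)
    if (length(idx)) {
      if (any(diff(idx) != 1L)) {
        abort("rearranged interval is no longer contiguous in the derived genome")
      }
      return(list(bc = bc, idx = idx))
    }
  }
  abort(sprintf("interval [%g,%g) of %s not found in derived genome",
                start, end, src_chrom))
}

apply_event <- function(segs, ev) {
  switch(ev$kind,
    inversion = {
      segs <- split_at(segs, ev$chrom, ev$start)
      segs <- split_at(segs, ev$chrom, ev$end)
      loc <- inside_idx(segs, ev$chrom, ev$start, ev$end)
      s <- segs[[loc$bc]]
      inv <- s[rev(loc$idx), ]
      inv$orient <- -inv$orient
      s[loc$idx, ] <- inv
      segs[[loc$bc]] <- s
      segs
    },
    indel = {
      segs <- split_at(segs, ev$chrom, ev$start)
      segs <- split_at(segs, ev$chrom, ev$end)
      loc <- inside_idx(segs, ev$chrom, ev$start, ev$end)
      segs[[loc$bc]] <- segs[[loc$bc]][-loc$idx, ]
      segs
    },
    fission = {
      segs <- split_at(segs, ev$chrom, ev$start)
      bc <- NULL
      for (cand in names(segs)) {
        s <- segs[[cand]]
        k <- which(s$src_chrom == ev$chrom &
                     (s$src_start == ev$start | s$src_end == ev$start))
        if (length(k)) { bc <- cand; break }
      }
      if (is.null(bc)) abort("fission point not found in derived genome")
      s <- segs[[bc]]
      cut <- which(s$src_chrom == ev$chrom & ((s$orient == 1L &
               s$src_start == ev$start) | (s$orient == -1L &
               s$src_end == ev$start)))[1]
      new_name <- paste0(bc, "_fis")
      segs[[bc]] <- s[seq_len(cut - 1L), ]
      segs[[new_name]] <- s[seq(cut, nrow(s)), ]
      segs
    },
    fusion = {
      bc1 <- find_home(segs, ev$chrom); bc2 <- find_home(segs, ev$chrom2)
      if (bc1 == bc2) abort("fusion partners already share a derived chromosome")
      segs[[bc1]] <- bind_rows(segs[[bc1]], segs[[bc2]])
      segs[[bc2]] <- NULL
      segs
    },
    translocation = {
      segs <- split_at(segs, ev$chrom, ev$start)
      segs <- split_at(segs, ev$chrom, ev$end)
      loc <- inside_idx(segs, ev$chrom, ev$start, ev$end)
      moved <- segs[[loc$bc]][loc$idx, ]
      segs[[loc$bc]] <- segs[[loc$bc]][-loc$idx, ]
      dest <- find_home(segs, ev$chrom2)
      if (is.na(ev$pos)) {
        segs[[dest]] <- bind_rows(segs[[dest]], moved)
      } else {
        segs <- split_at(segs, ev$chrom2, ev$pos)
        s <- segs[[dest]]
        at <- which(s$src_chrom == ev$chrom2 & ((s$orient == 1L &
                 s$src_start >= ev$pos) | (s$orient == -1L &
                 s$src_end <= ev$pos)))[1]
        if (is.na(at)) at <- nrow(s) + 1L
        segs[[dest]] <- bind_rows(s[seq_len(at - 1L), ], moved,
                                  s[seq(at, length.out = nrow(s) - at + 1L), ])
      }
      segs
    },
    abort(sprintf("unknown event kind '%s'", ev$kind)))
}

# Derived chromosome whose first segment originates from ancestral `chrom`.
find_home <- function(segs, chrom) {
  for (bc in names(segs)) {
    if (any(segs[[bc]]$src_chrom == chrom)) return(bc)
  }
  abort(sprintf("chromosome '%s' not found in derived genome", chrom))
}

# Flatten the segment lists into one tibble with derived (b_) offsets.
layout_segments <- function(segs) {
  purrr::imap_dfr(segs, function(s, bc) {
    if (nrow(s) == 0L) return(tibble())
    len <- s$src_end - s$src_start
    s |>
      mutate(tgt_chrom = bc,
             tgt_start = cumsum(dplyr::lag(len, default = 0)),
             tgt_end = .data$tgt_start + len)
  })
}

# Map features (chrom/start/end/strand in A coords) through the layout.
# Features cut by a breakpoint or deleted map to NA.
map_features <- function(feat, lay) {
  if (nrow(feat) == 0L) {
    return(mutate(feat, tgt_chrom = character(), tgt_start = numeric(),
                  tgt_end = numeric(), tgt_strand = character()))
  }
  res <- purrr::pmap_dfr(feat, function(chrom, start, end, strand, ...) {
    seg <- lay |> filter(.data$src_chrom == chrom, .data$src_start <= start,
                         end <= .data$src_end)
    if (nrow(seg) == 0L) {
      return(tibble(tgt_chrom = NA_character_, tgt_start = NA_real_,
                    tgt_end = NA_real_, tgt_strand = NA_character_))
    }
    seg <- seg[1, ]
    if (seg$orient == 1L) {
      tibble(tgt_chrom = seg$tgt_chrom,
             tgt_start = seg$tgt_start + (start - seg$src_start),
             tgt_end = seg$tgt_start + (end - seg$src_start),
             tgt_strand = strand)
    } else {
      tibble(tgt_chrom = seg$tgt_chrom,
             tgt_start = seg$tgt_start + (seg$src_end - end),
             tgt_end = seg$tgt_start + (seg$src_end - start),
             tgt_strand = if_else(strand == "+", "-", "+"))
    }
  })
  bind_cols(feat, res)
}

place_genes <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    lens <- config$chrom_length_bp
    chroms <- paste0("chrA", seq_along(lens))
    names(lens) <- chroms
    per <- pmax(1L, round(config$n_genes * lens / sum(lens)))
    glen <- config$gene_length_bp
    purrr::map_dfr(seq_along(chroms), function(ci) {
      n <- per[ci]; L <- lens[ci]
      starts <- if (config$gene_spacing_model == "uniform") {
        sort(runif(n, 0, L - glen[2]))
      } else {
        centers <- runif(max(2L, ceiling(n / 20)), 0, L - glen[2])
        s <- rnorm(n, sample(centers, n, replace = TRUE), L / 50)
        sort(pmin(pmax(s, 0), L - glen[2]))
      }
      lengths <- runif(n, glen[1], glen[2])
      tb <- tibble(chrom = chroms[ci], start = starts,
                   end = starts + lengths,
                   strand = sample(c("+", "-"), n, replace = TRUE))
      # drop overlapping neighbours so each gene is a clean interval
      keep <- c(TRUE, tb$start[-1] >= cummax(tb$end)[-n])
      tb[keep, ]
    }) |>
      mutate(gene_id = sprintf("g%05d", row_number())) |>
      select("gene_id", "chrom", "start", "end", "strand")
  })
}

#' Simulate a rearranged genome pair with known breakpoints
#'
#' Builds genome A from `config`, derives genome B by applying the
#' rearrangement script, and returns both assemblies, the ortholog table
#' (genes lost to deletions or cut by a breakpoint carry NA target
#' coordinates), and the ground-truth evolutionary breakpoint regions in both
#' genomes' coordinates. Truth EBRs span the gap between the innermost
#' orthologous markers flanking each applied breakpoint, mirroring the
#' marker resolution of gene-order detection.
#'
#' @param config A [genome_config()].
#' @return List of class `synrec_comparison` with elements `assembly_ref`,
#'   `assembly_tgt` (each: `chrom_lengths`, `n_runs`, `genes`), `orthologs`,
#'   `truth_ebrs`, `truth_events`.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "synrec_genome_config"))
  lens <- config$chrom_length_bp
  chroms <- paste0("chrA", seq_along(lens))
  names(lens) <- chroms

  genes <- if (!is.null(config$genes)) {
    as_tibble(config$genes) |>
      stopifnot_cols(c("gene_id", "chrom", "start", "end", "strand"), "genes")
  } else {
    place_genes(config)
  }
  events <- config$rearrangements
  validate_events(events, lens)

  n_runs <- tibble(
    chrom = chroms,
    start = round(lens * config$centromere_rel_pos),
    end = round(lens * config$centromere_rel_pos) + config$centromere_n_bp)
  n_runs$end <- pmin(n_runs$end, lens)

  segs <- new_segments(lens)
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) segs <- apply_event(segs, events[i, ])
  }
  segs <- segs[vapply(segs, nrow, 1L) > 0L]
  lay <- layout_segments(segs)

  orth <- map_features(genes, lay) |>
    rename(ref_chrom = "chrom", ref_start = "start", ref_end = "end",
           ref_strand = "strand")
  n_runs_b <- map_features(mutate(n_runs, strand = "+"), lay) |>
    filter(!is.na(.data$tgt_chrom)) |>
    select(chrom = "tgt_chrom", start = "tgt_start", end = "tgt_end")

  tgt_lens <- lay |> group_by(.data$tgt_chrom) |>
    summarise(len = max(.data$tgt_end), .groups = "drop")
  tgt_lengths <- setNames(tgt_lens$len, tgt_lens$tgt_chrom)

  genes_b <- orth |>
    filter(!is.na(.data$tgt_chrom)) |>
    select("gene_id", chrom = "tgt_chrom", start = "tgt_start",
           end = "tgt_end", strand = "tgt_strand")

  truth <- truth_ebrs(events, segs, lay, orth, lens, tgt_lengths)

  structure(list(
    assembly_ref = list(chrom_lengths = lens, n_runs = n_runs, genes = genes),
    assembly_tgt = list(chrom_lengths = tgt_lengths, n_runs = n_runs_b,
                        genes = genes_b),
    orthologs = orth,
    truth_ebrs = truth,
    truth_events = events,
    segments = lay,
    config = config), class = "synrec_comparison")
}

# Ground-truth EBRs: for every ancestral breakpoint, the interval between the
# innermost flanking orthologs retained in both genomes; and for every
# non-ancestral segment junction in B, the analogous interval in B coords.
truth_ebrs <- function(events, segs, lay, orth, ref_lens, tgt_lens) {
  retained <- orth |> filter(!is.na(.data$tgt_chrom))
  out <- list()
  if (nrow(events) > 0L) {
    bps <- purrr::pmap_dfr(events, function(kind, chrom, start, end, ...) {
      switch(kind,
        inversion = ,
        translocation = tibble(chrom = chrom, lo = c(start, end),
                               hi = c(start, end)),
        indel = tibble(chrom = chrom, lo = start, hi = end),
        fission = tibble(chrom = chrom, lo = start, hi = start),
        fusion = tibble(chrom = character(), lo = numeric(), hi = numeric()))
    })
    if (nrow(bps) > 0L) {
      out$ref <- purrr::pmap_dfr(bps, function(chrom, lo, hi) {
        g <- retained |> filter(.data$ref_chrom == chrom)
        left <- suppressWarnings(max(g$ref_end[g$ref_end <= lo]))
        right <- suppressWarnings(min(g$ref_start[g$ref_start >= hi]))
        tibble(genome = "ref", chrom = chrom,
               start = if (is.finite(left)) left else 0,
               end = if (is.finite(right)) right else ref_lens[[chrom]])
      })
    }
  }
  # junctions in B between segments that are not ancestrally adjacent
  juncs <- lay |>
    group_by(.data$tgt_chrom) |>
    arrange(.data$tgt_start, .by_group = TRUE) |>
    mutate(adj = .data$src_chrom == lag(.data$src_chrom) &
             .data$orient == lag(.data$orient) &
             ((.data$orient == 1L & .data$src_start == lag(.data$src_end)) |
              (.data$orient == -1L & .data$src_end == lag(.data$src_start)))) |>
    filter(!is.na(.data$adj), !.data$adj) |>
    ungroup() |>
    select(chrom = "tgt_chrom", pos = "tgt_start")
  if (nrow(juncs) > 0L) {
    out$tgt <- purrr::pmap_dfr(juncs, function(chrom, pos) {
      g <- retained |> filter(.data$tgt_chrom == chrom)
      left <- suppressWarnings(max(g$tgt_end[g$tgt_end <= pos]))
      right <- suppressWarnings(min(g$tgt_start[g$tgt_start >= pos]))
      tibble(genome = "tgt", chrom = chrom,
             start = if (is.finite(left)) left else 0,
             end = if (is.finite(right)) right else tgt_lens[[chrom]])
    })
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(genome = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  distinct(res)
}

#' Simulate 100-Kbp window landscapes by region label
#'
#' Draws tandem-repeat bp (negative binomial, mildly overdispersed, clipped to
#' the window) and gene counts (Poisson) per non-overlapping window, at
#' label-specific expected rates. This is the window-level counterpart of the
#' genome generator, used for the statistical comparisons of window groups.
#'
#' @param n_windows Named integer: windows to draw per label.
#' @param tr_rate,gene_rate Named numerics (per 100-Kbp window) as in
#'   [genome_config()].
#' @param window_bp Window width in bp.
#' @param dispersion Negative-binomial size parameter for tr_bp.
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `label`, `tr_bp`,
#'   `gene_count`.
#' @export
simulate_window_landscape <- function(n_windows = c(telomere = 200,
                                                    centromere = 200,
                                                    HSB = 1000, EBR = 1000),
                                      tr_rate = c(telomere = 5000,
                                                  centromere = 6000,
                                                  HSB = 1500, EBR = 1600),
                                      gene_rate = c(telomere = 0.9,
                                                    centromere = 0.4,
                                                    HSB = 0.73, EBR = 1.48),
                                      window_bp = 100e3,
                                      dispersion = 5,
                                      seed = 1L) {
  with_seed(derive_seed(seed, 7L), {
    purrr::imap_dfr(n_windows, function(n, lab) {
      tibble(chrom = "sim",
             start = seq_len(n) * window_bp - window_bp,
             end = seq_len(n) * window_bp,
             label = lab,
             tr_bp = pmin(window_bp,
                          stats::rnbinom(n, size = dispersion,
                                         mu = tr_rate[[lab]])),
             gene_count = rpois(n, gene_rate[[lab]]))
    })
  })
}
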