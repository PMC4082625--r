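#' Run the full synthetic analysis pipeline
#'
#' Chains the stages end to end on simulated inputs: genome-pair simulation,
#' dual-reference HSB/EBR detection with two detector profiles (a lenient
#' chain and a stricter chain followed by marker narrowing), merge, masking
#' and filtering, rearrangement classification, window landscapes with group
#' comparisons, annotation enrichment with a planted term, and meiotic
#' recombination summaries. All randomness derives from `seed`; identical
#' seed and configuration give identical results. When `outdir` is given,
#' every stage's tables are written there (BED/TSV/CSV).
#'
#' @param genome A [genome_config()].
#' @param meiosis A [meiosis_config()] or `NULL` to skip the recombination
#'   stage.
#' @param stages Character subset of
#'   `c("simulate", "detect", "classify", "landscape", "enrich", "recomb")`;
#'   later stages depend on earlier ones and are skipped if a dependency is
#'   missing from `stages`.
#' @param outdir Optional output directory.
#' @param min_markers,max_marker_gap_bp,max_ebr_bp Detection parameters.
#' @param seed Integer seed overriding the configs' seeds.
#' @return Named list with each stage's results (`comparison`, `detection`,
#'   `ebrs`, `masks`, `classified`, `windows`, `window_tests`, `gene_density`,
#'   `term_stats`, `clusters`, `cells`, `recomb`).
#' @export
run_pipeline <- function(genome, meiosis = NULL,
                         stages = c("simulate", "detect", "classify",
                                    "landscape", "enrich", "recomb"),
                         outdir = NULL,
                         min_markers = 2, max_marker_gap_bp = 4e6,
                         max_ebr_bp = 4e6, seed = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) {
    genome$seed <- as.integer(seed)
    if (!is.null(meiosis)) meiosis$seed <- as.integer(seed)
  }
  out <- list()
  save <- function(obj, fn, writer) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      writer(obj, file.path(outdir, fn))
    }
  }

  if (!"simulate" %in% stages) abort("the simulate stage is required")
  out$comparison <- simulate_genome_pair(genome)
  save(out$comparison$orthologs, "orthologs.tsv", write_ortholog_tsv)
  save(out$comparison$truth_ebrs |> select("chrom", "start", "end"),
       "truth_ebrs.bed", write_bed)

  if ("detect" %in% stages) {
    orth <- out$comparison$orthologs
    lens_ref <- out$comparison$assembly_ref$chrom_lengths
    lens_tgt <- out$comparison$assembly_tgt$chrom_lengths
    lenient <- dual_reference_run(orth, lens_ref, lens_tgt,
                                  min_markers = min_markers,
                                  max_marker_gap_bp = max_marker_gap_bp,
                                  max_ebr_bp = max_ebr_bp)
    strict <- dual_reference_run(orth, lens_ref, lens_tgt,
                                 min_markers = min_markers + 1,
                                 max_marker_gap_bp = max_marker_gap_bp,
                                 max_ebr_bp = max_ebr_bp)
    out$detection <- lenient
    merged <- merge_ebr_sets(lenient$ref_ebrs, strict$ref_ebrs)
    out$masks <- build_region_masks(out$comparison$assembly_ref)
    out$ebrs <- filter_ebrs(merged, out$masks)
    save(out$ebrs |> mutate(name = paste(.data$detector, .data$status,
                                         sep = "/")),
         "ebrs.bed", write_bed)
    save(out$masks |> rename(name = "label"), "masks.bed", write_bed)
  }

  if ("classify" %in% stages && !is.null(out$ebrs)) {
    out$classified <- classify_rearrangements(out$detection$ref_hsbs,
                                              retained_ebrs(out$ebrs))
    save(out$classified |> select(-"member_ebrs"), "classified.tsv",
         function(x, p) readr::write_tsv(x, p))
    out$ebr_summary <- summarise_ebrs(out$ebrs)
  }

  if ("landscape" %in% stages && !is.null(out$ebrs)) {
    wins <- window_scan(out$comparison$assembly_ref,
                        genes = out$comparison$assembly_ref$genes)
    out$windows <- label_windows(wins, out$masks, out$detection$ref_hsbs,
                                 retained_ebrs(out$ebrs))
    labs <- unique(out$windows$label[!is.na(out$windows$label)])
    out$window_tests <- if (all(c("EBR", "HSB") %in% labs)) {
      list(gene_count = compare_window_groups(out$windows, "gene_count",
                                              intersect(c("EBR", "HSB"),
                                                        labs)))
    } else list()
    out$gene_density <- purrr::map_dbl(
      setNames(labs, labs), function(l) mean_gene_density(out$windows, l))
    # label-rate landscape drawn at the generator's configured TR/gene
    # rates, for the repeat-density comparisons across region classes
    out$rate_windows <- simulate_window_landscape(
      tr_rate = genome$tr_rate_by_region,
      gene_rate = genome$gene_rate_by_region, seed = genome$seed)
    out$window_tests$tr_bp <- compare_window_groups(out$rate_windows,
                                                    "tr_bp")
    save(out$windows, "windows.tsv", function(x, p) readr::write_tsv(x, p))
  }

  if ("enrich" %in% stages && !is.null(out$ebrs) &&
      nrow(retained_ebrs(out$ebrs)) > 0L) {
    genes <- out$comparison$assembly_ref$genes
    first_ebr <- retained_ebrs(out$ebrs)[1, ]
    planted <- tibble(term_id = "PLANTED", n_members = 15, fold = 8,
                      region = list(first_ebr |>
                                      mutate(start = pmax(0, .data$start -
                                                            200e3),
                                             end = .data$end + 200e3) |>
                                      select("chrom", "start", "end")))
    ann <- simulate_annotations(genes, planted, seed = genome$seed)
    fg <- genes_in_ebr_neighborhoods(genes, retained_ebrs(out$ebrs))
    bg <- build_background(genes, out$masks)
    out$term_stats <- term_stats(ann, fg, bg)
    out$clusters <- cluster_terms(out$term_stats, intersect(fg, bg),
                                  min_genes = 3)
    save(ann, "annotations.tsv", write_annotation_tsv)
    save(out$clusters |> select(-"term_ids", -"gene_ids"), "clusters.tsv",
         function(x, p) readr::write_tsv(x, p))
  }

  if ("recomb" %in% stages && !is.null(meiosis)) {
    out$cells <- simulate_meiotic_cells(meiosis)
    out$recomb <- list(
      genetic_length_cM = genetic_length(out$cells),
      mean_foci_per_cell = genetic_length(out$cells) / 50,
      per_sc = purrr::map_dfr(unique(out$cells$sc_id), function(s) {
        recombination_summary(out$cells, s)
      }))
    save(out$cells, "foci.csv", write_foci_csv)
    save(out$recomb$per_sc, "recombination.tsv",
         function(x, p) readr::write_tsv(x, p))
  }
  out
}

#' Per-genome EBR summary (counts and length quantiles)
#'
#' Counts and min/median/max lengths of retained EBRs — the headline summary
#' of a detection run.
#'
#' @param ebrs EBR tibble after filtering.
#' @return One row per genome label with `n_retained`, `n_gap`, `n_masked`,
#'   `min_kbp`, `median_kbp`, `max_kbp`.
#' @export
summarise_ebrs <- function(ebrs) {
  ebrs |>
    group_by(.data$genome) |>
    summarise(
      n_retained = sum(.data$status == "retained"),
      n_gap = sum(.data$status == "gap"),
      n_masked = sum(.data$status %in% c("telomeric", "centromeric")),
      min_kbp = min((.data$end - .data$start)[.data$status == "retained"] /
                      1e3),
      median_kbp = median((.data$end - .data$start)[.data$status ==
                                                      "retained"] / 1e3),
      max_kbp = max((.data$end - .data$start)[.data$status == "retained"] /
                      1e3),
      .groups = "drop")
}
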