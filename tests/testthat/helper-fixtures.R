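# Small constructors for hand-built fixtures.

# Ortholog table with markers every `spacing` bp on one reference chromosome.
# `tgt_order` permutes the markers on the target; `tgt_strand_flip` marks
# markers whose strand differs between genomes. Widths 10 kb.
make_orth <- function(n, tgt_order = seq_len(n), tgt_strand_flip = rep(FALSE, n),
                      spacing = 100e3, ref_chrom = "r1", tgt_chrom = "t1",
                      width = 10e3) {
  ref_start <- (seq_len(n) - 1) * spacing
  tgt_pos <- (order(tgt_order) - 1) * spacing  # marker i sits at rank in tgt
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    ref_chrom = ref_chrom, ref_start = ref_start,
    ref_end = ref_start + width, ref_strand = "+",
    tgt_chrom = tgt_chrom, tgt_start = tgt_pos,
    tgt_end = tgt_pos + width,
    tgt_strand = ifelse(tgt_strand_flip, "-", "+"))
}

# One-SC cells table built directly from focus positions.
make_cells <- function(foci_list, sc_length_um = 10, centromere_um = 4,
                       sc_id = "sc1", bac = NULL) {
  tibble::tibble(
    cell_id = seq_along(foci_list), sc_id = sc_id,
    sc_length_um = sc_length_um, centromere_um = centromere_um,
    foci_um = lapply(foci_list, sort),
    bac_markers = rep(list(if (is.null(bac)) setNames(numeric(), character())
                           else bac), length(foci_list)))
}

# Random base sequence with a motif run embedded at a known position.
embed_repeat <- function(flank1, motif, copies, flank2, seed = 1) {
  withr::with_seed(seed, {
    paste0(paste(sample(c("A", "C", "G", "T"), flank1, replace = TRUE),
                 collapse = ""),
           strrep(motif, copies),
           paste(sample(c("A", "C", "G", "T"), flank2, replace = TRUE),
                 collapse = ""))
  })
}
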