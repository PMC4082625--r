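#' Simulate functional-term annotations with planted enrichment
#'
#' Assigns background functional terms to genes uniformly at random, then adds
#' "planted" terms whose members are drawn with extra weight from genes inside
#' chosen regions (typically the neighbourhoods of truth breakpoint regions),
#' so that downstream enrichment statistics have a known positive control.
#' A planted fold of 1 makes the planted term indistinguishable from
#' background (null case).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param planted_terms Tibble with one row per planted term: `term_id`,
#'   `n_members` (term size), `fold` (weight multiplier, >= 1, for genes
#'   inside the region), and `region` (list-column of tibbles
#'   `chrom`/`start`/`end` defining the target region).
#' @param n_background_terms Number of uniform background terms.
#' @param genes_per_term Expected members per background term.
#' @param seed Integer seed.
#' @return Tibble annotation table: `gene_id`, `term_id`.
#' @export
simulate_annotations <- function(genes, planted_terms = NULL,
                                 n_background_terms = 40,
                                 genes_per_term = 20,
                                 seed = 1L) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0L) {
    return(tibble(gene_id = character(), term_id = character()))
  }
  stopifnot_cols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  if (!is.null(planted_terms) && any(planted_terms$fold < 1)) {
    abort("planted fold must be >= 1")
  }
  with_seed(derive_seed(seed, 3L), {
    bg <- purrr::map_dfr(seq_len(n_background_terms), function(t) {
      m <- min(nrow(genes), max(2L, rpois(1, genes_per_term)))
      tibble(gene_id = sample(genes$gene_id, m),
             term_id = sprintf("BG%04d", t))
    })
    pl <- if (is.null(planted_terms)) tibble() else
      purrr::pmap_dfr(planted_terms, function(term_id, n_members, fold,
                                              region, ...) {
        inside <- interval_hits_any(genes$chrom, genes$start, genes$end,
                                    as_tibble(region))
        w <- ifelse(inside, fold, 1)
        m <- min(n_members, nrow(genes))
        tibble(gene_id = sample(genes$gene_id, m, prob = w),
               term_id = term_id)
      })
    bind_rows(bg, pl) |> distinct() |> arrange(.data$term_id, .data$gene_id)
  })
}
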