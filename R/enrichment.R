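#' Genes in the neighbourhoods of breakpoint regions
#'
#' Foreground gene list for enrichment: genes overlapping any EBR extended by
#' `flank_bp` on each side (default +/- 200 Kbp, so genes overlapping EBR
#' starts/ends are covered), deduplicated.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param ebrs EBR tibble (`chrom`, `start`, `end`), typically retained EBRs.
#' @param flank_bp Flank size in bp.
#' @return Character vector of gene ids.
#' @export
genes_in_ebr_neighborhoods <- function(genes, ebrs, flank_bp = 200e3) {
  genes <- as_tibble(genes)
  if (nrow(genes) == 0L || nrow(ebrs) == 0L) return(character())
  flanked <- ebrs |> mutate(start = pmax(0, .data$start - flank_bp),
                            end = .data$end + flank_bp) |>
    select("chrom", "start", "end")
  hit <- interval_hits_any(genes$chrom, genes$start, genes$end, flanked)
  unique(genes$gene_id[hit])
}

#' Background gene list excluding masked regions
#'
#' All (protein-coding) genes not overlapping any telomeric or centromeric
#' mask interval.
#'
#' @param genes Gene table.
#' @param masks Output of [build_region_masks()] (may be empty).
#' @return Character vector of gene ids.
#' @export
build_background <- function(genes, masks) {
  genes <- as_tibble(genes)
  if (is.null(masks) || nrow(masks) == 0L) return(unique(genes$gene_id))
  hit <- interval_hits_any(genes$chrom, genes$start, genes$end,
                           select(masks, "chrom", "start", "end"))
  out <- unique(genes$gene_id[!hit])
  if (length(out) == 0L) abort("background gene list is empty")
  out
}

#' EASE score: conservative one-sided Fisher exact p-value
#'
#' The EASE score penalizes the Fisher exact test by removing one
#' term-positive gene from the foreground: with `k` foreground genes carrying
#' the term, `K` background genes carrying it, foreground size `n` and
#' background size `N`, the score is the upper-tail hypergeometric
#' probability P\[X >= k - 1\] for a foreground of size `n - 1` drawn from
#' `N` genes of which `K` carry the term. `k = 0` gives 1 by definition; the
#' result is always greater than or equal to the exact Fisher p-value of the
#' unpenalized table.
#'
#' @param k,K,n,N 2x2 table margins (vectorised).
#' @return Probability in \[0, 1\].
#' @export
ease_pvalue <- function(k, K, n, N) {
  if (any(k > K) || any(k > n) || any(K > N) || any(n > N) || any(k < 0)) {
    abort("invalid margins: need 0 <= k <= min(K, n) and K, n <= N")
  }
  p <- phyper(pmax(k - 1, 0) - 1, K, N - K, pmax(n - 1, 0),
              lower.tail = FALSE)
  p[k == 0] <- 1
  pmin(p, 1)
}

#' Per-term enrichment statistics
#'
#' Computes `k`, `K`, `n`, `N` and the EASE p-value for every term over a
#' foreground/background gene split.
#'
#' @param annotations Tibble `gene_id`, `term_id`.
#' @param foreground,background Character vectors of gene ids (foreground
#'   need not be a subset of background; it is intersected with it).
#' @return Tibble: `term_id`, `k`, `K`, `n`, `N`, `ease_p`, plus a
#'   `members` list-column of foreground genes carrying the term.
#' @export
term_stats <- function(annotations, foreground, background) {
  ann <- as_tibble(annotations) |>
    filter(.data$gene_id %in% background) |> distinct()
  fg <- intersect(foreground, background)
  n <- length(fg); N <- length(background)
  if (nrow(ann) == 0L || n == 0L) {
    return(tibble(term_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), ease_p = numeric(),
                  members = list()))
  }
  ann |>
    group_by(.data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = sum(unique(.data$gene_id) %in% fg),
              members = list(intersect(unique(.data$gene_id), fg)),
              .groups = "drop") |>
    mutate(n = n, N = N, ease_p = ease_pvalue(.data$k, .data$K, n, N)) |>
    select("term_id", "k", "K", "n", "N", "ease_p", "members") |>
    arrange(.data$ease_p, .data$term_id)
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Agreement of the two membership indicators over the gene universe.
#' Degenerate tables follow the documented convention: identical memberships
#' (including both empty over the universe) give kappa = 1; if only one
#' margin is degenerate the chance-corrected denominator vanishes and kappa
#' is 0.
#'
#' @param members_i,members_j Character vectors of member gene ids.
#' @param universe Character vector: the gene universe (foreground).
#' @return Kappa in \[-1, 1\].
#' @export
kappa_similarity <- function(members_i, members_j, universe) {
  a <- universe %in% members_i
  b <- universe %in% members_j
  if (identical(a, b)) return(1)
  t11 <- sum(a & b); t10 <- sum(a & !b); t01 <- sum(!a & b)
  t00 <- sum(!a & !b); tot <- length(universe)
  po <- (t11 + t00) / tot
  pe <- ((t11 + t10) * (t11 + t01) + (t01 + t00) * (t10 + t00)) / tot^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

#' Greedy kappa clustering of enriched terms
#'
#' Seeds a cluster from each individually significant term (EASE p <=
#' `p_max`) in order of significance; a term joins a cluster when its kappa
#' similarity reaches `kappa_min` with at least half of the current members.
#' Clusters whose member-gene counts fall outside `[min_genes, max_genes]`
#' are discarded. The cluster Enrichment Score is
#' `-log10(geometric mean of member EASE p-values)`; clusters are sorted by
#' score and flagged significant at `score >= 1.5`.
#'
#' @param stats Output of [term_stats()].
#' @param universe Foreground gene universe for the kappa computation.
#' @param kappa_min Kappa threshold (default 0.35).
#' @param min_genes,max_genes Cluster gene-count bounds (defaults 10 and
#'   3000).
#' @param p_max Per-term EASE significance cut-off (default 0.05).
#' @return Tibble of class `synrec_clusters`: `cluster_id`,
#'   `enrichment_score`, `significant`, `n_terms`, `n_genes`, `term_ids`,
#'   `gene_ids` (list-columns).
#' @export
cluster_terms <- function(stats, universe, kappa_min = 0.35,
                          min_genes = 10, max_genes = 3000, p_max = 0.05) {
  sig <- stats |> filter(.data$ease_p <= p_max) |> arrange(.data$ease_p)
  empty <- tibble(cluster_id = character(), enrichment_score = numeric(),
                  significant = logical(), n_terms = integer(),
                  n_genes = integer(), term_ids = list(), gene_ids = list())
  if (nrow(sig) == 0L) return(structure(empty,
                                        class = c("synrec_clusters",
                                                  class(tibble()))))
  assigned <- rep(FALSE, nrow(sig))
  clusters <- list()
  for (i in seq_len(nrow(sig))) {
    if (assigned[i]) next
    members <- i
    assigned[i] <- TRUE
    repeat {
      added <- FALSE
      for (j in seq_len(nrow(sig))) {
        if (assigned[j]) next
        kap <- vapply(members, function(m) {
          kappa_similarity(sig$members[[m]], sig$members[[j]], universe)
        }, numeric(1))
        if (mean(kap >= kappa_min) >= 0.5) {
          members <- c(members, j)
          assigned[j] <- TRUE
          added <- TRUE
        }
      }
      if (!added) break
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  res <- purrr::map_dfr(clusters, function(m) {
    genes <- unique(unlist(sig$members[m]))
    tibble(enrichment_score = -log10(exp(mean(log(sig$ease_p[m])))),
           n_terms = length(m), n_genes = length(genes),
           term_ids = list(sig$term_id[m]), gene_ids = list(genes))
  }) |>
    filter(.data$n_genes >= min_genes, .data$n_genes <= max_genes) |>
    arrange(dplyr::desc(.data$enrichment_score)) |>
    mutate(cluster_id = sprintf("cluster%02d", row_number()),
           significant = .data$enrichment_score >= 1.5) |>
    select("cluster_id", "enrichment_score", "significant", "n_terms",
           "n_genes", "term_ids", "gene_ids")
  structure(res, class = c("synrec_clusters", class(tibble())))
}

#' Genes inside a classified inversion
#'
#' Genes overlapping the inverted span (between the inner edges of the two
#' bounding EBRs) of a rearrangement classified as an inversion.
#'
#' @param genes Gene table.
#' @param rearrangement One row of [classify_rearrangements()] output with
#'   `type == "inversion"`.
#' @return Character vector of gene ids.
#' @export
genes_in_inversion <- function(genes, rearrangement) {
  r <- as_tibble(rearrangement)
  if (nrow(r) != 1L || r$type != "inversion") {
    abort("rearrangement must be a single classified inversion")
  }
  genes <- as_tibble(genes)
  hit <- genes$chrom == r$chrom &
    overlaps(genes$start, genes$end, r$region_start, r$region_end)
  unique(genes$gene_id[hit])
}
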