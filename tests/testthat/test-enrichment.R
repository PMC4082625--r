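test_that("foreground selection respects the ±200 Kbp flanks with deduplication", {
  genes <- tibble::tibble(
    gene_id = c("near", "far", "between"),
    chrom = "c1",
    start = c(5.15e6, 5.55e6, 6.1e6),   # 150 Kbp and 250 Kbp from EBR end
    end = c(5.16e6, 5.56e6, 6.11e6))
  ebrs <- tibble::tibble(chrom = "c1", start = c(4.9e6, 6.2e6),
                         end = c(5.0e6, 6.3e6))
  fg <- genes_in_ebr_neighborhoods(genes, ebrs)
  expect_true("near" %in% fg)
  expect_false("far" %in% fg)
  # gene inside two EBR flanks counted once
  expect_equal(sum(fg == "between"), 1L)
})

test_that("background excludes masked genes", {
  genes <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), chrom = "c1",
                          start = seq(0, 99e6, by = 1e6),
                          end = seq(0, 99e6, by = 1e6) + 1e4)
  masks <- tibble::tibble(chrom = "c1", start = c(0, 50e6),
                          end = c(5e6, 55e6),
                          label = c("telomeric", "centromeric"))
  bg <- build_background(genes, masks)
  expect_equal(length(bg), 90L)
  expect_equal(length(build_background(genes, NULL)), 100L)
  expect_error(build_background(genes,
                                tibble::tibble(chrom = "c1", start = 0,
                                               end = 100e6,
                                               label = "telomeric")),
               "empty")
})

test_that("EASE equals the direct hypergeometric summation and bounds Fisher", {
  # defined boundaries
  expect_equal(ease_pvalue(0, 20, 50, 1000), 1)
  expect_equal(ease_pvalue(1, 20, 50, 1000), 1)
  # the worked margins: P[X >= 9] drawing 49 from 1000 with 20 positive
  expect_equal(ease_pvalue(10, 20, 50, 1000),
               oracle_hyper_tail(9, 20, 49, 1000))
  expect_error(ease_pvalue(25, 20, 50, 1000), "margins")
})

test_that("EASE matches the oracle on an exhaustive small grid and larger margins", {
  bad <- 0L; total <- 0L
  for (N in 2:25) {
    for (K in 0:N) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          total <- total + 1L
          if (abs(ease_pvalue(k, K, n, N) - oracle_ease(k, K, n, N)) >
              1e-10) {
            bad <- bad + 1L
          }
        }
      }
    }
  }
  expect_equal(bad, 0L)
  expect_gt(total, 10000L)
  # systematic larger-margin grid up to N = 200
  withr::with_seed(3, {
    for (N in c(50, 100, 200)) {
      for (rep in 1:50) {
        K <- sample.int(N, 1); n <- sample.int(N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(ease_pvalue(k, K, n, N), oracle_ease(k, K, n, N),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("EASE is conservative relative to the exact Fisher p for every table", {
  withr::with_seed(14, {
    for (rep in 1:200) {
      N <- sample(10:300, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
      ks <- max(0, n + K - N):min(K, n)
      k <- ks[sample.int(length(ks), 1)]
      fisher_p <- stats::fisher.test(
        matrix(c(k, K - k, n - k, N - K - n + k), 2),
        alternative = "greater")$p.value
      expect_gte(ease_pvalue(k, K, n, N) + 1e-12, fisher_p)
    }
  })
})

test_that("kappa similarity covers the documented closed forms", {
  uni <- sprintf("g%02d", 1:20)
  expect_equal(kappa_similarity(uni[1:5], uni[1:5], uni), 1)
  expect_equal(kappa_similarity(uni[1:10], uni[11:20], uni), -1)
  # independent random memberships: kappa near 0 on average
  ks <- withr::with_seed(8, {
    vapply(1:200, function(i) {
      kappa_similarity(sample(uni, 8), sample(uni, 8), uni)
    }, numeric(1))
  })
  expect_lt(abs(mean(ks)), 0.1)
})

test_that("clustering composes enrichment scores geometrically", {
  uni <- sprintf("g%02d", 1:30)
  st <- tibble::tibble(
    term_id = c("t1", "t2"),
    k = c(10L, 11L), K = c(12L, 13L), n = 15L, N = 100L,
    ease_p = c(1e-2, 1e-4),
    members = list(uni[1:10], uni[1:11]))
  cl <- cluster_terms(st, uni, min_genes = 5)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$enrichment_score, -log10(sqrt(1e-6)), tolerance = 1e-9)
  expect_equal(cl$enrichment_score, 3, tolerance = 1e-9)
  expect_true(cl$significant)
  # singleton cluster: ES = -log10(p); order of members irrelevant
  st1 <- st[1, ] |> dplyr::mutate(ease_p = 1e-3)
  cl1 <- cluster_terms(st1, uni, min_genes = 5)
  expect_equal(cl1$enrichment_score, 3)
  cl_rev <- cluster_terms(st[2:1, ], uni, min_genes = 5)
  expect_equal(cl_rev$enrichment_score, cl$enrichment_score)
  # gene-count bounds discard clusters
  expect_equal(nrow(cluster_terms(st, uni, min_genes = 20)), 0L)
  expect_equal(nrow(cluster_terms(st[0, ], uni)), 0L)
})

test_that("planted enrichment yields a significant top cluster in >= 90% of seeds", {
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), chrom = "c1",
                          start = seq(0, 50e6 - 1e4, length.out = 1000),
                          end = seq(0, 50e6 - 1e4, length.out = 1000) + 5e3)
  region <- tibble::tibble(chrom = "c1", start = 15e6, end = 25e6)
  fg <- genes$gene_id[genes$start >= 14.8e6 & genes$end <= 25.2e6]
  hits <- vapply(1:200, function(seed) {
    planted <- tibble::tibble(term_id = "PLANTED", n_members = 15, fold = 8,
                              region = list(region))
    ann <- simulate_annotations(genes, planted, n_background_terms = 5,
                                seed = seed)
    st <- term_stats(ann, fg, genes$gene_id)
    cl <- cluster_terms(st, fg, min_genes = 3)
    nrow(cl) > 0L && cl$significant[1] &&
      "PLANTED" %in% cl$term_ids[[1]]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("the null generator rarely produces a significant cluster (regression guard)", {
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:600), chrom = "c1",
                          start = seq(0, 50e6 - 1e4, length.out = 600),
                          end = seq(0, 50e6 - 1e4, length.out = 600) + 5e3)
  fg <- genes$gene_id[genes$start >= 15e6 & genes$end <= 25e6]
  hits <- vapply(1:100, function(seed) {
    ann <- simulate_annotations(genes, NULL, n_background_terms = 20,
                                seed = seed + 500)
    st <- term_stats(ann, fg, genes$gene_id)
    cl <- cluster_terms(st, fg, min_genes = 3)
    nrow(cl) > 0L && any(cl$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})

test_that("genes inside an inversion span are recovered exactly", {
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), chrom = "c1",
                          start = (0:39) * 1e6, end = (0:39) * 1e6 + 1e4)
  rr <- tibble::tibble(rearr_id = "r1", type = "inversion",
                       size_class = "macro", chrom = "c1",
                       region_start = 10e6, region_end = 20e6,
                       span_bp = 10e6, member_ebrs = list(c("e1", "e2")))
  inside <- genes_in_inversion(genes, rr)
  # half-open span: the gene starting exactly at the inner edge 20 Mbp is out
  expect_equal(sort(inside), sprintf("g%02d", 11:20))
  expect_error(genes_in_inversion(genes,
                                  rr |> dplyr::mutate(type = "indel")),
               "inversion")
  # generator truth: a simulated inversion containing a known gene count
  cfg <- genome_config(n_chromosomes = 1, chrom_length_bp = 40e6,
                       n_genes = 400,
                       rearrangements = rearrangement("inversion", "chrA1",
                                                      15e6, 20e6),
                       seed = 33)
  cmp <- simulate_genome_pair(cfg)
  d <- dual_reference_run(cmp$orthologs, cmp$assembly_ref$chrom_lengths,
                          cmp$assembly_tgt$chrom_lengths)
  cls <- classify_rearrangements(d$ref_hsbs,
                                 d$ref_ebrs[d$ref_ebrs$status ==
                                              "candidate", ])
  inv_genes <- genes_in_inversion(cmp$assembly_ref$genes, cls[1, ])
  truth <- cmp$assembly_ref$genes
  n_truth <- sum(truth$start < 20e6 & truth$end > 15e6)
  expect_equal(length(inv_genes), n_truth, tolerance = 0.05)
})
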