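test_that("collinear markers form a single same-orientation block", {
  orth <- make_orth(10)
  hsbs <- detect_hsbs(orth)
  expect_equal(nrow(hsbs), 1L)
  expect_equal(hsbs$orientation, "same")
  expect_equal(hsbs$marker_count, 10L)
  expect_equal(hsbs$ref_start, 0)
  expect_equal(hsbs$tgt_end, 9 * 100e3 + 10e3)
})

test_that("a reversed strand-flipped suffix yields a second inverted block", {
  orth <- make_orth(10, tgt_order = c(1:5, 10:6),
                    tgt_strand_flip = c(rep(FALSE, 5), rep(TRUE, 5)))
  hsbs <- detect_hsbs(orth)
  expect_equal(nrow(hsbs), 2L)
  expect_equal(hsbs$orientation, c("same", "inverted"))
  expect_equal(hsbs$marker_count, c(5L, 5L))
  orc <- oracle_hsbs(orth)
  expect_equal(hsbs$ref_start, orc$ref_start)
  expect_equal(hsbs$orientation, orc$orientation)
})

test_that("chaining equals the exhaustive maximal-run oracle on random tables", {
  withr::with_seed(42, {
    for (case in 1:300) {
      n <- sample(2:8, 1)
      orth <- make_orth(n, tgt_order = sample(n),
                        tgt_strand_flip = sample(c(TRUE, FALSE), n,
                                                 replace = TRUE),
                        spacing = sample(c(50e3, 2e6, 3.9e6), 1))
      for (mm in 1:2) {
        hsbs <- detect_hsbs(orth, min_markers = mm)
        orc <- oracle_hsbs(orth, min_markers = mm)
        expect_equal(nrow(hsbs), nrow(orc))
        if (nrow(orc) > 0L) {
          expect_equal(hsbs$ref_start, orc$ref_start)
          expect_equal(hsbs$ref_end, orc$ref_end)
          expect_equal(hsbs$orientation, orc$orientation)
          expect_equal(vapply(hsbs$marker_ids, paste, "", collapse = ","),
                       orc$marker_str)
        }
      }
    }
  })
})

test_that("markers missing a target ortholog break chains in this direction only", {
  orth <- make_orth(9)
  orth[5, c("tgt_chrom", "tgt_strand")] <- NA_character_
  orth[5, c("tgt_start", "tgt_end")] <- NA_real_
  hsbs <- detect_hsbs(orth)
  expect_equal(nrow(hsbs), 2L)
  expect_equal(hsbs$marker_count, c(4L, 4L))
  # swapped direction: the NA marker does not exist, chain stays whole
  swapped <- detect_hsbs(synrec:::swap_orthologs(orth))
  expect_equal(nrow(swapped), 1L)
  expect_equal(swapped$marker_count, 8L)
})

test_that("degenerate inputs are handled", {
  orth <- make_orth(4)
  expect_error(detect_hsbs(bind_rows(orth, orth[1, ])), "duplicated")
  expect_equal(nrow(detect_hsbs(orth[0, ])), 0L)
})

test_that("shrinking the marker gap never merges blocks", {
  withr::with_seed(7, {
    for (case in 1:20) {
      n <- 10
      orth <- make_orth(n, tgt_order = sample(n), spacing = 1.5e6)
      gaps <- c(8e6, 4e6, 2e6, 1e6)
      counts <- vapply(gaps, function(g) {
        nrow(detect_hsbs(orth, max_marker_gap_bp = g))
      }, numeric(1))
      sizes <- vapply(gaps, function(g) {
        sum(detect_hsbs(orth, max_marker_gap_bp = g)$marker_count)
      }, numeric(1))
      # blocks can only split or lose markers as the gap tightens
      expect_true(all(diff(sizes) <= 0 | diff(counts) >= 0))
    }
  })
})

test_that("EBR candidates fill inter-block intervals; oversize ones become gaps", {
  hsbs <- tibble::tibble(
    hsb_id = c("h1", "h2", "h3"),
    ref_chrom = "r1", ref_start = c(0, 10.1e6, 20e6),
    ref_end = c(10e6, 15e6, 25e6),
    tgt_chrom = "t1", tgt_start = c(0, 10.1e6, 20e6),
    tgt_end = c(10e6, 15e6, 25e6),
    orientation = "same", marker_count = c(10L, 5L, 5L),
    marker_ids = list("a", "b", "c"))
  ebrs <- derive_ebrs(hsbs, c(r1 = 30e6))
  expect_equal(nrow(ebrs), 2L)
  expect_equal(ebrs$end - ebrs$start, c(100e3, 5e6))
  expect_equal(ebrs$status, c("candidate", "gap"))
  # single HSB spanning a chromosome: no EBRs
  expect_equal(nrow(derive_ebrs(hsbs[1, ], c(r1 = 30e6))), 0L)
  # HSB outside bounds rejected
  expect_error(derive_ebrs(hsbs, c(r1 = 20e6)), "outside")
})

test_that("narrowing tightens to flank markers and never widens", {
  hsbs <- tibble::tibble(
    hsb_id = c("h1", "h2"), ref_chrom = "r1",
    ref_start = c(0, 2.03e6), ref_end = c(1.03e6, 3e6),
    tgt_chrom = "t1", tgt_start = c(0, 2.03e6), tgt_end = c(1.03e6, 3e6),
    orientation = "same", marker_count = c(5L, 5L),
    marker_ids = list("a", "b"))
  # EBR bounds 30 kb outside each flank marker edge
  ebr <- tibble::tibble(ebr_id = "e1", genome = "ref", chrom = "r1",
                        start = 1e6, end = 2.06e6,
                        flank_left = "h1", flank_right = "h2",
                        detector = "chain", status = "candidate")
  nr <- narrow_ebrs(ebr, hsbs)
  expect_equal(nr$start, 1.03e6)
  expect_equal(nr$end, 2.03e6)
  expect_equal(nr$detector, "narrowed")
  expect_false(nr$flagged)
  # abutting bounds are a fixed point
  ebr2 <- ebr |> dplyr::mutate(start = 1.03e6, end = 2.03e6)
  nr2 <- narrow_ebrs(ebr2, hsbs)
  expect_equal(nr2$start, 1.03e6)
  expect_equal(nr2$end, 2.03e6)
  expect_equal(nr2$detector, "chain")
  # missing flank: unchanged, flagged
  ebr3 <- ebr |> dplyr::mutate(flank_left = "missing")
  nr3 <- narrow_ebrs(ebr3, hsbs)
  expect_true(nr3$flagged)
  expect_equal(nr3$start, 1e6)
})

test_that("dual-reference run recovers inversions in both genomes' coordinates", {
  cfg <- genome_config(n_chromosomes = 1, chrom_length_bp = 30e6,
                       n_genes = 300,
                       rearrangements = rearrangement("inversion", "chrA1",
                                                      10e6, 12e6),
                       seed = 11)
  cmp <- simulate_genome_pair(cfg)
  d <- dual_reference_run(cmp$orthologs, cmp$assembly_ref$chrom_lengths,
                          cmp$assembly_tgt$chrom_lengths)
  expect_equal(nrow(d$ref_ebrs), 2L)
  expect_equal(nrow(d$tgt_ebrs), 2L)
  truth_ref <- cmp$truth_ebrs[cmp$truth_ebrs$genome == "ref", ]
  truth_tgt <- cmp$truth_ebrs[cmp$truth_ebrs$genome == "tgt", ]
  expect_equal(d$ref_ebrs$start, truth_ref$start)
  expect_equal(d$ref_ebrs$end, truth_ref$end)
  expect_equal(sort(d$tgt_ebrs$start), sort(truth_tgt$start))

  # collinear: no EBRs either way
  cfg0 <- genome_config(n_chromosomes = 1, chrom_length_bp = 30e6,
                        n_genes = 200, seed = 11)
  cmp0 <- simulate_genome_pair(cfg0)
  d0 <- dual_reference_run(cmp0$orthologs, cmp0$assembly_ref$chrom_lengths,
                           cmp0$assembly_tgt$chrom_lengths)
  expect_equal(nrow(d0$ref_ebrs), 0L)
  expect_equal(nrow(d0$tgt_ebrs), 0L)
})

test_that("an indel yields an EBR in the reference direction only", {
  cfg <- genome_config(n_chromosomes = 1, chrom_length_bp = 30e6,
                       n_genes = 300,
                       rearrangements = rearrangement("indel", "chrA1",
                                                      14e6, 15.5e6),
                       seed = 13)
  cmp <- simulate_genome_pair(cfg)
  expect_true(sum(is.na(cmp$orthologs$tgt_chrom)) > 0)
  d <- dual_reference_run(cmp$orthologs, cmp$assembly_ref$chrom_lengths,
                          cmp$assembly_tgt$chrom_lengths)
  expect_equal(nrow(d$ref_ebrs), 1L)
  expect_equal(nrow(d$tgt_ebrs), 0L)
  truth <- cmp$truth_ebrs[cmp$truth_ebrs$genome == "ref", ]
  expect_true(d$ref_ebrs$start <= truth$start[1] + 1e-6 &&
                d$ref_ebrs$end >= truth$end[1] - 1e-6)
})

test_that("HSBs and EBR candidates partition the marker-covered span", {
  withr::with_seed(99, {
    for (case in 1:10) {
      n <- 30
      orth <- make_orth(n, tgt_order = sample(n),
                        tgt_strand_flip = sample(c(TRUE, FALSE), n, TRUE),
                        spacing = 200e3)
      hsbs <- detect_hsbs(orth, min_markers = 1)
      ebrs <- derive_ebrs(hsbs, c(r1 = 30e6))
      pieces <- dplyr::bind_rows(
        hsbs |> dplyr::transmute(start = .data$ref_start,
                                 end = .data$ref_end),
        ebrs |> dplyr::select("start", "end")) |>
        dplyr::arrange(.data$start)
      # with min_markers = 1 every marker is in a block: perfect tiling
      expect_equal(pieces$start[1], min(orth$ref_start))
      expect_equal(pieces$end[nrow(pieces)], max(orth$ref_end))
      expect_true(all(abs(pieces$start[-1] -
                            pieces$end[-nrow(pieces)]) < 1e-6))
    }
  })
})
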