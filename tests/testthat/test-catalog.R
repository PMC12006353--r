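test_that("support filter applies the per-novelty read minima", {
  counts <- tibble::tibble(
    transcript_id = c("k1", "k0", "nk3", "nk2", "nn2", "nn1"),
    s1 = c(1, 0, 3, 2, 2, 1), s2 = c(0, 0, 0, 0, 0, 0)
  )
  novelty <- tibble::tibble(
    transcript_id = counts$transcript_id,
    novelty = c("known", "known", "novel_known_locus", "novel_known_locus",
                "novel_novel_locus", "novel_novel_locus")
  )
  tpm <- counts  # values high enough that the TPM filter never triggers
  tpm[, -1] <- tpm[, -1] * 10
  got <- filter_by_support(counts, novelty, tpm = tpm)
  keep <- setNames(got$keep, got$transcript_id)
  expect_true(keep[["k1"]])    # annotated: 1 read suffices
  expect_false(keep[["k0"]])
  expect_true(keep[["nk3"]])   # novel at known locus: needs 3
  expect_false(keep[["nk2"]])
  expect_true(keep[["nn2"]])   # novel at novel locus: needs 2
  expect_false(keep[["nn1"]])
})

test_that("low-TPM transcripts are dropped unless autonomously expressed TE", {
  counts <- tibble::tibble(transcript_id = c("a", "b"), s1 = c(5, 5))
  novelty <- tibble::tibble(transcript_id = c("a", "b"),
                            novelty = c("known", "known"))
  tpm <- tibble::tibble(transcript_id = c("a", "b"), s1 = c(0.5, 0.5))
  got <- filter_by_support(counts, novelty, tpm = tpm, te_alone_ids = "b")
  expect_equal(got$keep, c(FALSE, TRUE))
  expect_equal(got$reason[1], "low_tpm")
  expect_error(
    filter_by_support(counts,
                      tibble::tibble(transcript_id = c("a", "b"),
                                     novelty = c("weird", "known"))),
    "unknown novelty"
  )
})

test_that("exonic TE overlap matches a per-base bitmap oracle", {
  tx <- mk_transcripts(list(id = "T1"))
  ex <- mk_exons("T1", list(c(100, 300), c(500, 700)))
  # two TE copies overlapping each other across the first exon
  copies <- mk_copies(
    list(id = "A", start = 50, end = 220, subfamily = "SFA"),
    list(id = "B", start = 180, end = 360, subfamily = "SFB")
  )
  prof <- compute_te_overlap(tx, ex, copies)
  expect_equal(prof$exonic_length, 400)
  expect_equal(prof$exonic_te_bp, bitmap_te_bp(ex, copies))
  # shared bases counted once: copies overlap on [180,220)
  expect_equal(prof$exonic_te_bp, 200)
  comp <- prof$components[[1]]
  expect_equal(sum(comp$bp), prof$exonic_te_bp)
  # priority: earlier-starting copy owns the shared bases
  expect_equal(comp$bp[comp$subfamily == "SFA"], 120)
  expect_equal(comp$bp[comp$subfamily == "SFB"], 80)
})

test_that("first-exon TE evidence is strand-aware", {
  copies <- mk_copies(list(id = "A", start = 500, end = 800))
  tx_plus <- mk_transcripts(list(id = "P"))
  ex_plus <- mk_exons("P", list(c(100, 200), c(550, 700)))
  prof_p <- compute_te_overlap(tx_plus, ex_plus, copies)
  expect_false(prof_p$tss_in_te)
  expect_equal(prof_p$first_exon_te_bp, 0)

  tx_minus <- mk_transcripts(list(id = "M", strand = "-"))
  ex_minus <- mk_exons("M", list(c(100, 200), c(550, 700)), strand = "-")
  prof_m <- compute_te_overlap(tx_minus, ex_minus, copies)
  # the genomically last exon is the first exon of a minus-strand transcript
  expect_true(prof_m$tss_in_te)
  expect_equal(prof_m$first_exon_te_bp, 150)
})

test_that("te_fraction is invariant under a whole-locus strand flip", {
  copies <- mk_copies(list(id = "A", start = 100, end = 400))
  ex <- list(c(150, 250), c(300, 380))
  p1 <- compute_te_overlap(mk_transcripts(list(id = "T")),
                           mk_exons("T", ex), copies)
  p2 <- compute_te_overlap(mk_transcripts(list(id = "T", strand = "-")),
                           mk_exons("T", ex, strand = "-"), copies)
  expect_equal(p1$te_fraction, p2$te_fraction)
})

test_that("classification thresholds sit exactly at the stated boundaries", {
  prof <- tibble::tibble(
    transcript_id = sprintf("T%d", 1:6),
    exonic_length = c(1000, 1000, 1000, 1000, 1000, 1000),
    exonic_te_bp = c(950, 900, 20, 10, 9, 0),
    te_fraction = c(0.95, 0.90, 0.02, 0.01, 0.009, 0),
    first_exon_length = 200, first_exon_te_bp = c(200, 200, 0, 0, 0, 0),
    tss_in_te = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  cls <- classify_transcript(prof)
  expect_equal(cls, c("TE_alone",  # >90% with TE-covered start
                      "TE_gene",   # exactly 90% fails the strict rule
                      "TE_gene",   # 20 bp overlap
                      "TE_gene",   # 10 bp is the smallest TE fragment
                      "gene",      # 9 bp falls into the documented gap
                      "gene"))
  # high TE fraction without first-exon evidence is still chimeric
  prof2 <- prof[1, ]
  prof2$tss_in_te <- FALSE
  prof2$first_exon_te_bp <- 0
  expect_equal(classify_transcript(prof2), "TE_gene")
})

test_that("TE-fraction bins split at 20/40/60/80 with [80,100] closed", {
  got <- te_fraction_bin(c(0, 0.199, 0.2, 0.45, 0.799, 0.8, 1))
  expect_equal(as.character(got),
               c("0-20", "0-20", "20-40", "40-60", "60-80", "80-100",
                 "80-100"))
})

test_that("chimera resolution picks the largest component and flags ties", {
  comp <- function(sf, frac) {
    tibble::tibble(subfamily = sf, family = "F", te_type = "LTR",
                   bp = round(1000 * frac), fraction = frac)
  }
  prof <- tibble::tibble(
    transcript_id = c("chim", "single", "tie"),
    components = list(
      dplyr::bind_rows(comp("A", 0.6), comp("B", 0.3)),
      comp("A", 1),
      dplyr::bind_rows(comp("B", 0.45), comp("A", 0.45))
    )
  )
  got <- resolve_chimera(prof)
  expect_equal(got$major_subfamily, c("A", "A", "A"))
  expect_equal(got$chimeric, c(TRUE, FALSE, TRUE))
  expect_equal(got$major_tie, c(FALSE, FALSE, TRUE))
  empty <- tibble::tibble(transcript_id = "x",
                          components = list(comp("A", 1)[0, ]))
  expect_error(resolve_chimera(empty, classes = "TE_alone"), "no TE components")
})

test_that("classification partitions every transcript exactly once", {
  sim <- simulate_zta_dataset(fixture_spec(seed = 2))
  cat <- classify_transcripts(sim$transcripts, sim$exons, sim$copies)
  expect_equal(nrow(cat), nrow(sim$transcripts))
  expect_true(all(cat$class %in% c("TE_alone", "TE_gene", "gene")))
  expect_equal(sum(table(cat$class)), nrow(sim$transcripts))
})

test_that("redundancy merging follows the per-category identity rules", {
  tx <- mk_transcripts(
    list(id = "ann1", category = "annotated"),
    list(id = "ann2", category = "annotated"),
    list(id = "ism1", category = "ISM"),
    list(id = "ism2", category = "ISM"),
    list(id = "nnc1", category = "NNC"),
    list(id = "nnc2", category = "NNC"),
    list(id = "nnc3", category = "NNC")
  )
  base <- paste(rep("ACGT", 100), collapse = "")       # 400 bp
  near <- paste0(substr(base, 1, 395), "TTTTT")        # ~98.75% identical
  seqs <- c(ann1 = base, ann2 = base, ism1 = base, ism2 = near,
            nnc1 = base, nnc2 = base, nnc3 = near)
  counts <- tibble::tibble(transcript_id = names(seqs), s1 = 1)
  got <- merge_redundant(tx, seqs, counts)
  cl <- setNames(got$clusters$cluster_id, got$clusters$transcript_id)
  expect_false(cl[["ann1"]] == cl[["ann2"]])  # annotated never merged
  expect_equal(cl[["ism1"]], cl[["ism2"]])    # ISM merges at >= 98%
  expect_equal(cl[["nnc1"]], cl[["nnc2"]])    # identical NNC merge
  expect_false(cl[["nnc3"]] == cl[["nnc1"]])  # NNC needs 100%
  merged <- dplyr::filter(got$counts, transcript_id == cl[["nnc1"]])
  expect_equal(merged$s1, 2)
  # idempotent: merging the representatives changes nothing
  reps <- got$clusters$transcript_id[got$clusters$representative]
  again <- merge_redundant(dplyr::filter(tx, transcript_id %in% reps),
                           seqs[reps])
  expect_true(all(again$clusters$representative))
  # excluded (TE-alone) candidates are kept apart
  got2 <- merge_redundant(tx, seqs, exclude_ids = c("nnc1", "nnc2"))
  cl2 <- setNames(got2$clusters$cluster_id, got2$clusters$transcript_id)
  expect_false(cl2[["nnc1"]] == cl2[["nnc2"]])
  expect_error(merge_redundant(tx, seqs[-3]), "ism1")
})

test_that("splice signals are read on the coding strand", {
  # plus-strand: intron [200,300) with GT..AG
  g <- paste(rep("A", 1000), collapse = "")
  substr(g, 201, 202) <- "GT"; substr(g, 299, 300) <- "AG"
  # second intron [500,600) GC..AG (non-canonical)
  substr(g, 501, 502) <- "GC"; substr(g, 599, 600) <- "AG"
  genome <- c(chr1 = g)
  tx <- mk_transcripts(list(id = "P"), list(id = "Q"))
  ex <- dplyr::bind_rows(mk_exons("P", list(c(100, 200), c(300, 400))),
                         mk_exons("Q", list(c(400, 500), c(600, 700))))
  got <- splice_signal_stats(tx, ex, genome,
                             groups = tibble::tibble(
                               transcript_id = c("P", "Q"),
                               group = c("DNA", "DNA")))
  expect_equal(got$introns$canonical, c(TRUE, FALSE))
  expect_equal(got$summary$canonical_fraction, 0.5)

  # minus-strand: genomic CT..AC reads GT..AG after reverse-complement
  g2 <- paste(rep("A", 1000), collapse = "")
  substr(g2, 201, 202) <- "CT"; substr(g2, 299, 300) <- "AC"
  got2 <- splice_signal_stats(
    mk_transcripts(list(id = "M", strand = "-")),
    mk_exons("M", list(c(100, 200), c(300, 400)), strand = "-"),
    c(chr1 = g2)
  )
  expect_true(got2$introns$canonical)
})

test_that("single-exon transcripts contribute no introns; short introns warn", {
  genome <- c(chr1 = paste(rep("A", 500), collapse = ""))
  got <- splice_signal_stats(mk_transcripts(list(id = "S")),
                             mk_exons("S", list(c(10, 100))), genome)
  expect_equal(nrow(got$introns), 0)
  expect_warning(
    got2 <- splice_signal_stats(
      mk_transcripts(list(id = "T")),
      mk_exons("T", list(c(10, 100), c(102, 200))), genome),
    "shorter than 4"
  )
  expect_false(got2$introns$canonical)
})

test_that("domain classes follow the per-type required-domain sets", {
  dom <- tibble::tibble(
    transcript_id = c("l1", "e1", "n1", "d1"),
    te_type = c("LINE", "ERV", "LINE", "DNA"),
    has_orf = c(TRUE, TRUE, FALSE, TRUE),
    present_domains = list(c("APE", "RT"),
                           c("GAG", "AP", "RT", "RH", "INT"),  # ENV missing
                           c("APE", "RT"),
                           character())
  )
  got <- classify_domains(dom)
  expect_equal(got$domain_class, c("complete", "partial", "no_orf",
                                   "partial"))
  bad <- dom[1, ]
  bad$present_domains <- list("XYZ")
  expect_error(classify_domains(bad), "vocabulary")
})

test_that("structure summary reports printed-style percentages and LTR calls", {
  catalog <- tibble::tibble(
    transcript_id = sprintf("T%d", 1:5),
    gene_id = c("L1", "L1", "L2", "L3", "L4"),
    class = c(rep("TE_alone", 4), "gene"),
    major_te_type = c("DNA", "DNA", "DNA", "LINE", NA)
  )
  exons <- dplyr::bind_rows(
    mk_exons("T1", list(c(0, 100), c(200, 300))),
    mk_exons("T2", list(c(0, 100))),
    mk_exons("T3", list(c(0, 100), c(150, 250))),
    mk_exons("T4", list(c(0, 100)))
  )
  got <- structure_summary(catalog, exons)
  dna <- dplyr::filter(got$by_type, te_type == "DNA")
  expect_equal(dna$multi_exon_pct, percentage(2, 3))
  expect_equal(dna$n_loci, 2)
  expect_equal(dna$multi_isoform_pct, percentage(1, 2))
  ltr <- structure_summary(
    catalog, exons,
    ltr_parts = tibble::tibble(
      locus_id = c("A", "B", "C"),
      has_ltr5 = c(TRUE, TRUE, TRUE),
      has_internal = c(TRUE, TRUE, FALSE),
      has_ltr3 = c(TRUE, FALSE, FALSE)
    )
  )$ltr
  expect_equal(ltr$intact_call, c("intact", "truncated", "truncated"))
  expect_equal(ltr$single_loss, c(FALSE, TRUE, FALSE))
})
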