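test_that("spec validation rejects inconsistent parameters", {
  expect_error(fixture_spec(trajectory_mix = rep(0.2, 8)), "sum to 1")
  expect_error(fixture_spec(trajectory_mix = c(0.5, 0.5)), "length 8")
  expect_error(fixture_spec(noise_dispersion = -1), ">= 0")
  expect_error(fixture_spec(stage_names = c("a", "a", "b", "c", "d", "e")),
               "unique")
  expect_error(fixture_spec(nuclear_bias = c(TE_alone = 0, TE_gene = 1,
                                             gene = 1)), "> 0")
  expect_error(fixture_spec(truncation = list(prob = 1.2, loss5 = c(0, 1),
                                              loss3 = c(0, 1))), "\\[0, 1\\]")
})

test_that("zero substitution probability yields consensus-identical copies", {
  spec <- fixture_spec(seed = 21, substitution_prob = 0,
                       truncation = list(prob = 0, loss5 = c(0, 0),
                                         loss3 = c(0, 0)))
  gen <- simulate_te_genome(spec)
  expect_true(all(gen$ground_truth$realized_divergence == 0))
  expect_true(all(gen$copies$kimura_divergence == 0))
  expect_false(any(gen$ground_truth$truncated))
})

test_that("realized mismatch tracks the planted substitution probability", {
  spec <- fixture_spec(seed = 22, substitution_prob = 0.05,
                       n_subfamilies = 3, copies_per_subfamily = 12,
                       truncation = list(prob = 0, loss5 = c(0, 0),
                                         loss3 = c(0, 0)))
  gen <- simulate_te_genome(spec)
  d <- gen$ground_truth$realized_divergence
  lens <- gen$copies$end - gen$copies$start
  # binomial oracle: mean mismatch ~ p within 3 standard errors
  se <- sqrt(0.05 * 0.95 / sum(lens))
  expect_lt(abs(weighted.mean(d, lens) - 0.05), 3 * se + 0.002)
})

test_that("forced truncation defeats the intactness rule on every copy", {
  spec <- fixture_spec(seed = 23,
                       truncation = list(prob = 1, loss5 = c(40, 60),
                                         loss3 = c(0, 0)))
  gen <- simulate_te_genome(spec)
  calls <- classify_intact(
    (gen$copies$consensus_end - gen$copies$consensus_begin + 1) /
      (gen$copies$consensus_end + gen$copies$consensus_left),
    gen$copies$consensus_begin - 1L,
    gen$copies$consensus_left
  )
  expect_true(all(calls == "truncated"))
})

test_that("planted transcript classes are recovered exactly", {
  sim <- simulate_zta_dataset(fixture_spec(seed = 24))
  cat <- classify_transcripts(sim$transcripts, sim$exons, sim$copies)
  j <- dplyr::inner_join(cat, sim$ground_truth$transcripts,
                         by = "transcript_id", suffix = c("", ".gt"))
  expect_equal(mean(j$class == j$true_class), 1)
  expect_equal(j$chimeric, j$chimeric.gt)
  tea <- dplyr::filter(j, true_class == "TE_alone")
  expect_true(all(tea$te_fraction > 0.9))
  expect_true(all(tea$major_subfamily == tea$major_subfamily.gt))
  gene <- dplyr::filter(j, true_class == "gene")
  expect_true(all(gene$exonic_te_bp == 0))
})

test_that("noise-free counts equal the archetype means exactly", {
  spec <- fixture_spec(seed = 25, noise_dispersion = 0)
  sim <- simulate_zta_dataset(spec)
  sc <- setdiff(names(sim$counts), "transcript_id")
  expect_equal(as.matrix(sim$counts[, sc]),
               as.matrix(sim$templates[, sc]) * spec$library_size / 1e6)
  # TPM normalization returns the planted templates
  tpm <- tpm_normalize(sim$counts)
  expect_equal(as.matrix(tpm[, sc]), as.matrix(sim$templates[, sc]))
})

test_that("noise-free activation calls recover every planted stage", {
  sim <- simulate_zta_dataset(fixture_spec(seed = 26, noise_dispersion = 0))
  tpm <- dplyr::filter(tpm_normalize(sim$counts),
                       transcript_id != "TX_FILLER")
  act <- call_activation(tpm)
  j <- dplyr::inner_join(act, sim$ground_truth$dynamics,
                         by = "transcript_id")
  expect_equal(mean(j$status == j$true_status), 1)
  z <- dplyr::filter(j, true_status == "zygotic")
  expect_equal(mean(z$activation_stage == z$true_activation_stage), 1)
  m <- dplyr::filter(j, true_status == "maternal")
  expect_true(all(is.na(m$activation_stage)))
})

test_that("unit nuclear bias gives unit localization ratios", {
  spec <- fixture_spec(seed = 27,
                       nuclear_bias = c(TE_alone = 1, TE_gene = 1,
                                        gene = 1))
  sim <- simulate_zta_dataset(spec)
  grp <- dplyr::transmute(sim$ground_truth$transcripts, transcript_id,
                          group = true_class)
  got <- group_nc_proportion(sim$nuclear, sim$cytosolic, grp)
  expect_equal(got$ratio, rep(1, nrow(got)), tolerance = 1e-12)
})

test_that("a class absent from the data yields no localization row for it", {
  spec <- fixture_spec(seed = 28,
                       transcripts_per_class = c(TE_alone = 10, TE_gene = 0,
                                                 gene = 10))
  sim <- simulate_zta_dataset(spec)
  expect_false(any(sim$ground_truth$transcripts$true_class == "TE_gene"))
  grp <- dplyr::transmute(sim$ground_truth$transcripts, transcript_id,
                          group = true_class)
  got <- group_nc_proportion(sim$nuclear, sim$cytosolic, grp)
  expect_false("TE_gene" %in% got$group)
})

test_that("strain panel plants presence groups and origin scenarios", {
  sp <- simulate_strain_panel(fixture_spec(seed = 29),
                              loci = sprintf("L%03d", 1:60))
  j <- dplyr::inner_join(sp$panel, sp$ground_truth, by = "locus_id")
  tu_only <- dplyr::filter(j, true_group == "TU")
  expect_true(all(tu_only$tu & !tu_only$ab & !tu_only$nadia & !tu_only$cb))
  dup <- dplyr::filter(j, true_mechanism == "segmental_duplication")
  expect_true(all(dup$flank5_identity >= 0.8 & dup$flank3_identity >= 0.8))
  tra <- dplyr::filter(j, true_mechanism == "transposition")
  expect_true(all(tra$flank5_identity < 0.8 | tra$flank5_coverage < 0.5))
  unc <- dplyr::filter(j, true_mechanism == "unclassified")
  expect_true(all(is.na(unc$donor_id)))
  # downstream ops recover the plants perfectly
  age <- assign_strain_age(sp$panel)
  expect_equal(age$group, sp$ground_truth$true_group)
  expect_equal(age$age_class, sp$ground_truth$true_age_class)
  org <- classify_origin(sp$panel)
  expect_equal(org$mechanism, sp$ground_truth$true_mechanism)
})

test_that("generation is byte-deterministic under a fixed seed", {
  s1 <- simulate_zta_dataset(fixture_spec(seed = 30))
  s2 <- simulate_zta_dataset(fixture_spec(seed = 30))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$copies, s2$copies)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$sequences, s2$sequences)
  s3 <- simulate_zta_dataset(fixture_spec(seed = 31))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("emitted files round-trip through the readers without loss", {
  sim <- simulate_zta_dataset(fixture_spec(seed = 32))
  dir <- withr::local_tempdir()
  write_zta_dataset(sim, dir)
  back <- read_zta_dataset(dir)
  expect_equal(back$copies$start, dplyr::arrange(sim$copies, chrom,
                                                 start)$start)
  expect_identical(back$genome, sim$genome)
  expect_equal(dplyr::arrange(back$transcripts, transcript_id),
               dplyr::arrange(sim$transcripts, transcript_id))
  ea <- dplyr::arrange(sim$exons, transcript_id, exon_rank)
  eb <- dplyr::arrange(back$exons, transcript_id, exon_rank) |>
    dplyr::mutate(exon_rank = as.integer(exon_rank),
                  start = as.integer(start), end = as.integer(end))
  expect_equal(as.data.frame(eb), as.data.frame(ea))
})
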