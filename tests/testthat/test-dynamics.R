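test_that("TPM normalization scales by column sums times 1e6", {
  counts <- tibble::tibble(
    transcript_id = c("a", "b"),
    s1 = c(3, 2999997), s2 = c(0, 10)
  )
  tpm <- tpm_normalize(counts)
  expect_equal(tpm$s1[1], 1)  # 3 reads in a 3e6 library = 1 TPM
  expect_equal(tpm$s2[1], 0)
  expect_equal(sum(tpm$s1), 1e6)
  expect_equal(sum(tpm$s2), 1e6)
  expect_warning(
    z <- tpm_normalize(tibble::tibble(transcript_id = "a", s1 = 0)),
    "zero total"
  )
  expect_equal(z$s1, 0)
})

test_that("maternal calls follow the zebrafish and mouse thresholds", {
  tpm <- tibble::tibble(
    transcript_id = c("m", "z", "mouse4", "mouse6"),
    st1 = c(0, 0, 4, 6), st2 = c(0.5, 0, 0, 0),
    st3 = c(0, 10, 10, 10)
  )
  zf <- classify_maternal(tpm, maternal_stages = c("st1", "st2"),
                          threshold = 0)
  expect_equal(zf$status, c("maternal", "zygotic", "maternal", "maternal"))
  mouse <- classify_maternal(tpm, maternal_stages = "st1", threshold = 5)
  expect_equal(mouse$status[3:4], c("zygotic", "maternal"))
})

test_that("activation stage needs prev < 5, stage >= 5 and a sustained rise", {
  expect_equal(call_activation_stage(c(0, 0, 2, 6, 8, 9)), 4)
  expect_true(is.na(call_activation_stage(rep(10, 6))))
  expect_true(is.na(call_activation_stage(c(0, 0, 6, 4, 3))))
  # truncated series near the end: increase over the remaining stage
  expect_equal(call_activation_stage(c(0, 0, 0, 0, 6, 9)), 5)
  # the very last stage cannot activate (no following stage to rise into)
  expect_true(is.na(call_activation_stage(c(0, 0, 0, 0, 0, 6))))
  expect_error(call_activation_stage(c(1)), "at least 2")
  # absolute thresholds: doubling TPM moves the call earlier
  v <- c(0, 3, 4.9, 6, 8, 10)
  expect_equal(call_activation_stage(v), 4)
  expect_equal(call_activation_stage(2 * v), 2)
})

test_that("maternal transcripts receive no activation stage", {
  tpm <- tibble::tibble(
    transcript_id = c("m", "z"),
    a = c(3, 0), b = c(2, 0), c = c(1, 8), d = c(9, 12), e = c(10, 20)
  )
  got <- call_activation(tpm, maternal_stages = c("a", "b"))
  expect_equal(got$status, c("maternal", "zygotic"))
  expect_true(is.na(got$activation_stage[1]))
  expect_equal(got$activation_stage[2], "c")
})

test_that("trajectory clustering recovers planted noise-free archetypes", {
  sim <- simulate_zta_dataset(fixture_spec(seed = 13, noise_dispersion = 0))
  gt <- sim$ground_truth$dynamics
  z <- dplyr::filter(gt, true_status == "zygotic")
  tpm <- dplyr::filter(tpm_normalize(sim$counts),
                       transcript_id %in% z$transcript_id)
  tr <- cluster_trajectories(tpm, k = 8)
  labs <- dplyr::inner_join(generics::tidy(tr), gt, by = "transcript_id")
  expect_equal(ari(labs$cluster, labs$true_archetype), 1)
  # duplicated trajectory rows land in the same cluster
  dup <- dplyr::bind_rows(tpm[1, ], dplyr::mutate(tpm[1, ],
                                                  transcript_id = "copy"))
  tr2 <- cluster_trajectories(dplyr::bind_rows(dup, tpm[-1, ]), k = 4)
  a <- generics::tidy(tr2)
  expect_equal(a$cluster[1], a$cluster[2])
  expect_error(cluster_trajectories(tpm, k = 1), "at least 2")
  expect_error(cluster_trajectories(tpm[1:3, ], k = 5), "exceeds")
  g <- generics::glance(tr)
  expect_equal(g$k, 8)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})

test_that("subfamily entropy is the plug-in Shannon entropy in nats", {
  mk <- function(sf, cl) tibble::tibble(subfamily = sf, cluster = cl)
  expect_equal(subfamily_entropy(mk("A", rep(1, 5)))$entropy, 0)
  expect_equal(subfamily_entropy(mk("A", rep(1:4, 3)))$entropy, log(4))
  e <- subfamily_entropy(mk("A", c(1, 1, 2, 3)))$entropy
  expect_equal(e, -(0.5 * log(0.5) + 0.25 * log(0.25) + 0.25 * log(0.25)))
  expect_equal(round(e, 4), 1.0397)
  # bits on request
  expect_equal(subfamily_entropy(mk("A", rep(1:4, 3)), base = 2)$entropy, 2)
  # entropy is bounded by ln(#patterns)
  for (s in 1:5) {
    cl <- sample(1:8, 20, replace = TRUE)
    ent <- subfamily_entropy(mk("A", cl))
    expect_gte(ent$entropy, 0)
    expect_lte(ent$entropy, log(ent$n_patterns) + 1e-12)
  }
})

test_that("subfamily spread counts distinct stages and clusters", {
  calls <- tibble::tibble(
    subfamily = c("A", "A", "A", "B"),
    activation_stage = c("oblong", "oblong", "sphere", "dome"),
    cluster = c(1, 2, 2, 3)
  )
  got <- subfamily_spread(calls)
  expect_equal(got$n_activation_stages, c(2, 1))
  expect_equal(got$n_clusters, c(2, 1))
})

test_that("aggregation conserves total abundance at every level", {
  tpm <- tibble::tibble(transcript_id = c("a", "b", "c"),
                        s1 = c(1, 2, 4), s2 = c(10, 20, 40))
  groups <- tibble::tibble(transcript_id = c("a", "b", "c"),
                           group = c("g1", "g1", "g2"))
  agg <- aggregate_expression(tpm, groups)
  expect_equal(sum(agg$s1), sum(tpm$s1))
  expect_equal(sum(agg$s2), sum(tpm$s2))
  expect_equal(agg$s1[agg$group == "g1"], 3)
  # one transcript per group is the identity
  solo <- aggregate_expression(tpm, tibble::tibble(
    transcript_id = c("a", "b", "c"), group = c("a", "b", "c")))
  expect_equal(solo$s1, tpm$s1)
})

test_that("stage correlations are Pearson on log2(TPM + 1)", {
  x <- c(1, 5, 20, 80)
  tpm <- tibble::tibble(transcript_id = letters[1:4],
                        s1 = x, s2 = x,
                        s3 = 2^(10 - log2(x + 1)) - 1)
  m <- adjacent_stage_correlation(tpm)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["s1", "s2"], 1)
  expect_equal(m["s1", "s3"], -1)
  # matches the direct formula on a random fixture
  set.seed(42)
  r <- tibble::tibble(transcript_id = letters[1:6],
                      s1 = runif(6, 0, 50), s2 = runif(6, 0, 50))
  expect_equal(adjacent_stage_correlation(r)["s1", "s2"],
               cor(log2(r$s1 + 1), log2(r$s2 + 1)))
})

test_that("fold change is the ratio of stage totals", {
  tpm <- tibble::tibble(transcript_id = c("a", "b"),
                        s1 = c(1, 2), s2 = c(3, 6), s3 = c(0, 0))
  expect_equal(fold_change(tpm, "s1", "s2")$fold_change, 3)
  expect_equal(fold_change(tpm, "s1", "s1")$fold_change, 1)
  z <- fold_change(tpm, "s3", "s1")
  expect_true(z$undefined)
  expect_true(is.na(z$fold_change))
})
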