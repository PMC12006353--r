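#' Specification for a synthetic ZTA dataset
#'
#' Bundles and validates every tunable of the synthetic-data generator. The
#' defaults describe a small genome shaped like the study system: TE copies
#' are mutated, optionally truncated instances of subfamily consensus
#' sequences; transcripts of all three classes are planted with known
#' exon/TE overlap structure; stage-wise counts follow eight trajectory
#' archetypes over the eleven zebrafish stages with negative-binomial noise;
#' nuclear/cytosolic matrices carry a per-class localization bias; and a
#' strain panel plants presence groups and origin mechanisms.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param n_subfamilies,copies_per_subfamily Size of the TE annotation.
#' @param stage_names Ordered developmental stages (default the eleven
#'   zebrafish stages, fertilized egg through shield).
#' @param trajectory_mix Proportions over the 8 trajectory archetypes
#'   (must sum to 1).
#' @param noise_dispersion Negative-binomial dispersion of stage counts
#'   (>= 0; 0 means noise-free counts equal to the archetype means).
#' @param nuclear_bias Named per-class nuclear:cytoplasmic abundance ratios
#'   (> 0).
#' @param substitution_prob Per-site substitution probability of copies
#'   versus consensus; a scalar, or a length-2 range sampled per copy.
#' @param truncation List: `prob` (probability a copy is truncated),
#'   `loss5`, `loss3` (length-2 bp ranges for 5'/3' consensus loss).
#' @param consensus_length Length-2 bp range for subfamily consensus
#'   sequences.
#' @param transcripts_per_class Named counts of planted transcripts.
#' @param chimera_fraction Fraction of TE-alone transcripts planted as
#'   chimeras spanning two adjacent subfamilies.
#' @param maternal_fraction Named per-class probability that a transcript is
#'   maternally deposited.
#' @param noncanonical_rate Fraction of planted introns given a
#'   non-canonical donor.
#' @param library_size Per-stage library size (3e6 makes 3 reads equal
#'   1 TPM).
#' @param origin_mix Proportions of segmental-duplication / transposition /
#'   unclassified origins in the strain panel.
#' @return A validated `fixture_spec` object (list).
#' @export
fixture_spec <- function(seed = 1L,
                         n_subfamilies = 6,
                         copies_per_subfamily = 8,
                         stage_names = zebrafish_stages(),
                         trajectory_mix = rep(1 / 8, 8),
                         noise_dispersion = 0.1,
                         nuclear_bias = c(TE_alone = 4, TE_gene = 2,
                                          gene = 1),
                         substitution_prob = c(0.02, 0.15),
                         truncation = list(prob = 0.25, loss5 = c(0, 200),
                                           loss3 = c(0, 300)),
                         consensus_length = c(1500, 3000),
                         transcripts_per_class = c(TE_alone = 30,
                                                   TE_gene = 30, gene = 30),
                         chimera_fraction = 0.2,
                         maternal_fraction = c(TE_alone = 0.05,
                                               TE_gene = 0.4, gene = 0.6),
                         noncanonical_rate = 0.15,
                         library_size = 3e6,
                         origin_mix = c(segmental_duplication = 0.4,
                                        transposition = 0.5,
                                        unclassified = 0.1)) {
  if (abs(sum(trajectory_mix) - 1) > 1e-8) {
    abort("trajectory_mix must sum to 1")
  }
  if (length(trajectory_mix) != 8) abort("trajectory_mix must have length 8")
  if (length(stage_names) < 6 || anyDuplicated(stage_names)) {
    abort("stage_names must be at least 6 unique ordered stages")
  }
  if (noise_dispersion < 0) abort("noise_dispersion must be >= 0")
  if (any(nuclear_bias <= 0)) abort("nuclear_bias ratios must be > 0")
  if (truncation$prob < 0 || truncation$prob > 1) {
    abort("truncation probability must be in [0, 1]")
  }
  if (any(substitution_prob < 0 | substitution_prob > 0.75)) {
    abort("substitution_prob must be in [0, 0.75]")
  }
  structure(
    list(seed = as.integer(seed), n_subfamilies = n_subfamilies,
         copies_per_subfamily = copies_per_subfamily,
         stage_names = stage_names, trajectory_mix = trajectory_mix,
         noise_dispersion = noise_dispersion, nuclear_bias = nuclear_bias,
         substitution_prob = substitution_prob, truncation = truncation,
         consensus_length = consensus_length,
         transcripts_per_class = transcripts_per_class,
         chimera_fraction = chimera_fraction,
         maternal_fraction = maternal_fraction,
         noncanonical_rate = noncanonical_rate,
         library_size = library_size, origin_mix = origin_mix),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Synthetic ZTA dataset spec: seed", x$seed, "-",
      x$n_subfamilies, "subfamilies x", x$copies_per_subfamily, "copies,",
      length(x$stage_names), "stages,",
      sum(x$transcripts_per_class), "transcripts\n")
  invisible(x)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each site with probability p, uniformly among the 3 other bases
# (the Jukes-Cantor single-step substitution kernel)
mutate_seq <- function(seq, p) {
  if (p == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(bases, b), 1), character(1))
  }
  paste(ch, collapse = "")
}

revcomp_str <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

draw_range <- function(x) {
  if (length(x) == 1) x else runif(1, x[1], x[2])
}

draw_int_range <- function(x) {
  if (length(x) == 1) as.integer(x) else
    sample(seq(as.integer(x[1]), as.integer(x[2])), 1)
}

#' Simulate a TE-bearing genome
#'
#' Generates subfamily consensus sequences, instantiates each genomic copy
#' by mutating the consensus at a planted per-site substitution probability
#' (Jukes-Cantor kernel) and optionally truncating its ends, and assembles
#' the copies into chromosomes separated by random spacer sequence. A subset
#' of copy pairs from different subfamilies is placed adjacently (40-60 bp
#' apart) to host chimeric TE-alone transcripts. The annotation records
#' consensus-span coordinates and the realized Kimura divergence of each
#' copy (recomputed from the emitted sequence, not the planted rate).
#'
#' @param spec A [fixture_spec()].
#' @return List: `genome` (named chromosome sequences), `copies` (TE copy
#'   tibble in [read_repeatmasker_out()] layout), `consensus` (named
#'   sequences), `ground_truth` (per-copy planted and realized divergence,
#'   truncation losses).
#' @export
simulate_te_genome <- function(spec) {
  withr::with_seed(spec$seed, {
    types <- c("DNA", "LINE", "LTR")
    subfams <- sprintf("SF%02d", seq_len(spec$n_subfamilies))
    sf_type <- types[(seq_len(spec$n_subfamilies) - 1) %% 3 + 1]
    sf_family <- paste0(sf_type, "-F",
                        (seq_len(spec$n_subfamilies) - 1) %/% 3 + 1)
    consensus <- setNames(
      vapply(seq_len(spec$n_subfamilies),
             function(i) rand_dna(draw_int_range(spec$consensus_length)),
             character(1)),
      subfams
    )
    n_copies <- spec$n_subfamilies * spec$copies_per_subfamily
    copy_sf <- rep(seq_len(spec$n_subfamilies),
                   each = spec$copies_per_subfamily)

    gt_rows <- vector("list", n_copies)
    seqs <- character(n_copies)
    meta <- vector("list", n_copies)
    for (i in seq_len(n_copies)) {
      sf <- copy_sf[i]
      cons <- consensus[[sf]]
      L <- nchar(cons)
      p_plant <- draw_range(spec$substitution_prob)
      mutated <- mutate_seq(cons, p_plant)
      loss5 <- 0L; loss3 <- 0L
      if (runif(1) < spec$truncation$prob) {
        loss5 <- draw_int_range(spec$truncation$loss5)
        loss3 <- draw_int_range(spec$truncation$loss3)
      }
      body <- substr(mutated, loss5 + 1L, L - loss3)
      strand <- sample(c("+", "-"), 1, prob = c(0.8, 0.2))
      seqs[i] <- if (strand == "-") revcomp_str(body) else body
      meta[[i]] <- list(sf = sf, strand = strand, loss5 = loss5,
                        loss3 = loss3, L = L, p_plant = p_plant)
    }

    # placement: chimera-host pairs first (small gaps), then singles
    n_pairs <- min(
      ceiling(spec$chimera_fraction *
                spec$transcripts_per_class[["TE_alone"]]),
      floor(n_copies / 4)
    )
    ord <- sample(n_copies)
    # pick pair partners from different subfamilies
    pairs <- list()
    used <- logical(n_copies)
    for (k in seq_len(n_pairs)) {
      cand <- ord[!used[ord]]
      a <- cand[1]
      b_ok <- cand[copy_sf[cand] != copy_sf[a]]
      if (length(b_ok) < 2) break
      b <- b_ok[2]
      used[c(a, b)] <- TRUE
      pairs[[k]] <- c(a, b)
    }
    singles <- ord[!used[ord]]

    n_chrom <- 2L
    chrom_seqs <- setNames(rep("", n_chrom), paste0("chr", seq_len(n_chrom)))
    rows <- list()
    place <- function(chrom, idx, gap) {
      cur <- nchar(chrom_seqs[[chrom]])
      spacer <- rand_dna(gap)
      start <- cur + gap
      chrom_seqs[[chrom]] <<- paste0(chrom_seqs[[chrom]], spacer, seqs[idx])
      rows[[length(rows) + 1]] <<- tibble(
        copy_idx = idx, chrom = chrom, start = start,
        end = start + nchar(seqs[idx]), paired = gap < 100
      )
    }
    units <- c(pairs, as.list(singles))
    units <- units[sample(length(units))]
    for (u in seq_along(units)) {
      chrom <- paste0("chr", (u - 1) %% n_chrom + 1)
      unit <- units[[u]]
      place(chrom, unit[1], sample(500:900, 1))
      if (length(unit) == 2) place(chrom, unit[2], sample(40:60, 1))
    }
    # chromosome tails leave room for planted TE-free gene loci
    n_gene <- spec$transcripts_per_class[["gene"]]
    tail_len <- max(600L, as.integer(ceiling(n_gene / n_chrom) * 520 + 600))
    for (ch in names(chrom_seqs)) {
      chrom_seqs[[ch]] <- paste0(chrom_seqs[[ch]], rand_dna(tail_len))
    }

    placed <- list_rbind(rows) |> arrange(.data$chrom, .data$start)
    copies <- placed |>
      mutate(
        copy_id = sprintf("TE%04d", row_number()),
        strand = map_chr(.data$copy_idx, ~ meta[[.x]]$strand),
        subfamily = subfams[copy_sf[.data$copy_idx]],
        family = sf_family[copy_sf[.data$copy_idx]],
        te_type = sf_type[copy_sf[.data$copy_idx]],
        consensus_begin = map_int(.data$copy_idx,
                                  ~ meta[[.x]]$loss5 + 1L),
        consensus_end = map_int(.data$copy_idx,
                                ~ as.integer(meta[[.x]]$L - meta[[.x]]$loss3)),
        consensus_left = map_int(.data$copy_idx,
                                 ~ as.integer(meta[[.x]]$loss3)),
        kimura_divergence = NA_real_
      )
    copies <- realized_divergence(chrom_seqs, copies, consensus)
    gt <- copies |>
      transmute(
        .data$copy_id, .data$subfamily, .data$te_type,
        planted_divergence = map_dbl(.data$copy_idx, ~ meta[[.x]]$p_plant),
        realized_divergence = .data$realized_divergence,
        loss5 = map_int(.data$copy_idx, ~ as.integer(meta[[.x]]$loss5)),
        loss3 = map_int(.data$copy_idx, ~ as.integer(meta[[.x]]$loss3)),
        truncated = .data$loss5 > 0 | .data$loss3 > 0,
        paired = .data$paired
      )
    copies <- copies |>
      select("copy_id", "chrom", "start", "end", "strand", "subfamily",
             "family", "te_type", "kimura_divergence", "consensus_begin",
             "consensus_end", "consensus_left", "realized_divergence")
    list(genome = chrom_seqs, copies = copies, consensus = consensus,
         ground_truth = gt)
  })
}

#' Recompute realized divergence of TE copies from the genome
#'
#' Compares each annotated copy's genomic sequence (oriented to the
#' consensus) with the consensus span it derives from and rewrites
#' `kimura_divergence` (percent, transition/transversion-corrected) plus the
#' raw `realized_divergence` (mismatch fraction). Used after any operation
#' that edits genome bases (e.g. splice-signal planting) so the annotation
#' always reflects the emitted sequence.
#'
#' @param genome Named chromosome sequences.
#' @param copies TE copy tibble.
#' @param consensus Named consensus sequences by subfamily.
#' @return `copies` with updated `kimura_divergence` and
#'   `realized_divergence`.
#' @export
realized_divergence <- function(genome, copies, consensus) {
  stats <- pmap(
    list(copies$chrom, copies$start, copies$end, copies$strand,
         copies$subfamily, copies$consensus_begin, copies$consensus_end),
    function(chrom, start, end, strand, sf, cb, ce) {
      obs <- substr(genome[[chrom]], start + 1L, end)
      if (strand == "-") obs <- revcomp_str(obs)
      ref <- substr(consensus[[sf]], cb, ce)
      alignment_summary(obs, ref, aligned = TRUE)
    }
  ) |> list_rbind()
  copies |>
    mutate(kimura_divergence = kimura2p(stats$p, stats$q, percent = TRUE),
           realized_divergence = stats$d)
}

#' Simulate an inter-LTR pair of known insertion age
#'
#' Starts from a random ancestral LTR (identical 5' and 3' repeats at
#' insertion) and evolves each repeat independently for `age_years` under
#' the Jukes-Cantor process at rate `mu`: each site substitutes with
#' probability \eqn{\frac{3}{4}(1 - e^{-\frac{4}{3}\mu T})}.
#'
#' @param length LTR length in bp.
#' @param age_years Planted insertion age.
#' @param mu Neutral substitution rate per site per year.
#' @return List: `ltr5`, `ltr3` (sequences), `d` (realized divergence
#'   fraction), `age_years`.
#' @export
simulate_ltr_pair <- function(length = 5000, age_years = 1e5, mu = 1.46e-8) {
  p_branch <- 0.75 * (1 - exp(-4 / 3 * mu * age_years))
  anc <- rand_dna(length)
  ltr5 <- mutate_seq(anc, p_branch)
  ltr3 <- mutate_seq(anc, p_branch)
  d <- alignment_summary(ltr5, ltr3, aligned = TRUE)$d
  list(ltr5 = ltr5, ltr3 = ltr3, d = d, age_years = age_years)
}

set_substr <- function(x, pos, value) {
  # pos is 1-based; value replaces nchar(value) characters
  paste0(substr(x, 1, pos - 1), value,
         substr(x, pos + nchar(value), nchar(x)))
}

#' Simulate a transcriptome over a TE genome
#'
#' Plants transcripts of all three classes with known overlap structure:
#' TE-alone transcripts (single- or two-exon, fully inside one copy, plus
#' chimeras spanning two adjacent copies of different subfamilies at > 90%
#' exonic TE content with the TSS inside the first copy), TE-gene chimeras
#' (first exon TE-free, second exon overlapping a copy well above 10 bp but
#' far below the 90% rule), and gene transcripts with zero TE overlap. A
#' share of TE-alone loci receives a second isoform. Donor/acceptor bases of
#' planted introns are written into the genome (GT..AG, or GC..AG at the
#' planted non-canonical rate), so the returned genome supersedes the input
#' one.
#'
#' @param spec A [fixture_spec()].
#' @param genome_sim Result of [simulate_te_genome()].
#' @return List: `transcripts`, `exons` (internal transcript-model tibbles),
#'   `sequences` (spliced transcript sequences), `genome` (edited),
#'   `copies` (annotation with divergence recomputed against the edited
#'   genome), `ground_truth` (per-transcript true class, chimera flag and
#'   planted major subfamily).
#' @export
simulate_transcriptome <- function(spec, genome_sim) {
  withr::with_seed(spec$seed + 1L, {
    genome <- genome_sim$genome
    copies <- genome_sim$copies
    n_tx <- spec$transcripts_per_class

    copies_by_pos <- copies |> arrange(.data$chrom, .data$start)
    # adjacent different-subfamily pairs with small gaps host chimeras
    pair_tbl <- copies_by_pos |>
      group_by(.data$chrom) |>
      mutate(gap_next = lead(.data$start) - .data$end,
             next_id = lead(.data$copy_id),
             next_subfamily = lead(.data$subfamily),
             next_len = lead(.data$end) - lead(.data$start)) |>
      ungroup() |>
      filter(!is.na(.data$gap_next), .data$gap_next <= 100,
             .data$subfamily != .data$next_subfamily,
             .data$end - .data$start >= 710, .data$next_len >= 310)

    # spacer intervals (chrom regions not covered by any copy); the final
    # interval per chromosome is the tail reserved for gene loci
    spacers <- copies_by_pos |>
      group_by(.data$chrom) |>
      reframe(sp_start = c(0L, .data$end),
              sp_end = c(.data$start, nchar(genome[[first(.data$chrom)]]))) |>
      group_by(.data$chrom) |>
      mutate(is_tail = row_number() == n()) |>
      ungroup() |>
      filter(.data$sp_end - .data$sp_start >= 450) |>
      mutate(used = FALSE)
    tails <- spacers |>
      filter(.data$is_tail) |>
      mutate(cursor = .data$sp_start + 50L)

    tx_rows <- list(); ex_rows <- list(); gt_rows <- list()
    tx_n <- 0L
    add_tx <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       novelty, category, true_class, chimeric = FALSE,
                       major_subfamily = NA_character_) {
      tx_n <<- tx_n + 1L
      id <- sprintf("TX%04d", tx_n)
      k <- length(exon_starts)
      rank <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
      tx_rows[[tx_n]] <<- tibble(
        transcript_id = id, gene_id = gene_id, chrom = chrom,
        strand = strand, novelty = novelty, structural_category = category
      )
      ex_rows[[tx_n]] <<- tibble(
        transcript_id = id, exon_rank = rank,
        start = as.integer(exon_starts), end = as.integer(exon_ends)
      ) |> arrange(.data$exon_rank)
      gt_rows[[tx_n]] <<- tibble(
        transcript_id = id, gene_id = gene_id, true_class = true_class,
        chimeric = chimeric, major_subfamily = major_subfamily
      )
      id
    }
    plant_intron <- function(chrom, strand, istart, iend) {
      donor <- if (runif(1) < spec$noncanonical_rate) "GC" else "GT"
      if (strand == "+") {
        genome[[chrom]] <<- set_substr(genome[[chrom]], istart + 1L, donor)
        genome[[chrom]] <<- set_substr(genome[[chrom]], iend - 1L, "AG")
      } else {
        genome[[chrom]] <<- set_substr(genome[[chrom]], iend - 1L,
                                       revcomp_str(donor))
        genome[[chrom]] <<- set_substr(genome[[chrom]], istart + 1L, "CT")
      }
    }

    # --- chimeric TE-alone transcripts over planted adjacent pairs
    n_chim <- min(ceiling(spec$chimera_fraction * n_tx[["TE_alone"]]),
                  nrow(pair_tbl))
    for (i in seq_len(n_chim)) {
      pr <- pair_tbl[i, ]
      la <- 600L; lb <- 300L
      s <- pr$end - la
      e <- pr$end + pr$gap_next + lb  # = next copy's start + lb
      add_tx(gene_id = paste0("LOC_TEA_C", i), chrom = pr$chrom,
             strand = "+", exon_starts = s, exon_ends = e,
             novelty = "novel_novel_locus", category = "NNC",
             true_class = "TE_alone", chimeric = TRUE,
             major_subfamily = pr$subfamily)
    }

    # --- singular TE-alone transcripts (and some second isoforms)
    host_ids <- setdiff(copies_by_pos$copy_id,
                        c(pair_tbl$copy_id[seq_len(n_chim)],
                          pair_tbl$next_id[seq_len(n_chim)]))
    hosts <- copies_by_pos |>
      filter(.data$copy_id %in% host_ids, .data$end - .data$start >= 700)
    n_single <- n_tx[["TE_alone"]] - n_chim
    n_loci <- min(nrow(hosts), n_single)
    extra <- n_single - n_loci  # second isoforms on the first loci
    for (i in seq_len(n_loci)) {
      h <- hosts[i, ]
      gene_id <- paste0("LOC_TEA_S", i)
      strand <- sample(c("+", "-"), 1, prob = c(0.7, 0.3))
      multi <- runif(1) < 0.5 && h$end - h$start >= 900
      if (multi) {
        e1s <- h$start + 10L; e1e <- e1s + 200L
        i_len <- 120L
        e2s <- e1e + i_len; e2e <- h$end - 10L
        if (strand == "-") {  # first exon must be the 3'-most genomic one
          plant_intron(h$chrom, "-", e1e, e2s)
        } else {
          plant_intron(h$chrom, "+", e1e, e2s)
        }
        add_tx(gene_id, h$chrom, strand, c(e1s, e2s), c(e1e, e2e),
               "novel_novel_locus", "NNC", "TE_alone",
               major_subfamily = h$subfamily)
      } else {
        s <- h$start + 10L; e <- h$end - 10L
        add_tx(gene_id, h$chrom, strand, s, e,
               "novel_novel_locus", "NNC", "TE_alone",
               major_subfamily = h$subfamily)
      }
      if (i <= extra) {  # shorter second isoform at the same locus
        s2 <- h$start + 30L; e2 <- h$start + 30L + 500L
        add_tx(gene_id, h$chrom, "+", s2, e2,
               "novel_novel_locus", "NNC", "TE_alone",
               major_subfamily = h$subfamily)
      }
    }

    # --- TE-gene chimeras: exon 1 in the spacer before a copy, exon 2
    #     running into the copy
    tg_hosts <- copies_by_pos
    tg_done <- 0L
    for (i in seq_len(nrow(tg_hosts))) {
      if (tg_done >= n_tx[["TE_gene"]]) break
      h <- tg_hosts[i, ]
      sp <- spacers |>
        filter(.data$chrom == h$chrom, .data$sp_end == h$start,
               !.data$used, !.data$is_tail)
      if (nrow(sp) == 0) next
      spacers$used[spacers$chrom == h$chrom &
                     spacers$sp_end == h$start] <- TRUE
      overlap <- sample(60:200, 1)
      e1s <- h$start - 400L; e1e <- e1s + 150L
      e2s <- h$start - 80L; e2e <- h$start + overlap
      plant_intron(h$chrom, "+", e1e, e2s)
      tg_done <- tg_done + 1L
      nv <- sample(c("known", "novel_known_locus"), 1)
      add_tx(paste0("LOC_TG", tg_done), h$chrom, "+",
             c(e1s, e2s), c(e1e, e2e), nv,
             ifelse(nv == "known", "annotated", sample(c("ISM", "NIC"), 1)),
             "TE_gene")
    }

    # --- gene transcripts carved from the TE-free chromosome tails
    g_done <- 0L
    while (g_done < n_tx[["gene"]]) {
      i <- which(tails$cursor + 450L <= tails$sp_end)[1]
      if (is.na(i)) break
      u <- tails$cursor[i]
      tails$cursor[i] <- u + 520L
      g_done <- g_done + 1L
      e1s <- u; e1e <- u + 140L; e2s <- u + 240L; e2e <- u + 400L
      plant_intron(tails$chrom[i], "+", e1e, e2s)
      add_tx(paste0("LOC_G", g_done), tails$chrom[i], "+",
             c(e1s, e2s), c(e1e, e2e), "known", "annotated", "gene")
    }

    transcripts <- list_rbind(tx_rows)
    exons <- list_rbind(ex_rows)
    gt <- list_rbind(gt_rows)

    seqs <- exons |>
      left_join(select(transcripts, "transcript_id", "chrom", "strand"),
                by = "transcript_id") |>
      group_by(.data$transcript_id) |>
      arrange(.data$start, .by_group = TRUE) |>
      summarise(
        seq = {
          s <- paste(substr(rep(genome[first(.data$chrom)], n()),
                            .data$start + 1L, .data$end), collapse = "")
          if (first(.data$strand) == "-") revcomp_str(s) else s
        },
        .groups = "drop"
      )
    sequences <- setNames(seqs$seq, seqs$transcript_id)

    copies <- realized_divergence(genome, copies, genome_sim$consensus)
    list(transcripts = transcripts, exons = exons, sequences = sequences,
         genome = genome, copies = copies, ground_truth = gt)
  })
}

# archetype template TPM trajectories over n_stages (integer-valued);
# returns list(matrix 8 x n_stages, activation_index vector)
trajectory_archetypes <- function(n_stages) {
  acts <- round(seq(3, n_stages - 3, length.out = 6))
  tmpl <- matrix(0, nrow = 8, ncol = n_stages)
  # flat-then-rise: zygotic induction is sharply exponential at onset
  # (10 TPM tripling over the next two stages, the window the onset rule
  # tests), then keeps growing more slowly
  rise <- function(len) {
    v <- 10
    for (i in seq_len(len)) {
      v <- c(v, floor(tail(v, 1) * if (i <= 2) 3 else 1.5))
    }
    v
  }
  for (k in 1:6) {
    a <- acts[k]
    tmpl[k, a:n_stages] <- rise(n_stages - a)
  }
  # rise-then-fall: activates early, peaks mid, declines
  a7 <- acts[1]
  peak <- ceiling((a7 + n_stages) / 2)
  tmpl[7, a7:peak] <- rise(peak - a7)
  fall <- tmpl[7, peak]
  for (s in seq(peak + 1, n_stages)) {
    fall <- max(2, floor(fall * 0.5))
    tmpl[7, s] <- fall
  }
  # late riser: activation near the series end, rise over what remains
  a8 <- n_stages - 2
  tmpl[8, a8:n_stages] <- c(10, 30, 90)
  list(templates = tmpl, activation = c(acts, acts[1], a8))
}

#' Simulate stage-wise counts with planted dynamics
#'
#' Each transcript is assigned maternal or zygotic status (per-class
#' maternal probabilities) and, if zygotic, one of eight trajectory
#' archetypes (six flat-then-rise templates activating at successive stages,
#' one rise-then-fall, one late riser) scaled by a random integer factor.
#' Maternal transcripts decay from a positive level at the first two stages.
#' Templates are in TPM units; a filler housekeeping transcript tops each
#' stage up to exactly 1e6 TPM so that, at dispersion 0, TPM normalization
#' returns the templates exactly. Counts are negative-binomial around
#' `template * library_size / 1e6` with the spec dispersion (dispersion 0
#' gives the means exactly).
#'
#' @param spec A [fixture_spec()].
#' @param transcriptome Result of [simulate_transcriptome()].
#' @return List: `counts` (tibble `transcript_id` + stage columns, includes
#'   the filler transcript `TX_FILLER`), `templates` (planted TPM means),
#'   `ground_truth` (per-transcript `true_status`,
#'   `true_activation_stage`, `true_archetype`).
#' @export
simulate_stage_counts <- function(spec, transcriptome) {
  withr::with_seed(spec$seed + 2L, {
    stages <- spec$stage_names
    S <- length(stages)
    arch <- trajectory_archetypes(S)
    gt_class <- transcriptome$ground_truth
    n <- nrow(gt_class)
    status <- character(n); arche <- rep(NA_integer_, n)
    tmpl <- matrix(0, nrow = n, ncol = S)
    for (i in seq_len(n)) {
      cls <- gt_class$true_class[i]
      if (runif(1) < spec$maternal_fraction[[cls]]) {
        status[i] <- "maternal"
        m0 <- sample(20:60, 1)
        tmpl[i, ] <- pmax(round(m0 * 0.7^(0:(S - 1))), c(1, 1,
                                                         rep(0, S - 2)))
      } else {
        status[i] <- "zygotic"
        arche[i] <- sample.int(8, 1, prob = spec$trajectory_mix)
        u <- sample(1:4, 1)
        tmpl[i, ] <- u * arch$templates[arche[i], ]
      }
    }
    ids <- gt_class$transcript_id
    filler <- 1e6 - colSums(tmpl)
    if (any(filler < 0)) abort("planted templates exceed the TPM budget")
    tmpl_all <- rbind(tmpl, filler)
    ids_all <- c(ids, "TX_FILLER")
    mu <- tmpl_all * spec$library_size / 1e6
    counts <- if (spec$noise_dispersion == 0) {
      mu
    } else {
      matrix(rnbinom(length(mu), mu = mu,
                     size = 1 / spec$noise_dispersion),
             nrow = nrow(mu))
    }
    counts_tbl <- bind_cols(
      tibble(transcript_id = ids_all),
      as_tibble(setNames(as.data.frame(counts), stages))
    )
    templates_tbl <- bind_cols(
      tibble(transcript_id = ids_all),
      as_tibble(setNames(as.data.frame(tmpl_all), stages))
    )
    gt <- tibble(
      transcript_id = ids, true_status = status,
      true_archetype = arche,
      true_activation_stage = ifelse(is.na(arche), NA_character_,
                                     stages[arch$activation[arche]])
    ) |>
      mutate(true_activation_stage = ifelse(.data$true_status == "maternal",
                                            NA_character_,
                                            .data$true_activation_stage))
    list(counts = counts_tbl, templates = templates_tbl, ground_truth = gt)
  })
}

#' Simulate nuclear and cytosolic abundance matrices
#'
#' Plants a per-class nuclear:cytoplasmic abundance ratio: cytosolic
#' abundance equals each transcript's mean planted expression, nuclear
#' abundance multiplies it by the class bias. The matrices are exact means
#' (no sampling noise), so estimated group ratios match the closed-form
#' planted ratios (each class bias normalized by the abundance-weighted mean
#' bias).
#'
#' @param spec A [fixture_spec()].
#' @param stage_sim Result of [simulate_stage_counts()].
#' @param classes Tibble mapping `transcript_id` to `class` (use the planted
#'   truth or a computed catalog).
#' @return List: `nuclear`, `cytosolic` (tibbles with `transcript_id`,
#'   `tpm`), `ground_truth` (planted per-class bias).
#' @export
simulate_nc_counts <- function(spec, stage_sim, classes) {
  tmpl <- stage_sim$templates |>
    filter(.data$transcript_id != "TX_FILLER")
  sc <- stage_cols(tmpl)
  base <- tibble(
    transcript_id = tmpl$transcript_id,
    abundance = rowMeans(as.matrix(tmpl[, sc]))
  ) |>
    inner_join(classes, by = "transcript_id")
  bias <- spec$nuclear_bias
  nuclear <- base |>
    transmute(.data$transcript_id,
              tpm = .data$abundance * unname(bias[.data$class]))
  cytosolic <- base |> transmute(.data$transcript_id,
                                 tpm = .data$abundance)
  list(nuclear = nuclear, cytosolic = cytosolic,
       ground_truth = tibble(class = names(bias), bias = unname(bias)))
}

#' Simulate a strain presence/homology panel
#'
#' Assigns each TE-alone locus a nested strain-presence group (TU, TU-AB,
#' TU-AB-Nadia, or all four, uniformly) and an origin mechanism per the spec
#' mix. Segmental-duplication loci get a donor hit with high-identity,
#' full-coverage 500 bp flanks on both sides; transposition loci get a donor
#' hit whose flanks are essentially unalignable; unclassified loci get no
#' donor hit.
#'
#' @param spec A [fixture_spec()].
#' @param loci Character vector of TE-alone locus ids.
#' @return List: `panel` (presence + flank-homology tibble), `ground_truth`
#'   (`locus_id`, `true_group`, `true_age_class`, `true_mechanism`).
#' @export
simulate_strain_panel <- function(spec, loci) {
  withr::with_seed(spec$seed + 3L, {
    n <- length(loci)
    groups <- c("TU", "TU-AB", "TU-AB-Nadia", "TU-AB-Nadia-CB")
    grp <- sample(groups, n, replace = TRUE)
    mech <- sample(names(spec$origin_mix), n, replace = TRUE,
                   prob = spec$origin_mix)
    panel <- tibble(
      locus_id = loci,
      tu = TRUE,
      ab = grp != "TU",
      nadia = grp %in% c("TU-AB-Nadia", "TU-AB-Nadia-CB"),
      cb = grp == "TU-AB-Nadia-CB",
      donor_id = ifelse(mech == "unclassified", NA_character_,
                        paste0("DONOR_", seq_len(n))),
      te_identity = ifelse(mech == "unclassified", NA_real_,
                           runif(n, 0.85, 0.99)),
      flank5_identity = case_when(
        mech == "segmental_duplication" ~ runif(n, 0.85, 0.99),
        mech == "transposition" ~ runif(n, 0.2, 0.5),
        .default = NA_real_
      ),
      flank5_coverage = case_when(
        mech == "segmental_duplication" ~ 1,
        mech == "transposition" ~ runif(n, 0, 0.3),
        .default = NA_real_
      ),
      flank3_identity = case_when(
        mech == "segmental_duplication" ~ runif(n, 0.85, 0.99),
        mech == "transposition" ~ runif(n, 0.2, 0.5),
        .default = NA_real_
      ),
      flank3_coverage = case_when(
        mech == "segmental_duplication" ~ 1,
        mech == "transposition" ~ runif(n, 0, 0.3),
        .default = NA_real_
      )
    )
    gt <- tibble(
      locus_id = loci, true_group = grp,
      true_age_class = ifelse(grp %in% c("TU", "TU-AB"), "young", "old"),
      true_mechanism = mech
    )
    list(panel = panel, ground_truth = gt)
  })
}

#' Simulate a complete synthetic ZTA dataset
#'
#' Chains [simulate_te_genome()], [simulate_transcriptome()],
#' [simulate_stage_counts()], [simulate_nc_counts()] and
#' [simulate_strain_panel()] into one object holding every pipeline input
#' plus the planted ground truth. Deterministic: the same spec (seed) always
#' yields byte-identical outputs.
#'
#' @param spec A [fixture_spec()].
#' @return List with `spec`, `genome`, `consensus`, `copies`,
#'   `transcripts`, `exons`, `sequences`, `counts`, `templates`, `nuclear`,
#'   `cytosolic`, `strain_panel` and a `ground_truth` list (`copies`,
#'   `transcripts`, `dynamics`, `nc_bias`, `strain`).
#' @export
simulate_zta_dataset <- function(spec = fixture_spec()) {
  gen <- simulate_te_genome(spec)
  trx <- simulate_transcriptome(spec, gen)
  cnt <- simulate_stage_counts(spec, trx)
  ncs <- simulate_nc_counts(
    spec, cnt,
    trx$ground_truth |> transmute(.data$transcript_id,
                                  class = .data$true_class)
  )
  te_loci <- trx$ground_truth |>
    filter(.data$true_class == "TE_alone") |>
    distinct(.data$gene_id) |>
    pull()
  strains <- simulate_strain_panel(spec, te_loci)
  list(
    spec = spec, genome = trx$genome, consensus = gen$consensus,
    copies = trx$copies, transcripts = trx$transcripts, exons = trx$exons,
    sequences = trx$sequences, counts = cnt$counts,
    templates = cnt$templates, nuclear = ncs$nuclear,
    cytosolic = ncs$cytosolic, strain_panel = strains$panel,
    ground_truth = list(copies = gen$ground_truth,
                        transcripts = trx$ground_truth,
                        dynamics = cnt$ground_truth,
                        nc_bias = ncs$ground_truth,
                        strain = strains$ground_truth)
  )
}

#' Write a simulated dataset to a directory of standard files
#'
#' Emits FASTA (genome, transcript sequences), RepeatMasker-style `.out` and
#' BED6 (TE copies), GTF (transcript models) and TSV (counts, N/C matrices,
#' strain panel, ground-truth tables) files that round-trip through the
#' package readers.
#'
#' @param sim Result of [simulate_zta_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_zta_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_fasta(sim$sequences, p("transcripts.fa"))
  write_repeatmasker_out(select(sim$copies, -"realized_divergence"),
                         p("te.out"))
  write_bed6(sim$copies, p("te.bed"))
  write_gtf_transcripts(sim$transcripts, sim$exons, p("transcripts.gtf"))
  write_matrix(sim$counts, p("counts.tsv"))
  readr::write_tsv(sim$nuclear, p("nuclear.tsv"))
  readr::write_tsv(sim$cytosolic, p("cytosolic.tsv"))
  readr::write_tsv(sim$strain_panel, p("strain_panel.tsv"))
  readr::write_tsv(sim$ground_truth$transcripts, p("truth_transcripts.tsv"))
  readr::write_tsv(sim$ground_truth$dynamics, p("truth_dynamics.tsv"))
  readr::write_tsv(sim$ground_truth$copies, p("truth_copies.tsv"))
  readr::write_tsv(sim$ground_truth$strain, p("truth_strain.tsv"))
  invisible(dir)
}
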