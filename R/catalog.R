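te_gr <- function(copies) {
  GenomicRanges::GRanges(
    seqnames = copies$chrom,
    ranges = IRanges::IRanges(start = copies$start + 1L, end = copies$end),
    strand = "*"
  )
}

exon_gr <- function(exons, transcripts) {
  ex <- left_join(exons, select(transcripts, "transcript_id", "chrom"),
                  by = "transcript_id")
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = "*"
  )
}

#' Exonic TE overlap profile of transcripts
#'
#' Computes, for each transcript, how much of its exonic (spliced) sequence
#' lies inside TE annotation: total exonic length, exonic TE bp (each exonic
#' base counted once even where TE copies overlap each other), TE fraction,
#' the TE overlap of the first (5'-most, strand-aware) exon, whether the TSS
#' base lies inside a TE, and the per-subfamily component breakdown. Where
#' copies overlap, each base is assigned to a single copy (the one starting
#' first, ties broken by lexicographically smaller subfamily), so component
#' bp always sum to the exonic TE bp.
#'
#' @param transcripts,exons Transcript model tibbles
#'   (see [read_gtf_transcripts()]).
#' @param copies TE copy tibble (see [read_repeatmasker_out()]).
#' @return Tibble with one row per transcript: `transcript_id`,
#'   `exonic_length`, `exonic_te_bp`, `te_fraction`, `first_exon_length`,
#'   `first_exon_te_bp`, `tss_in_te`, and a `components` list-column of
#'   tibbles (`subfamily`, `family`, `te_type`, `bp`, `fraction`).
#' @export
compute_te_overlap <- function(transcripts, exons, copies) {
  tx_ids <- transcripts$transcript_id
  empty_comp <- tibble(subfamily = character(), family = character(),
                       te_type = character(), bp = integer(),
                       fraction = double())
  exlen <- exons |>
    group_by(.data$transcript_id) |>
    summarise(exonic_length = sum(.data$end - .data$start), .groups = "drop")
  base <- transcripts |>
    select("transcript_id", "strand") |>
    left_join(exlen, by = "transcript_id")
  if (nrow(copies) == 0) {
    return(base |>
             mutate(exonic_te_bp = 0L,
                    te_fraction = 0,
                    first_exon_length = NA_integer_, first_exon_te_bp = 0L,
                    tss_in_te = FALSE,
                    components = list(empty_comp)) |>
             select(-"strand"))
  }
  tgr <- te_gr(copies)
  # assign each genomic base covered by TEs to exactly one copy
  dj <- GenomicRanges::disjoin(tgr)
  hits <- GenomicRanges::findOverlaps(dj, tgr)
  pick <- tibble(
    seg = S4Vectors::queryHits(hits),
    copy = S4Vectors::subjectHits(hits),
    copy_start = copies$start[S4Vectors::subjectHits(hits)],
    subfamily = copies$subfamily[S4Vectors::subjectHits(hits)]
  ) |>
    group_by(.data$seg) |>
    arrange(.data$copy_start, .data$subfamily, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  seg_owner <- pick$copy[order(pick$seg)]

  egr <- exon_gr(exons, transcripts)
  eh <- GenomicRanges::findOverlaps(egr, dj)
  ov <- IRanges::pintersect(egr[S4Vectors::queryHits(eh)],
                            dj[S4Vectors::subjectHits(eh)])
  owner <- seg_owner[S4Vectors::subjectHits(eh)]
  per_comp <- tibble(
    transcript_id = exons$transcript_id[S4Vectors::queryHits(eh)],
    exon_rank = exons$exon_rank[S4Vectors::queryHits(eh)],
    subfamily = copies$subfamily[owner],
    family = copies$family[owner],
    te_type = copies$te_type[owner],
    bp = GenomicRanges::width(ov)
  )
  totals <- per_comp |>
    group_by(.data$transcript_id) |>
    summarise(exonic_te_bp = sum(.data$bp), .groups = "drop")
  first_bp <- per_comp |>
    filter(.data$exon_rank == 1) |>
    group_by(.data$transcript_id) |>
    summarise(first_exon_te_bp = sum(.data$bp), .groups = "drop")
  comps <- per_comp |>
    group_by(.data$transcript_id, .data$subfamily, .data$family,
             .data$te_type) |>
    summarise(bp = sum(.data$bp), .groups = "drop") |>
    nest(components = c("subfamily", "family", "te_type", "bp"))

  first_exon <- exons |>
    filter(.data$exon_rank == 1) |>
    left_join(select(transcripts, "transcript_id", "chrom", "strand"),
              by = "transcript_id") |>
    mutate(
      first_exon_length = .data$end - .data$start,
      tss = ifelse(.data$strand == "-", .data$end - 1L, .data$start)
    )
  tss_gr <- GenomicRanges::GRanges(
    seqnames = first_exon$chrom,
    ranges = IRanges::IRanges(start = first_exon$tss + 1L, width = 1L)
  )
  first_exon$tss_in_te <- GenomicRanges::countOverlaps(tss_gr, tgr) > 0

  base |>
    left_join(totals, by = "transcript_id") |>
    left_join(first_bp, by = "transcript_id") |>
    left_join(select(first_exon, "transcript_id", "first_exon_length",
                     "tss_in_te"),
              by = "transcript_id") |>
    left_join(comps, by = "transcript_id") |>
    mutate(
      exonic_te_bp = coalesce(.data$exonic_te_bp, 0L),
      first_exon_te_bp = coalesce(.data$first_exon_te_bp, 0L),
      te_fraction = .data$exonic_te_bp / .data$exonic_length,
      components = map(.data$components, ~ if (is.null(.x)) empty_comp else
        mutate(.x, fraction = NA_real_))
    ) |>
    mutate(components = map2(.data$components, .data$exonic_length,
                             ~ mutate(.x, fraction = .data$bp / .y))) |>
    select("transcript_id", "exonic_length", "exonic_te_bp", "te_fraction",
           "first_exon_length", "first_exon_te_bp", "tss_in_te",
           "components") |>
    arrange(match(.data$transcript_id, tx_ids))
}

#' Three-way transcript classification from a TE overlap profile
#'
#' A transcript is `TE_alone` (autonomously expressed from a TE locus) when
#' more than `te_fraction_min` of its exonic sequence lies within TE
#' annotation and its first exon shows TE evidence (by default the TSS base
#' lies inside a TE copy, i.e. TE promoter-driven transcription; the
#' alternative rule requires at least half the first-exon bases in TE).
#' Otherwise it is `TE_gene` when the exonic TE overlap reaches `min_te_bp`
#' (10 bp, the smallest annotated TE fragment), else `gene`. Overlaps of
#' 1-9 bp therefore fall to `gene`.
#'
#' @param profile Tibble from [compute_te_overlap()].
#' @param te_fraction_min Exonic TE fraction above which a transcript can be
#'   TE-alone (default 0.9; the rule is strict: fraction must exceed it).
#' @param min_te_bp Minimum exonic TE overlap for TE-gene (default 10).
#' @param first_exon_rule `"tss"` (default) or `"half"`.
#' @return Character vector of class labels, parallel to `profile` rows.
#' @export
classify_transcript <- function(profile, te_fraction_min = 0.9,
                                min_te_bp = 10,
                                first_exon_rule = c("tss", "half")) {
  first_exon_rule <- match.arg(first_exon_rule)
  first_ok <- if (first_exon_rule == "tss") {
    profile$tss_in_te
  } else {
    profile$first_exon_te_bp >= 0.5 * profile$first_exon_length
  }
  case_when(
    profile$te_fraction > te_fraction_min & first_ok ~ "TE_alone",
    profile$exonic_te_bp >= min_te_bp ~ "TE_gene",
    .default = "gene"
  )
}

#' TE-fraction bin labels
#'
#' Bins `[0,20) [20,40) [40,60) [60,80) [80,100]` on the percent scale, the
#' five subgroups used for TE-gene chimeric transcripts.
#'
#' @param te_fraction Numeric fractions in `[0, 1]`.
#' @return Factor with levels `0-20`, `20-40`, `40-60`, `60-80`, `80-100`.
#' @export
te_fraction_bin <- function(te_fraction) {
  cut(100 * te_fraction, breaks = c(0, 20, 40, 60, 80, 100.000001),
      right = FALSE, include.lowest = TRUE,
      labels = c("0-20", "20-40", "40-60", "60-80", "80-100"))
}

#' Major/minor TE components of TE-alone transcripts
#'
#' The major component is the subfamily contributing the largest fraction of
#' the transcript; a TE-alone transcript is chimeric when at least two
#' distinct subfamilies contribute. Exact fraction ties are broken toward the
#' lexicographically smaller subfamily and flagged.
#'
#' @param profile Tibble from [compute_te_overlap()] with a `components`
#'   list-column. TE-alone rows must have non-empty components.
#' @param classes Class labels parallel to `profile` (used only to validate
#'   TE-alone rows).
#' @return Tibble: `transcript_id`, `major_subfamily`, `major_family`,
#'   `major_te_type`, `chimeric`, `major_tie`; all NA/FALSE for transcripts
#'   without TE components.
#' @export
resolve_chimera <- function(profile, classes = NULL) {
  if (!is.null(classes)) {
    bad <- classes == "TE_alone" &
      map_int(profile$components, nrow) == 0
    if (any(bad)) {
      abort(paste0("TE_alone entry with no TE components: ",
                   paste(profile$transcript_id[bad], collapse = ", ")))
    }
  }
  res <- map2(profile$components, profile$transcript_id, function(cmp, id) {
    if (nrow(cmp) == 0) {
      return(tibble(transcript_id = id, major_subfamily = NA_character_,
                    major_family = NA_character_,
                    major_te_type = NA_character_,
                    chimeric = FALSE, major_tie = FALSE))
    }
    bysub <- cmp |>
      group_by(.data$subfamily) |>
      summarise(family = first(.data$family), te_type = first(.data$te_type),
                fraction = sum(.data$fraction), .groups = "drop") |>
      arrange(desc(.data$fraction), .data$subfamily)
    tie <- nrow(bysub) > 1 && bysub$fraction[2] == bysub$fraction[1]
    tibble(transcript_id = id, major_subfamily = bysub$subfamily[1],
           major_family = bysub$family[1], major_te_type = bysub$te_type[1],
           chimeric = nrow(bysub) >= 2, major_tie = tie)
  })
  list_rbind(res)
}

#' Build the transcript classification catalog
#'
#' Chains [compute_te_overlap()], [classify_transcript()],
#' [te_fraction_bin()] and [resolve_chimera()] into the full per-transcript
#' catalog. Classification is a partition: every transcript receives exactly
#' one class.
#'
#' @inheritParams compute_te_overlap
#' @inheritParams classify_transcript
#' @return Catalog tibble: `transcript_id`, `gene_id`, `class`,
#'   `exonic_length`, `exonic_te_bp`, `te_fraction`, `te_fraction_bin`,
#'   `first_exon_te_bp`, `tss_in_te`, `major_subfamily`, `major_family`,
#'   `major_te_type`, `chimeric`, `major_tie`, `components` (list-column).
#' @export
classify_transcripts <- function(transcripts, exons, copies,
                                 te_fraction_min = 0.9, min_te_bp = 10,
                                 first_exon_rule = c("tss", "half")) {
  profile <- compute_te_overlap(transcripts, exons, copies)
  cls <- classify_transcript(profile, te_fraction_min, min_te_bp,
                             match.arg(first_exon_rule))
  major <- resolve_chimera(profile, cls)
  profile |>
    mutate(class = cls, te_fraction_bin = te_fraction_bin(.data$te_fraction),
           chimeric = major$chimeric & cls == "TE_alone") |>
    left_join(select(major, -"chimeric"), by = "transcript_id") |>
    left_join(select(transcripts, "transcript_id", "gene_id"),
              by = "transcript_id") |>
    select("transcript_id", "gene_id", "class", "exonic_length",
           "exonic_te_bp", "te_fraction", "te_fraction_bin",
           "first_exon_te_bp", "tss_in_te", "major_subfamily",
           "major_family", "major_te_type", "chimeric", "major_tie",
           "components")
}

#' Read-support and expression filter
#'
#' Keeps a transcript according to its novelty label: annotated (`known`)
#' transcripts need at least 1 supporting read at some stage, novel
#' transcripts from a known locus at least 3, and novel transcripts from an
#' unannotated locus at least 2. In addition, transcripts below 1 TPM at
#' every stage are dropped, except autonomously expressed TE (TE-alone)
#' transcripts.
#'
#' @param counts Count tibble (`transcript_id` + stage columns).
#' @param novelty Tibble mapping `transcript_id` to `novelty` in
#'   `{known, novel_known_locus, novel_novel_locus}`.
#' @param tpm Optional TPM tibble for the low-expression filter (computed
#'   from `counts` when `NULL`).
#' @param te_alone_ids Transcript ids exempt from the TPM filter.
#' @param min_reads Named minima per novelty label.
#' @param min_tpm Low-expression cutoff (default 1; a transcript must reach
#'   it at some stage).
#' @return Tibble: `transcript_id`, `keep`, `reason` (`"ok"`,
#'   `"low_support"`, or `"low_tpm"`).
#' @export
filter_by_support <- function(counts, novelty, tpm = NULL,
                              te_alone_ids = character(),
                              min_reads = c(known = 1,
                                            novel_known_locus = 3,
                                            novel_novel_locus = 2),
                              min_tpm = 1) {
  sc <- assert_stages(counts)
  unknown <- setdiff(unique(novelty$novelty), names(min_reads))
  if (length(unknown) > 0) {
    abort(paste0("unknown novelty label: ", paste(unknown, collapse = ", ")))
  }
  tpm <- tpm %||% tpm_normalize(counts)
  maxc <- apply(as.matrix(counts[, sc, drop = FALSE]), 1, max)
  maxt <- apply(as.matrix(tpm[, sc, drop = FALSE]), 1, max)[
    match(counts$transcript_id, tpm$transcript_id)]
  counts |>
    select("transcript_id") |>
    mutate(max_count = maxc, max_tpm = maxt) |>
    inner_join(novelty, by = "transcript_id") |>
    mutate(
      support_ok = .data$max_count >= unname(min_reads[.data$novelty]),
      tpm_ok = .data$max_tpm >= min_tpm |
        .data$transcript_id %in% te_alone_ids,
      keep = .data$support_ok & .data$tpm_ok,
      reason = case_when(!.data$support_ok ~ "low_support",
                         !.data$tpm_ok ~ "low_tpm",
                         .default = "ok")
    ) |>
    select("transcript_id", "keep", "reason")
}

align_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Merge redundant transcript models
#'
#' Collapses near-identical transcript models arising from incomplete reads.
#' Annotated transcripts and TE-alone candidates are treated as true
#' transcripts and never merged. ISM (incomplete splice match) transcripts
#' cluster at >= 98% global identity; NIC/NNC (novel) transcripts only at
#' 100% identity, to minimize the loss of genuinely novel isoforms. Merging
#' never crosses structural categories. Clustering is greedy longest-first;
#' the representative is the longest member and cluster counts are summed
#' onto it. Identity is matches / alignment length of a global alignment
#' with gaps penalized.
#'
#' @param transcripts Transcript tibble with `transcript_id` and
#'   `structural_category` in `{annotated, ISM, NIC, NNC, other}`.
#' @param sequences Named character vector of transcript sequences.
#' @param counts Optional count tibble; cluster counts are summed onto
#'   representatives.
#' @param exclude_ids Transcript ids never merged (TE-alone candidates).
#' @param ism_identity Identity threshold for ISM clustering (default 0.98).
#' @return List with `clusters` (`transcript_id`, `cluster_id`,
#'   `representative`) and, when `counts` is given, `counts` (summed, one row
#'   per representative).
#' @export
merge_redundant <- function(transcripts, sequences, counts = NULL,
                            exclude_ids = character(),
                            ism_identity = 0.98) {
  mergeable <- transcripts |>
    filter(.data$structural_category %in% c("ISM", "NIC", "NNC"),
           !(.data$transcript_id %in% exclude_ids))
  missing <- setdiff(mergeable$transcript_id, names(sequences))
  if (length(missing) > 0) {
    abort(paste0("missing sequence for: ", paste(missing, collapse = ", ")))
  }
  assign_clusters <- function(ids, threshold) {
    lens <- nchar(sequences[ids])
    ids <- ids[order(-lens, ids)]
    cluster <- setNames(rep(NA_character_, length(ids)), ids)
    for (id in ids) {
      if (!is.na(cluster[id])) next
      cluster[id] <- id
      rest <- ids[is.na(cluster[ids])]
      for (other in rest) {
        idv <- if (threshold >= 1) {
          as.numeric(sequences[id] == sequences[other])
        } else {
          align_identity(sequences[id], sequences[other])
        }
        if (idv >= threshold) cluster[other] <- id
      }
    }
    cluster
  }
  out <- transcripts |>
    select("transcript_id", "structural_category") |>
    mutate(cluster_id = .data$transcript_id)
  for (cat in c("ISM", "NIC", "NNC")) {
    ids <- mergeable$transcript_id[mergeable$structural_category == cat]
    if (length(ids) < 2) next
    thr <- if (cat == "ISM") ism_identity else 1
    cl <- assign_clusters(ids, thr)
    out$cluster_id[match(names(cl), out$transcript_id)] <- unname(cl)
  }
  out <- out |>
    mutate(representative = .data$transcript_id == .data$cluster_id) |>
    select("transcript_id", "cluster_id", "representative")
  res <- list(clusters = out)
  if (!is.null(counts)) {
    sc <- assert_stages(counts)
    res$counts <- counts |>
      inner_join(out, by = "transcript_id") |>
      group_by(transcript_id = .data$cluster_id) |>
      summarise(across(all_of(sc), sum), .groups = "drop")
  }
  res
}

#' Splice-signal survey
#'
#' Extracts every intron's donor and acceptor dinucleotides on the
#' transcript's coding strand and scores them canonical when they read
#' GT..AG (GU-AG on the RNA). Single-exon transcripts contribute no introns;
#' introns shorter than 4 bp are counted non-canonical with a warning.
#'
#' @param transcripts,exons Transcript model tibbles.
#' @param genome Named character vector of chromosome sequences.
#' @param groups Optional tibble (`transcript_id`, `group`) for the summary
#'   (e.g. the catalog's major TE type).
#' @return List with `introns` (per-intron tibble: `transcript_id`, `start`,
#'   `end`, `donor`, `acceptor`, `canonical`) and `summary` (per-group
#'   canonical fraction; `NULL` without `groups`).
#' @export
splice_signal_stats <- function(transcripts, exons, genome, groups = NULL) {
  revcomp <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""), character(1)))
  }
  introns <- exons |>
    left_join(select(transcripts, "transcript_id", "chrom", "strand"),
              by = "transcript_id") |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(
      chrom = first(.data$chrom), strand = first(.data$strand),
      istart = head(.data$end, -1), iend = tail(.data$start, -1)
    ) |>
    rename(start = "istart", end = "iend")
  if (nrow(introns) == 0) {
    return(list(introns = tibble(transcript_id = character(),
                                 start = integer(), end = integer(),
                                 donor = character(), acceptor = character(),
                                 canonical = logical()),
                summary = NULL))
  }
  short <- introns$end - introns$start < 4
  if (any(short)) warn(paste0(sum(short), " intron(s) shorter than 4 bp"))
  left2 <- substr(genome[introns$chrom], introns$start + 1, introns$start + 2)
  right2 <- substr(genome[introns$chrom], introns$end - 1, introns$end)
  donor <- ifelse(introns$strand == "-", unname(revcomp(right2)),
                  unname(left2))
  acceptor <- ifelse(introns$strand == "-", unname(revcomp(left2)),
                     unname(right2))
  introns <- introns |>
    mutate(donor = donor, acceptor = acceptor,
           canonical = donor == "GT" & acceptor == "AG" & !short) |>
    select("transcript_id", "start", "end", "donor", "acceptor", "canonical")
  summary <- NULL
  if (!is.null(groups)) {
    summary <- introns |>
      inner_join(groups, by = "transcript_id") |>
      group_by(.data$group) |>
      summarise(n_introns = n(),
                canonical_fraction = mean(.data$canonical),
                .groups = "drop")
  }
  list(introns = introns, summary = summary)
}

required_domains <- list(
  DNA = c("TP"),
  LINE = c("APE", "RT"),
  LTR = c("GAG", "AP", "RT", "RH", "INT"),
  ERV = c("GAG", "AP", "RT", "RH", "INT", "ENV")
)

domain_vocabulary <- c("TP", "APE", "RT", "GAG", "AP", "RH", "INT", "ENV")

#' Conserved-domain class of TE transcripts
#'
#' From a per-transcript domain-presence table (domain scanning itself is an
#' input, not performed here): transcripts without an ORF are `no_orf`; a
#' transcript with an ORF is `complete` when it retains all core domains
#' required for its TE type (DNA transposon: TP; LINE: APE + RT; LTR:
#' GAG + AP + RT + RH + INT; ERV additionally ENV), else `partial`.
#'
#' @param domains Tibble: `transcript_id`, `te_type` in
#'   `{DNA, LINE, LTR, ERV}`, `has_orf` (logical), `present_domains`
#'   (list-column of character vectors, or a comma-separated string column).
#' @return Input tibble with a `domain_class` column in
#'   `{no_orf, partial, complete}`.
#' @export
classify_domains <- function(domains) {
  pres <- domains$present_domains
  if (is.character(pres)) {
    pres <- map(pres, ~ if (is.na(.x) || .x == "") character() else
      strsplit(.x, ",\\s*")[[1]])
  }
  bad_type <- setdiff(unique(domains$te_type), names(required_domains))
  if (length(bad_type) > 0) {
    abort(paste0("unknown te_type: ", paste(bad_type, collapse = ", ")))
  }
  bad <- setdiff(unique(unlist(pres)), domain_vocabulary)
  if (length(bad) > 0) {
    abort(paste0("domain not in vocabulary: ", paste(bad, collapse = ", ")))
  }
  domains |>
    mutate(domain_class = pmap(
      list(.data$has_orf, .data$te_type, pres),
      function(orf, type, dom) {
        if (!orf) return("no_orf")
        if (all(required_domains[[type]] %in% dom)) "complete" else "partial"
      }
    ) |> unlist())
}

#' Structural summary per TE type
#'
#' Per TE type of the TE-alone catalog: the percentage of transcripts with
#' multiple exons and the percentage of loci expressing multiple isoforms.
#' When an LTR parts table is supplied, LTR loci are additionally called
#' intact (5'LTR + internal + 3'LTR all annotated) or truncated (any part
#' missing), with single-part losses flagged separately.
#'
#' @param catalog Catalog tibble from [classify_transcripts()] (TE-alone
#'   entries are summarized by `major_te_type`).
#' @param exons Exon tibble (to count exons per transcript).
#' @param ltr_parts Optional tibble: `locus_id`, `has_ltr5`, `has_internal`,
#'   `has_ltr3`.
#' @return List with `by_type` (per-type tibble: `n_transcripts`,
#'   `n_multi_exon`, `multi_exon_pct`, `n_loci`, `n_multi_isoform_loci`,
#'   `multi_isoform_pct`) and `ltr` (`locus_id`, `intact_call`,
#'   `single_loss`; `NULL` without `ltr_parts`).
#' @export
structure_summary <- function(catalog, exons, ltr_parts = NULL) {
  nex <- exons |> count(.data$transcript_id, name = "n_exons")
  te <- catalog |>
    filter(.data$class == "TE_alone") |>
    left_join(nex, by = "transcript_id")
  by_type <- te |>
    group_by(te_type = .data$major_te_type) |>
    summarise(
      n_transcripts = n(),
      n_multi_exon = sum(.data$n_exons >= 2),
      multi_exon_pct = percentage(sum(.data$n_exons >= 2), n()),
      n_loci = n_distinct(.data$gene_id),
      n_multi_isoform_loci = sum(table(.data$gene_id) >= 2),
      multi_isoform_pct = percentage(sum(table(.data$gene_id) >= 2),
                                     n_distinct(.data$gene_id)),
      .groups = "drop"
    )
  ltr <- NULL
  if (!is.null(ltr_parts)) {
    ltr <- ltr_parts |>
      mutate(
        n_missing = (!.data$has_ltr5) + (!.data$has_internal) +
          (!.data$has_ltr3),
        intact_call = ifelse(.data$n_missing == 0, "intact", "truncated"),
        single_loss = .data$n_missing == 1
      ) |>
      select("locus_id", "intact_call", "single_loss")
  }
  list(by_type = by_type, ltr = ltr)
}
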