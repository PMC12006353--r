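#' Kimura two-parameter distance
#'
#' Transition/transversion-corrected evolutionary distance
#' \eqn{K = -\frac{1}{2}\ln\left[(1-2p-q)\sqrt{1-2q}\right]}, where `p` is
#' the observed transition fraction and `q` the transversion fraction.
#' Vectorized over `p` and `q`.
#'
#' @param p Transition fraction(s), per aligned (ungapped, non-N) site.
#' @param q Transversion fraction(s).
#' @param percent If `TRUE`, return the distance in percent (the RepeatMasker
#'   serialization convention). Default `FALSE` (substitutions per site).
#' @return Numeric vector of distances.
#' @export
kimura2p <- function(p, q, percent = FALSE) {
  if (any(p < 0 | q < 0)) abort("p and q must be non-negative")
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  if (any(a <= 0 | b <= 0)) {
    abort("divergence too high: Kimura correction undefined (1-2p-q or 1-2q <= 0)")
  }
  k <- -0.5 * log(a * sqrt(b))
  if (percent) 100 * k else k
}

#' Summarize a pairwise alignment into substitution fractions
#'
#' Counts transitions (A<->G, C<->T) and transversions over aligned columns,
#' excluding gap columns and ambiguous bases (N) from both the counts and the
#' aligned length. If the inputs are unaligned, an end-gap-free global
#' alignment (Biostrings) is computed first.
#'
#' @param query,subject Character scalars (DNA). If `aligned = TRUE` they must
#'   be equal-length gapped alignment strings.
#' @param aligned Whether the inputs are already aligned.
#' @return One-row tibble: `aligned_length` (ungapped, non-N columns), `p`
#'   (transition fraction), `q` (transversion fraction), `d` (= p + q),
#'   `identity` (= 1 - d), `query_coverage`, `subject_coverage`.
#' @export
alignment_summary <- function(query, subject, aligned = FALSE) {
  if (!aligned) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      type = "global"
    )
    qs <- as.character(Biostrings::alignedPattern(aln))
    ss <- as.character(Biostrings::alignedSubject(aln))
  } else {
    qs <- str_to_upper(query)
    ss <- str_to_upper(subject)
    if (nchar(qs) != nchar(ss)) abort("aligned strings must have equal length")
  }
  qc <- strsplit(qs, "")[[1]]
  sc <- strsplit(ss, "")[[1]]
  ok <- qc %in% c("A", "C", "G", "T") & sc %in% c("A", "C", "G", "T")
  qc <- qc[ok]; sc <- sc[ok]
  n <- length(qc)
  if (n == 0) abort("no aligned unambiguous columns")
  purine <- c("A", "G")
  diff <- qc != sc
  ts <- diff & ((qc %in% purine) == (sc %in% purine))
  tv <- diff & !ts
  qlen <- sum(strsplit(gsub("-", "", qs), "")[[1]] %in% c("A", "C", "G", "T", "N"))
  slen <- sum(strsplit(gsub("-", "", ss), "")[[1]] %in% c("A", "C", "G", "T", "N"))
  tibble(
    aligned_length = n,
    p = sum(ts) / n,
    q = sum(tv) / n,
    d = sum(diff) / n,
    identity = 1 - sum(diff) / n,
    query_coverage = n / qlen,
    subject_coverage = n / slen
  )
}

#' Intactness call for a TE copy
#'
#' A copy is intact when it covers at least 80% of its subfamily consensus
#' and has lost no more than 30 bp at the 5' end and no more than 100 bp at
#' the 3' end; any other copy is truncated. Vectorized.
#'
#' @param consensus_coverage Fraction of the consensus covered by the copy.
#' @param loss5,loss3 Consensus bp missing at the 5' / 3' end.
#' @param min_coverage,max_loss5,max_loss3 Rule thresholds.
#' @return Character vector, `"intact"` or `"truncated"`.
#' @export
classify_intact <- function(consensus_coverage, loss5, loss3,
                            min_coverage = 0.8, max_loss5 = 30,
                            max_loss3 = 100) {
  ifelse(consensus_coverage >= min_coverage & loss5 <= max_loss5 &
           loss3 <= max_loss3, "intact", "truncated")
}

#' Jukes-Cantor LTR insertion age
#'
#' The two long terminal repeats of an LTR element are identical at insertion;
#' their present-day divergence `d` dates the insertion via the Jukes-Cantor
#' correction \eqn{K = -\frac{3}{4}\ln(1 - \frac{4d}{3})} and
#' \eqn{T = K / (2\mu)} with a neutral substitution rate \eqn{\mu} per site
#' per year (default 1.46e-8, fish genomic evolution). Vectorized over `d`.
#'
#' @param d Inter-LTR divergence (fraction of differing sites,
#'   `d = 1 - identity`), in `[0, 0.75)`.
#' @param mu Neutral substitution rate per site per year.
#' @return Insertion age(s) in years.
#' @export
ltr_insertion_time <- function(d, mu = 1.46e-8) {
  if (any(d < 0 | d >= 0.75)) {
    abort("d must be in [0, 0.75): Jukes-Cantor correction saturates at 0.75")
  }
  k <- -0.75 * log(1 - 4 * d / 3)
  k / (2 * mu)
}

#' Compare Kimura divergence between active and silent copies
#'
#' Splits TE copies into active (members of the expressed catalog) and silent
#' sets and, per TE type, reports the divergence distributions' medians and a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param copies TE copy tibble with `copy_id`, `te_type`,
#'   `kimura_divergence`.
#' @param active_ids Copy ids that underlie expressed (catalog) loci.
#' @return Tibble per `te_type`: `n_active`, `n_silent`, `median_active`,
#'   `median_silent`, `p_value`.
#' @export
compare_kd <- function(copies, active_ids) {
  if (length(active_ids) == 0) abort("active set is empty")
  copies |>
    mutate(active = .data$copy_id %in% active_ids) |>
    group_by(.data$te_type) |>
    summarise(
      n_active = sum(.data$active),
      n_silent = sum(!.data$active),
      median_active = median(.data$kimura_divergence[.data$active]),
      median_silent = median(.data$kimura_divergence[!.data$active]),
      p_value = if (sum(.data$active) > 0 && sum(!.data$active) > 0) {
        wilcox.test(.data$kimura_divergence[.data$active],
                    .data$kimura_divergence[!.data$active],
                    alternative = "two.sided", exact = FALSE)$p.value
      } else NA_real_,
      .groups = "drop"
    )
}

#' Strain-presence age group for TE-alone loci
#'
#' Assigns each locus to an evolutionary age group from its presence/absence
#' across the four zebrafish strains TU, AB, Nadia and CB, ordered young to
#' old along the strain phylogeny: `TU` (TU only), `TU-AB`, `TU-AB-Nadia`,
#' `TU-AB-Nadia-CB` (all four). `TU` and `TU-AB` form the young class, the
#' other two nested groups the old class. Presence patterns that are not
#' nested along the phylogeny (e.g. TU + Nadia without AB) are reported as
#' `inconsistent` / `unassigned`, never forced into a group.
#'
#' @param presence Tibble with `locus_id` and logical columns `tu`, `ab`,
#'   `nadia`, `cb`.
#' @return Tibble with `locus_id`, `group`, `age_class`.
#' @export
assign_strain_age <- function(presence) {
  presence |>
    mutate(
      group = case_when(
        .data$tu & !.data$ab & !.data$nadia & !.data$cb ~ "TU",
        .data$tu & .data$ab & !.data$nadia & !.data$cb ~ "TU-AB",
        .data$tu & .data$ab & .data$nadia & !.data$cb ~ "TU-AB-Nadia",
        .data$tu & .data$ab & .data$nadia & .data$cb ~ "TU-AB-Nadia-CB",
        .default = "inconsistent"
      ),
      age_class = case_when(
        .data$group %in% c("TU", "TU-AB") ~ "young",
        .data$group %in% c("TU-AB-Nadia", "TU-AB-Nadia-CB") ~ "old",
        .default = "unassigned"
      )
    ) |>
    select("locus_id", "group", "age_class")
}

#' Origin mechanism of a TE-alone locus
#'
#' Distinguishes segmental duplication from transposition from the best
#' non-self donor hit of each locus: a duplication copies the TE body
#' together with its flanking sequence, so both 500 bp flank windows align at
#' high identity; a transposition moves only the TE body, so the body aligns
#' but at least one flank does not. Loci without a donor hit are
#' `unclassified`.
#'
#' @param hits Tibble with one row per locus: `locus_id`, `donor_id` (NA when
#'   no hit), `te_identity`, `flank5_identity`, `flank5_coverage`,
#'   `flank3_identity`, `flank3_coverage` (identities/coverages in `[0,1]`,
#'   computed over `flank_window` bp windows).
#' @param min_identity Minimum alignment identity for a body or flank window
#'   to count as homologous (default 0.8).
#' @param min_flank_coverage Minimum fraction of the flank window that must
#'   align (default 0.5).
#' @param flank_window Flank window size in bp (recorded in the output).
#' @return Tibble: `locus_id`, `donor_id`, `mechanism` in
#'   `{segmental_duplication, transposition, unclassified}`.
#' @export
classify_origin <- function(hits, min_identity = 0.8,
                            min_flank_coverage = 0.5, flank_window = 500) {
  flank_ok <- function(id, cov) {
    !is.na(id) & !is.na(cov) & id >= min_identity & cov >= min_flank_coverage
  }
  hits |>
    mutate(
      body_ok = !is.na(.data$donor_id) & !is.na(.data$te_identity) &
        .data$te_identity >= min_identity,
      f5 = flank_ok(.data$flank5_identity, .data$flank5_coverage),
      f3 = flank_ok(.data$flank3_identity, .data$flank3_coverage),
      mechanism = case_when(
        is.na(.data$donor_id) ~ "unclassified",
        .data$body_ok & .data$f5 & .data$f3 ~ "segmental_duplication",
        .data$body_ok ~ "transposition",
        .default = "unclassified"
      ),
      flank_window = flank_window
    ) |>
    select("locus_id", "donor_id", "mechanism", "flank_window")
}
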