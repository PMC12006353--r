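# Small hand-built fixtures shared across tests. Coordinates are 0-based
# half-open, matching the package's internal convention.

mk_transcripts <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      transcript_id = r$id, gene_id = r$gene %||% r$id,
      chrom = r$chrom %||% "chr1", strand = r$strand %||% "+",
      novelty = r$novelty %||% "known",
      structural_category = r$category %||% "annotated"
    )
  }))
}

mk_exons <- function(id, exons, strand = "+") {
  k <- length(exons)
  rank <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
  tibble::tibble(
    transcript_id = id,
    exon_rank = rank,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2)
  ) |> dplyr::arrange(exon_rank)
}

mk_copies <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    tibble::tibble(
      copy_id = r$id %||% sprintf("TE%02d", i),
      chrom = r$chrom %||% "chr1",
      start = r$start, end = r$end, strand = r$strand %||% "+",
      subfamily = r$subfamily %||% "SFA",
      family = r$family %||% "FAM",
      te_type = r$te_type %||% "LTR",
      kimura_divergence = r$kd %||% 5,
      consensus_begin = r$cb %||% 1L,
      consensus_end = r$ce %||% as.integer(r$end - r$start),
      consensus_left = r$cl %||% 0L
    )
  }))
}

`%||%` <- rlang::`%||%`

# per-base bitmap oracle for exonic TE overlap (independent of the
# GenomicRanges-based implementation)
bitmap_te_bp <- function(exons_tbl, copies_tbl, chrom_len = 100000) {
  te <- logical(chrom_len)
  for (i in seq_len(nrow(copies_tbl))) {
    te[(copies_tbl$start[i] + 1):copies_tbl$end[i]] <- TRUE
  }
  sum(vapply(seq_len(nrow(exons_tbl)), function(i) {
    sum(te[(exons_tbl$start[i] + 1):exons_tbl$end[i]])
  }, numeric(1)))
}

# independent adjusted Rand index (mclust) with a tiny fallback
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
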