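#' Read a RepeatMasker .out annotation
#'
#' Parses the standard RepeatMasker `.out` layout (three header lines followed
#' by whitespace-delimited rows) into a tibble of TE copies. Coordinates are
#' converted from RepeatMasker's 1-based inclusive convention to the package's
#' internal 0-based half-open convention; rows on the complement strand
#' (`C`) are mapped to strand `-` and their consensus begin/left columns are
#' swapped back per the `.out` convention.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A tibble with one row per TE copy: `copy_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `subfamily`, `family`, `te_type`,
#'   `kimura_divergence` (the `% div` column, in percent), `consensus_begin`,
#'   `consensus_end`, `consensus_left`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readr::read_lines(path)
  # header: two column-name lines + one blank line (tolerate their absence)
  body <- lines[-seq_len(min(3L, length(lines)))]
  if (length(lines) >= 1 && !grepl("^\\s*\\d", lines[1])) {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    body <- body[grepl("^\\s*\\d", body)]
  } else {
    body <- lines[grepl("^\\s*\\d", lines)]
  }
  if (length(body) == 0) {
    return(tibble(
      copy_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), subfamily = character(),
      family = character(), te_type = character(),
      kimura_divergence = double(), consensus_begin = integer(),
      consensus_end = integer(), consensus_left = integer()
    ))
  }
  strip_paren <- function(x) as.integer(gsub("[()]", "", x))
  rows <- map2(body, seq_along(body), function(line, i) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 14) {
      abort(paste0("malformed RepeatMasker row at line ", i, ": ", line))
    }
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    # consensus columns: '+' rows are begin,end,(left); 'C' rows (left),end,begin
    if (strand == "+") {
      cb <- strip_paren(f[12]); ce <- strip_paren(f[13]); cl <- strip_paren(f[14])
    } else {
      cl <- strip_paren(f[12]); ce <- strip_paren(f[13]); cb <- strip_paren(f[14])
    }
    cls <- strsplit(f[11], "/")[[1]]
    tibble(
      copy_id = if (length(f) >= 15) f[15] else as.character(i),
      chrom = f[5],
      start = as.integer(f[6]) - 1L,
      end = as.integer(f[7]),
      strand = strand,
      subfamily = f[10],
      family = if (length(cls) > 1) cls[2] else cls[1],
      te_type = cls[1],
      kimura_divergence = as.numeric(f[2]),
      consensus_begin = cb, consensus_end = ce, consensus_left = cl
    )
  })
  out <- list_rbind(rows)
  bad <- which(out$start >= out$end | is.na(out$start) | is.na(out$end))
  if (length(bad)) {
    abort(paste0("malformed RepeatMasker row at line ", bad[1] + 3L,
                 ": start >= end"))
  }
  out
}

#' Write TE copies in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()]: internal 0-based half-open
#' coordinates are serialized back to 1-based inclusive, minus-strand rows are
#' written with strand `C` and swapped consensus columns.
#'
#' @param copies Tibble of TE copies as returned by [read_repeatmasker_out()]
#'   or [simulate_te_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(copies, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query           matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)  strand repeat    class/family  begin  end   (left)  ID",
    ""
  )
  rows <- pmap(copies, function(copy_id, chrom, start, end, strand, subfamily,
                                family, te_type, kimura_divergence,
                                consensus_begin, consensus_end, consensus_left,
                                ...) {
    st <- if (strand == "-") "C" else "+"
    c1 <- if (st == "C") paste0("(", consensus_left, ")") else consensus_begin
    c3 <- if (st == "C") consensus_begin else paste0("(", consensus_left, ")")
    paste(1000, sprintf("%.1f", kimura_divergence), "0.0", "0.0", chrom,
          start + 1L, end, "(0)", st, subfamily,
          paste0(te_type, "/", family), c1, consensus_end, c3, copy_id)
  })
  readr::write_lines(c(hdr, unlist(rows)), path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Imports exon features, groups them per transcript, and converts GTF 1-based
#' inclusive coordinates to the internal 0-based half-open convention. If a
#' counts table is given, per-stage counts are attached by `transcript_id`;
#' transcripts missing from it get all-zero counts with a warning. The stage
#' order is taken from the counts-file column order, never sorted.
#'
#' @param path GTF file with `exon` features carrying `transcript_id` and
#'   `gene_id` attributes (and optionally `novelty` and `structural_category`).
#' @param counts_path Optional TSV of per-stage counts keyed by
#'   `transcript_id`.
#' @return A list with `transcripts` (one row per transcript: ids, `chrom`,
#'   `strand`, `novelty`, `structural_category`), `exons` (one row per exon:
#'   `transcript_id`, `exon_rank` in transcript orientation, `start`, `end`)
#'   and, when `counts_path` is given, `counts`.
#' @export
read_gtf_transcripts <- function(path, counts_path = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    novelty = if (!is.null(gr$novelty)) gr$novelty else NA_character_,
    structural_category = if (!is.null(gr$structural_category))
      gr$structural_category else NA_character_
  )
  if (any(ex$end < ex$start)) abort("exon with end < start")
  multi_chrom <- ex |>
    distinct(.data$transcript_id, .data$chrom) |>
    count(.data$transcript_id) |>
    filter(.data$n > 1)
  if (nrow(multi_chrom) > 0) {
    abort(paste0("transcript_id on multiple chromosomes: ",
                 paste(multi_chrom$transcript_id, collapse = ", ")))
  }
  transcripts <- ex |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id), chrom = first(.data$chrom),
      strand = first(.data$strand), novelty = first(.data$novelty),
      structural_category = first(.data$structural_category),
      .groups = "drop"
    )
  # exon_rank follows transcript orientation: 5'-most exon first
  exons <- ex |>
    select("transcript_id", "strand", "start", "end") |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (first(.data$strand) == "-") rev(seq_len(n()))
           else seq_len(n())) |>
    ungroup() |>
    arrange(.data$transcript_id, .data$exon_rank) |>
    select("transcript_id", "exon_rank", "start", "end")
  out <- list(transcripts = transcripts, exons = exons)
  if (!is.null(counts_path)) {
    counts <- read_matrix(counts_path)
    missing <- setdiff(transcripts$transcript_id, counts$transcript_id)
    if (length(missing) > 0) {
      warn(paste0(length(missing),
                  " transcript(s) lack count rows; set to zero"))
      zero <- as_tibble(setNames(
        as.list(rep(0, ncol(counts) - 1L)), stage_cols(counts)))
      counts <- bind_rows(counts, tibble(transcript_id = missing, zero))
    }
    out$counts <- counts |>
      filter(.data$transcript_id %in% transcripts$transcript_id) |>
      arrange(match(.data$transcript_id, transcripts$transcript_id))
  }
  out
}

#' Write transcript models to GTF
#'
#' @param transcripts,exons Tibbles as returned by [read_gtf_transcripts()]
#'   or [simulate_transcriptome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(transcripts, exons, path) {
  ex <- exons |>
    left_join(transcripts, by = "transcript_id") |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "ztakit", type = "exon",
    transcript_id = ex$transcript_id, gene_id = ex$gene_id,
    novelty = ex$novelty, structural_category = ex$structural_category
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write a transcripts-by-stages matrix as TSV
#'
#' The first column is `transcript_id`; remaining columns are stages in
#' developmental order (column order is preserved, never sorted). Writes are
#' deterministic: rows sorted by `transcript_id`.
#'
#' @param x Tibble with a `transcript_id` column and numeric stage columns.
#' @param path File path.
#' @return For `read_matrix`, the tibble; for `write_matrix`, `path`
#'   invisibly.
#' @export
write_matrix <- function(x, path) {
  readr::write_tsv(arrange(x, .data$transcript_id), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read/write a transcript classification catalog as TSV
#'
#' Deterministic column order and row sort (by `transcript_id`) so that a
#' write/read round trip returns an identical object. List-columns (the
#' per-transcript TE component breakdown) are not serialized.
#'
#' @param entries Catalog tibble from [classify_transcripts()].
#' @param path File path.
#' @return For `read_catalog`, the tibble; for `write_catalog`, `path`
#'   invisibly.
#' @export
write_catalog <- function(entries, path) {
  flat <- entries |>
    select(!where(is.list)) |>
    arrange(.data$transcript_id)
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read/write sequences as FASTA
#'
#' Thin wrappers over Biostrings that keep the package's tibble-first surface.
#'
#' @param x Named character vector or `DNAStringSet`.
#' @param path File path.
#' @return For `read_fasta`, a named character vector; for `write_fasta`,
#'   `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read/write TE copies as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged. The BED name field holds `copy_id|subfamily`.
#'
#' @param copies TE copy tibble.
#' @param path File path.
#' @return For `read_bed6`, a tibble with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; for `write_bed6`, `path` invisibly.
#' @export
write_bed6 <- function(copies, path) {
  bed <- copies |>
    transmute(.data$chrom, .data$start, .data$end,
              name = paste0(.data$copy_id, "|", .data$subfamily),
              score = 0L, .data$strand) |>
    arrange(.data$chrom, .data$start)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                  show_col_types = FALSE, progress = FALSE)
}
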