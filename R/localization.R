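#' Relative nuclear/cytoplasmic proportion per group
#'
#' Absolute abundances are not comparable between the nuclear and cytosolic
#' compartments, so localization is summarized relatively: each group's share
#' of total nuclear abundance divided by its share of total cytosolic
#' abundance. A ratio above 1 indicates nuclear bias. Shares sum to 1 within
#' each compartment for any grouping scheme, and the statistic is invariant
#' to rescaling either compartment.
#'
#' Transcripts present in only one compartment table are treated as zero in
#' the other (the union of transcript ids is used); the stage columns of the
#' two tables must match.
#'
#' @param nuclear,cytosolic Tibbles with `transcript_id` and one or more
#'   identically named abundance (TPM) columns.
#' @param grouping Tibble mapping `transcript_id` to a `group` column; each
#'   transcript belongs to exactly one group. Transcripts without a group are
#'   dropped from the grouped shares but kept in the denominators.
#' @return Tibble per (`group`, `stage`): `p_nuc`, `p_cyt`, `ratio`
#'   (`NA` with `undefined = TRUE` when `p_cyt` is 0).
#' @export
group_nc_proportion <- function(nuclear, cytosolic, grouping) {
  sc_n <- assert_stages(nuclear)
  sc_c <- assert_stages(cytosolic)
  if (!identical(sc_n, sc_c)) abort("nuclear/cytosolic stage columns differ")
  if (anyDuplicated(grouping$transcript_id)) {
    abort("grouping assigns a transcript to more than one group")
  }
  ids <- union(nuclear$transcript_id, cytosolic$transcript_id)
  fill <- function(x) {
    miss <- setdiff(ids, x$transcript_id)
    if (length(miss)) {
      zero <- as_tibble(setNames(as.list(rep(0, length(sc_n))), sc_n))
      x <- bind_rows(x, tibble(transcript_id = miss, zero))
    }
    x
  }
  long <- function(x, compartment) {
    fill(x) |>
      pivot_longer(all_of(sc_n), names_to = "stage", values_to = "tpm") |>
      mutate(compartment = compartment)
  }
  both <- bind_rows(long(nuclear, "nuc"), long(cytosolic, "cyt")) |>
    group_by(.data$compartment, .data$stage) |>
    mutate(total = sum(.data$tpm)) |>
    ungroup() |>
    inner_join(grouping, by = "transcript_id")
  shares <- both |>
    group_by(.data$compartment, .data$stage, .data$group) |>
    summarise(share = sum(.data$tpm) / first(.data$total), .groups = "drop") |>
    pivot_wider(names_from = "compartment", values_from = "share",
                names_prefix = "p_") |>
    mutate(
      ratio = ifelse(.data$p_cyt > 0, .data$p_nuc / .data$p_cyt, NA_real_),
      undefined = .data$p_cyt == 0
    ) |>
    arrange(.data$group, match(.data$stage, sc_n))
  shares
}

#' Sanity benchmark: lincRNA versus protein-coding localization
#'
#' lincRNAs are expected to be nuclear-biased and protein-coding transcripts
#' cytoplasm-biased; this benchmark computes the relative N/C proportion of
#' the two groups, restricted to zygotic transcripts (maternally deposited
#' ones are removed first), and reports whether the expected ordering holds.
#'
#' @param nuclear,cytosolic As in [group_nc_proportion()].
#' @param lincRNA_ids,coding_ids Transcript id sets for the two groups.
#' @param zygotic_ids Optional transcript ids to keep (the zygotic set);
#'   `NULL` keeps all.
#' @return Tibble per stage: `ratio_lincRNA`, `ratio_coding`, `verdict`
#'   (`TRUE` when lincRNA > coding; `NA` when either group is empty or
#'   undefined).
#' @export
benchmark_nc <- function(nuclear, cytosolic, lincRNA_ids, coding_ids,
                         zygotic_ids = NULL) {
  grouping <- bind_rows(
    tibble(transcript_id = lincRNA_ids, group = "lincRNA"),
    tibble(transcript_id = coding_ids, group = "coding")
  )
  if (!is.null(zygotic_ids)) {
    grouping <- filter(grouping, .data$transcript_id %in% zygotic_ids)
  }
  if (!all(c("lincRNA", "coding") %in% grouping$group)) {
    warn("empty lincRNA or coding set after maternal removal")
  }
  props <- group_nc_proportion(nuclear, cytosolic, grouping)
  wide <- props |>
    select("group", "stage", "ratio") |>
    pivot_wider(names_from = "group", values_from = "ratio",
                names_prefix = "ratio_")
  if (!"ratio_lincRNA" %in% names(wide)) wide$ratio_lincRNA <- NA_real_
  if (!"ratio_coding" %in% names(wide)) wide$ratio_coding <- NA_real_
  mutate(wide, verdict = .data$ratio_lincRNA > .data$ratio_coding)
}

#' Per-transcript relative N/C value
#'
#' `(tpm_nuc / total_nuc) / (tpm_cyt / total_cyt)` per transcript and stage;
#' the per-transcript analogue of [group_nc_proportion()].
#'
#' @inheritParams group_nc_proportion
#' @return Tibble: `transcript_id`, `stage`, `nc_value` (`NA` where the
#'   cytosolic share is 0).
#' @export
transcript_nc_value <- function(nuclear, cytosolic) {
  sc <- assert_stages(nuclear)
  if (!identical(sc, assert_stages(cytosolic))) {
    abort("nuclear/cytosolic stage columns differ")
  }
  grouping <- tibble(
    transcript_id = union(nuclear$transcript_id, cytosolic$transcript_id)
  ) |> mutate(group = .data$transcript_id)
  group_nc_proportion(nuclear, cytosolic, grouping) |>
    transmute(transcript_id = .data$group, .data$stage,
              nc_value = .data$ratio)
}

#' Regression of localization on TE sequence fraction
#'
#' Tests for a linear relationship between the relative N/C proportion of
#' TE-gene chimeric transcripts and the fraction of TE sequence they carry.
#' By default the five TE-fraction bins (0-20 ... 80-100%) are the units:
#' the bin-level relative N/C proportions are regressed on bin midpoints
#' (10, 30, 50, 70, 90). A per-transcript mode regresses transcript N/C
#' values on te_fraction directly.
#'
#' @param catalog Catalog tibble with `transcript_id`, `te_fraction` and
#'   `te_fraction_bin` (TE-gene entries are used).
#' @param nuclear,cytosolic Abundance tibbles as in [group_nc_proportion()];
#'   a single stage column is expected for the regression.
#' @param level `"bin"` (default) or `"transcript"`.
#' @return Object of class `nc_regression` wrapping the `lm` fit, with
#'   `tidy()`, `glance()` and `autoplot()` methods. `glance()` reports
#'   `slope`, `intercept`, `r`, `r_squared`, `n`.
#' @export
te_fraction_regression <- function(catalog, nuclear, cytosolic,
                                   level = c("bin", "transcript")) {
  level <- match.arg(level)
  entries <- filter(catalog, .data$class == "TE_gene")
  if (nrow(entries) == 0) abort("no TE-gene entries in catalog")
  if (level == "bin") {
    props <- group_nc_proportion(
      nuclear, cytosolic,
      entries |> transmute(.data$transcript_id,
                           group = as.character(.data$te_fraction_bin))
    )
    mids <- c("0-20" = 10, "20-40" = 30, "40-60" = 50, "60-80" = 70,
              "80-100" = 90)
    data <- props |>
      filter(!.data$undefined) |>
      transmute(x = unname(mids[.data$group]), y = .data$ratio,
                unit = .data$group)
  } else {
    vals <- transcript_nc_value(nuclear, cytosolic)
    data <- entries |>
      inner_join(vals, by = "transcript_id") |>
      filter(!is.na(.data$nc_value)) |>
      transmute(x = 100 * .data$te_fraction, y = .data$nc_value,
                unit = .data$transcript_id)
  }
  if (nrow(data) < 2) abort("fewer than 2 points for regression")
  fit <- lm(y ~ x, data = data)
  r <- suppressWarnings(cor(data$x, data$y))
  structure(list(fit = fit, data = data, level = level, r = r),
            class = "nc_regression")
}

#' @export
print.nc_regression <- function(x, ...) {
  g <- glance(x)
  cat("N/C ~ TE fraction (", x$level, " level): slope = ",
      signif(g$slope, 4), ", r = ", signif(g$r, 4), ", n = ", g$n, "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.nc_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @export
glance.nc_regression <- function(x, ...) {
  cf <- coef(x$fit)
  tibble(
    slope = unname(cf[2]), intercept = unname(cf[1]), r = x$r,
    r_squared = suppressWarnings(summary(x$fit))$r.squared, n = nrow(x$data)
  )
}

#' @export
autoplot.nc_regression <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = "TE fraction (%)", y = "relative N/C proportion") +
    theme_bw()
}
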