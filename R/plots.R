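#' Class composition barplot
#'
#' Quick QC view of the catalog: transcript counts per class, optionally
#' split by major TE type.
#'
#' @param catalog Catalog tibble from [classify_transcripts()].
#' @param by_type Facet TE-alone entries by major TE type.
#' @return A ggplot object.
#' @export
plot_class_composition <- function(catalog, by_type = FALSE) {
  p <- ggplot(count(catalog, .data$class),
              aes(x = .data$class, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "transcripts") +
    theme_bw()
  if (by_type) {
    dat <- catalog |>
      filter(.data$class == "TE_alone") |>
      count(.data$major_te_type)
    p <- ggplot(dat, aes(x = .data$major_te_type, y = .data$n)) +
      geom_col() +
      labs(x = NULL, y = "TE-alone transcripts") +
      theme_bw()
  }
  p
}

#' Relative N/C proportion plot
#'
#' Dot plot of group localization ratios per stage; the horizontal unit line
#' separates nuclear- from cytoplasm-biased groups.
#'
#' @param nc Tibble from [group_nc_proportion()].
#' @return A ggplot object.
#' @export
plot_nc_proportion <- function(nc) {
  ggplot(nc, aes(x = .data$group, y = .data$ratio)) +
    geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~stage) +
    labs(x = NULL, y = "relative N/C proportion") +
    theme_bw()
}
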