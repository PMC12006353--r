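#' TPM-normalize a staged count matrix
#'
#' `tpm[i, s] = count[i, s] / colsum[s] * 1e6`, with the per-stage library
#' size taken as the column sum of the combined (FL + non-FL) counts. An
#' all-zero stage column yields an all-zero TPM column with a warning.
#'
#' @param counts Tibble with `transcript_id` and one numeric column per stage
#'   in developmental order.
#' @return Tibble of the same shape with TPM values.
#' @export
tpm_normalize <- function(counts) {
  sc <- assert_stages(counts)
  out <- counts
  for (s in sc) {
    tot <- sum(counts[[s]])
    if (tot == 0) {
      warn(paste0("stage ", s, " has zero total counts; TPM set to 0"))
      out[[s]] <- 0
    } else {
      out[[s]] <- counts[[s]] / tot * 1e6
    }
  }
  out
}

#' Maternal versus zygotic status
#'
#' A transcript is maternally deposited when its TPM exceeds `threshold` at
#' any maternal stage; otherwise it is zygotically activated. The zebrafish
#' rule is TPM > 0 at the fertilized-egg or 1-cell stage; the mouse preset
#' uses TPM > 5 at the 1-cell / 0 hpf stage.
#'
#' @param tpm TPM tibble (`transcript_id` + stage columns).
#' @param maternal_stages Stage column names counted as maternal; defaults to
#'   the first two stage columns.
#' @param threshold TPM threshold (exclusive). 0 for the zebrafish rule, 5
#'   for the mouse preset.
#' @return Tibble: `transcript_id`, `status` in `{maternal, zygotic}`.
#' @export
classify_maternal <- function(tpm, maternal_stages = NULL, threshold = 0) {
  sc <- assert_stages(tpm)
  maternal_stages <- maternal_stages %||% sc[seq_len(min(2L, length(sc)))]
  if (!all(maternal_stages %in% sc)) abort("unknown maternal stage column")
  m <- as.matrix(tpm[, maternal_stages, drop = FALSE])
  tibble(
    transcript_id = tpm$transcript_id,
    status = ifelse(apply(m > threshold, 1, any), "maternal", "zygotic")
  )
}

#' Activation stage of a single expression trajectory
#'
#' The activation stage is the earliest stage whose previous stage is below
#' `off_max` TPM, whose own expression is at least `on_min` TPM, and which is
#' followed by a continuous (strict) increase over the next `rise_len`
#' stages. Near the end of the series the increase is required over all
#' remaining stages (at least one must remain). Returns `NA` when no stage
#' qualifies.
#'
#' @param tpm Numeric vector of per-stage TPMs in developmental order.
#' @param stages Optional stage labels (defaults to indices).
#' @param off_max Maximum TPM at the stage before activation (default 5).
#' @param on_min Minimum TPM at the activation stage (default 5).
#' @param rise_len Number of following stages that must strictly increase
#'   (default 2).
#' @return The activation stage label (or index), or `NA` if none.
#' @export
call_activation_stage <- function(tpm, stages = NULL, off_max = 5,
                                  on_min = 5, rise_len = 2) {
  n <- length(tpm)
  if (n < 2) abort("need at least 2 stages")
  stages <- stages %||% seq_len(n)
  for (s in 2:n) {
    if (tpm[s - 1] < off_max && tpm[s] >= on_min) {
      remaining <- min(rise_len, n - s)
      if (remaining < 1) next
      seg <- tpm[s:(s + remaining)]
      if (all(diff(seg) > 0)) return(stages[s])
    }
  }
  stages[NA_integer_]
}

#' Maternal/zygotic status and activation stage for a catalog
#'
#' Applies [classify_maternal()] and [call_activation_stage()] across a TPM
#' table. Maternal transcripts get no activation stage (they are inherited,
#' not activated).
#'
#' @param tpm TPM tibble (`transcript_id` + stage columns in order).
#' @param maternal_stages,maternal_threshold Passed to [classify_maternal()].
#'   `preset = "mouse"` sets `maternal_threshold = 5`.
#' @param off_max,on_min,rise_len Passed to [call_activation_stage()].
#' @param preset `"zebrafish"` (maternal TPM > 0) or `"mouse"`
#'   (maternal TPM > 5).
#' @return Tibble: `transcript_id`, `status`, `activation_stage` (stage label
#'   or `NA`).
#' @export
call_activation <- function(tpm, maternal_stages = NULL,
                            maternal_threshold = NULL, off_max = 5,
                            on_min = 5, rise_len = 2,
                            preset = c("zebrafish", "mouse")) {
  preset <- match.arg(preset)
  maternal_threshold <- maternal_threshold %||%
    if (preset == "mouse") 5 else 0
  if (preset == "mouse") {
    maternal_stages <- maternal_stages %||% stage_cols(tpm)[1]
  }
  sc <- assert_stages(tpm)
  status <- classify_maternal(tpm, maternal_stages, maternal_threshold)
  m <- as.matrix(tpm[, sc, drop = FALSE])
  act <- vapply(seq_len(nrow(m)), function(i) {
    as.character(call_activation_stage(m[i, ], stages = sc,
                                       off_max = off_max, on_min = on_min,
                                       rise_len = rise_len))
  }, character(1))
  status |>
    mutate(activation_stage = ifelse(.data$status == "maternal",
                                     NA_character_, act))
}

#' Cluster zygotic expression trajectories
#'
#' Rows are transformed (`log2(TPM + 1)` then per-row z-score; constant rows
#' become zero vectors), clustered agglomeratively with Ward linkage
#' (`hclust(method = "ward.D")`) on Euclidean distances, and the tree is cut
#' at `k` clusters (`cutree`). Cluster ids are renumbered by the activation
#' order of the cluster mean trajectories, so cluster 1 activates earliest.
#'
#' @param tpm TPM tibble (`transcript_id` + stage columns), typically
#'   restricted to zygotic transcripts.
#' @param k Number of clusters (default 8).
#' @param transform Apply the log/z-score transform (default `TRUE`).
#' @return An object of class `zta_traj`: list with `assignments`
#'   (`transcript_id`, `cluster`), `centers` (per-cluster mean TPM
#'   trajectories, long tibble), `stages`, `k`, `hclust`.
#' @export
cluster_trajectories <- function(tpm, k = 8, transform = TRUE) {
  sc <- assert_stages(tpm)
  n <- nrow(tpm)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("k exceeds the number of trajectories")
  m <- as.matrix(tpm[, sc, drop = FALSE])
  rownames(m) <- tpm$transcript_id
  x <- if (transform) {
    lg <- log2(m + 1)
    t(apply(lg, 1, function(r) {
      s <- sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  } else m
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D")
  raw <- cutree(hc, k = k)
  # renumber clusters by activation order of their mean TPM trajectories
  centers_raw <- vapply(seq_len(k), function(cl) {
    colMeans(m[raw == cl, , drop = FALSE])
  }, numeric(length(sc)))
  act_idx <- vapply(seq_len(k), function(cl) {
    a <- call_activation_stage(centers_raw[, cl], stages = seq_along(sc))
    if (is.na(a)) Inf else as.numeric(a)
  }, numeric(1))
  peak_idx <- apply(centers_raw, 2, which.max)
  ord <- order(act_idx, peak_idx, seq_len(k))
  relabel <- match(seq_len(k), ord)
  cluster <- relabel[raw]
  centers <- tibble(
    cluster = rep(seq_len(k), each = length(sc)),
    stage = factor(rep(sc, k), levels = sc),
    mean_tpm = as.numeric(centers_raw[, ord])
  )
  structure(
    list(
      assignments = tibble(transcript_id = tpm$transcript_id,
                           cluster = unname(cluster)),
      centers = centers, stages = sc, k = k, hclust = hc
    ),
    class = "zta_traj"
  )
}

#' @export
print.zta_traj <- function(x, ...) {
  cat("Trajectory clustering:", nrow(x$assignments), "trajectories in",
      x$k, "clusters over", length(x$stages), "stages\n")
  print(count(x$assignments, .data$cluster))
  invisible(x)
}

#' @export
tidy.zta_traj <- function(x, ...) x$assignments

#' @export
glance.zta_traj <- function(x, ...) {
  tibble(n = nrow(x$assignments), k = x$k, n_stages = length(x$stages))
}

#' @export
autoplot.zta_traj <- function(object, ...) {
  ggplot(object$centers, aes(x = .data$stage, y = .data$mean_tpm,
                             group = .data$cluster)) +
    geom_line() +
    facet_wrap(~cluster, scales = "free_y") +
    labs(x = NULL, y = "mean TPM", title = "Cluster mean trajectories") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Expression-pattern entropy per subfamily
#'
#' Plug-in Shannon entropy (natural log, nats) of the empirical distribution
#' of trajectory-cluster labels among each subfamily's transcripts: 0 for a
#' homogeneous subfamily, `ln(k)` for one spread uniformly over `k` patterns.
#'
#' @param assignments Tibble with `subfamily` and `cluster` columns (join the
#'   catalog onto [cluster_trajectories()] assignments).
#' @param base Logarithm base; `exp(1)` (default, nats) or `2` (bits).
#' @return Tibble: `subfamily`, `n`, `n_patterns`, `entropy`.
#' @export
subfamily_entropy <- function(assignments, base = exp(1)) {
  assignments |>
    filter(!is.na(.data$cluster)) |>
    group_by(.data$subfamily) |>
    summarise(
      n = n(),
      n_patterns = n_distinct(.data$cluster),
      entropy = {
        p <- as.numeric(table(.data$cluster)) / n()
        -sum(p * log(p, base = base))
      },
      .groups = "drop"
    )
}

#' Activation-stage and cluster spread per subfamily
#'
#' For each subfamily, the number of distinct activation stages and distinct
#' trajectory clusters its transcripts cover.
#'
#' @param calls Tibble with `subfamily`, `activation_stage` and `cluster`
#'   columns.
#' @return Tibble: `subfamily`, `n`, `n_activation_stages`, `n_clusters`.
#' @export
subfamily_spread <- function(calls) {
  calls |>
    group_by(.data$subfamily) |>
    summarise(
      n = n(),
      n_activation_stages = n_distinct(.data$activation_stage[
        !is.na(.data$activation_stage)]),
      n_clusters = n_distinct(.data$cluster[!is.na(.data$cluster)]),
      .groups = "drop"
    )
}

#' Aggregate expression to locus, subfamily, family or type level
#'
#' Column-wise sums of per-transcript expression within groups; total
#' abundance is conserved at every level.
#'
#' @param tpm TPM (or count) tibble with `transcript_id` + stage columns.
#' @param groups Tibble mapping `transcript_id` to a `group` column.
#' @return Tibble: `group` + summed stage columns.
#' @export
aggregate_expression <- function(tpm, groups) {
  sc <- assert_stages(tpm)
  tpm |>
    inner_join(groups, by = "transcript_id") |>
    group_by(.data$group) |>
    summarise(across(all_of(sc), sum), .groups = "drop")
}

#' Stage-by-stage Pearson correlation of expression
#'
#' Pearson correlations between stage columns computed on `log2(TPM + 1)`.
#' Typically applied per transcript class to expose the correlation drop at
#' activation waves between adjacent stages.
#'
#' @param tpm TPM tibble (`transcript_id` + stage columns).
#' @return Stage-by-stage correlation matrix (diagonal 1).
#' @export
adjacent_stage_correlation <- function(tpm) {
  sc <- assert_stages(tpm)
  m <- log2(as.matrix(tpm[, sc, drop = FALSE]) + 1)
  cor(m, method = "pearson")
}

#' Fold change of total abundance between two stages
#'
#' @param tpm TPM tibble (`transcript_id` + stage columns) or an aggregated
#'   series.
#' @param stage_a,stage_b Stage column names (ratio is `b / a`).
#' @return One-row tibble: `stage_a`, `stage_b`, `total_a`, `total_b`,
#'   `fold_change` (`NA` with `undefined = TRUE` when `total_a` is zero).
#' @export
fold_change <- function(tpm, stage_a, stage_b) {
  sc <- assert_stages(tpm)
  if (!all(c(stage_a, stage_b) %in% sc)) abort("unknown stage column")
  ta <- sum(tpm[[stage_a]])
  tb <- sum(tpm[[stage_b]])
  tibble(
    stage_a = stage_a, stage_b = stage_b, total_a = ta, total_b = tb,
    fold_change = if (ta == 0) NA_real_ else tb / ta,
    undefined = ta == 0
  )
}
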