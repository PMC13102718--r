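#' Bootstrap differential translation test
#'
#' Compares per-replicate pseudobulk rates (EPR or EditsC) between two
#' groups by resampling: in each iteration the pooled replicate values of
#' a feature are resampled with replacement and randomly reassigned to the
#' two groups (original group sizes preserved), and the empirical p-value
#' is the fraction of iterations whose mean difference is at least the
#' observed one. The default decision is two-sided on absolute
#' differences; `sided = "one"` uses the signed difference as observed.
#' The resampling is vectorised per feature.
#'
#' @param data Long tibble of per-replicate values: columns `feature`,
#'   `group`, `value` (one row per feature x group x replicate).
#' @param group_a,group_b Names of the two groups in `group`; fold change
#'   is `log2(mean_a / mean_b)`.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param sided `"two"` (default) or `"one"`.
#' @param smooth If `TRUE`, report `(1 + k) / (1 + n_boot)` instead of the
#'   plain fraction, avoiding exact zeros.
#' @return Tibble with one row per feature: `feature`, `mean_a`, `mean_b`,
#'   `log2fc` (finite only when both means are positive), `p`, `test`,
#'   `n_boot`.
#' @export
bootstrap_differential <- function(data, group_a, group_b, n_boot = 10000L,
                                   seed = 1L, sided = c("two", "one"),
                                   smooth = FALSE) {
  sided <- match.arg(sided)
  if (n_boot <= 0) stop_input("n_boot must be positive")
  assert_cols(data, c("feature", "group", "value"))
  data <- data |> filter(.data$group %in% c(group_a, group_b))
  set.seed(seed)
  res <- data |>
    group_by(.data$feature) |>
    dplyr::group_map(function(df, key) {
      va <- df$value[df$group == group_a]
      vb <- df$value[df$group == group_b]
      na <- length(va)
      nb <- length(vb)
      v <- c(va, vb)
      m <- na + nb
      obs <- mean(va) - mean(vb)
      idx <- matrix(sample.int(m, n_boot * m, replace = TRUE), n_boot, m)
      vm <- matrix(v[idx], n_boot, m)
      d <- rowMeans(vm[, seq_len(na), drop = FALSE]) -
        rowMeans(vm[, na + seq_len(nb), drop = FALSE])
      k <- if (sided == "two") sum(abs(d) >= abs(obs)) else sum(d >= obs)
      p <- if (smooth) (1 + k) / (1 + n_boot) else k / n_boot
      ma <- mean(va)
      mb <- mean(vb)
      tibble(feature = key$feature, mean_a = ma, mean_b = mb,
             log2fc = if (ma > 0 && mb > 0) log2(ma / mb) else NA_real_,
             p = p)
    }) |>
    bind_rows()
  res |> mutate(test = "bootstrap", n_boot = as.integer(n_boot))
}

#' Welch differential translation test
#'
#' Two-sample unequal-variance t-test of per-sample rates between two
#' groups, with Welch-Satterthwaite degrees of freedom, applied per
#' feature. When both groups have zero variance, the p-value is 1 for
#' equal means and 0 otherwise.
#'
#' @param data Long tibble of per-sample values: columns `feature`,
#'   `group`, `value`.
#' @param group_a,group_b Names of the two groups; fold change is
#'   `log2(mean_a / mean_b)`.
#' @return Tibble per feature: `feature`, `mean_a`, `mean_b`, `log2fc`,
#'   `statistic`, `df`, `p`, `test`.
#' @export
welch_differential <- function(data, group_a, group_b) {
  assert_cols(data, c("feature", "group", "value"))
  data <- data |> filter(.data$group %in% c(group_a, group_b))
  res <- data |>
    group_by(.data$feature) |>
    dplyr::group_map(function(df, key) {
      va <- df$value[df$group == group_a]
      vb <- df$value[df$group == group_b]
      if (length(va) < 2 || length(vb) < 2) {
        stop_input("feature '%s' has fewer than 2 samples in a group",
                   key$feature)
      }
      w <- welch_stat(va, vb)
      ma <- mean(va)
      mb <- mean(vb)
      tibble(feature = key$feature, mean_a = ma, mean_b = mb,
             log2fc = if (ma > 0 && mb > 0) log2(ma / mb) else NA_real_,
             statistic = w$t, df = w$df, p = w$p)
    }) |>
    bind_rows()
  res |> mutate(test = "welch")
}

# Closed-form Welch statistic with degenerate guards.
welch_stat <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  se2 <- va + vb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Identify genes with discordant isoform translation
#'
#' A gene is discordant between two cell types when at least one of its
#' isoforms shows significantly increased translation (positive log2 fold
#' change, p below `alpha`) and another significantly decreased
#' translation.
#'
#' @param results Per-transcript differential results (`feature`,
#'   `log2fc`, `p`), e.g. from [welch_differential()].
#' @param gene_map Tibble `feature`, `gene`.
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble of the significant isoforms of discordant genes:
#'   `gene`, `feature`, `log2fc`, `p`, `direction` (`up`/`down`).
#' @export
find_discordant_isoforms <- function(results, gene_map, alpha = 0.05) {
  assert_cols(results, c("feature", "log2fc", "p"))
  assert_cols(gene_map, c("feature", "gene"))
  sig <- results |>
    filter(.data$p < alpha, !is.na(.data$log2fc), .data$log2fc != 0) |>
    inner_join(gene_map, by = "feature") |>
    mutate(direction = if_else(.data$log2fc > 0, "up", "down"))
  disc <- sig |>
    group_by(.data$gene) |>
    summarise(has_up = any(.data$direction == "up"),
              has_down = any(.data$direction == "down"), .groups = "drop") |>
    filter(.data$has_up & .data$has_down)
  sig |>
    semi_join(disc, by = "gene") |>
    select("gene", "feature", "log2fc", "p", "direction") |>
    arrange(.data$gene, dplyr::desc(.data$log2fc))
}

#' Stratify transcripts by translation level
#'
#' `mode = "quartiles"` assigns rank-based quartile labels (Q1 lowest to
#' Q4 highest, near-equal bin sizes, ties broken by feature id) to
#' transcripts with non-zero edits in every sample. `mode = "extremes"`
#' additionally requires total reads across samples above
#' `min_total_reads` and, for each gene with at least two remaining
#' isoforms, returns the isoform pair with the highest and lowest mean
#' rate.
#'
#' @param pb Per-sample pseudobulk tibble: `feature`, `sample`, `edits`,
#'   `reads`, `rate`.
#' @param mode `"quartiles"` or `"extremes"`.
#' @param gene_map Tibble `feature`, `gene` (required for extremes mode).
#' @param min_total_reads Read filter for extremes mode (strictly greater
#'   than; default 20).
#' @return Quartile mode: tibble `feature`, `mean_rate`, `quartile`.
#'   Extremes mode: tibble `gene`, `high_isoform`, `low_isoform`,
#'   `high_rate`, `low_rate`.
#' @export
stratify_extremes <- function(pb, mode = c("quartiles", "extremes"),
                              gene_map = NULL, min_total_reads = 20) {
  mode <- match.arg(mode)
  assert_cols(pb, c("feature", "sample", "edits", "reads", "rate"))
  per_feat <- pb |>
    group_by(.data$feature) |>
    summarise(all_edited = all(.data$edits > 0),
              total_reads = sum(.data$reads),
              mean_rate = mean(.data$rate), .groups = "drop")

  if (mode == "quartiles") {
    kept <- per_feat |> filter(.data$all_edited)
    if (nrow(kept) < 4) stop_input("need at least 4 transcripts, got %d",
                                   nrow(kept))
    kept |>
      arrange(.data$mean_rate, .data$feature) |>
      mutate(quartile = paste0("Q", ntile(row_number(), 4))) |>
      select("feature", "mean_rate", "quartile")
  } else {
    if (is.null(gene_map)) stop_input("extremes mode requires gene_map")
    assert_cols(gene_map, c("feature", "gene"))
    kept <- per_feat |>
      filter(.data$all_edited, .data$total_reads > min_total_reads) |>
      inner_join(gene_map, by = "feature")
    kept |>
      group_by(.data$gene) |>
      filter(n() >= 2) |>
      summarise(
        high_isoform = .data$feature[order(-.data$mean_rate, .data$feature)][1],
        low_isoform = .data$feature[order(.data$mean_rate, .data$feature)][1],
        high_rate = max(.data$mean_rate),
        low_rate = min(.data$mean_rate), .groups = "drop")
  }
}

#' Pairwise rank correlations between isoforms of the same gene
#'
#' For every unordered pair of isoforms of a gene, computes the Spearman
#' correlation of their mean values across cell types. Applied identically
#' to RNA counts and EditsC, the contrast between the two correlation
#' distributions reveals isoform pairs that are co-expressed but not
#' co-translated. Pairs involving a constant profile have undefined rank
#' correlation and are skipped (counted in the `n_skipped` attribute).
#'
#' @param data Long tibble: `feature`, `group` (cell type), `value` (mean
#'   value of the feature in the cell type).
#' @param gene_map Tibble `feature`, `gene`.
#' @return Tibble `gene`, `feature_1`, `feature_2`, `rho`, with attributes
#'   `n_skipped` and `frac_nonpositive` (share of pairs with rho <= 0).
#' @export
isoform_pair_correlations <- function(data, gene_map) {
  assert_cols(data, c("feature", "group", "value"))
  assert_cols(gene_map, c("feature", "gene"))
  n_types <- dplyr::n_distinct(data$group)
  if (n_types < 3) stop_input("need at least 3 cell types, got %d", n_types)
  wide <- data |>
    tidyr::pivot_wider(names_from = "group", values_from = "value") |>
    inner_join(gene_map, by = "feature")
  mat <- as.matrix(wide[, setdiff(names(wide), c("feature", "gene"))])
  rownames(mat) <- wide$feature

  n_skipped <- 0L
  rows <- wide |>
    group_by(.data$gene) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2) return(NULL)
      pairs <- utils::combn(sort(df$feature), 2)
      purrr::map(seq_len(ncol(pairs)), function(j) {
        v1 <- mat[pairs[1, j], ]
        v2 <- mat[pairs[2, j], ]
        ok <- complete.cases(v1, v2)
        if (sd(v1[ok]) == 0 || sd(v2[ok]) == 0) {
          n_skipped <<- n_skipped + 1L
          return(NULL)
        }
        tibble(gene = key$gene, feature_1 = pairs[1, j],
               feature_2 = pairs[2, j],
               rho = cor(v1[ok], v2[ok], method = "spearman"))
      }) |> bind_rows()
    }) |>
    bind_rows()
  structure(rows, n_skipped = n_skipped,
            frac_nonpositive = if (nrow(rows) > 0) mean(rows$rho <= 0) else NA_real_)
}

#' Volcano plot of differential translation results
#'
#' @param object Tibble from [bootstrap_differential()] or
#'   [welch_differential()].
#' @param alpha Significance threshold drawn as a horizontal line.
#' @param lfc Fold-change threshold drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_volcano <- function(object, alpha = 0.05, lfc = 0.5, ...) {
  assert_cols(object, c("feature", "log2fc", "p"))
  df <- object |>
    filter(!is.na(.data$log2fc)) |>
    mutate(significant = .data$p < alpha & abs(.data$log2fc) > lfc,
           mlog10p = -log10(pmax(.data$p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$mlog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
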