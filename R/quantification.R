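#' Compute edits-per-read (EPR) for a cell-by-feature table
#'
#' EPR is the per cell-feature ratio of C-to-U edit counts to read counts,
#' the single-cell analogue of a translational-efficiency metric: edits are
#' deposited on the same molecules that are sequenced, so the ratio is
#' internally normalised. Low-coverage observations are masked: wherever
#' `reads < min_reads` both the rate and the edit count are set to zero, so
#' downstream sums only see well-covered gene-cell pairs.
#'
#' @param cfm Tibble with columns `barcode`, `feature`, `edits`, `reads`
#'   (long form; absent pairs are implicit zeros).
#' @param min_reads Read-depth mask threshold (default 5).
#' @return The input tibble with `edits` masked and a `rate` column added.
#' @export
compute_epr <- function(cfm, min_reads = 5L) {
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  cfm |>
    mutate(edits = if_else(.data$reads >= min_reads, .data$edits, 0),
           rate = if_else(.data$reads >= min_reads,
                          .data$edits / .data$reads, 0))
}

#' Drop cells with too few edited features
#'
#' Short-read mode retains cells with at least `min_edited` edited
#' features; long-read mode drops cells with `min_edited` or fewer (i.e.
#' retains strictly more), matching the two retention rules used for the
#' respective libraries.
#'
#' @param cfm Cell-by-feature tibble with `edits` (after masking).
#' @param min_edited Threshold number of edited features (default 5).
#' @param mode `"short"` (keep `>=`) or `"long"` (keep `>`).
#' @return Row-filtered tibble.
#' @export
filter_cells <- function(cfm, min_edited = 5L, mode = c("short", "long")) {
  mode <- match.arg(mode)
  assert_cols(cfm, c("barcode", "feature", "edits"))
  per_cell <- cfm |>
    group_by(.data$barcode) |>
    summarise(n_edited = sum(.data$edits > 0), .groups = "drop")
  keep <- if (mode == "short") {
    per_cell$barcode[per_cell$n_edited >= min_edited]
  } else {
    per_cell$barcode[per_cell$n_edited > min_edited]
  }
  if (length(keep) == 0) {
    rlang::warn("no cells pass the edited-feature threshold")
  }
  cfm |> filter(.data$barcode %in% keep)
}

#' Per-cell mean EPR over edited features
#'
#' The per-cell summary used as the dependent variable of the editor
#' expression regression: the mean of `edits/reads` over features with at
#' least one edit and at least `min_reads` reads (default 3, the
#' regression's gene-inclusion rule, intentionally looser than the
#' 5-read matrix mask).
#'
#' @param cfm Cell-by-feature tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @param min_reads Minimum reads for a feature to count as edited.
#' @return Tibble `barcode`, `mean_epr`, `n_edited`. Cells with no
#'   qualifying features get `mean_epr = 0`.
#' @export
cell_mean_epr <- function(cfm, min_reads = 3L) {
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  cfm |>
    group_by(.data$barcode) |>
    summarise(
      n_edited = sum(.data$edits > 0 & .data$reads >= min_reads),
      mean_epr = {
        sel <- .data$edits > 0 & .data$reads >= min_reads
        if (any(sel)) mean(.data$edits[sel] / .data$reads[sel]) else 0
      },
      .groups = "drop")
}

#' Fit the editor-expression normalization regression
#'
#' Mean per-cell editing rate scales with expression of the editor
#' construct itself, a technical confounder. The correction regresses
#' `log(mean EPR + 1)` on `log(editor CPM + 1)` by ordinary least squares
#' over cells with non-zero editor expression, and derives per-cell
#' correction factors from the exponentiated residuals, min-max rescaled
#' onto the range of the uncorrected mean EPR so the corrected values keep
#' the original dynamic range and sign.
#'
#' @param cells Tibble with columns `barcode`, `mean_epr` (from
#'   [cell_mean_epr()]), `stamp_counts` (raw editor-transcript counts) and
#'   `total_counts` (cell library size, for CPM).
#' @param log_base `"natural"` (default) or `"ten"`; base of the log1p
#'   transform on both axes.
#' @return An object of class `"stamp_fit"`: slope `A`, intercept `b`,
#'   per-cell table with residuals, corrected mean EPR and correction
#'   `factor` (1 for zero-expression cells), `residual_range`,
#'   `target_range`, and a `degenerate` flag. Supports [tidy()] and
#'   [glance()].
#' @export
fit_stamp_normalization <- function(cells, log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  assert_cols(cells, c("barcode", "mean_epr", "stamp_counts", "total_counts"))
  lg <- if (log_base == "natural") log1p else function(x) log10(1 + x)
  unlg <- if (log_base == "natural") exp else function(x) 10^x

  cells <- cells |>
    mutate(stamp_cpm = 1e6 * .data$stamp_counts / .data$total_counts,
           x = lg(.data$stamp_cpm), y = lg(.data$mean_epr))
  fit_cells <- cells |> filter(.data$stamp_counts > 0)
  degenerate <- FALSE
  if (nrow(fit_cells) < 3 || sd(fit_cells$x) == 0) {
    if (nrow(fit_cells) > 0 && sd(fit_cells$x) == 0) {
      rlang::warn("constant editor expression; degenerate fit, factors = 1")
    }
    degenerate <- TRUE
    A <- 0
    b <- if (nrow(fit_cells) > 0) mean(fit_cells$y) else 0
  } else {
    # closed-form simple OLS
    A <- cov(fit_cells$x, fit_cells$y) / var(fit_cells$x)
    b <- mean(fit_cells$y) - A * mean(fit_cells$x)
  }

  fit_cells <- fit_cells |>
    mutate(residual = .data$y - (A * .data$x + b),
           resid_exp = unlg(.data$residual))
  target_range <- if (nrow(fit_cells) > 0) {
    range(fit_cells$mean_epr)
  } else c(0, 0)
  residual_range <- if (nrow(fit_cells) > 0) {
    range(fit_cells$resid_exp)
  } else c(0, 0)

  if (degenerate || diff(residual_range) == 0) {
    fit_cells <- fit_cells |>
      mutate(corrected_mean_epr = .data$mean_epr, factor = 1)
  } else {
    fit_cells <- fit_cells |>
      mutate(
        corrected_mean_epr =
          (.data$resid_exp - residual_range[1]) / diff(residual_range) *
          diff(target_range) + target_range[1],
        factor = if_else(.data$mean_epr > 0,
                         .data$corrected_mean_epr / .data$mean_epr, 1))
  }

  all_cells <- cells |>
    left_join(fit_cells |> select("barcode", "residual", "resid_exp",
                                  "corrected_mean_epr", "factor"),
              by = "barcode") |>
    mutate(factor = dplyr::coalesce(.data$factor, 1),
           corrected_mean_epr = dplyr::coalesce(.data$corrected_mean_epr,
                                                .data$mean_epr))

  structure(list(A = A, b = b, log_base = log_base,
                 residual_range = residual_range,
                 target_range = target_range,
                 degenerate = degenerate,
                 cells = all_cells,
                 n_fit = nrow(fit_cells)),
            class = "stamp_fit")
}

#' @method tidy stamp_fit
#' @export
tidy.stamp_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"), estimate = c(x$A, x$b))
}

#' @method glance stamp_fit
#' @export
glance.stamp_fit <- function(x, ...) {
  tibble(A = x$A, b = x$b, n_fit = x$n_fit, degenerate = x$degenerate,
         residual_min = x$residual_range[1],
         residual_max = x$residual_range[2],
         target_min = x$target_range[1], target_max = x$target_range[2])
}

#' @method print stamp_fit
#' @export
print.stamp_fit <- function(x, ...) {
  cat(sprintf(
    "<stamp_fit> log(mean EPR + 1) = %.4g x log(editor CPM + 1) + %.4g\n",
    x$A, x$b))
  cat(sprintf("  %d cells in fit%s\n", x$n_fit,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Apply the editor-expression correction to a cell-by-feature table
#'
#' Multiplies each cell's edit counts by its correction factor from
#' [fit_stamp_normalization()] (fractional edits allowed), re-applies the
#' read-depth mask, and recomputes the rate as corrected edits over
#' unadjusted reads.
#'
#' @param cfm Cell-by-feature tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @param fit A `"stamp_fit"` object.
#' @param min_reads Read-depth mask threshold (default 5).
#' @return Corrected tibble with `edits` scaled and `rate` recomputed.
#' @export
apply_stamp_normalization <- function(cfm, fit, min_reads = 5L) {
  stopifnot(inherits(fit, "stamp_fit"))
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  factors <- setNames(fit$cells$factor, fit$cells$barcode)
  cfm |>
    mutate(factor = unname(factors[.data$barcode]),
           factor = dplyr::coalesce(.data$factor, 1),
           edits = .data$edits * .data$factor,
           edits = if_else(.data$reads >= min_reads, .data$edits, 0),
           rate = if_else(.data$reads >= min_reads,
                          .data$edits / .data$reads, 0)) |>
    select(-"factor")
}

#' Pseudobulk EPR by group and sample
#'
#' Pools cells within each (group, sample): the pseudobulk EPR of a feature
#' is the pooled ratio sum(edits)/sum(reads) over that sample's cells (not
#' the mean of per-cell ratios). Observations with `reads < min_reads` are
#' excluded before pooling. A feature is retained when, in at least one
#' group, all of that group's samples satisfy: total reads >=
#' `min_total_reads`, total edits >= `min_total_edits`, and at least
#' `min_cells` cells passing the read threshold. `min_cells = 1` is the
#' cell-type-level preset; `min_cells = 5` the stricter within-cell-type
#' preset.
#'
#' @param cfm Cell-by-feature tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @param groups Tibble mapping cells to groups: `barcode`, `group`,
#'   `sample`.
#' @param min_reads Per-observation read threshold before pooling.
#' @param min_total_reads,min_total_edits,min_cells Retention conditions
#'   (see above).
#' @return Tibble `feature`, `group`, `sample`, `total_edits`,
#'   `total_reads`, `n_cells_pass`, `epr`, `mean_epr` (mean of `epr`
#'   across the group's samples), restricted to retained features.
#' @export
pseudobulk_epr <- function(cfm, groups, min_reads = 5L,
                           min_total_reads = 5L, min_total_edits = 5L,
                           min_cells = 1L) {
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  assert_cols(groups, c("barcode", "group", "sample"))
  unmapped <- setdiff(unique(cfm$barcode), groups$barcode)
  if (length(unmapped) > 0) {
    stop_input("cell(s) not mapped to a group: %s",
               paste(head(unmapped, 5), collapse = ", "))
  }
  sample_grid <- groups |> distinct(.data$group, .data$sample)
  obs <- cfm |>
    select("barcode", "feature", "edits", "reads") |>
    inner_join(groups |> select("barcode", "group", "sample"),
               by = "barcode") |>
    filter(.data$reads >= min_reads)

  pb <- obs |>
    group_by(.data$feature, .data$group, .data$sample) |>
    summarise(total_edits = sum(.data$edits),
              total_reads = sum(.data$reads),
              n_cells_pass = dplyr::n_distinct(.data$barcode),
              .groups = "drop")

  # complete the (feature x group x sample) grid so "all samples" is
  # evaluated against every sample a group has
  full <- tidyr::expand_grid(feature = unique(pb$feature), sample_grid) |>
    left_join(pb, by = c("feature", "group", "sample")) |>
    mutate(across(c("total_edits", "total_reads", "n_cells_pass"),
                  ~ dplyr::coalesce(.x, 0)))

  flags <- full |>
    group_by(.data$feature, .data$group) |>
    summarise(pass = all(.data$total_reads >= min_total_reads) &&
                all(.data$total_edits >= min_total_edits) &&
                all(.data$n_cells_pass >= min_cells),
              .groups = "drop")
  kept <- flags |>
    group_by(.data$feature) |>
    summarise(keep = any(.data$pass), .groups = "drop") |>
    filter(.data$keep)

  full |>
    semi_join(kept, by = "feature") |>
    mutate(epr = if_else(.data$total_reads > 0,
                         .data$total_edits / .data$total_reads, 0)) |>
    group_by(.data$feature, .data$group) |>
    mutate(mean_epr = mean(.data$epr)) |>
    ungroup() |>
    arrange(.data$feature, .data$group, .data$sample)
}

#' Build pseudocells by pooling same-type cells
#'
#' Edits are sparse per cell; pooling random groups of cells of the same
#' type densifies the signal for clustering. Within each type, cells are
#' shuffled with a seeded generator and chunked into groups of `size`
#' (remainder cells dropped); edits and reads are summed per chunk and the
#' pooled rate recomputed. The shuffle is repeated `n_repeats` times with
#' distinct derived seeds.
#'
#' @param cfm Cell-by-feature tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @param cell_types Tibble `barcode`, `type`.
#' @param size Cells per pseudocell (the analyses use 5, 10 or 15).
#' @param n_repeats Number of independent shuffles (default 5).
#' @param seed Integer seed; each repeat derives its own stream.
#' @return A list of `n_repeats` tibbles with columns `pseudocell`,
#'   `type`, `feature`, `edits`, `reads`, `rate`, plus a `members`
#'   attribute mapping pseudocells to their member barcodes.
#' @export
make_pseudocells <- function(cfm, cell_types, size, n_repeats = 5L, seed = 1L) {
  stopifnot(size >= 1)
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  assert_cols(cell_types, c("barcode", "type"))
  purrr::map(seq_len(n_repeats), function(k) {
    rs <- derive_seed(seed, k)
    assign_one <- function(barcodes, type) {
      n_chunks <- floor(length(barcodes) / size)
      if (n_chunks == 0) {
        rlang::warn(sprintf("type '%s' has fewer than %d cells; skipped",
                            type, size))
        return(NULL)
      }
      shuffled <- sample(barcodes)
      used <- shuffled[seq_len(n_chunks * size)]
      tibble(barcode = used, type = type,
             pseudocell = sprintf("%s_r%d_p%d", type, k,
                                  rep(seq_len(n_chunks), each = size)))
    }
    set.seed(rs)
    members <- cell_types |>
      group_by(.data$type) |>
      dplyr::group_map(~ assign_one(.x$barcode, .y$type)) |>
      bind_rows()
    out <- cfm |>
      inner_join(members, by = "barcode") |>
      group_by(.data$pseudocell, .data$type, .data$feature) |>
      summarise(edits = sum(.data$edits), reads = sum(.data$reads),
                .groups = "drop") |>
      mutate(rate = if_else(.data$reads > 0, .data$edits / .data$reads, 0))
    structure(out, members = members)
  })
}

#' Compute EditsC for an isoform-level table
#'
#' EditsC quantifies isoform translation from long reads as the ratio of
#' edited cytosines to total cytosines across the transcript's exons and
#' total reads: `edits / (C_content x reads)`. Normalising by the
#' transcript's cytosine content makes values comparable across isoforms
#' of different length and composition. Transcripts observed edited in
#' `min_edited_cells` or fewer cells are removed. The editor-expression
#' correction ([fit_stamp_normalization()]) applies to this table
#' unchanged.
#'
#' @param cfm Cell-by-isoform tibble (`barcode`, `feature`, `edits`,
#'   `reads`).
#' @param c_content Tibble `feature`, `c_count`: total cytosines on the
#'   spliced transcript sense strand (see [transcript_c_content()]).
#' @param min_edited_cells Exclusion threshold: transcripts kept only when
#'   strictly more than this many cells carry edits (default 5).
#' @return Filtered tibble with a `rate` column holding EditsC.
#' @export
compute_editsc <- function(cfm, c_content, min_edited_cells = 5L) {
  assert_cols(cfm, c("barcode", "feature", "edits", "reads"))
  assert_cols(c_content, c("feature", "c_count"))
  if (any(c_content$c_count <= 0)) {
    stop_input("non-positive C content for: %s",
               paste(c_content$feature[c_content$c_count <= 0], collapse = ", "))
  }
  missing <- setdiff(unique(cfm$feature), c_content$feature)
  if (length(missing) > 0) {
    stop_input("isoform(s) missing C content: %s",
               paste(head(missing, 5), collapse = ", "))
  }
  out <- cfm |>
    inner_join(c_content, by = "feature") |>
    mutate(rate = if_else(.data$reads > 0,
                          .data$edits / (.data$c_count * .data$reads), 0))
  keep <- out |>
    group_by(.data$feature) |>
    summarise(n_pos = sum(.data$edits > 0), .groups = "drop") |>
    filter(.data$n_pos > min_edited_cells)
  out |> semi_join(keep, by = "feature") |> select(-"c_count")
}

#' Quantile-band cell filter
#'
#' Retains cells whose value of a covariate lies inside an inclusive
#' quantile window, e.g. matching editor RNA levels between state groups
#' before comparing their editing rates (the analyses use the 0.65-0.80
#' band).
#'
#' @param cells Tibble with a `barcode` column.
#' @param values Numeric column name (string) holding the covariate.
#' @param lower,upper Quantile bounds in `[0, 1]`.
#' @return Row-filtered tibble.
#' @export
filter_quantile_band <- function(cells, values, lower = 0.65, upper = 0.80) {
  assert_cols(cells, c("barcode", values))
  v <- cells[[values]]
  qs <- quantile(v, c(lower, upper), names = FALSE, type = 7)
  cells[v >= qs[1] & v <= qs[2], , drop = FALSE]
}
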