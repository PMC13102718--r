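# EPR/EditsC formulas, read-depth masking, cell filters, the editor
# expression normalization, pseudobulk pooling and pseudocells.

cfm_of <- function(edits, reads, barcode = "b1") {
  tibble::tibble(barcode = barcode,
                 feature = sprintf("g%03d", seq_along(edits)),
                 edits = edits, reads = reads)
}

test_that("EPR is edits over reads with a 5-read mask that also zeroes edits", {
  out <- compute_epr(cfm_of(c(4, 2, 0), c(20, 4, 100)))
  expect_equal(out$rate, c(0.2, 0, 0))
  expect_equal(out$edits, c(4, 0, 0))       # masked entry loses its edits
  # invariant: rate x reads == edits wherever reads pass the mask
  ok <- out$reads >= 5
  expect_equal(out$rate[ok] * out$reads[ok], out$edits[ok], tolerance = 1e-12)
})

test_that("cell filter thresholds differ between short- and long-read modes", {
  mk <- function(bc, n_edited) {
    tibble::tibble(barcode = bc, feature = sprintf("g%02d", 1:8),
                   edits = c(rep(1, n_edited), rep(0, 8 - n_edited)),
                   reads = 10)
  }
  cfm <- dplyr::bind_rows(mk("c4", 4), mk("c5", 5), mk("c6", 6))
  expect_setequal(unique(filter_cells(cfm, mode = "short")$barcode),
                  c("c5", "c6"))                      # keep >= 5
  expect_setequal(unique(filter_cells(cfm, mode = "long")$barcode),
                  "c6")                               # keep > 5
  expect_warning(filter_cells(mk("c0", 0), mode = "short"), "no cells")
})

test_that("per-cell mean EPR averages edited genes at the 3-read rule", {
  cfm <- tibble::tibble(
    barcode = "b1", feature = c("g1", "g2", "g3", "g4"),
    edits = c(2, 1, 0, 3), reads = c(10, 2, 50, 4))
  # g2 fails the 3-read rule, g3 has no edits; mean over g1 (0.2), g4 (0.75)
  m <- cell_mean_epr(cfm)
  expect_equal(m$n_edited, 2L)
  expect_equal(m$mean_epr, mean(c(0.2, 0.75)))
})

test_that("normalization regression recovers the planted slope", {
  sim <- simulate_matrices(n_cells = 2000, n_genes = 200, A = 0.5, b = 0.1,
                           sigma = 0.05, seed = 7)
  cells <- cell_mean_epr(sim$cfm) |>
    dplyr::inner_join(sim$cells, by = "barcode")
  fit <- fit_stamp_normalization(cells)
  expect_lt(abs(fit$A - 0.5), 0.03)

  # the fitted coefficients equal closed-form least squares on the same pairs
  fc <- fit$cells |> dplyr::filter(stamp_counts > 0)
  ols <- lm(log1p(mean_epr) ~ log1p(1e6 * stamp_counts / total_counts),
            data = fc)
  expect_equal(fit$A, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$b, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("noise-free collinear data has zero residuals; zero expression is a no-op", {
  cells <- tibble::tibble(
    barcode = sprintf("c%d", 1:50),
    stamp_counts = seq(1, 50),
    total_counts = 1e6,
    mean_epr = expm1(0.4 * log1p(seq(1, 50)) + 0.2))
  fit <- fit_stamp_normalization(cells)
  expect_equal(max(abs(fit$cells$residual)), 0, tolerance = 1e-12)

  # all cells zero editor expression: degenerate fit, factors 1
  cells0 <- cells |> dplyr::mutate(stamp_counts = 0L)
  fit0 <- fit_stamp_normalization(cells0)
  expect_true(fit0$degenerate)
  expect_true(all(fit0$cells$factor == 1))

  # constant non-zero expression warns and degenerates
  cellsc <- cells |> dplyr::mutate(stamp_counts = 5L)
  expect_warning(fitc <- fit_stamp_normalization(cellsc), "constant")
  expect_true(all(fitc$cells$factor == 1))
})

test_that("correction preserves the dynamic range and per-cell identities", {
  sim <- simulate_matrices(n_cells = 800, n_genes = 150, seed = 11)
  cells <- cell_mean_epr(sim$cfm) |>
    dplyr::inner_join(sim$cells, by = "barcode")
  fit <- fit_stamp_normalization(cells)
  fc <- fit$cells |> dplyr::filter(stamp_counts > 0)
  expect_equal(min(fc$corrected_mean_epr), min(fc$mean_epr), tolerance = 1e-9)
  expect_equal(max(fc$corrected_mean_epr), max(fc$mean_epr), tolerance = 1e-9)

  norm <- apply_stamp_normalization(sim$cfm, fit)
  # a cell with factor 1 keeps its masked edit row unchanged
  f1 <- fit$cells$barcode[which.min(abs(fit$cells$factor - 1))]
  fac <- fit$cells$factor[fit$cells$barcode == f1]
  before <- compute_epr(sim$cfm) |> dplyr::filter(barcode == f1)
  after <- norm |> dplyr::filter(barcode == f1)
  expect_equal(after$edits, before$edits * fac, tolerance = 1e-12)

  # rate x reads == edits after normalization too
  ok <- norm$reads >= 5
  expect_equal(norm$rate[ok] * norm$reads[ok], norm$edits[ok],
               tolerance = 1e-9)

  # ranking of corrected mean EPR follows the residuals
  expect_equal(order(fc$corrected_mean_epr), order(fc$residual))
})

test_that("correction removes the editor-expression dependence", {
  sim <- simulate_matrices(n_cells = 3000, n_genes = 150, A = 0.5, b = 0.1,
                           sigma = 0.05, seed = 13)
  cells <- cell_mean_epr(sim$cfm) |>
    dplyr::inner_join(sim$cells, by = "barcode")
  fit <- fit_stamp_normalization(cells)
  fc <- fit$cells |> dplyr::filter(stamp_counts > 0)
  rho_before <- cor(fc$mean_epr, fc$stamp_cpm, method = "spearman")
  rho_after <- cor(fc$corrected_mean_epr, fc$stamp_cpm, method = "spearman")
  expect_gt(abs(rho_before), 0.5)
  expect_lt(abs(rho_after), 0.05)
})

test_that("pseudobulk pools ratios rather than averaging them", {
  cfm <- tibble::tibble(barcode = c("c1", "c2"), feature = "g1",
                        edits = c(2, 3), reads = c(10, 40))
  groups <- tibble::tibble(barcode = c("c1", "c2"), group = "T",
                           sample = "s1")
  pb <- pseudobulk_epr(cfm, groups, min_reads = 5, min_total_reads = 0,
                       min_total_edits = 0, min_cells = 0)
  expect_equal(pb$epr, 0.1)                 # 5/50, not mean(0.2, 0.075)
  expect_false(isTRUE(all.equal(pb$epr, mean(c(2 / 10, 3 / 40)))))
})

test_that("pseudobulk retention requires all samples of some group to pass", {
  groups <- tidyr::expand_grid(group = c("T1", "T2"), sample = c("s1", "s2")) |>
    dplyr::mutate(barcode = paste0(group, sample))
  mk <- function(feature, edits) {
    groups |> dplyr::mutate(feature = feature, edits = edits, reads = 50)
  }
  cfm <- dplyr::bind_rows(
    mk("gPass", 6),
    mk("gEditFail", 6) |>
      dplyr::mutate(edits = dplyr::if_else(sample == "s2", 4, 6)),
    mk("gOneGroup", 6) |>
      dplyr::mutate(edits = dplyr::if_else(group == "T2", 0, 6)))
  pb <- pseudobulk_epr(cfm, groups |> dplyr::select(barcode, group, sample))
  # gEditFail has a 4-edit sample in every group -> dropped
  expect_false("gEditFail" %in% pb$feature)
  # gOneGroup passes in T1 only -> retained (with both groups reported)
  expect_true("gOneGroup" %in% pb$feature)
  expect_true("gPass" %in% pb$feature)

  # thresholds of zero retain everything
  pb0 <- pseudobulk_epr(cfm, groups |> dplyr::select(barcode, group, sample),
                        min_reads = 0, min_total_reads = 0,
                        min_total_edits = 0, min_cells = 0)
  expect_setequal(unique(pb0$feature), unique(cfm$feature))
})

test_that("pseudocells chunk, conserve reads and reduce to identity at size 1", {
  sim <- simulate_matrices(n_cells = 60, n_genes = 30, seed = 3)
  types <- tibble::tibble(barcode = unique(sim$cfm$barcode),
                          type = rep(c("T1", "T2"), length.out = 60))
  pcs <- make_pseudocells(sim$cfm, types, size = 10, n_repeats = 2, seed = 5)
  expect_length(pcs, 2L)
  # 30 cells per type / 10 -> 3 pseudocells per type
  expect_equal(dplyr::n_distinct(pcs[[1]]$pseudocell), 6L)
  # reads conserved against the member cells used
  members <- attr(pcs[[1]], "members")
  used <- sim$cfm |> dplyr::semi_join(members, by = "barcode")
  expect_equal(sum(pcs[[1]]$reads), sum(used$reads))
  expect_equal(sum(pcs[[1]]$edits), sum(used$edits))
  # pooled rate is the pooled ratio
  expect_equal(pcs[[1]]$rate, pcs[[1]]$edits / pcs[[1]]$reads)

  # size 1: pseudocell matrix equals the input up to row order
  pc1 <- make_pseudocells(sim$cfm, types, size = 1, n_repeats = 1, seed = 5)[[1]]
  members1 <- attr(pc1, "members")
  back <- pc1 |>
    dplyr::inner_join(members1, by = c("pseudocell", "type")) |>
    dplyr::select(barcode, feature, edits, reads) |>
    dplyr::arrange(barcode, feature)
  orig <- sim$cfm |> dplyr::filter(edits + reads > 0) |>
    dplyr::arrange(barcode, feature)
  expect_equal(as.data.frame(back),
               as.data.frame(orig |> dplyr::select(barcode, feature, edits,
                                                   reads)),
               ignore_attr = TRUE)

  # same seed reproduces the same grouping; a type smaller than size warns
  pcs2 <- make_pseudocells(sim$cfm, types, size = 10, n_repeats = 2, seed = 5)
  expect_identical(as.data.frame(pcs[[1]]), as.data.frame(pcs2[[1]]))
  expect_warning(
    make_pseudocells(sim$cfm, types |> dplyr::mutate(
      type = c("tiny", rep("T1", 59))), size = 10, n_repeats = 1, seed = 5),
    "tiny")
})

test_that("EditsC divides edits by cytosine content times reads", {
  cfm <- tibble::tibble(
    barcode = rep(sprintf("c%d", 1:7), each = 2),
    feature = rep(c("t1", "t2"), 7),
    edits = c(rep(c(2, 1), 6), 0, 0),
    reads = 4)
  cc <- tibble::tibble(feature = c("t1", "t2"), c_count = c(100L, 200L))
  out <- compute_editsc(cfm, cc)
  expect_equal(out$rate[out$feature == "t1" & out$edits == 2][1],
               2 / (100 * 4))               # 0.005
  # t1 edited in 6 cells (> 5) kept; t2 edited in 6 kept as well
  expect_setequal(unique(out$feature), c("t1", "t2"))

  # a transcript edited in exactly 5 cells is removed
  cfm5 <- cfm |>
    dplyr::mutate(edits = dplyr::if_else(feature == "t2" & barcode == "c6",
                                         0, edits))
  out5 <- compute_editsc(cfm5, cc)
  expect_false("t2" %in% out5$feature)

  # missing C content errors with the offending id
  expect_error(compute_editsc(cfm, cc[1, ]), "t2")
  expect_error(compute_editsc(cfm, cc |> dplyr::mutate(c_count = c(0L, 200L))),
               "t1")
})

test_that("EditsC on the isoform simulator equals per-read truth recomputation", {
  sim <- simulate_isoform_dataset(n_genes = 6, n_discordant = 0, seed = 9)
  out <- compute_editsc(sim$cfm, sim$c_content, min_edited_cells = 0)
  joined <- out |> dplyr::inner_join(sim$c_content, by = "feature")
  manual <- ifelse(joined$reads > 0,
                   joined$edits / (joined$c_count * joined$reads), 0)
  expect_equal(joined$rate, manual, tolerance = 1e-12)

  # the editor-expression correction applies unchanged to EditsC tables
  cells <- cell_total_rate(out) |>
    dplyr::transmute(barcode, mean_epr = total_rate,
                     stamp_counts = 1L, total_counts = 1000L)
  fit <- suppressWarnings(fit_stamp_normalization(cells))
  norm <- apply_stamp_normalization(out, fit, min_reads = 0)
  expect_equal(nrow(norm), nrow(out))
})

test_that("quantile-band filter keeps cells inside the inclusive window", {
  cells <- tibble::tibble(barcode = sprintf("c%02d", 1:100), v = 1:100)
  kept <- filter_quantile_band(cells, "v", 0.65, 0.80)
  qs <- quantile(1:100, c(0.65, 0.8))
  expect_true(all(kept$v >= qs[1] & kept$v <= qs[2]))
  expect_equal(nrow(kept), sum(cells$v >= qs[1] & cells$v <= qs[2]))
})
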