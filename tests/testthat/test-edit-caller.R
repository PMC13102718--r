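# Region partitioning, edit tabulation, coverage, the filter cascade and
# feature aggregation.

test_that("region partitioning tiles contigs exactly", {
  p <- partition_regions(c(chr1 = 10000L), 4000L)
  expect_equal(p$start, c(0L, 4000L, 8000L))
  expect_equal(p$end, c(4000L, 8000L, 10000L))

  # contig shorter than the interval: one region
  p <- partition_regions(c(chrS = 1500L), 4000L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$end, 1500L)

  # regions never span contigs and cover each exactly once
  p <- partition_regions(c(a = 7000L, b = 3000L), 2500L)
  expect_true(all(p$end[p$contig == "a"] <= 7000L))
  for (ct in c("a", "b")) {
    sub <- p[p$contig == ct, ]
    expect_equal(sub$start[1], 0L)
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
})

test_that("edit tabulation matches the brute-force oracle and groups by cell", {
  fx <- sim_fixture()
  reads <- stream_reads(fx$sim$paths$sam, config = fx$rc)
  tab <- tabulate_edits(reads, config = fx$rc)
  orc <- oracle_pileup(fx$sim$paths$sam, fx$sim$paths$fasta,
                       whitelist = fx$wl)$mismatches |>
    dplyr::count(contig, pos, ref, alt, barcode, name = "edit_count") |>
    dplyr::arrange(contig, pos, ref, alt, barcode)
  got <- tab |>
    dplyr::select(contig, pos, ref_base, alt_base, barcode, edit_count) |>
    dplyr::arrange(contig, pos, ref_base, alt_base, barcode)
  expect_equal(got$edit_count, orc$edit_count)
  expect_equal(got$pos, orc$pos)
  expect_equal(got$barcode, orc$barcode)

  # a site edited in two cells appears as two keyed rows
  two <- tab |> dplyr::count(contig, pos, alt_base) |> dplyr::filter(n >= 2)
  expect_gt(nrow(two), 0L)

  # reads identical to the reference produce an empty table
  clean <- make_read(strrep("A", 20), "20M", "20")
  expect_equal(nrow(tabulate_edits(clean)), 0L)
})

test_that("per-cell coverage equals the naive pileup oracle", {
  fx <- sim_fixture()
  reads <- stream_reads(fx$sim$paths$sam, config = fx$rc)
  sites <- fx$calls$sites
  cov <- compute_site_coverage(reads, sites, fx$rc, all_barcodes = TRUE)
  orc_bases <- oracle_pileup(fx$sim$paths$sam, fx$sim$paths$fasta,
                             whitelist = fx$wl)$bases
  orc <- orc_bases |>
    dplyr::inner_join(
      sites |> dplyr::select(contig, pos, ref_base, alt_base),
      by = c("contig", "pos")) |>
    dplyr::group_by(contig, pos, barcode) |>
    dplyr::summarise(ref_reads = sum(base == ref_base),
                     alt_reads = sum(base == alt_base), .groups = "drop") |>
    dplyr::arrange(contig, pos, barcode)
  expect_equal(as.data.frame(cov), as.data.frame(orc), ignore_attr = TRUE)
})

test_that("reads deleting or skipping a position contribute no coverage", {
  # deletion/skip spans reference 15-18; the site sits inside it
  sites <- tibble::tibble(contig = "chr1", pos = 16L, ref_base = "C",
                          alt_base = "T")
  cfg <- read_filter_config(min_base_qual = 0, min_dist_from_end = 0)
  del <- make_read("AAAAAAAAAA", "5M4D5M", "5^CCCC5", start = 10L)
  cov <- compute_site_coverage(del, sites, cfg, all_barcodes = TRUE)
  expect_equal(nrow(cov), 0L)
  skip <- make_read("AAAAAAAAAA", "5M4N5M", "10", start = 10L)
  cov <- compute_site_coverage(skip, sites, cfg, all_barcodes = TRUE)
  expect_equal(nrow(cov), 0L)
  # a barcode with no read overlapping the site is absent
  far <- make_read("AAAAA", "5M", "5", start = 500L, barcode = "BCX")
  cov <- compute_site_coverage(dplyr::bind_rows(del, far), sites, cfg,
                               all_barcodes = TRUE)
  expect_false("BCX" %in% cov$barcode)
})

test_that("filter cascade drops each decoy by its intended rule", {
  fx <- sim_fixture()
  truth_sites <- fx$sim$truth$sites

  # per-rule drop counts equal the truth projection
  expected_counts <- truth_sites |>
    dplyr::filter(!expected %in% c("kept", "absent")) |>
    dplyr::count(expected)
  drops <- fx$calls$drops |> dplyr::filter(n > 0)
  expect_equal(
    drops |> dplyr::arrange(rule) |> dplyr::pull(n),
    expected_counts |> dplyr::arrange(expected) |> dplyr::pull(n))
  expect_setequal(drops$rule, expected_counts$expected)

  # kept sites are exactly the truth's kept set
  kept_truth <- truth_sites |> dplyr::filter(expected == "kept")
  expect_equal(
    fx$calls$sites |> dplyr::select(contig, pos) |> dplyr::arrange(contig, pos),
    kept_truth |> dplyr::select(contig, pos) |> dplyr::arrange(contig, pos))

  # sites visible only through low-quality or read-end bases never surface
  absent <- truth_sites |> dplyr::filter(expected == "absent")
  expect_equal(nrow(dplyr::semi_join(fx$calls$sites, absent,
                                     by = c("contig", "pos"))), 0L)

  # minus-strand gene sites are re-oriented to sense C>T
  expect_true(all(fx$calls$sites$ref_base == "C" &
                    fx$calls$sites$alt_base == "T"))
})

test_that("filter rules act on constructed single-site examples", {
  base <- tibble::tibble(contig = "chr1", ref_base = "C", site_strand = "+",
                         n_alt_types = 1L)
  cfg <- site_filter_config(snp_mask = tibble::tibble(contig = "chr1",
                                                      pos = 99L))
  sites <- dplyr::bind_rows(
    base |> dplyr::mutate(pos = 10L, alt_base = "T", n_alt_types = 2L,
                          total_edits = 10L, ref_reads = 90L,
                          alt_reads = 10L, edited_fraction = 0.03),
    base |> dplyr::mutate(pos = 20L, alt_base = "T", total_edits = 2L,
                          ref_reads = 90L, alt_reads = 2L,
                          edited_fraction = 2 / 92),
    base |> dplyr::mutate(pos = 30L, alt_base = "T", total_edits = 3L,
                          ref_reads = 37L, alt_reads = 3L,
                          edited_fraction = 0.075),
    base |> dplyr::mutate(pos = 99L, alt_base = "T", total_edits = 10L,
                          ref_reads = 200L, alt_reads = 10L,
                          edited_fraction = 10 / 210),
    base |> dplyr::mutate(pos = 40L, alt_base = "G", total_edits = 10L,
                          ref_reads = 200L, alt_reads = 10L,
                          edited_fraction = 10 / 210),
    base |> dplyr::mutate(pos = 50L, alt_base = "T", total_edits = 5L,
                          ref_reads = 200L, alt_reads = 5L,
                          edited_fraction = 5 / 205))
  res <- apply_site_filters(sites, cfg)
  expect_equal(res$kept$pos, 50L)
  drop_of <- setNames(res$drops$n, res$drops$rule)
  expect_equal(unname(drop_of["multi_edit_type"]), 1L)   # {T, A} site
  expect_equal(unname(drop_of["snp_mask"]), 1L)
  expect_equal(unname(drop_of["min_total_edits"]), 1L)   # 2 < 3 edits
  expect_equal(unname(drop_of["max_edited_fraction"]), 1L) # 7.5% > 5%
  expect_equal(unname(drop_of["non_target"]), 1L)        # C>G conversion
})

test_that("feature aggregation sums site edits per cell and fans out overlaps", {
  site_cells <- tibble::tibble(
    contig = "chr1", pos = c(10L, 20L, 10L),
    barcode = c("b1", "b1", "b2"), edit_count = c(3L, 1L, 2L))
  fmap <- tibble::tibble(contig = "chr1", pos = c(10L, 20L, 10L),
                         feature = c("gA", "gA", "gB"))
  rc <- tidyr::expand_grid(barcode = c("b1", "b2"),
                           feature = c("gA", "gB")) |>
    dplyr::mutate(reads = 10L)
  out <- aggregate_to_features(site_cells, fmap, rc)
  expect_equal(out$edits[out$barcode == "b1" & out$feature == "gA"], 4)
  expect_equal(out$edits[out$barcode == "b2" & out$feature == "gB"], 2)
  # site 10 maps to both gA and gB: counted in each
  expect_equal(out$edits[out$barcode == "b2" & out$feature == "gA"], 2)

  # a feature with edits but missing from the read matrix is an error
  expect_error(
    aggregate_to_features(site_cells, fmap,
                          rc |> dplyr::filter(feature == "gA")),
    "gB")
})

test_that("aggregated matrix conserves kept-site edit totals on the fixture", {
  fx <- sim_fixture()
  fmap <- map_sites_to_features(fx$calls$sites, fx$models, level = "gene")
  cfm <- aggregate_to_features(fx$calls$cells, fmap,
                               fx$sim$truth$read_counts)
  mapped <- dplyr::semi_join(fx$calls$cells, fmap, by = c("contig", "pos"))
  expect_equal(sum(cfm$edits), sum(mapped$edit_count))

  # and equals a direct truth re-aggregation
  truth_cfm <- fx$sim$truth$cell_edits |>
    dplyr::semi_join(fx$calls$sites, by = c("contig", "pos")) |>
    dplyr::inner_join(fmap, by = c("contig", "pos")) |>
    dplyr::group_by(barcode, feature) |>
    dplyr::summarise(edits = sum(edit_count), .groups = "drop")
  got <- cfm |> dplyr::filter(edits > 0) |>
    dplyr::select(barcode, feature, edits)
  expect_equal(as.data.frame(got), as.data.frame(truth_cfm),
               ignore_attr = TRUE)
})

test_that("region-partitioned calling is bit-identical to a single pass", {
  fx <- sim_fixture()
  single <- fx$calls
  parts <- call_edits(fx$sim$paths$sam, fx$rc, fx$sc, models = fx$models,
                      interval_size = 1300L)
  expect_identical(as.data.frame(single$sites), as.data.frame(parts$sites))
  expect_identical(as.data.frame(single$cells), as.data.frame(parts$cells))
  expect_identical(single$drops, parts$drops)
})

test_that("identical inputs give byte-identical site TSV output", {
  fx <- sim_fixture()
  rerun <- call_edits(fx$sim$paths$sam, fx$rc, fx$sc, models = fx$models)
  d1 <- tempfile(); d2 <- tempfile()
  write_edit_calls(fx$calls, d1)
  write_edit_calls(rerun, d2)
  expect_identical(readLines(file.path(d1, "sites.tsv")),
                   readLines(file.path(d2, "sites.tsv")))
  expect_identical(readLines(file.path(d1, "edits.mtx")),
                   readLines(file.path(d2, "edits.mtx")))
})

test_that("MTX round trip preserves the cell-by-feature table", {
  cfm <- tibble::tibble(
    barcode = c("b1", "b1", "b2"), feature = c("f1", "f2", "f1"),
    edits = c(1, 0, 3), reads = c(10, 5, 8))
  d <- tempfile()
  write_cfm_mtx(cfm, d)
  back <- read_cfm_mtx(d)
  expect_equal(as.data.frame(back),
               as.data.frame(dplyr::arrange(cfm, barcode, feature)))
})
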