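# Writers for edit-calling outputs and sparse cell-by-feature exchange.

#' Write edit-calling outputs
#'
#' Writes the kept-site table as TSV, a BED file of kept sites, a
#' bedGraph of pooled edited fraction, the per-rule drop counts, and MTX
#' triplets (edits and coverage) with barcode/site label files.
#'
#' @param calls An `"edit_calls"` object from [call_edits()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_edit_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "edit_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sites = file.path(dir, "sites.tsv"),
    bed = file.path(dir, "sites.bed"),
    bedgraph = file.path(dir, "edited_fraction.bedgraph"),
    drops = file.path(dir, "drop_counts.tsv"),
    edits_mtx = file.path(dir, "edits.mtx"),
    coverage_mtx = file.path(dir, "coverage.mtx"),
    barcodes = file.path(dir, "barcodes.tsv"),
    features = file.path(dir, "sites_index.tsv"))
  readr::write_tsv(calls$sites, paths$sites)
  readr::write_tsv(calls$drops, paths$drops)

  s <- calls$sites
  if (nrow(s) > 0) {
    gr <- GenomicRanges::GRanges(
      s$contig, IRanges::IRanges(s$pos + 1L, s$pos + 1L),
      strand = s$site_strand,
      name = paste0(s$ref_base, ">", s$alt_base),
      score = s$total_edits)
    rtracklayer::export(gr, paths$bed, format = "BED")
    grf <- GenomicRanges::GRanges(
      s$contig, IRanges::IRanges(s$pos + 1L, s$pos + 1L),
      score = s$edited_fraction)
    rtracklayer::export(grf, paths$bedgraph, format = "bedGraph")
  } else {
    file.create(paths$bed)
    file.create(paths$bedgraph)
  }

  cells <- calls$cells
  site_id <- paste0(cells$contig, ":", cells$pos)
  barcodes <- sort(unique(cells$barcode))
  site_ids <- sort(unique(site_id))
  if (length(site_ids) > 0) {
    m_edit <- Matrix::sparseMatrix(
      i = match(cells$barcode, barcodes), j = match(site_id, site_ids),
      x = cells$edit_count, dims = c(length(barcodes), length(site_ids)))
    m_cov <- Matrix::sparseMatrix(
      i = match(cells$barcode, barcodes), j = match(site_id, site_ids),
      x = cells$ref_reads + cells$alt_reads,
      dims = c(length(barcodes), length(site_ids)))
    Matrix::writeMM(m_edit, paths$edits_mtx)
    Matrix::writeMM(m_cov, paths$coverage_mtx)
  }
  writeLines(barcodes, paths$barcodes)
  writeLines(site_ids, paths$features)
  invisible(paths)
}

#' Write a long cell-by-feature table as MTX triplets
#'
#' @param cfm Tibble `barcode`, `feature`, plus the value columns to
#'   write (each to its own `.mtx` file).
#' @param dir Output directory.
#' @param values Value columns to export (default `edits` and `reads`).
#' @return Invisibly, written paths.
#' @export
write_cfm_mtx <- function(cfm, dir, values = c("edits", "reads")) {
  assert_cols(cfm, c("barcode", "feature", values))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  barcodes <- sort(unique(cfm$barcode))
  features <- sort(unique(cfm$feature))
  paths <- list(barcodes = file.path(dir, "barcodes.tsv"),
                features = file.path(dir, "features.tsv"))
  writeLines(barcodes, paths$barcodes)
  writeLines(features, paths$features)
  for (v in values) {
    m <- Matrix::sparseMatrix(
      i = match(cfm$barcode, barcodes), j = match(cfm$feature, features),
      x = cfm[[v]], dims = c(length(barcodes), length(features)))
    p <- file.path(dir, paste0(v, ".mtx"))
    Matrix::writeMM(m, p)
    paths[[v]] <- p
  }
  invisible(paths)
}

#' Read MTX triplets into a long cell-by-feature table
#'
#' @param dir Directory holding `barcodes.tsv`, `features.tsv` and one or
#'   more `<value>.mtx` files.
#' @param values Value columns to read.
#' @return Tibble `barcode`, `feature`, one column per value (rows where
#'   all values are zero are omitted).
#' @export
read_cfm_mtx <- function(dir, values = c("edits", "reads")) {
  barcodes <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  features <- readr::read_lines(file.path(dir, "features.tsv"))
  mats <- purrr::map(values, function(v) {
    as(Matrix::readMM(file.path(dir, paste0(v, ".mtx"))), "CsparseMatrix")
  })
  names(mats) <- values
  nz <- Reduce(`+`, purrr::map(mats, ~ abs(.x))) != 0
  idx <- Matrix::which(nz, arr.ind = TRUE)
  out <- tibble(barcode = barcodes[idx[, 1]], feature = features[idx[, 2]])
  for (v in values) out[[v]] <- mats[[v]][idx]
  arrange(out, .data$barcode, .data$feature)
}
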