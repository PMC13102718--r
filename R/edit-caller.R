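#' Site-level filter configuration
#'
#' The edit-site filter cascade applied after tabulation and coverage:
#' sites with more than one observed alternate base are dropped, then
#' SNP-masked positions, then sites with fewer than `min_total_edits`
#' edits pooled over all cells, then sites where more than
#' `max_edited_fraction` of pooled covering reads carry the edit, then
#' (optionally) sites whose supporting-read strand conflicts with every
#' overlapping annotated gene, and finally only the `target_ref` to
#' `target_alt` conversion is retained. When `require_sense_strand` is on,
#' sites are re-oriented to transcript strand before target matching, so a
#' C-to-U event on a minus-strand gene (G>A in genomic forward space) is
#' recognised as C>T.
#'
#' For long-read libraries, where per-read edits are aggregated by isoform,
#' use `snp_mask` only: `min_total_edits = 0`, `max_edited_fraction = 1`,
#' `drop_multi_edit_type = FALSE`, `require_sense_strand = FALSE`.
#'
#' @param target_ref,target_alt Reference and alternate base of the edit
#'   conversion of interest (default C>T, i.e. C-to-U on the sense strand).
#' @param snp_mask Tibble of masked positions (`contig`, `pos` 0-based) as
#'   returned by [load_snp_mask()], or `NULL`.
#' @param drop_multi_edit_type Drop sites at which more than one alternate
#'   base was observed.
#' @param min_total_edits Minimum pooled edit count across all cells.
#' @param max_edited_fraction Maximum pooled fraction of covering reads
#'   carrying the alternate base.
#' @param require_sense_strand Apply the strand-specific annotation
#'   intersection (antisense filter) and strand-aware target matching.
#' @return A list of class `"site_filter_config"`.
#' @export
site_filter_config <- function(target_ref = "C", target_alt = "T",
                               snp_mask = NULL,
                               drop_multi_edit_type = TRUE,
                               min_total_edits = 3L,
                               max_edited_fraction = 0.05,
                               require_sense_strand = TRUE) {
  stopifnot(max_edited_fraction > 0, max_edited_fraction <= 1,
            min_total_edits >= 0)
  structure(
    list(target_ref = target_ref, target_alt = target_alt,
         snp_mask = snp_mask,
         drop_multi_edit_type = isTRUE(drop_multi_edit_type),
         min_total_edits = as.integer(min_total_edits),
         max_edited_fraction = max_edited_fraction,
         require_sense_strand = isTRUE(require_sense_strand)),
    class = "site_filter_config")
}

#' Partition contigs into processing regions
#'
#' Tiles each contig with half-open intervals of at most `interval_size`
#' bases. Regions never span contigs; their union covers every contig
#' exactly once, which underpins the region-parallel processing contract:
#' per-region tabulation merged by summation is identical to a single
#' whole-genome pass.
#'
#' @param contig_lengths Named integer vector (or named list) of contig
#'   lengths in bases.
#' @param interval_size Region size in bases; must be positive.
#' @return Tibble with columns `contig`, `start`, `end` (0-based half-open).
#' @export
partition_regions <- function(contig_lengths, interval_size) {
  stopifnot(interval_size > 0)
  contig_lengths <- unlist(contig_lengths)
  purrr::imap(contig_lengths, function(len, contig) {
    starts <- seq(0L, max(0L, len - 1L), by = interval_size)
    tibble(contig = contig, start = as.integer(starts),
           end = as.integer(pmin(starts + interval_size, len)))
  }) |> bind_rows()
}

#' Tabulate per-cell edit counts from reads
#'
#' Counts every substitution type at every non-reference position, keyed by
#' site, alternate base and cell barcode (optionally also isoform), so the
#' multi-edit-type filter can act on the full table. Counts are order
#' independent.
#'
#' @param reads Tibble from [stream_reads()].
#' @param group_by_isoform Additionally key counts by `isoform_id`.
#' @param config A [read_filter_config()] providing the base-level filters.
#' @return Tibble with columns `contig`, `pos`, `ref_base`, `alt_base`,
#'   `barcode` (and `isoform_id` if requested), `read_strand` counts
#'   `n_plus`/`n_minus`, and `edit_count`.
#' @export
tabulate_edits <- function(reads, group_by_isoform = FALSE,
                           config = read_filter_config()) {
  obs <- extract_mismatches(reads, config)
  keys <- c("contig", "pos", "ref_base", "alt_base", "barcode",
            if (group_by_isoform) "isoform_id")
  out <- obs |>
    group_by(across(all_of(keys))) |>
    summarise(edit_count = n(),
              n_plus = sum(.data$read_strand == "+"),
              n_minus = sum(.data$read_strand == "-"),
              .groups = "drop") |>
    arrange(across(all_of(keys)))
  structure(out, n_skipped = attr(obs, "n_skipped"))
}

# Collapse a per-cell edit table to site level: one row per
# (contig, pos, ref_base), recording the number of distinct alternate
# bases, the dominant alternate base and its pooled count, and the
# site strand inferred from supporting reads (majority vote, '+' on ties).
summarize_sites <- function(cell_edits) {
  by_alt <- cell_edits |>
    group_by(.data$contig, .data$pos, .data$ref_base, .data$alt_base) |>
    summarise(n_edits = sum(.data$edit_count),
              n_plus = sum(.data$n_plus), n_minus = sum(.data$n_minus),
              .groups = "drop")
  by_alt |>
    group_by(.data$contig, .data$pos, .data$ref_base) |>
    summarise({
      ab <- .data$alt_base
      ne <- .data$n_edits
      np <- .data$n_plus
      nm <- .data$n_minus
      o <- order(-ne, ab)
      tibble(n_alt_types = dplyr::n_distinct(ab),
             alt_base = ab[o[1]], total_edits = ne[o[1]],
             site_strand = if (sum(nm) > sum(np)) "-" else "+")
    }, .groups = "drop")
}

#' Compute per-cell coverage at candidate sites
#'
#' For each (site, barcode) pair, counts passing reads whose aligned base
#' at the site equals the site reference (`ref_reads`) or alternate
#' (`alt_reads`). Reads whose alignment skips or deletes the position
#' contribute nothing, as do `N` bases and bases failing the base-quality
#' or read-end filters (the same base-level filters used for edit
#' tabulation, so edit and coverage counts are mutually consistent).
#'
#' By default only barcodes carrying at least one edit at the site are
#' reported (the cells in which coverage is needed to form edit
#' fractions); `all_barcodes = TRUE` reports every covering barcode.
#'
#' @param reads Tibble from [stream_reads()].
#' @param sites Site table with columns `contig`, `pos`, `ref_base`,
#'   `alt_base` (e.g. from [summarize_sites()] via [call_edits()]).
#' @param config A [read_filter_config()].
#' @param all_barcodes Report coverage for all barcodes, not only edited
#'   ones. Requires `cell_edits = NULL` semantics; see Details.
#' @param cell_edits Per-cell edit table used to restrict reporting to
#'   edited barcodes when `all_barcodes = FALSE`.
#' @return Tibble with columns `contig`, `pos`, `barcode`, `ref_reads`,
#'   `alt_reads`.
#' @export
compute_site_coverage <- function(reads, sites, config = read_filter_config(),
                                  all_barcodes = FALSE, cell_edits = NULL) {
  assert_cols(sites, c("contig", "pos", "ref_base", "alt_base"))
  empty <- tibble(contig = character(), pos = integer(), barcode = character(),
                  ref_reads = integer(), alt_reads = integer())
  if (nrow(reads) == 0 || nrow(sites) == 0) return(empty)

  site_pos <- sites |> distinct(.data$contig, .data$pos)
  # expand reads overlapping any site to per-base rows at site positions
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    span_hit <- site_pos$contig == r$contig & site_pos$pos >= r$start &
      site_pos$pos < r$start + nchar(r$seq) + 1000L
    if (!any(span_hit)) next
    ap <- aligned_pairs(r$cigar, r$start)
    hit <- ap$refpos %in% site_pos$pos[span_hit]
    if (!any(hit)) next
    qpos <- ap$qpos[hit]
    qlen <- nchar(r$seq)
    base <- substring(r$seq, qpos + 1L, qpos + 1L)
    qv <- r$quals[[1]][qpos + 1L]
    dist <- pmin(qpos, qlen - 1L - qpos)
    ok <- base != "N" & qv >= config$min_base_qual &
      dist >= config$min_dist_from_end
    if (!any(ok)) next
    rows[[i]] <- tibble(contig = r$contig, pos = ap$refpos[hit][ok],
                        barcode = r$barcode, base = base[ok])
  }
  bases <- bind_rows(rows)
  if (nrow(bases) == 0) return(empty)

  cov <- bases |>
    inner_join(sites |> select("contig", "pos", "ref_base", "alt_base"),
               by = c("contig", "pos")) |>
    group_by(.data$contig, .data$pos, .data$barcode) |>
    summarise(ref_reads = sum(.data$base == .data$ref_base),
              alt_reads = sum(.data$base == .data$alt_base),
              .groups = "drop")
  if (!all_barcodes) {
    if (is.null(cell_edits)) {
      stop_input("cell_edits must be supplied when all_barcodes = FALSE")
    }
    cov <- cov |>
      semi_join(cell_edits, by = c("contig", "pos", "barcode"))
  }
  arrange(cov, .data$contig, .data$pos, .data$barcode)
}

# Map sites onto overlapping transcript models; returns, per site, the
# set of overlapping gene strands (distinct gene_id/strand pairs).
overlapping_genes <- function(sites, models) {
  if (is.null(models) || nrow(sites) == 0) {
    return(tibble(contig = character(), pos = integer(),
                  gene_id = character(), gene_strand = character()))
  }
  ex <- models |> filter(.data$region == "exon")
  gr_ex <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start + 1L, ex$end),
    gene_id = ex$gene_id, gene_strand = ex$strand)
  gr_site <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_site, gr_ex, ignore.strand = TRUE)
  tibble(contig = sites$contig[S4Vectors::queryHits(hits)],
         pos = sites$pos[S4Vectors::queryHits(hits)],
         gene_id = gr_ex$gene_id[S4Vectors::subjectHits(hits)],
         gene_strand = gr_ex$gene_strand[S4Vectors::subjectHits(hits)]) |>
    distinct()
}

#' Apply the edit-site filter cascade
#'
#' Applies, in order: multi-edit-type, SNP mask, minimum pooled edits,
#' maximum pooled edited fraction, antisense (strand conflict with every
#' overlapping annotated gene; only when `require_sense_strand`), and
#' finally the target-conversion rule (strand re-oriented when
#' `require_sense_strand`). Each dropped site is attributed to the first
#' rule it fails; per-rule counts are returned for auditability.
#'
#' @param sites Site table from [summarize_sites()] with pooled coverage
#'   columns `ref_reads`, `alt_reads` and `edited_fraction` attached (see
#'   [call_edits()]).
#' @param cfg A [site_filter_config()].
#' @param models Optional transcript models from [load_transcript_models()]
#'   (needed for the antisense rule and strand-aware orientation).
#' @return A list with `kept` (site tibble, re-oriented `ref_base`/
#'   `alt_base` when strand-aware) and `drops` (tibble of `rule`, `n`).
#' @export
apply_site_filters <- function(sites, cfg = site_filter_config(),
                               models = NULL) {
  rules <- c("multi_edit_type", "snp_mask", "min_total_edits",
             "max_edited_fraction", "antisense", "non_target")
  drops <- setNames(integer(length(rules)), rules)
  if (nrow(sites) == 0) {
    return(list(kept = sites,
                drops = tibble(rule = rules, n = unname(drops))))
  }
  active <- rep(TRUE, nrow(sites))
  drop_by <- function(active, fail, rule) {
    fail <- active & fail
    drops[rule] <<- sum(fail)
    active & !fail
  }

  if (cfg$drop_multi_edit_type) {
    active <- drop_by(active, sites$n_alt_types > 1L, "multi_edit_type")
  }
  if (!is.null(cfg$snp_mask) && nrow(cfg$snp_mask) > 0) {
    key <- paste(sites$contig, sites$pos)
    in_mask <- key %in% paste(cfg$snp_mask$contig, cfg$snp_mask$pos)
    active <- drop_by(active, in_mask, "snp_mask")
  }
  active <- drop_by(active, sites$total_edits < cfg$min_total_edits,
                    "min_total_edits")
  active <- drop_by(active, sites$edited_fraction > cfg$max_edited_fraction,
                    "max_edited_fraction")

  oriented_ref <- sites$ref_base
  oriented_alt <- sites$alt_base
  if (cfg$require_sense_strand) {
    ov <- overlapping_genes(sites, models)
    key <- paste(sites$contig, sites$pos)
    ov_key <- paste(ov$contig, ov$pos)
    has_gene <- key %in% ov_key
    ov_site_strand <- sites$site_strand[match(ov_key, key)]
    sense_ok <- key %in% unique(ov_key[ov$gene_strand == ov_site_strand])
    # a site conflicts only if it overlaps >=1 gene and none share its strand
    active <- drop_by(active, has_gene & !sense_ok, "antisense")
    flip <- sites$site_strand == "-"
    oriented_ref[flip] <- complement_base(oriented_ref[flip])
    oriented_alt[flip] <- complement_base(oriented_alt[flip])
  }
  is_target <- oriented_ref == cfg$target_ref & oriented_alt == cfg$target_alt
  active <- drop_by(active, !is_target, "non_target")

  kept <- sites[active, , drop = FALSE]
  kept$ref_base <- oriented_ref[active]
  kept$alt_base <- oriented_alt[active]
  list(kept = kept, drops = tibble(rule = rules, n = unname(drops)))
}

#' Call edits from an alignment file
#'
#' End-to-end orchestration of the edit-calling engine: stream reads,
#' tabulate per-cell substitutions, summarise candidate sites, compute
#' pooled and per-cell coverage, and apply the site-filter cascade.
#' Processing can be split into genomic regions (reads are assigned to the
#' region containing their leftmost aligned position); merged per-region
#' results are identical to a single pass.
#'
#' @param path SAM/BAM file path.
#' @param read_config A [read_filter_config()].
#' @param site_config A [site_filter_config()].
#' @param models Optional transcript models from [load_transcript_models()].
#' @param interval_size Optional region size in bases for partitioned
#'   processing; `NULL` processes the whole file in one pass.
#' @param group_by_isoform Key edit counts additionally by isoform tag.
#' @return A list of class `"edit_calls"`: `sites` (kept sites with pooled
#'   coverage and edited fraction), `cells` (per-site, per-barcode edit and
#'   coverage counts for kept sites), `drops` (per-rule drop counts),
#'   `n_skipped` (malformed reads).
#' @export
call_edits <- function(path, read_config = read_filter_config(),
                       site_config = site_filter_config(),
                       models = NULL, interval_size = NULL,
                       group_by_isoform = FALSE) {
  reads <- stream_reads(path, config = read_config)
  if (!is.null(interval_size)) {
    lens <- contig_lengths_from_header(path)
    regions <- partition_regions(lens, interval_size)
    chunks <- purrr::pmap(regions, function(contig, start, end) {
      reads[reads$contig == contig & reads$start >= start &
              reads$start < end, , drop = FALSE]
    })
  } else {
    chunks <- list(reads)
  }

  keys <- c("contig", "pos", "ref_base", "alt_base", "barcode",
            if (group_by_isoform) "isoform_id")
  tabs <- purrr::map(chunks, tabulate_edits,
                     group_by_isoform = group_by_isoform,
                     config = read_config)
  n_skipped <- sum(purrr::map_int(tabs, ~ attr(.x, "n_skipped") %||% 0L))
  cell_edits <- bind_rows(tabs) |>
    group_by(across(all_of(keys))) |>
    summarise(edit_count = sum(.data$edit_count),
              n_plus = sum(.data$n_plus), n_minus = sum(.data$n_minus),
              .groups = "drop")

  sites <- summarize_sites(cell_edits)
  # restrict the per-cell table to each site's dominant alternate base
  site_cells <- cell_edits |>
    inner_join(sites |> select("contig", "pos", "ref_base", "alt_base"),
               by = c("contig", "pos", "ref_base", "alt_base"))

  covs <- purrr::map(chunks, compute_site_coverage, sites = sites,
                     config = read_config, all_barcodes = TRUE)
  cov <- bind_rows(covs) |>
    group_by(.data$contig, .data$pos, .data$barcode) |>
    summarise(ref_reads = sum(.data$ref_reads),
              alt_reads = sum(.data$alt_reads), .groups = "drop")

  pooled <- cov |>
    group_by(.data$contig, .data$pos) |>
    summarise(ref_reads = sum(.data$ref_reads),
              alt_reads = sum(.data$alt_reads), .groups = "drop") |>
    mutate(edited_fraction = if_else(
      .data$ref_reads + .data$alt_reads > 0,
      .data$alt_reads / (.data$ref_reads + .data$alt_reads), 0))
  sites <- sites |>
    left_join(pooled, by = c("contig", "pos")) |>
    mutate(ref_reads = dplyr::coalesce(.data$ref_reads, 0L),
           alt_reads = dplyr::coalesce(.data$alt_reads, 0L),
           edited_fraction = dplyr::coalesce(.data$edited_fraction, 0))

  filtered <- apply_site_filters(sites, site_config, models)
  kept_cells <- site_cells |>
    semi_join(filtered$kept, by = c("contig", "pos")) |>
    left_join(cov, by = c("contig", "pos", "barcode")) |>
    mutate(ref_reads = dplyr::coalesce(.data$ref_reads, 0L),
           alt_reads = dplyr::coalesce(.data$alt_reads, 0L)) |>
    arrange(across(all_of(keys)))

  structure(list(sites = arrange(filtered$kept, .data$contig, .data$pos),
                 cells = kept_cells,
                 drops = filtered$drops,
                 n_skipped = n_skipped),
            class = "edit_calls")
}

contig_lengths_from_header <- function(path) {
  bam <- ensure_bam(path)
  h <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  h
}

#' Aggregate kept edit sites to a cell-by-feature table
#'
#' Sums per-cell edit counts over each feature's sites (a site overlapping
#' several same-strand genes is counted in each) and joins externally
#' supplied per-cell read counts, producing the long-form cell-by-feature
#' table used by the quantification functions.
#'
#' @param site_cells Per-site, per-barcode edit counts (`contig`, `pos`,
#'   `barcode`, `edit_count`), e.g. `cells` from [call_edits()].
#' @param feature_map Tibble mapping sites to features: `contig`, `pos`,
#'   `feature`.
#' @param read_counts Tibble of per-cell read counts: `barcode`, `feature`,
#'   `reads`.
#' @return Tibble with columns `barcode`, `feature`, `edits`, `reads`
#'   (absent cell-feature pairs are implicit zeros; pairs present in
#'   `read_counts` but without edits are kept with `edits = 0`).
#' @export
aggregate_to_features <- function(site_cells, feature_map, read_counts) {
  assert_cols(feature_map, c("contig", "pos", "feature"))
  assert_cols(read_counts, c("barcode", "feature", "reads"))
  edits <- site_cells |>
    inner_join(feature_map, by = c("contig", "pos"),
               relationship = "many-to-many") |>
    group_by(.data$barcode, .data$feature) |>
    summarise(edits = sum(.data$edit_count), .groups = "drop")
  missing <- setdiff(unique(edits$feature), unique(read_counts$feature))
  if (length(missing) > 0) {
    stop_input("feature(s) with edits absent from read counts: %s",
               paste(missing, collapse = ", "))
  }
  read_counts |>
    left_join(edits, by = c("barcode", "feature")) |>
    mutate(edits = dplyr::coalesce(.data$edits, 0L)) |>
    select("barcode", "feature", "edits", "reads") |>
    arrange(.data$barcode, .data$feature)
}

#' Map edit sites to overlapping features
#'
#' Builds a site-to-feature map by overlapping site positions with exon
#' intervals of the transcript models, at gene or transcript level.
#'
#' @param sites Site table with `contig`, `pos` (0-based).
#' @param models Transcript models from [load_transcript_models()].
#' @param level `"gene"` or `"transcript"`.
#' @param same_strand_only Keep only features on the site's inferred
#'   strand (requires a `site_strand` column).
#' @return Tibble `contig`, `pos`, `feature`.
#' @export
map_sites_to_features <- function(sites, models,
                                  level = c("gene", "transcript"),
                                  same_strand_only = FALSE) {
  level <- match.arg(level)
  ex <- models |> filter(.data$region == "exon")
  feat_id <- if (level == "gene") ex$gene_id else ex$transcript_id
  gr_ex <- GenomicRanges::GRanges(
    ex$contig, IRanges::IRanges(ex$start + 1L, ex$end),
    feature = feat_id, feat_strand = ex$strand)
  gr_site <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  hits <- GenomicRanges::findOverlaps(gr_site, gr_ex, ignore.strand = TRUE)
  out <- tibble(contig = sites$contig[S4Vectors::queryHits(hits)],
                pos = sites$pos[S4Vectors::queryHits(hits)],
                feature = gr_ex$feature[S4Vectors::subjectHits(hits)],
                feat_strand = gr_ex$feat_strand[S4Vectors::subjectHits(hits)])
  if (same_strand_only) {
    assert_cols(sites, "site_strand")
    strand <- sites$site_strand[S4Vectors::queryHits(hits)]
    out <- out[out$feat_strand == strand, , drop = FALSE]
  }
  out |> select("contig", "pos", "feature") |> distinct()
}
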