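#' Read-level filter configuration
#'
#' Bundles the read- and base-level exclusion thresholds applied when
#' streaming alignments and extracting mismatches. Defaults reflect common
#' practice for 10x-style short-read libraries: no mapping-quality floor
#' (barcoded reads are already confidently placed upstream), Phred 20 for
#' individual bases, and a 5-bp exclusion zone at read ends where base
#' quality decays.
#'
#' @param min_mapq Minimum mapping quality; reads below are dropped.
#' @param min_base_qual Minimum Phred base quality for a mismatch to count.
#' @param min_dist_from_end Minimum distance (bases) of a mismatch from
#'   either end of the stored read sequence.
#' @param require_umi_rep_tag If `TRUE`, keep only reads carrying `xf:i:25`,
#'   the tag marking the confidently mapped representative read of a UMI.
#'   Use `FALSE` for bulk or long-read libraries deduplicated upstream.
#' @param barcode_whitelist Optional character vector of valid cell
#'   barcodes; reads with a `CB` tag outside the whitelist are dropped.
#'   `NULL` disables whitelist filtering.
#' @return A list of class `"read_filter_config"`.
#' @export
read_filter_config <- function(min_mapq = 0L,
                               min_base_qual = 20L,
                               min_dist_from_end = 5L,
                               require_umi_rep_tag = TRUE,
                               barcode_whitelist = NULL) {
  stopifnot(min_mapq >= 0, min_base_qual >= 0, min_dist_from_end >= 0)
  structure(
    list(min_mapq = as.integer(min_mapq),
         min_base_qual = as.integer(min_base_qual),
         min_dist_from_end = as.integer(min_dist_from_end),
         require_umi_rep_tag = isTRUE(require_umi_rep_tag),
         barcode_whitelist = barcode_whitelist),
    class = "read_filter_config")
}

# SAM flag bits used by the read-level exclusions.
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

# Convert a SAM file to a sorted, indexed BAM next to it (in tempdir) so a
# single reader path handles both dialects.
ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
    bam
  } else {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
      Rsamtools::indexBam(path)
    }
    path
  }
}

#' Stream aligned reads into a tibble
#'
#' Parses a coordinate-sorted SAM/BAM file (tags `CB`, `xf`, `IB`/`IS`,
#' `MD`) and applies the read-level exclusions: unmapped, secondary,
#' supplementary and QC-fail reads are always dropped; reads below
#' `min_mapq`, reads lacking the `xf:i:25` UMI-representative tag (when
#' required) and reads whose barcode is missing from the whitelist are
#' dropped per the configuration.
#'
#' @param path Path to a SAM or BAM file.
#' @param region Optional region as a `GRanges` of length 1 or a
#'   `"contig:start-end"` string (1-based, as in samtools).
#' @param config A [read_filter_config()].
#' @return A tibble with one row per retained read: `read_id`, `contig`,
#'   `start` (0-based), `strand`, `mapq`, `flag`, `cigar`, `md`, `seq`,
#'   `quals` (list-column of integer Phred scores), `barcode`,
#'   `isoform_id`, `has_umi_rep_tag`. Rows follow file order within the
#'   region.
#' @export
stream_reads <- function(path, region = NULL, config = read_filter_config()) {
  if (!file.exists(path)) stop_input("alignment file not found: %s", path)
  bam <- ensure_bam(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  tags <- c("CB", "xf", "IB", "IS", "MD")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, tag = tags)
  } else {
    if (is.character(region)) {
      m <- regmatches(region,
                      regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
      if (length(m) != 4) stop_input("cannot parse region '%s'", region)
      region <- GenomicRanges::GRanges(
        m[2], IRanges::IRanges(as.integer(m[3]), as.integer(m[4])))
    }
    param <- Rsamtools::ScanBamParam(what = what, tag = tags, which = region)
  }
  res <- unname(Rsamtools::scanBam(bam, param = param))
  # concatenate chunks (one element per region; NULL region gives one)
  fields <- purrr::map(what, function(w) do.call(c, purrr::map(res, ~ .x[[w]])))
  names(fields) <- what
  tagv <- purrr::map(tags, function(tg) {
    do.call(c, purrr::map(res, function(chunk) {
      v <- chunk$tag[[tg]]
      n <- length(chunk$qname)
      if (is.null(v)) rep(NA, n) else v
    }))
  })
  names(tagv) <- tags

  n <- length(fields$qname)
  if (n == 0) return(empty_reads())
  quals <- as.list(as(Biostrings::PhredQuality(fields$qual), "IntegerList"))
  reads <- tibble(
    read_id = fields$qname,
    contig = as.character(fields$rname),
    start = fields$pos - 1L,
    strand = ifelse(bitwAnd(fields$flag, FLAG_REVERSE) > 0L, "-", "+"),
    mapq = fields$mapq,
    flag = fields$flag,
    cigar = fields$cigar,
    md = as.character(tagv$MD),
    seq = as.character(fields$seq),
    quals = quals,
    barcode = as.character(tagv$CB),
    isoform_id = dplyr::coalesce(as.character(tagv$IB), as.character(tagv$IS)),
    has_umi_rep_tag = !is.na(tagv$xf) & tagv$xf == 25L
  )
  apply_read_filters(reads, config)
}

empty_reads <- function() {
  tibble(read_id = character(), contig = character(), start = integer(),
         strand = character(), mapq = integer(), flag = integer(),
         cigar = character(), md = character(), seq = character(),
         quals = list(), barcode = character(), isoform_id = character(),
         has_umi_rep_tag = logical())
}

apply_read_filters <- function(reads, config) {
  bad <- bitwAnd(reads$flag,
                 FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY +
                   FLAG_QCFAIL) > 0L
  keep <- !bad & reads$mapq >= config$min_mapq
  if (config$require_umi_rep_tag) keep <- keep & reads$has_umi_rep_tag
  if (!is.null(config$barcode_whitelist)) {
    keep <- keep & !is.na(reads$barcode) &
      reads$barcode %in% config$barcode_whitelist
  }
  reads[keep, , drop = FALSE]
}

#' Extract substitution observations from reads
#'
#' Reconstructs every single-base substitution carried by the reads from
#' their MD and CIGAR tags, without consulting the reference genome.
#' Insertions and deleted reference bases contribute nothing. Observations
#' at `N` reference or read bases, below `min_base_qual`, or closer than
#' `min_dist_from_end` to either read end are omitted.
#'
#' Reads whose MD tag is inconsistent with their CIGAR/sequence are skipped
#' and counted in the `n_skipped` attribute of the result.
#'
#' @param reads Tibble from [stream_reads()] (or a compatible tibble).
#' @param config A [read_filter_config()].
#' @return Tibble of observations: `contig`, `pos` (0-based), `ref_base`,
#'   `alt_base`, `read_strand`, `barcode`, `isoform_id`, `base_qual`,
#'   `dist_from_end`, `read_id`; attribute `n_skipped` counts malformed
#'   reads.
#' @export
extract_mismatches <- function(reads, config = read_filter_config()) {
  assert_cols(reads, c("read_id", "contig", "start", "strand", "cigar",
                       "md", "seq", "quals", "barcode", "isoform_id"))
  empty <- tibble(contig = character(), pos = integer(),
                  ref_base = character(), alt_base = character(),
                  read_strand = character(), barcode = character(),
                  isoform_id = character(), base_qual = integer(),
                  dist_from_end = integer(), read_id = character())
  if (nrow(reads) == 0) return(structure(empty, n_skipped = 0L))

  # Only reads whose MD contains a substitution letter can yield rows
  # (letters after '^' are deletions, stripped before the scan).
  has_sub <- grepl("[ACGTN]", gsub("\\^[A-Z]+", "", reads$md))
  cand <- reads[has_sub & !is.na(reads$md), , drop = FALSE]
  n_skipped <- 0L
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    if (cigar_query_length(r$cigar) != nchar(r$seq)) {
      n_skipped <- n_skipped + 1L
      next
    }
    sub <- md_substitutions(r$cigar, r$md, r$seq, r$start)
    if (is.null(sub)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (nrow(sub) == 0) next
    qlen <- nchar(r$seq)
    alt <- substring(r$seq, sub$qpos + 1L, sub$qpos + 1L)
    qv <- r$quals[[1]][sub$qpos + 1L]
    dist <- pmin(sub$qpos, qlen - 1L - sub$qpos)
    keep <- alt != "N" & sub$ref_base != "N" &
      qv >= config$min_base_qual & dist >= config$min_dist_from_end
    if (!any(keep)) next
    rows[[i]] <- tibble(
      contig = r$contig, pos = sub$refpos[keep],
      ref_base = sub$ref_base[keep], alt_base = alt[keep],
      read_strand = r$strand, barcode = r$barcode,
      isoform_id = r$isoform_id, base_qual = qv[keep],
      dist_from_end = dist[keep], read_id = r$read_id)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty
  structure(out, n_skipped = n_skipped)
}

#' Load transcript models from a GTF file
#'
#' Imports gene/transcript/exon/CDS features and returns one row per
#' transcript region interval, in 0-based half-open coordinates. When a
#' transcript has CDS but no explicit UTR features, 5' and 3' UTRs are
#' derived from the exon/CDS geometry (strand-aware); explicit
#' `five_prime_utr`/`three_prime_utr` (or `UTR`) features take precedence.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes.
#' @return A tibble with columns `transcript_id`, `gene_id`, `biotype`,
#'   `contig`, `strand`, `region` (`exon`, `cds`, `utr5`, `utr3`), `start`,
#'   `end` (0-based half-open), sorted by transcript and start.
#' @export
load_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!"transcript_id" %in% names(df)) {
    stop_input("GTF lacks transcript_id attributes: %s", path)
  }
  if (!"transcript_biotype" %in% names(df)) df$transcript_biotype <- NA_character_
  feat <- df |>
    filter(!is.na(.data$transcript_id)) |>
    mutate(start0 = .data$start - 1L, end0 = .data$end,
           type = as.character(.data$type),
           strand = as.character(.data$strand))

  exons <- feat |> filter(.data$type == "exon")
  if (nrow(exons) == 0) stop_input("GTF contains no exon features: %s", path)
  no_exon <- setdiff(unique(feat$transcript_id), unique(exons$transcript_id))
  if (length(no_exon) > 0) {
    stop_input("transcript(s) with no exons: %s", paste(no_exon, collapse = ", "))
  }

  per_tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(gene_id = dplyr::first(.data$gene_id),
              biotype = dplyr::first(.data$transcript_biotype),
              contig = as.character(dplyr::first(.data$seqnames)),
              strand = dplyr::first(.data$strand), .groups = "drop")

  interval_rows <- function(sub, region) {
    tibble(transcript_id = sub$transcript_id, region = region,
           start = sub$start0, end = sub$end0)
  }
  out <- interval_rows(exons, "exon")
  cds <- feat |> filter(.data$type == "CDS")
  if (nrow(cds) > 0) out <- bind_rows(out, interval_rows(cds, "cds"))

  utr_types <- c(five_prime_utr = "utr5", three_prime_utr = "utr3")
  explicit <- feat |> filter(.data$type %in% names(utr_types))
  if (nrow(explicit) > 0) {
    out <- bind_rows(out, explicit |>
      mutate(region = unname(utr_types[.data$type])) |>
      select("transcript_id", "region", start = "start0", end = "end0"))
  }

  # Derive UTRs where a CDS exists but no explicit UTR features were given.
  need <- setdiff(unique(cds$transcript_id), unique(explicit$transcript_id))
  for (tx in need) {
    ex <- out |> filter(.data$transcript_id == tx, .data$region == "exon")
    cd <- out |> filter(.data$transcript_id == tx, .data$region == "cds")
    strand <- per_tx$strand[per_tx$transcript_id == tx]
    exr <- IRanges::IRanges(ex$start + 1L, ex$end)
    cds_lo <- min(cd$start)
    cds_hi <- max(cd$end)
    up <- IRanges::restrict(exr, end = cds_lo)       # [.., cds_lo) in 0-based
    dn <- IRanges::restrict(exr, start = cds_hi + 1L)
    to_tbl <- function(ir, region) {
      ir <- ir[IRanges::width(ir) > 0]
      if (length(ir) == 0) return(NULL)
      tibble(transcript_id = tx, region = region,
             start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }
    if (strand == "+") {
      out <- bind_rows(out, to_tbl(up, "utr5"), to_tbl(dn, "utr3"))
    } else {
      out <- bind_rows(out, to_tbl(dn, "utr5"), to_tbl(up, "utr3"))
    }
  }

  out |>
    inner_join(per_tx, by = "transcript_id") |>
    select("transcript_id", "gene_id", "biotype", "contig", "strand",
           "region", "start", "end") |>
    arrange(.data$transcript_id, .data$region, .data$start)
}

#' Load a SNP mask from VCF or BED
#'
#' Returns the set of masked genomic positions in 0-based coordinates.
#' VCF records contribute their (1-based) `POS` converted to 0-based;
#' multi-allelic records contribute their position once. BED intervals are
#' expanded to the individual positions they cover.
#'
#' @param path Path to a `.vcf` (or `.vcf.gz`) or `.bed` file.
#' @return A tibble with columns `contig`, `pos` (0-based), one row per
#'   distinct masked position.
#' @export
load_snp_mask <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    out <- tibble(contig = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr) - 1L)
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0) {
      return(tibble(contig = character(), pos = integer()))
    }
    pos <- unlist(purrr::map2(GenomicRanges::start(gr), GenomicRanges::end(gr),
                              function(s, e) seq(s - 1L, e - 1L)))
    out <- tibble(
      contig = rep(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::width(gr)),
      pos = as.integer(pos))
  } else {
    stop_input("unknown SNP mask extension (expect .vcf or .bed): %s", path)
  }
  distinct(out)
}

#' Load a cell-barcode whitelist
#'
#' @param path Plain-text file with one barcode per line.
#' @return Character vector of barcodes.
#' @export
load_whitelist <- function(path) {
  bc <- readr::read_lines(path, progress = FALSE)
  bc[nzchar(bc)]
}
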