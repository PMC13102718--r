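#' GC content of nucleotide sequences
#'
#' Fraction of G and C among the unambiguous bases (A/C/G/T); `N` bases
#' are excluded from the denominator. A sequence with no unambiguous base
#' yields `NA`.
#'
#' @param sequence Character vector of sequences over `{A,C,G,T,N}`.
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(sequence) {
  bad <- !grepl("^[ACGTN]*$", sequence)
  if (any(bad)) {
    stop_input("illegal character(s) in sequence(s): %s",
               paste(head(which(bad), 5), collapse = ", "))
  }
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(sequence), c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- (counts[, "G"] + counts[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  unname(gc)
}

#' Spliced region lengths per transcript
#'
#' Sums interval widths of the 5' UTR, CDS and 3' UTR per transcript
#' (introns excluded). Transcripts with no CDS get `cds_len = 0` and are
#' flagged noncoding.
#'
#' @param models Transcript models from [load_transcript_models()].
#' @return Tibble `transcript_id`, `utr5_len`, `cds_len`, `utr3_len`,
#'   `noncoding`.
#' @export
region_lengths <- function(models) {
  assert_cols(models, c("transcript_id", "region", "start", "end"))
  len <- models |>
    filter(.data$region %in% c("utr5", "cds", "utr3")) |>
    group_by(.data$transcript_id, .data$region) |>
    summarise(len = sum(.data$end - .data$start), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "len",
                       values_fill = 0L)
  for (col in c("utr5", "cds", "utr3")) {
    if (!col %in% names(len)) len[[col]] <- 0L
  }
  models |>
    distinct(.data$transcript_id) |>
    left_join(len, by = "transcript_id") |>
    mutate(across(c("utr5", "cds", "utr3"), ~ dplyr::coalesce(.x, 0L))) |>
    transmute(transcript_id = .data$transcript_id,
              utr5_len = .data$utr5, cds_len = .data$cds,
              utr3_len = .data$utr3, noncoding = .data$cds == 0L)
}

#' Count binding-site intervals overlapping transcript regions
#'
#' For each transcript's region set (e.g. its 3' UTR intervals), counts
#' the site intervals (BED-style, 0-based half-open) with at least 1 bp of
#' overlap. Each site is counted once per transcript even when it touches
#' several of the transcript's intervals.
#'
#' @param regions Tibble of transcript intervals: `transcript_id`,
#'   `contig`, `start`, `end` (0-based half-open), optionally `strand`.
#' @param sites Tibble of site intervals: `contig`, `start`, `end`,
#'   optionally `strand`; or a path to a BED file.
#' @param strand_aware Require matching strand (both inputs need strand).
#' @return Tibble `transcript_id`, `n_sites` (zero-count transcripts
#'   included).
#' @export
count_overlaps <- function(regions, sites, strand_aware = FALSE) {
  assert_cols(regions, c("transcript_id", "contig", "start", "end"))
  if (is.character(sites) && length(sites) == 1) {
    gr <- rtracklayer::import(sites, format = "bed")
    sites <- tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  }
  assert_cols(sites, c("contig", "start", "end"))
  all_tx <- distinct(regions, .data$transcript_id)
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    return(all_tx |> mutate(n_sites = 0L))
  }
  gr_reg <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end),
    strand = if (strand_aware) regions$strand else "*")
  gr_site <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$start + 1L, sites$end),
    strand = if (strand_aware && "strand" %in% names(sites)) sites$strand else "*")
  hits <- GenomicRanges::findOverlaps(gr_site, gr_reg,
                                      ignore.strand = !strand_aware)
  counted <- tibble(site = S4Vectors::queryHits(hits),
                    transcript_id =
                      regions$transcript_id[S4Vectors::subjectHits(hits)]) |>
    distinct() |>
    count(.data$transcript_id, name = "n_sites")
  all_tx |>
    left_join(counted, by = "transcript_id") |>
    mutate(n_sites = as.integer(dplyr::coalesce(.data$n_sites, 0L)))
}

#' Two-sided Mann-Whitney U comparison
#'
#' Rank-sum comparison of two groups of values: exact p by complete
#' enumeration when both groups have at most 8 observations and there are
#' no ties, otherwise the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @return Tibble with `u` (number of (a, b) pairs with a > b, ties
#'   counting one half), `p` (two-sided) and `method`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop_input("both groups must be non-empty")
  }
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = FALSE))
  tibble(u = unname(wt$statistic), p = wt$p.value,
         method = if (exact) "exact" else "normal_tie_corrected")
}

#' Spliced sense-strand sequence per transcript
#'
#' Concatenates the exon sequences in genomic order and reverse-complements
#' for minus-strand transcripts, giving the mRNA sense sequence.
#'
#' @param models Transcript models from [load_transcript_models()].
#' @param genome A named `DNAStringSet` (one entry per contig) or a path
#'   to a FASTA file.
#' @param region Which region to splice (default `"exon"`).
#' @return Tibble `transcript_id`, `sequence`.
#' @export
transcript_sequences <- function(models, genome, region = "exon") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  sel <- models |> filter(.data$region == !!region)
  sel |>
    group_by(.data$transcript_id) |>
    dplyr::group_map(function(df, key) {
      df <- df[order(df$start), ]
      contig <- df$contig[1]
      if (!contig %in% names(genome)) {
        stop_input("contig '%s' absent from genome", contig)
      }
      parts <- substring(as.character(genome[[contig]]),
                         df$start + 1L, df$end)
      seq <- paste(parts, collapse = "")
      if (df$strand[1] == "-") {
        seq <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      tibble(transcript_id = key$transcript_id, sequence = seq)
    }) |>
    bind_rows()
}

#' Cytosine content of spliced transcripts
#'
#' Counts C on the mRNA sense strand across all exons (the EditsC
#' denominator): C on plus-strand genes, G on minus-strand genes in
#' genomic forward space.
#'
#' @inheritParams transcript_sequences
#' @return Tibble `feature` (transcript id), `c_count`.
#' @export
transcript_c_content <- function(models, genome) {
  seqs <- transcript_sequences(models, genome)
  tibble(feature = seqs$transcript_id,
         c_count = as.integer(Biostrings::letterFrequency(
           Biostrings::DNAStringSet(seqs$sequence), "C")[, 1]))
}

#' Transcript feature profiles
#'
#' Combines region lengths, per-region GC content and binding-site
#' overlap counts into one row per transcript. The optional 5'TOP column
#' is a heuristic scan (5'-terminal C followed by four or more
#' pyrimidines); supply a curated list instead where available.
#'
#' @param models Transcript models from [load_transcript_models()].
#' @param genome Genome as in [transcript_sequences()].
#' @param mirna_sites,rbp_sites Optional site interval tibbles (or BED
#'   paths) counted against the 3' UTR; see [count_overlaps()].
#' @param strand_aware Strand-aware site counting (default `TRUE`).
#' @param detect_top_motif Add the heuristic `top_motif` flag.
#' @return Tibble with one row per transcript: lengths, GC fractions
#'   (`NA` where a region is absent), site counts.
#' @export
transcript_feature_profile <- function(models, genome, mirna_sites = NULL,
                                       rbp_sites = NULL, strand_aware = TRUE,
                                       detect_top_motif = FALSE) {
  lens <- region_lengths(models)
  prof <- lens
  gc_of_region <- function(region) {
    present <- models |> filter(.data$region == !!region)
    if (nrow(present) == 0) {
      return(tibble(transcript_id = character(), gc = numeric()))
    }
    seqs <- transcript_sequences(models |>
                                   semi_join(present, by = "transcript_id"),
                                 genome, region = region)
    tibble(transcript_id = seqs$transcript_id, gc = gc_content(seqs$sequence))
  }
  prof <- prof |>
    left_join(gc_of_region("utr5") |> rename(gc5 = "gc"), by = "transcript_id") |>
    left_join(gc_of_region("cds") |> rename(gc_cds = "gc"), by = "transcript_id") |>
    left_join(gc_of_region("utr3") |> rename(gc3 = "gc"), by = "transcript_id")

  utr3 <- models |> filter(.data$region == "utr3") |>
    select("transcript_id", "contig", "start", "end", "strand")
  count_on_utr3 <- function(sites) {
    if (is.null(sites)) return(NULL)
    count_overlaps(utr3, sites, strand_aware = strand_aware)
  }
  mi <- count_on_utr3(mirna_sites)
  if (!is.null(mi)) {
    prof <- prof |> left_join(mi |> rename(mirna_sites = "n_sites"),
                              by = "transcript_id") |>
      mutate(mirna_sites = as.integer(dplyr::coalesce(.data$mirna_sites, 0L)))
  }
  rb <- count_on_utr3(rbp_sites)
  if (!is.null(rb)) {
    prof <- prof |> left_join(rb |> rename(rbp_sites = "n_sites"),
                              by = "transcript_id") |>
      mutate(rbp_sites = as.integer(dplyr::coalesce(.data$rbp_sites, 0L)))
  }
  if (detect_top_motif) {
    seqs <- transcript_sequences(models, genome)
    prof <- prof |>
      left_join(tibble(transcript_id = seqs$transcript_id,
                       top_motif = grepl("^C[CT]{4}", seqs$sequence)),
                by = "transcript_id")
  }
  prof
}
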