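# Shared fixtures, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

# Full synthetic alignment dataset plus an edit-calling run over it.
sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    sim <- simulate_alignments(seed = 101)
    models <- load_transcript_models(sim$paths$gtf)
    snps <- load_snp_mask(sim$paths$vcf)
    wl <- load_whitelist(sim$paths$whitelist)
    rc <- read_filter_config(barcode_whitelist = wl)
    sc <- site_filter_config(snp_mask = snps)
    calls <- call_edits(sim$paths$sam, rc, sc, models = models)
    .fixture_env$sim <- list(sim = sim, models = models, snps = snps,
                             wl = wl, rc = rc, sc = sc, calls = calls)
  }
  .fixture_env$sim
}

# Build a single-row reads tibble for unit-level mismatch tests.
make_read <- function(seq, cigar, md, start = 0L, contig = "chr1",
                      strand = "+", barcode = "BC1", mapq = 60L,
                      quals = NULL, read_id = "r1", isoform_id = NA_character_) {
  if (is.null(quals)) quals <- rep(37L, nchar(seq))
  tibble::tibble(read_id = read_id, contig = contig, start = start,
                 strand = strand, mapq = mapq, flag = 0L, cigar = cigar,
                 md = md, seq = seq, quals = list(quals), barcode = barcode,
                 isoform_id = isoform_id, has_umi_rep_tag = TRUE)
}

# Write a small GTF from a tibble of features.
write_mini_gtf <- function(rows, path = tempfile(fileext = ".gtf")) {
  lines <- purrr::pmap_chr(rows, function(contig, type, start, end, strand,
                                          gene_id, transcript_id, ...) {
    paste(contig, "test", type, start + 1L, end, ".", strand, ".",
          sprintf('gene_id "%s"; transcript_id "%s";', gene_id, transcript_id),
          sep = "\t")
  })
  writeLines(lines, path)
  path
}
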