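# Synthetic-data generators.
#
# The alignment generator builds a miniature two-contig genome with six
# genes (one spliced, two on the minus strand), plants C-to-U edits at
# chosen sense-strand cytosines with per-cell-type rates, and writes
# reference FASTA, GTF, VCF SNP mask, barcode whitelist and a
# coordinate-sorted SAM with CB/xf tags and MD/CIGAR consistent with the
# sequences. Decoy sites exercising every rule of the site-filter cascade
# are planted deterministically so each has a known expected fate, and a
# machine-readable truth table accompanies the alignments.

default_gene_layout <- function() {
  tibble(
    gene_id = paste0("g", 1:6),
    transcript_id = paste0("g", 1:6, ".t1"),
    contig = rep(c("chr1", "chr2"), each = 3),
    strand = c("+", "+", "-", "+", "+", "-"),
    exons = list(
      cbind(500L, 1100L),
      cbind(c(2000L, 2350L), c(2250L, 2600L)),
      cbind(4000L, 4600L),
      cbind(500L, 1100L),
      cbind(2000L, 2600L),
      cbind(4000L, 4600L)),
    cds = list(
      cbind(620L, 980L),
      cbind(c(2050L, 2350L), c(2250L, 2500L)),
      cbind(4120L, 4480L),
      cbind(620L, 980L),
      cbind(2120L, 2480L),
      cbind(4120L, 4480L)))
}

# Planted-site layout: offsets are genomic offsets from the first exon
# start. Regular edit sites, one SNP per gene, and one decoy per rule.
default_site_layout <- function(genes) {
  site_rows <- function(gene_id, offs, kind) {
    g <- genes[genes$gene_id == gene_id, ]
    tibble(gene_id = gene_id, contig = g$contig, strand = g$strand,
           pos = g$exons[[1]][1, 1] + offs, kind = kind)
  }
  bind_rows(
    site_rows("g1", c(100L, 180L, 260L, 340L), "edit"),
    site_rows("g1", 150L, "snp"),
    site_rows("g1", 420L, "multi_alt"),
    site_rows("g1", 460L, "lowqual"),
    # g2 is spliced; offsets land inside its first and second exon
    site_rows("g2", c(100L, 180L), "edit"),
    site_rows("g2", 400L, "edit"),     # second exon (2350 + 50)
    site_rows("g2", 150L, "snp"),
    site_rows("g3", c(100L, 180L, 260L, 340L), "edit"),
    site_rows("g3", 150L, "snp"),
    site_rows("g4", c(100L, 180L, 260L, 340L), "edit"),
    site_rows("g4", 150L, "snp"),
    site_rows("g4", 420L, "low_count"),
    site_rows("g4", 460L, "nearend"),
    site_rows("g5", c(100L, 180L, 260L, 340L), "edit"),
    site_rows("g5", 150L, "snp"),
    site_rows("g5", 300L, "antisense"),
    site_rows("g6", c(100L, 180L, 260L, 340L), "edit"),
    site_rows("g6", 150L, "snp"),
    site_rows("g6", 420L, "high_fraction"))
}

# Query offset of a genomic position within a read's M segments, or NA.
query_offset <- function(segs, pos) {
  qoff <- 0L
  for (i in seq_len(nrow(segs))) {
    gstart <- segs[i, 1]
    glen <- segs[i, 2]
    if (pos >= gstart && pos < gstart + glen) return(qoff + pos - gstart)
    qoff <- qoff + glen
  }
  NA_integer_
}

#' Simulate barcoded alignments with planted edits
#'
#' Generates a complete miniature single-cell editing dataset: reference
#' genome, gene annotation, SNP mask, cell-barcode whitelist and a
#' coordinate-sorted SAM file whose reads carry `CB` and `xf:i:25` tags
#' and MD/CIGAR tags consistent with their sequences. C-to-U edits are
#' planted at sense-strand cytosines (genomic G>A on minus-strand genes)
#' with per-cell-type Bernoulli rates, and one deterministic decoy per
#' site-filter rule is planted: a multi-alternate site, an all-cell SNP
#' site, a two-edit site, a 50%-edited site, an antisense site, plus
#' sites visible only through low-quality or read-end bases (which a
#' correct caller must not report). Read-level decoys (unmapped,
#' secondary, missing UMI tag, off-whitelist barcode, low mapping
#' quality, indel and soft-clip CIGARs) are appended.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_cells Number of cells (split between two cell types).
#' @param reads_mu,reads_size Negative-binomial read count per cell-gene.
#' @param edit_rates Named per-type Bernoulli edit rate at regular sites.
#' @param read_len Read length in bases.
#' @param edit_buffer Minimum query distance from read ends at which
#'   edits are planted (matches the default base-level filter).
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return List with file `paths` (fasta, gtf, vcf, whitelist, sam), the
#'   gene layout, `cells` (barcode, type), and `truth`: `sites` (planted
#'   sites with realized counts and expected filter fate), `cell_edits`
#'   (per site and barcode planted passing edits), `coverage` (per site
#'   and barcode ref/alt depths under the default base filters) and
#'   `read_counts` (passing reads per cell and gene).
#' @export
simulate_alignments <- function(out_dir = tempfile("simaln"),
                                n_cells = 24L,
                                reads_mu = 25, reads_size = 50,
                                edit_rates = c(A = 0.04, B = 0.015),
                                read_len = 90L,
                                edit_buffer = 5L,
                                seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contig_len <- c(chr1 = 6000L, chr2 = 6000L)
  genes <- default_gene_layout()

  # reference sequence, then patch planted sites to the needed ref base
  ref <- purrr::map(contig_len, function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c(0.3, 0.2, 0.2, 0.3))
  })
  sites <- default_site_layout(genes)
  # sense-strand C: genomic C on + genes, genomic G on - genes; the
  # antisense decoy carries a minus-strand C>U over a plus-strand gene
  sites <- sites |>
    mutate(ref = if_else(.data$strand == "+", "C", "G"),
           alt = if_else(.data$strand == "+", "T", "A"))
  sites$ref[sites$kind == "antisense"] <- "G"
  sites$alt[sites$kind == "antisense"] <- "A"
  for (i in seq_len(nrow(sites))) {
    ref[[sites$contig[i]]][sites$pos[i] + 1L] <- sites$ref[i]
  }

  cells <- tibble(barcode = sprintf("BC%03d", seq_len(n_cells)),
                  type = rep(names(edit_rates), length.out = n_cells))

  # ---- base reads ---------------------------------------------------
  tx_len <- purrr::map_int(genes$exons, ~ sum(.x[, 2] - .x[, 1]))
  tx_to_segs <- function(exons, s, len) {
    # map transcript interval [s, s+len) onto genomic M segments
    out <- NULL
    off <- 0L
    for (i in seq_len(nrow(exons))) {
      w <- exons[i, 2] - exons[i, 1]
      lo <- max(s, off)
      hi <- min(s + len, off + w)
      if (hi > lo) {
        out <- rbind(out, c(exons[i, 1] + lo - off, hi - lo))
      }
      off <- off + w
    }
    out
  }

  read_rows <- list()
  for (ci in seq_len(n_cells)) {
    for (gi in seq_len(nrow(genes))) {
      n <- rnbinom(1, mu = reads_mu, size = reads_size)
      if (n == 0) next
      starts <- sample.int(tx_len[gi] - read_len + 1L, n, replace = TRUE) - 1L
      for (s in starts) {
        read_rows[[length(read_rows) + 1L]] <- list(
          gene = genes$gene_id[gi],
          contig = genes$contig[gi],
          strand = genes$strand[gi],
          barcode = cells$barcode[ci],
          type = cells$type[ci],
          segs = tx_to_segs(genes$exons[[gi]], s, read_len),
          flag = if (genes$strand[gi] == "-") 16L else 0L,
          mapq = 255L, xf = 25L, in_whitelist = TRUE)
      }
    }
  }

  # antisense decoy reads: minus-strand reads over plus-strand gene g5
  g5 <- genes[genes$gene_id == "g5", ]
  anti_pos <- sites$pos[sites$kind == "antisense"]
  for (j in seq_len(80)) {
    s <- anti_pos - edit_buffer - sample.int(read_len - 2L * edit_buffer, 1L)
    read_rows[[length(read_rows) + 1L]] <- list(
      gene = "g5", contig = "chr2", strand = "-",
      barcode = cells$barcode[1L + (j - 1L) %% n_cells],
      type = cells$type[1L + (j - 1L) %% n_cells],
      segs = cbind(as.integer(s), read_len),
      flag = 16L, mapq = 255L, xf = 25L, in_whitelist = TRUE)
  }

  n_reads <- length(read_rows)
  reads <- tibble(
    idx = seq_len(n_reads),
    gene = purrr::map_chr(read_rows, "gene"),
    contig = purrr::map_chr(read_rows, "contig"),
    strand = purrr::map_chr(read_rows, "strand"),
    barcode = purrr::map_chr(read_rows, "barcode"),
    type = purrr::map_chr(read_rows, "type"),
    flag = purrr::map_int(read_rows, "flag"),
    mapq = purrr::map_int(read_rows, "mapq"),
    segs = purrr::map(read_rows, "segs"))
  reads$start <- purrr::map_int(reads$segs, ~ .x[1, 1])

  # ---- plant mismatches ---------------------------------------------
  # mism: one row per planted alternate base on a read
  mism <- list()
  add_mism <- function(ridx, pos, alt, lowqual = FALSE) {
    mism[[length(mism) + 1L]] <<- tibble(idx = ridx, pos = pos, alt = alt,
                                         lowqual = lowqual)
  }

  site_meta <- vector("list", nrow(sites))
  for (si in seq_len(nrow(sites))) {
    st <- sites[si, ]
    cand <- reads |> filter(.data$contig == st$contig)
    qoffs <- purrr::map_int(cand$segs, query_offset, pos = st$pos)
    covered <- !is.na(qoffs)
    dist <- pmin(qoffs, read_len - 1L - qoffs)
    usable <- covered & dist >= edit_buffer
    nearend_only <- covered & dist < edit_buffer
    u_idx <- cand$idx[which(usable)]
    u_type <- cand$type[which(usable)]
    kind <- st$kind
    chosen <- integer(0)
    if (kind == "edit") {
      # plant only on sense reads so the inferred site strand matches the
      # gene (antisense decoy reads may also cover plus-strand genes)
      sense <- cand$strand[which(usable)] == st$strand
      u_idx <- u_idx[sense]
      u_type <- u_type[sense]
      hit <- runif(length(u_idx)) < edit_rates[u_type]
      chosen <- u_idx[hit]
      for (r in chosen) add_mism(r, st$pos, st$alt)
    } else if (kind == "snp") {
      chosen <- u_idx
      for (r in chosen) add_mism(r, st$pos, st$alt)
    } else if (kind == "multi_alt") {
      chosen <- u_idx
      alts <- rep(c(st$alt, "A"), length.out = length(chosen))
      for (k in seq_along(chosen)) add_mism(chosen[k], st$pos, alts[k])
    } else if (kind == "low_count") {
      chosen <- head(u_idx, 2L)
      for (r in chosen) add_mism(r, st$pos, st$alt)
    } else if (kind == "high_fraction") {
      chosen <- u_idx[seq_along(u_idx) %% 2L == 1L]
      for (r in chosen) add_mism(r, st$pos, st$alt)
    } else if (kind == "antisense") {
      anti <- cand$idx[which(usable & cand$gene == "g5" & cand$strand == "-")]
      chosen <- head(anti, 3L)
      for (r in chosen) add_mism(r, st$pos, st$alt)
    } else if (kind == "lowqual") {
      chosen <- head(u_idx, 4L)
      for (r in chosen) add_mism(r, st$pos, st$alt, lowqual = TRUE)
    } else if (kind == "nearend") {
      ne <- cand$idx[which(nearend_only)]
      chosen <- head(ne, 4L)
      for (r in chosen) add_mism(r, st$pos, st$alt)
    }
    site_meta[[si]] <- list(chosen = chosen)
  }
  mism <- bind_rows(mism)

  # ---- sequences, quals, MD ----------------------------------------
  sam_rows <- character(n_reads)
  for (i in seq_len(n_reads)) {
    r <- reads[i, ]
    segs <- r$segs[[1]]
    refc <- ref[[r$contig]]
    gpos <- unlist(purrr::map(seq_len(nrow(segs)), function(k) {
      segs[k, 1] + seq_len(segs[k, 2]) - 1L
    }))
    bases <- refc[gpos + 1L]
    quals <- rep(37L, length(gpos))
    mm <- mism |> filter(.data$idx == i)
    mmq <- integer(0)
    if (nrow(mm) > 0) {
      at <- match(mm$pos, gpos)
      bases[at] <- mm$alt
      quals[at[mm$lowqual]] <- 11L
      mmq <- sort(at)
    }
    # MD: match-run lengths between substituted positions
    md_parts <- character(0)
    last <- 0L
    for (at in mmq) {
      md_parts <- c(md_parts, as.character(at - last - 1L), refc[gpos[at] + 1L])
      last <- at
    }
    md <- paste0(paste(md_parts, collapse = ""),
                 length(gpos) - last)
    # CIGAR with N gaps between segments
    cig_parts <- character(0)
    for (k in seq_len(nrow(segs))) {
      if (k > 1) {
        gap <- segs[k, 1] - (segs[k - 1, 1] + segs[k - 1, 2])
        cig_parts <- c(cig_parts, paste0(gap, "N"))
      }
      cig_parts <- c(cig_parts, paste0(segs[k, 2], "M"))
    }
    sam_rows[i] <- paste(
      sprintf("r%05d", i), r$flag, r$contig, r$start + 1L, r$mapq,
      paste(cig_parts, collapse = ""), "*", 0L, 0L,
      paste(bases, collapse = ""),
      rawToChar(as.raw(quals + 33L)),
      paste0("CB:Z:", r$barcode), "xf:i:25",
      paste0("MD:Z:", md),
      sep = "\t")
  }

  # ---- decoy reads --------------------------------------------------
  refseg <- function(contig, start, len) {
    paste(ref[[contig]][start + seq_len(len)], collapse = "")
  }
  q <- function(n) strrep("F", n)
  decoys <- c(
    # unmapped
    paste("d_unmapped", 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
          strrep("A", 30), q(30), "CB:Z:BC001", "xf:i:25", sep = "\t"),
    # secondary alignment over g1
    paste("d_secondary", 256L, "chr1", 701L, 255L, "90M", "*", 0L, 0L,
          refseg("chr1", 700L, 90L), q(90), "CB:Z:BC001", "xf:i:25",
          "MD:Z:90", sep = "\t"),
    # missing xf tag
    paste("d_noxf", 0L, "chr1", 1501L, 255L, "90M", "*", 0L, 0L,
          refseg("chr1", 1500L, 90L), q(90), "CB:Z:BC001", "MD:Z:90",
          sep = "\t"),
    # barcode not in whitelist
    paste("d_badbc", 0L, "chr1", 1601L, 255L, "90M", "*", 0L, 0L,
          refseg("chr1", 1600L, 90L), q(90), "CB:Z:ZZZZ", "xf:i:25",
          "MD:Z:90", sep = "\t"),
    # low mapping quality (intergenic)
    paste("d_lowmapq", 0L, "chr1", 1701L, 5L, "90M", "*", 0L, 0L,
          refseg("chr1", 1700L, 90L), q(90), "CB:Z:BC002", "xf:i:25",
          "MD:Z:90", sep = "\t"),
    # insertion (extra bases absent from reference)
    paste("d_ins", 0L, "chr1", 1801L, 255L, "40M2I48M", "*", 0L, 0L,
          paste0(refseg("chr1", 1800L, 40L), "AA", refseg("chr1", 1840L, 48L)),
          q(90), "CB:Z:BC003", "xf:i:25", "MD:Z:88", sep = "\t"),
    # deletion of 3 reference bases
    paste("d_del", 0L, "chr1", 1901L, 255L, "40M3D50M", "*", 0L, 0L,
          paste0(refseg("chr1", 1900L, 40L), refseg("chr1", 1943L, 50L)),
          q(90), "CB:Z:BC004", "xf:i:25",
          paste0("MD:Z:40^", refseg("chr1", 1940L, 3L), "50"), sep = "\t"),
    # soft clips at both ends
    paste("d_softclip", 0L, "chr2", 1501L, 255L, "5S80M5S", "*", 0L, 0L,
          paste0(strrep("A", 5), refseg("chr2", 1500L, 80L), strrep("A", 5)),
          q(90), "CB:Z:BC005", "xf:i:25", "MD:Z:80", sep = "\t"))

  # ---- write files --------------------------------------------------
  paths <- list(
    fasta = file.path(out_dir, "ref.fa"),
    gtf = file.path(out_dir, "genes.gtf"),
    vcf = file.path(out_dir, "snps.vcf"),
    whitelist = file.path(out_dir, "whitelist.txt"),
    sam = file.path(out_dir, "reads.sam"))

  fa <- Biostrings::DNAStringSet(purrr::map_chr(ref, paste, collapse = ""))
  names(fa) <- names(contig_len)
  Biostrings::writeXStringSet(fa, paths$fasta)

  gtf_lines <- character(0)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "protein_coding";',
                      g$gene_id, g$transcript_id)
    ex <- g$exons[[1]]
    cd <- g$cds[[1]]
    span <- c(min(ex[, 1]), max(ex[, 2]))
    gtf_lines <- c(
      gtf_lines,
      paste(g$contig, "sim", "gene", span[1] + 1L, span[2], ".", g$strand,
            ".", attr_g, sep = "\t"),
      paste(g$contig, "sim", "transcript", span[1] + 1L, span[2], ".",
            g$strand, ".", attr_t, sep = "\t"),
      purrr::map_chr(seq_len(nrow(ex)), function(k) {
        paste(g$contig, "sim", "exon", ex[k, 1] + 1L, ex[k, 2], ".",
              g$strand, ".", attr_t, sep = "\t")
      }),
      purrr::map_chr(seq_len(nrow(cd)), function(k) {
        paste(g$contig, "sim", "CDS", cd[k, 1] + 1L, cd[k, 2], ".",
              g$strand, "0", attr_t, sep = "\t")
      }))
  }
  writeLines(gtf_lines, paths$gtf)

  snps <- sites |> filter(.data$kind == "snp")
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    purrr::map_chr(names(contig_len), function(ct) {
      sprintf("##contig=<ID=%s,length=%d>", ct, contig_len[[ct]])
    }),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    purrr::map_chr(seq_len(nrow(snps)), function(k) {
      paste(snps$contig[k], snps$pos[k] + 1L, ".", snps$ref[k], snps$alt[k],
            ".", "PASS", ".", sep = "\t")
    }))
  writeLines(vcf_lines, paths$vcf)
  writeLines(cells$barcode, paths$whitelist)

  ord <- order(reads$contig, reads$start)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              purrr::map_chr(names(contig_len), function(ct) {
                sprintf("@SQ\tSN:%s\tLN:%d", ct, contig_len[[ct]])
              }))
  writeLines(c(header, sam_rows[ord], decoys), paths$sam)

  # ---- truth tables -------------------------------------------------
  truth <- build_truth(reads, mism, sites, site_meta, cells, edit_buffer,
                       read_len)
  list(paths = paths, genes = genes, cells = cells, truth = truth,
       contig_lengths = contig_len)
}

# Realized truth: per-site totals and per-barcode edit/coverage counts
# under the default base-level filters, plus the expected fate of each
# site in the filter cascade.
build_truth <- function(reads, mism, sites, site_meta, cells, edit_buffer,
                        read_len) {
  mism_pass <- mism |> filter(!.data$lowqual)
  mism_key <- paste(mism$idx, mism$pos)

  cov_rows <- list()
  edit_rows <- list()
  site_rows <- list()
  for (si in seq_len(nrow(sites))) {
    st <- sites[si, ]
    cand <- reads |> filter(.data$contig == st$contig)
    qoffs <- purrr::map_int(cand$segs, query_offset, pos = st$pos)
    covered <- which(!is.na(qoffs) &
                       pmin(qoffs, read_len - 1L - qoffs) >= edit_buffer)
    cv <- cand[covered, ]
    key <- paste(cv$idx, st$pos)
    hit <- match(key, mism_key)
    base_alt <- !is.na(hit) & !mism$lowqual[ifelse(is.na(hit), 1L, hit)]
    base_lowq <- !is.na(hit) & mism$lowqual[ifelse(is.na(hit), 1L, hit)]
    is_alt <- base_alt & mism$alt[ifelse(is.na(hit), 1L, hit)] == st$alt
    is_other <- base_alt & !is_alt
    contributes <- !base_lowq          # low-qual bases invisible entirely
    cvt <- tibble(barcode = cv$barcode,
                  ref_n = contributes & is.na(hit),
                  alt_n = contributes & is_alt)
    per_bc <- cvt |>
      group_by(.data$barcode) |>
      summarise(ref_reads = sum(.data$ref_n), alt_reads = sum(.data$alt_n),
                .groups = "drop")
    cov_rows[[si]] <- per_bc |> mutate(contig = st$contig, pos = st$pos)

    ed <- tibble(barcode = cv$barcode[is_alt]) |>
      count(.data$barcode, name = "edit_count")
    edit_rows[[si]] <- ed |> mutate(contig = st$contig, pos = st$pos)

    total_edits <- sum(is_alt)
    total_other <- sum(is_other)
    denom <- sum(per_bc$ref_reads) + sum(per_bc$alt_reads)
    frac <- if (denom > 0) sum(per_bc$alt_reads) / denom else 0
    expected <- switch(
      st$kind,
      multi_alt = "multi_edit_type",
      snp = "snp_mask",
      antisense = "antisense",
      lowqual = "absent",
      nearend = "absent",
      low_count = "min_total_edits",
      high_fraction = if (total_edits < 3) "min_total_edits"
                      else "max_edited_fraction",
      edit = if (total_edits == 0) "absent"
             else if (total_edits < 3) "min_total_edits"
             else if (frac > 0.05) "max_edited_fraction"
             else "kept")
    site_rows[[si]] <- st |>
      mutate(total_edits = total_edits, total_other_alts = total_other,
             edited_fraction = frac, expected = expected)
  }

  passing <- reads   # all generated (non-decoy) reads pass read filters
  read_counts <- passing |>
    count(.data$barcode, .data$gene, name = "reads") |>
    rename(feature = "gene")

  list(sites = bind_rows(site_rows),
       cell_edits = bind_rows(edit_rows) |>
         select("contig", "pos", "barcode", "edit_count"),
       coverage = bind_rows(cov_rows) |>
         select("contig", "pos", "barcode", "ref_reads", "alt_reads"),
       read_counts = read_counts)
}

#' Simulate cell-by-gene edit and read matrices
#'
#' Generates long-form cell-by-gene edit/read tables with a known
#' statistical structure, in one of two modes. In `"stamp"` mode the
#' per-cell mean editing rate follows the editor-expression confound that
#' the normalization regression removes: `log(mean rate + 1) = A x
#' log(editor CPM + 1) + b + e`, with Gaussian noise `e` of standard
#' deviation `sigma`. In `"states"` mode the per-cell rate is drawn from
#' a two-component Gaussian mixture of low and high translational states.
#' Read counts are negative binomial per cell-gene; edit counts are
#' Poisson with mean `reads x rate`.
#'
#' @param n_cells,n_genes Dimensions.
#' @param mode `"stamp"` or `"states"`.
#' @param A,b,sigma Regression slope, intercept and residual standard
#'   deviation (stamp mode).
#' @param x_range Range of `log(editor CPM + 1)` across cells (uniform).
#' @param state_means,state_sds,prop_high Mixture parameters (states
#'   mode): component means and standard deviations of the per-cell rate
#'   and the proportion of high-state cells.
#' @param reads_mu,reads_size Negative-binomial read-count parameters.
#' @param library_size Per-cell total RNA count (for editor CPM).
#' @param seed Integer seed.
#' @return List: `cfm` (tibble `barcode`, `feature`, `edits`, `reads`),
#'   `cells` (per-cell truth: `barcode`, `stamp_counts`, `total_counts`,
#'   `true_rate`, and `state` in states mode).
#' @export
simulate_matrices <- function(n_cells = 2000L, n_genes = 200L,
                              mode = c("stamp", "states"),
                              A = 0.5, b = 0.1, sigma = 0.05,
                              x_range = c(0.3, 2.2),
                              state_means = c(low = 0.4, high = 1.4),
                              state_sds = c(low = 0.1, high = 0.1),
                              prop_high = 0.1,
                              reads_mu = 60, reads_size = 20,
                              library_size = 1000000L,
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(sigma > 0)
  set.seed(derive_seed(seed, 1L))
  barcodes <- sprintf("C%05d", seq_len(n_cells))

  if (mode == "stamp") {
    # integer editor counts; the predictor log1p(CPM) is recomputed from
    # the rounded counts so the planted linear model holds exactly in the
    # realized data
    x_target <- runif(n_cells, x_range[1], x_range[2])
    stamp_counts <- pmax(1L, as.integer(round(expm1(x_target))))
    x <- log1p(stamp_counts / library_size * 1e6)
    rate <- expm1(A * x + b + rnorm(n_cells, 0, sigma))
    rate <- pmax(rate, 1e-4)
    cells <- tibble(barcode = barcodes, stamp_counts = stamp_counts,
                    total_counts = as.integer(library_size),
                    true_rate = rate)
  } else {
    state <- if_else(runif(n_cells) < prop_high, "high", "low")
    rate <- rnorm(n_cells, state_means[state], state_sds[state])
    rate <- pmax(rate, 1e-4)
    cells <- tibble(barcode = barcodes, stamp_counts = 0L,
                    total_counts = 1000L, true_rate = rate, state = state)
  }

  reads <- matrix(rnbinom(n_cells * n_genes, mu = reads_mu, size = reads_size),
                  n_cells, n_genes)
  edits <- matrix(rpois(n_cells * n_genes, lambda = reads * cells$true_rate),
                  n_cells, n_genes)
  cfm <- tibble(
    barcode = rep(barcodes, times = n_genes),
    feature = rep(sprintf("gene%04d", seq_len(n_genes)), each = n_cells),
    edits = as.integer(edits),
    reads = as.integer(reads))
  list(cfm = cfm, cells = cells)
}

#' Simulate per-replicate pseudobulk values for differential testing
#'
#' Draws feature-level per-replicate values for two groups: null features
#' share one mean; shifted features differ by `shift` standard deviations
#' in the second group. Used to study the calibration and power of the
#' bootstrap differential test.
#'
#' @param n_features Number of features.
#' @param n_replicates Replicates per group.
#' @param groups Names of the two groups.
#' @param base_mean,base_sd Feature mean and within-group standard
#'   deviation.
#' @param n_shifted Number of shifted features (placed first).
#' @param shift Shift size in units of `base_sd`.
#' @param seed Integer seed.
#' @return List: `values` (tibble `feature`, `group`, `value`) and
#'   `truth` (tibble `feature`, `shifted`).
#' @export
simulate_replicate_values <- function(n_features = 2000L, n_replicates = 3L,
                                      groups = c("CA3", "CA1"),
                                      base_mean = 0.05, base_sd = 0.005,
                                      n_shifted = 0L, shift = 10,
                                      seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  feats <- sprintf("f%05d", seq_len(n_features))
  shifted <- seq_len(n_features) <= n_shifted
  grid <- tidyr::expand_grid(feature = feats, group = groups,
                             replicate = seq_len(n_replicates))
  grid$value <- rnorm(nrow(grid), base_mean, base_sd) +
    if_else(grid$feature %in% feats[shifted] & grid$group == groups[2],
            shift * base_sd, 0)
  list(values = grid |> select("feature", "group", "value"),
       truth = tibble(feature = feats, shifted = shifted))
}

#' Simulate an isoform-level EditsC dataset
#'
#' Generates cell-level isoform edit/read tables for two cell types with
#' replicate structure, known cytosine content per isoform, and planted
#' discordant genes: in a discordant gene one isoform is translated more
#' in the first cell type and a second isoform more in the second, with
#' all remaining genes null. Effect sizes default to a four-fold EditsC
#' difference.
#'
#' @param n_genes Genes, two isoforms each.
#' @param n_discordant Discordant genes (placed first).
#' @param groups The two cell types.
#' @param n_replicates Samples per cell type.
#' @param cells_per_sample Cells per (cell type, sample).
#' @param base_rates Range of null per-isoform EditsC rates (uniform).
#' @param high_rate,low_rate Discordant isoform rates in favoured and
#'   disfavoured cell type.
#' @param reads_mu,reads_size Negative-binomial per cell-isoform reads.
#' @param c_count_range Range of per-isoform cytosine counts.
#' @param seed Integer seed.
#' @return List: `cfm` (barcode, feature, edits, reads), `cells`
#'   (barcode, group, sample), `gene_map` (feature, gene), `c_content`
#'   (feature, c_count), `truth` (gene, discordant flag and favoured
#'   directions).
#' @export
simulate_isoform_dataset <- function(n_genes = 12L, n_discordant = 4L,
                                     groups = c("Oligod", "Astro"),
                                     n_replicates = 3L,
                                     cells_per_sample = 30L,
                                     base_rates = c(0.001, 0.004),
                                     high_rate = 0.004, low_rate = 0.001,
                                     reads_mu = 10, reads_size = 20,
                                     c_count_range = c(150L, 300L),
                                     seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  genes <- sprintf("G%03d", seq_len(n_genes))
  iso <- tibble(
    gene = rep(genes, each = 2L),
    feature = paste0(rep(genes, each = 2L), "-", rep(1:2, n_genes)),
    iso_idx = rep(1:2, n_genes))
  iso$c_count <- sample(seq(c_count_range[1], c_count_range[2]),
                        nrow(iso), replace = TRUE)
  discordant <- genes[seq_len(n_discordant)]
  base <- runif(nrow(iso), base_rates[1], base_rates[2])
  # per-isoform rate per group
  rate_g1 <- base
  rate_g2 <- base
  d1 <- iso$gene %in% discordant & iso$iso_idx == 1L
  d2 <- iso$gene %in% discordant & iso$iso_idx == 2L
  rate_g1[d1] <- high_rate; rate_g2[d1] <- low_rate
  rate_g1[d2] <- low_rate;  rate_g2[d2] <- high_rate

  cells <- tidyr::expand_grid(group = groups, sample = seq_len(n_replicates),
                              cell = seq_len(cells_per_sample)) |>
    mutate(barcode = sprintf("%s_s%d_c%03d", .data$group, .data$sample,
                             .data$cell)) |>
    select("barcode", "group", "sample")

  n_iso <- nrow(iso)
  rows <- purrr::map(seq_len(nrow(cells)), function(ci) {
    rate <- if (cells$group[ci] == groups[1]) rate_g1 else rate_g2
    reads <- rnbinom(n_iso, mu = reads_mu, size = reads_size)
    edits <- rpois(n_iso, lambda = reads * iso$c_count * rate)
    tibble(barcode = cells$barcode[ci], feature = iso$feature,
           edits = edits, reads = reads)
  })
  cfm <- bind_rows(rows)
  list(cfm = cfm, cells = cells,
       gene_map = iso |> select("feature", "gene"),
       c_content = iso |> select("feature", "c_count"),
       truth = tibble(gene = genes, discordant = genes %in% discordant))
}
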