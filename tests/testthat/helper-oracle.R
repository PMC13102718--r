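# Brute-force pileup oracle, independent of the package's MD-based path:
# parses the SAM text directly and compares every aligned base to the
# reference FASTA.

oracle_pileup <- function(sam_path, fasta_path, whitelist = NULL,
                          min_base_qual = 20L, min_dist = 5L,
                          min_mapq = 0L) {
  fa <- readLines(fasta_path)
  heads <- grep("^>", fa)
  genome <- list()
  for (i in seq_along(heads)) {
    nm <- sub("^>(\\S+).*", "\\1", fa[heads[i]])
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(fa)
    genome[[nm]] <- strsplit(paste(fa[(heads[i] + 1):to], collapse = ""),
                             "")[[1]]
  }

  body <- readLines(sam_path)
  body <- body[!grepl("^@", body)]
  mism <- list()
  bases <- list()
  for (line in body) {
    f <- strsplit(line, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L + 256L + 512L + 2048L) > 0) next
    mapq <- as.integer(f[5])
    if (mapq < min_mapq) next
    tags <- f[-(1:11)]
    if (!"xf:i:25" %in% tags) next
    cb <- sub("^CB:Z:", "", grep("^CB:Z:", tags, value = TRUE))
    if (length(cb) == 0) next
    if (!is.null(whitelist) && !cb %in% whitelist) next
    contig <- f[3]
    pos <- as.integer(f[4]) - 1L
    seq <- strsplit(f[10], "")[[1]]
    qual <- utf8ToInt(f[11]) - 33L
    strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
    ops <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    q <- 0L
    r <- pos
    qlen <- length(seq)
    for (op in ops) {
      n <- as.integer(sub(".$", "", op))
      o <- sub("^\\d+", "", op)
      if (o %in% c("M", "=", "X")) {
        k <- seq_len(n)
        rb <- genome[[contig]][r + k]
        qb <- seq[q + k]
        qp <- q + k - 1L
        d <- pmin(qp, qlen - 1L - qp)
        ok <- qb != "N" & rb != "N" & qual[q + k] >= min_base_qual &
          d >= min_dist
        if (any(ok)) {
          bases[[length(bases) + 1]] <-
            data.frame(contig = contig, pos = (r + k - 1L)[ok],
                       barcode = cb, base = qb[ok], stringsAsFactors = FALSE)
          mm <- ok & qb != rb
          if (any(mm)) {
            mism[[length(mism) + 1]] <-
              data.frame(contig = contig, pos = (r + k - 1L)[mm],
                         ref = rb[mm], alt = qb[mm], barcode = cb,
                         strand = strand, stringsAsFactors = FALSE)
          }
        }
        q <- q + n
        r <- r + n
      } else if (o %in% c("I", "S")) {
        q <- q + n
      } else if (o %in% c("D", "N")) {
        r <- r + n
      }
    }
  }
  list(mismatches = dplyr::as_tibble(dplyr::bind_rows(mism)),
       bases = dplyr::as_tibble(dplyr::bind_rows(bases)))
}
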