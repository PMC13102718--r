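# CIGAR and MD walkers.
#
# Mismatch positions are reconstructed from the MD tag combined with the
# CIGAR string, without touching the reference genome: the MD tag records
# the reference base at every substituted or deleted position, and the
# CIGAR places each query base on the reference. All coordinates produced
# here are 0-based.

# Split a CIGAR string into parallel vectors of op lengths and op codes.
cigar_tokens <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1L) stop_input("malformed CIGAR string: '%s'", cigar)
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
       op  = sub("^\\d+", "", tok))
}

# Query length implied by the CIGAR (ops that consume the query).
cigar_query_length <- function(cigar) {
  tk <- cigar_tokens(cigar)
  sum(tk$len[tk$op %in% c("M", "I", "S", "=", "X")])
}

# Tokenise an MD tag into match runs, substituted reference bases and
# deletion runs.
md_tokens <- function(md) {
  tok <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (length(tok) == 0 || paste(tok, collapse = "") != md) {
    stop_input("malformed MD tag: '%s'", md)
  }
  tok
}

# One row per query base aligned to the reference (M/=/X ops only), for a
# single read. Soft clips and insertions consume query but produce no rows;
# deletions and reference skips consume reference only.
#   qpos: 0-based offset into the stored read sequence
#   refpos: 0-based reference position
aligned_pairs <- function(cigar, start) {
  tk <- cigar_tokens(cigar)
  qpos <- integer(0)
  refpos <- integer(0)
  q <- 0L
  r <- start
  for (i in seq_along(tk$op)) {
    len <- tk$len[i]
    op <- tk$op[i]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, q + seq_len(len) - 1L)
      refpos <- c(refpos, r + seq_len(len) - 1L)
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    }
  }
  list(qpos = qpos, refpos = refpos)
}

# Reconstruct substitutions for one read from (CIGAR, MD, seq).
#
# The MD tag runs over reference-consuming aligned positions: M-op matches
# are counted in its integer runs, substitutions appear as bare reference
# bases, and deleted reference bases follow '^'. N (reference skip) ops are
# absent from MD, so the walk is performed in "MD space": the ordered M-op
# positions of the alignment.
#
# Returns a data.frame with columns qpos, refpos, ref_base (possibly empty),
# or NULL if MD and CIGAR are inconsistent.
md_substitutions <- function(cigar, md, seq, start) {
  ap <- aligned_pairs(cigar, start)
  n_m <- length(ap$qpos)
  tk <- tryCatch(md_tokens(md), error = function(e) NULL)
  if (is.null(tk)) return(NULL)

  idx <- 1L          # next MD-space M position (1-based into ap)
  out_q <- integer(0)
  out_r <- integer(0)
  out_b <- character(0)
  for (t in tk) {
    if (grepl("^\\d+$", t)) {
      idx <- idx + as.integer(t)
    } else if (startsWith(t, "^")) {
      # deleted reference bases: consume no M positions
      next
    } else {
      if (idx > n_m) return(NULL)
      out_q <- c(out_q, ap$qpos[idx])
      out_r <- c(out_r, ap$refpos[idx])
      out_b <- c(out_b, t)
      idx <- idx + 1L
    }
  }
  if (idx != n_m + 1L) return(NULL)  # MD length disagrees with CIGAR M count
  data.frame(qpos = out_q, refpos = out_r, ref_base = out_b,
             stringsAsFactors = FALSE)
}
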